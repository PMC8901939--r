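#' Kruskal-Wallis test with degenerate-input conventions
#'
#' Rank-based k-sample test (tie-corrected H, p from the chi-square upper
#' tail with `k - 1` df) as used for batch-dependence screening. Input with
#' all values tied returns `H = 0, p = 1`; a single group is an error. An
#' exact permutation p-value (enumeration of all group-label permutations)
#' is available for validation at small n.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each with >= 1 value).
#' @param p_method `"chisq"` (default) or `"exact"` (feasible for
#'   `length(values) <= 10`).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' kw_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kw_test <- function(values, groups, p_method = c("chisq", "exact")) {
  p_method <- match.arg(p_method)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) abort("Kruskal-Wallis needs >= 2 groups")
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(statistic = 0, df = k - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  h <- unname(kt$statistic)
  p <- if (p_method == "chisq") {
    unname(kt$p.value)
  } else {
    kw_exact_p(values, groups, h)
  }
  tibble::tibble(statistic = h, df = k - 1L, p_value = p)
}

# tie-corrected H for a rank vector and group index matrix-free
kw_h <- function(ranks, groups, tie_correction) {
  n <- length(ranks)
  rs <- tapply(ranks, groups, sum)
  ns <- tabulate(groups)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  h / tie_correction
}

# exact permutation p-value: enumerate all assignments of the observed
# values to the group-size pattern
kw_exact_p <- function(values, groups, h_obs) {
  n <- length(values)
  if (n > 10L) abort("exact permutation p-value limited to n <= 10")
  ranks <- rank(values)
  ties <- table(ranks)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  gi <- as.integer(groups)
  perms <- permutations_of(n)
  hs <- apply(perms, 1L, function(p) kw_h(ranks[p], gi, tie_corr))
  mean(hs >= h_obs - 1e-12)
}

# all permutations of 1..n (n small), recursive
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Batch-dependence assessment of a feature table
#'
#' Runs a Kruskal-Wallis test per feature across the levels of a grouping
#' variable (batch label or a single acquisition parameter), flags features
#' with `p < alpha`, and reports the significant fraction. Features are
#' tested independently; no multiplicity correction is applied by default
#' (set `adjust = "BH"` for Benjamini-Hochberg-adjusted flags).
#' Zero-variance features are counted as non-significant and flagged.
#'
#' @param table Feature table containing the grouping column (for batch
#'   labels, pipe through [with_batches()] first).
#' @param grouping Name of the grouping column.
#' @param features Optional feature column names.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param stage Optional label (e.g. `"pre"`, `"post_combat"`) echoed in
#'   the output.
#' @return An object of class `radh_assessment`: a tibble with one row per
#'   feature (`feature`, `statistic`, `df`, `p_value`, `significant`,
#'   `zero_variance`) and attributes `grouping`, `alpha`, `stage`,
#'   `n_significant`, `fraction_significant`.
#' @export
significance_rate <- function(table, grouping, features = NULL, alpha = 0.05,
                              adjust = c("none", "BH"), stage = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(grouping %in% names(table))
  feats <- feature_columns(table, features)
  groups <- table[[grouping]]
  if (dplyr::n_distinct(groups[!is.na(groups)]) < 2L) {
    abort(paste0("grouping `", grouping, "` has fewer than 2 observed levels"))
  }
  small <- any(table(groups) < 5L)
  if (small) {
    inform("some groups have n < 5; chi-square p-values are asymptotic")
  }
  rows <- purrr::map_dfr(feats, function(f) {
    v <- table[[f]]
    zv <- length(unique(v[!is.na(v)])) == 1L
    kt <- kw_test(v, groups)
    dplyr::mutate(kt, feature = f, zero_variance = zv, .before = 1L)
  })
  pv <- if (adjust == "BH") stats::p.adjust(rows$p_value, "BH") else rows$p_value
  rows$significant <- pv < alpha & !rows$zero_variance
  out <- structure(rows, class = c("radh_assessment", class(rows)))
  attr(out, "grouping") <- grouping
  attr(out, "alpha") <- alpha
  attr(out, "stage") <- stage %||% ""
  attr(out, "n_significant") <- sum(rows$significant)
  attr(out, "fraction_significant") <- mean(rows$significant)
  out
}

#' @export
print.radh_assessment <- function(x, ...) {
  cat("<assessment> grouping ", attr(x, "grouping"),
      if (nzchar(attr(x, "stage"))) paste0(" [", attr(x, "stage"), "]"),
      ": ", attr(x, "n_significant"), "/", nrow(x),
      " features significant (",
      round(100 * attr(x, "fraction_significant"), 1), "%) at alpha ",
      attr(x, "alpha"), "\n", sep = "")
  NextMethod()
}

#' Tidy / summarize an assessment
#'
#' @param x A `radh_assessment`.
#' @param ... Unused.
#' @return `tidy()`: the per-feature tibble; `glance()`: one row with
#'   grouping, stage, counts and the significant fraction.
#' @export
tidy.radh_assessment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.radh_assessment
#' @export
glance.radh_assessment <- function(x, ...) {
  tibble::tibble(
    grouping = attr(x, "grouping"),
    stage = attr(x, "stage"),
    alpha = attr(x, "alpha"),
    n_features = nrow(x),
    n_significant = attr(x, "n_significant"),
    fraction_significant = attr(x, "fraction_significant")
  )
}

#' Compare batch dependence before and after harmonization
#'
#' Tabulates per-grouping significant-feature counts pre vs post. Inputs
#' are single assessments or (named) lists of assessments over several
#' grouping variables (batch plus single acquisition parameters); feature
#' sets must match.
#'
#' @param pre,post A `radh_assessment` or list of them.
#' @return A list with `summary` (tibble: grouping, n_features,
#'   n_significant_pre, n_significant_post, fraction_pre, fraction_post)
#'   and `detail` (per feature x grouping tibble with pre/post p-values).
#' @export
compare_pre_post <- function(pre, post) {
  as_list <- function(x) {
    if (inherits(x, "radh_assessment")) {
      setNames(list(x), attr(x, "grouping"))
    } else x
  }
  pre <- as_list(pre)
  post <- as_list(post)
  if (!identical(names(pre), names(post))) {
    abort("pre and post assessments cover different groupings")
  }
  detail <- purrr::map_dfr(names(pre), function(gp) {
    a <- pre[[gp]]
    b <- post[[gp]]
    if (!identical(sort(a$feature), sort(b$feature))) {
      abort(paste0("feature sets differ for grouping ", gp))
    }
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(a), "feature",
                    p_value_pre = "p_value", significant_pre = "significant"),
      dplyr::select(tibble::as_tibble(b), "feature",
                    p_value_post = "p_value", significant_post = "significant"),
      by = "feature"
    ) |>
      dplyr::mutate(grouping = gp, .before = 1L)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(detail, .data$grouping),
    n_features = dplyr::n(),
    n_significant_pre = sum(.data$significant_pre),
    n_significant_post = sum(.data$significant_post),
    fraction_pre = mean(.data$significant_pre),
    fraction_post = mean(.data$significant_post),
    .groups = "drop"
  )
  list(summary = summary, detail = detail)
}

#' Export tidy box-plot data for one feature
#'
#' Long-format data sufficient to regenerate per-group box plots: one row
#' per observation with the group label and value, plus the group's
#' quartiles and Tukey whiskers repeated on each row.
#'
#' @param table Feature table containing the grouping column.
#' @param feature Feature column name.
#' @param grouping Grouping column name.
#' @return A tibble with columns `group`, `value`, `q1`, `median`, `q3`,
#'   `whisker_lo`, `whisker_hi`.
#' @export
export_boxplot_data <- function(table, feature, grouping) {
  stopifnot(feature %in% names(table), grouping %in% names(table))
  dat <- tibble::tibble(group = table[[grouping]], value = table[[feature]])
  dat <- dat[!is.na(dat$group), ]
  stats <- dplyr::summarise(
    dplyr::group_by(dat, .data$group),
    q1 = quantile(.data$value, 0.25, names = FALSE),
    median = median(.data$value),
    q3 = quantile(.data$value, 0.75, names = FALSE),
    .groups = "drop"
  )
  stats$iqr <- stats$q3 - stats$q1
  joined <- dplyr::left_join(dat, stats, by = "group")
  joined$whisker_lo <- pmax(joined$q1 - 1.5 * joined$iqr,
                            ave_min(joined$value, joined$group))
  joined$whisker_hi <- pmin(joined$q3 + 1.5 * joined$iqr,
                            ave_max(joined$value, joined$group))
  dplyr::select(joined, "group", "value", "q1", "median", "q3",
                "whisker_lo", "whisker_hi")
}

ave_min <- function(x, g) stats::ave(x, g, FUN = min)
ave_max <- function(x, g) stats::ave(x, g, FUN = max)
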