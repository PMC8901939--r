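#' Assign harmonization batches from acquisition keys
#'
#' Every distinct observed combination of the key parameters (default:
#' convolution kernel and kVp) becomes one batch. Combinations are sorted
#' lexicographically (kernel alphabetically, then kVp ascending) and
#' numbered 1..K; a user-supplied `numbering` tibble (key columns plus
#' `batch_id`) can impose any other labeling, e.g. to reproduce a published
#' protocol table. Observations with a missing key value are excluded and
#' logged.
#'
#' @param table Feature table with the key columns and `obs_id`.
#' @param keys Character vector of key column names.
#' @param numbering Optional tibble mapping key combinations to `batch_id`.
#' @return An object of class `batch_assignment`: list with `observations`
#'   (tibble `obs_id`, `batch_id`), `batches` (tibble `batch_id`, keys,
#'   `frequency`), `keys`, and `excluded` (tibble of dropped observations).
#' @export
assign_batches <- function(table, keys = c("kernel", "kvp"), numbering = NULL) {
  stopifnot(is.data.frame(table), all(keys %in% names(table)),
            "obs_id" %in% names(table))
  ok <- complete.cases(table[keys])
  excluded <- tibble::tibble(obs_id = table$obs_id[!ok],
                             reason = "missing batch key")
  if (nrow(excluded) > 0) {
    inform(paste0(nrow(excluded), " observation(s) excluded: missing batch key"))
  }
  tab <- table[ok, , drop = FALSE]
  combos <- dplyr::distinct(tab[keys])
  combos <- dplyr::arrange(combos, !!!rlang::syms(keys))
  if (is.null(numbering)) {
    combos$batch_id <- seq_len(nrow(combos))
  } else {
    combos <- dplyr::left_join(combos, numbering, by = keys)
    if (any(is.na(combos$batch_id)) || anyDuplicated(combos$batch_id)) {
      abort("`numbering` must map every observed key combination to a unique batch_id")
    }
  }
  obs <- dplyr::left_join(tab[c("obs_id", keys)], combos, by = keys)
  freq <- dplyr::count(obs, .data$batch_id, name = "frequency")
  batches <- dplyr::arrange(dplyr::left_join(combos, freq, by = "batch_id"),
                            .data$batch_id)
  structure(list(observations = tibble::as_tibble(obs[c("obs_id", "batch_id")]),
                 batches = tibble::as_tibble(batches[c("batch_id", keys, "frequency")]),
                 keys = keys, excluded = excluded),
            class = "batch_assignment")
}

#' @export
print.batch_assignment <- function(x, ...) {
  cat("<batch_assignment> ", nrow(x$batches), " batches over keys (",
      paste(x$keys, collapse = ", "), "), ", nrow(x$observations),
      " observations\n", sep = "")
  print(x$batches)
  invisible(x)
}

#' Join batch labels onto a feature table
#'
#' @param table Feature table with `obs_id`.
#' @param assignment A [assign_batches()] result.
#' @return `table` restricted to assigned observations, with a `batch_id`
#'   column.
#' @export
with_batches <- function(table, assignment) {
  stopifnot(inherits(assignment, "batch_assignment"))
  dplyr::inner_join(table, assignment$observations, by = "obs_id")
}

#' Drop batches below a minimum frequency
#'
#' ComBat needs at least two observations per batch to estimate a scale
#' effect, so batches with `frequency < min_n` are removed together with
#' their observations; every dropped batch is logged.
#'
#' @param table Feature table.
#' @param assignment A [assign_batches()] result.
#' @param min_n Minimum batch frequency (default 2).
#' @return List with filtered `table`, updated `assignment` and an
#'   `exclusions` tibble naming each dropped batch.
#' @export
filter_min_frequency <- function(table, assignment, min_n = 2L) {
  stopifnot(inherits(assignment, "batch_assignment"))
  drop <- assignment$batches$batch_id[assignment$batches$frequency < min_n]
  keep <- setdiff(assignment$batches$batch_id, drop)
  if (length(keep) == 0L) abort("no batch satisfies minimum frequency")
  exclusions <- dplyr::filter(assignment$batches, .data$batch_id %in% drop)
  obs <- dplyr::filter(assignment$observations, .data$batch_id %in% keep)
  out_asg <- assignment
  out_asg$observations <- obs
  out_asg$batches <- dplyr::filter(assignment$batches, .data$batch_id %in% keep)
  out_table <- dplyr::filter(table, .data$obs_id %in% obs$obs_id)
  if (nrow(exclusions) > 0) {
    inform(paste0("dropped batch(es) below frequency ", min_n, ": ",
                  paste(exclusions$batch_id, collapse = ", ")))
  }
  list(table = out_table, assignment = out_asg, exclusions = exclusions)
}

#' Longitudinal eligibility filter
#'
#' Longitudinal harmonization needs at least two timepoints per subject and
#' at least one observation per batch. Subjects with fewer than two distinct
#' timepoints are removed iteratively, then batches left without
#' observations are dropped, until stable.
#'
#' @param table Feature table.
#' @param assignment A [assign_batches()] result.
#' @param subject,time Column names for subject and timepoint.
#' @return List with filtered `table`, updated `assignment`,
#'   `removed_subjects` and `removed_batches`.
#' @export
filter_longitudinal <- function(table, assignment,
                                subject = "patient_id", time = "timepoint") {
  stopifnot(inherits(assignment, "batch_assignment"),
            all(c(subject, time, "obs_id") %in% names(table)))
  tab <- with_batches(table, assignment)
  removed_subjects <- character(0)
  repeat {
    counts <- dplyr::summarise(
      dplyr::group_by(tab, .data[[subject]]),
      n_tp = dplyr::n_distinct(.data[[time]]), .groups = "drop")
    bad <- counts[[subject]][counts$n_tp < 2L]
    if (length(bad) == 0L) break
    removed_subjects <- c(removed_subjects, bad)
    tab <- dplyr::filter(tab, !(.data[[subject]] %in% bad))
  }
  if (nrow(tab) == 0L) abort("no subjects remain after longitudinal filtering")
  present <- unique(tab$batch_id)
  removed_batches <- setdiff(assignment$batches$batch_id, present)
  out_asg <- assignment
  out_asg$batches <- dplyr::filter(assignment$batches,
                                   .data$batch_id %in% present)
  out_asg$observations <- dplyr::filter(assignment$observations,
                                        .data$obs_id %in% tab$obs_id)
  list(table = dplyr::filter(table, .data$obs_id %in% tab$obs_id),
       assignment = out_asg,
       removed_subjects = removed_subjects,
       removed_batches = removed_batches)
}

# Cramér's V between two categorical vectors (complete pairs)
cramers_v <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  tab <- table(a[ok], b[ok])
  if (min(dim(tab)) < 2L) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  unname(sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1L))))
}

#' Screen acquisition parameters for influence on features
#'
#' For each candidate parameter, counts how many features differ
#' significantly across its observed levels (Kruskal-Wallis, `p < alpha`),
#' then applies the exclusion rules in order: (1) a-priori exclusions
#' (default: tube current, which modern scanners modulate per-region);
#' (2) missingness above `missing_threshold`; (3) redundancy - of a pair
#' with Cramér's V above `assoc_threshold`, the parameter with fewer
#' significant features is dropped; (4) parameters with zero significant
#' features. Parameters with a single observed level are excluded with a
#' logged reason rather than an error.
#'
#' @param table Feature table.
#' @param params Character vector of parameter column names to screen.
#' @param alpha Significance level (default 0.05).
#' @param features Optional feature column names.
#' @param a_priori_exclude Parameters excluded before testing.
#' @param missing_threshold Maximum tolerated fraction of missing values.
#' @param assoc_threshold Cramér's V above which a pair is redundant.
#' @return A list with `report` (tibble: parameter, n_levels, missing_frac,
#'   n_significant, decision, reason) and `retained` (character vector).
#' @export
screen_parameters <- function(table, params, alpha = 0.05, features = NULL,
                              a_priori_exclude = "tube_current_ma",
                              missing_threshold = 0.5,
                              assoc_threshold = 0.8) {
  stopifnot(is.data.frame(table), all(params %in% names(table)))
  feats <- feature_columns(table, features)
  info <- purrr::map_dfr(params, function(p) {
    x <- table[[p]]
    miss <- mean(is.na(x))
    lev <- unique(x[!is.na(x)])
    n_sig <- NA_integer_
    if (length(lev) >= 2L) {
      pv <- vapply(feats, function(f) {
        ok <- !is.na(x)
        kw_test(table[[f]][ok], x[ok])$p_value
      }, numeric(1))
      n_sig <- sum(pv < alpha, na.rm = TRUE)
    }
    tibble::tibble(parameter = p, n_levels = length(lev),
                   missing_frac = miss, n_significant = n_sig)
  })
  decision <- rep("retained", nrow(info))
  reason <- rep("", nrow(info))
  mark <- function(i, why) {
    decision[i] <<- "excluded"
    reason[i] <<- why
  }
  for (i in seq_len(nrow(info))) {
    p <- info$parameter[i]
    if (p %in% a_priori_exclude) {
      mark(i, "a-priori exclusion")
    } else if (info$missing_frac[i] > missing_threshold) {
      mark(i, sprintf("missingness %.0f%% above threshold",
                      100 * info$missing_frac[i]))
    } else if (info$n_levels[i] < 2L) {
      mark(i, "single observed level")
    }
  }
  # redundancy among survivors: drop the member with fewer significant
  # features of each strongly associated pair
  repeat {
    alive <- which(decision == "retained")
    if (length(alive) < 2L) break
    pairs <- utils::combn(alive, 2L)
    vs <- apply(pairs, 2L, function(ij) {
      cramers_v(table[[info$parameter[ij[1]]]], table[[info$parameter[ij[2]]]])
    })
    top <- which.max(vs)
    if (vs[top] <= assoc_threshold) break
    ij <- pairs[, top]
    loser <- if (info$n_significant[ij[1]] < info$n_significant[ij[2]]) {
      ij[1]
    } else if (info$n_significant[ij[1]] > info$n_significant[ij[2]]) {
      ij[2]
    } else ij[2]
    winner <- setdiff(ij, loser)
    mark(loser, sprintf("redundant with %s (Cramer's V %.2f)",
                        info$parameter[winner], vs[top]))
  }
  for (i in which(decision == "retained")) {
    if (!is.na(info$n_significant[i]) && info$n_significant[i] == 0L) {
      mark(i, "no significant features")
    }
  }
  report <- dplyr::bind_cols(info, tibble::tibble(decision = decision,
                                                  reason = reason))
  list(report = report, retained = report$parameter[decision == "retained"])
}
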