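#' Specify per-batch injected effects
#'
#' Builds the per-batch effect specification used by the synthetic feature
#' generator. Effects are expressed on the standardized scale of the
#' location/scale (L/S) batch model: `gamma` is an additive shift in units of
#' the feature standard deviation and `delta2` multiplies the residual
#' variance, so ground-truth values are directly comparable to ComBat
#' estimates.
#'
#' @param batch_id Integer batch labels (unique, >= 1).
#' @param gamma Additive standardized location shift per batch.
#' @param delta2 Multiplicative residual-variance factor per batch (> 0).
#' @param n_lesions Number of lesion observations per batch (>= 1).
#' @param kernel,kvp Optional acquisition labels attached to each batch;
#'   defaults generate synthetic kernel names and a 120 kVp setting.
#' @return A tibble with one row per batch.
#' @export
batch_effects <- function(batch_id, gamma, delta2, n_lesions,
                          kernel = NULL, kvp = NULL) {
  n <- length(batch_id)
  if (anyDuplicated(batch_id)) abort("`batch_id` values must be unique")
  if (any(batch_id < 1)) abort("`batch_id` must be >= 1")
  gamma <- rep_len(gamma, n)
  delta2 <- rep_len(delta2, n)
  n_lesions <- rep_len(as.integer(n_lesions), n)
  if (any(!is.finite(delta2)) || any(delta2 <= 0)) {
    abort("`delta2` must be positive and finite")
  }
  if (any(n_lesions < 1L)) abort("`n_lesions` must be >= 1")
  tibble::tibble(
    batch_id = as.integer(batch_id),
    gamma = gamma,
    delta2 = delta2,
    n_lesions = n_lesions,
    kernel = if (is.null(kernel)) sprintf("K%02d", seq_len(n)) else rep_len(kernel, n),
    kvp = if (is.null(kvp)) rep(120, n) else rep_len(kvp, n)
  )
}

#' Default batch design: the reference 14-protocol profile
#'
#' The 14 (kernel, kVp) protocols that survive the frequency >= 2 filter of
#' [ct_protocol_profile()], with injected standardized location shifts of
#' order 1 (evenly spaced in \[-1.5, 1.5\]) and variance scale factors
#' log-spaced in \[0.5, 2\].
#'
#' @return A tibble as produced by [batch_effects()].
#' @export
default_batches <- function() {
  prof <- dplyr::filter(ct_protocol_profile(), .data$frequency >= 2)
  k <- nrow(prof)
  batch_effects(
    batch_id = seq_len(k),
    gamma = seq(-1.5, 1.5, length.out = k),
    delta2 = exp(seq(log(0.5), log(2), length.out = k))[order(seq_len(k) %% 3)],
    n_lesions = prof$frequency,
    kernel = prof$kernel,
    kvp = prof$kvp
  )
}

#' Synthetic study design
#'
#' Collects every knob of the synthetic feature-table generator. Feature
#' values follow the L/S batch model
#' \deqn{Y_{ijg} = \alpha_g + \sigma_g (\gamma_{ig} + \sqrt{\delta^2_{ig}}\,
#'   \varepsilon_{ijg})}
#' with per-feature batch effects drawn around the batch-level values of
#' `batches` (`gamma_sd`, `delta2_sdlog` control the across-feature spread,
#' the structure empirical-Bayes shrinkage assumes). In longitudinal mode a
#' subject random intercept (raw feature units, SD `subject_sd`) and a
#' baseline-to-follow-up shift of `time_effect` feature SDs are added.
#'
#' @param n_features Number of features (default 42; when 42 the registry
#'   names are used as column names, otherwise `F001`, ...).
#' @param batches Per-batch effect tibble from [batch_effects()].
#' @param feature_means,feature_sds Optional per-feature grand means and SDs;
#'   drawn reproducibly from `seed` when `NULL` (means uniform on
#'   \[-10, 10\], SDs uniform on \[0.5, 3\]).
#' @param subject_sd Random-intercept SD for longitudinal mode (>= 0).
#' @param time_effect Follow-up shift in feature SD units.
#' @param gamma_sd Across-feature SD of per-feature batch shifts around the
#'   batch-level `gamma`.
#' @param delta2_sdlog Across-feature SD of `log(delta2)` around the
#'   batch-level value.
#' @param residual_df Degrees of freedom for Student-t residuals, scaled to
#'   unit variance; `Inf` (default) gives Gaussian residuals.
#' @param single_timepoint_frac Fraction of subjects observed at a single
#'   timepoint in longitudinal mode (these are flagged ineligible).
#' @param seed Master seed; all random streams derive child seeds from it.
#' @return A list of class `synth_design`.
#' @export
synth_design <- function(n_features = 42L,
                         batches = default_batches(),
                         feature_means = NULL,
                         feature_sds = NULL,
                         subject_sd = 1,
                         time_effect = 0.5,
                         gamma_sd = 0.5,
                         delta2_sdlog = 0.25,
                         residual_df = Inf,
                         single_timepoint_frac = 0,
                         seed = 1L) {
  if (!is.numeric(n_features) || n_features < 1) {
    abort("`n_features` must be a positive integer")
  }
  if (!is.data.frame(batches) || nrow(batches) == 0L) {
    abort("`batches` must be a non-empty tibble from batch_effects()")
  }
  check_positive(batches$delta2, "delta2")
  if (any(batches$n_lesions < 1)) abort("`n_lesions` must be >= 1")
  check_scalar_number(subject_sd, "subject_sd", lower = 0)
  check_scalar_number(gamma_sd, "gamma_sd", lower = 0)
  check_scalar_number(delta2_sdlog, "delta2_sdlog", lower = 0)
  if (!is.null(feature_sds)) check_positive(feature_sds, "feature_sds")
  if (single_timepoint_frac < 0 || single_timepoint_frac >= 1) {
    abort("`single_timepoint_frac` must be in [0, 1)")
  }
  structure(list(
    n_features = as.integer(n_features), batches = batches,
    feature_means = feature_means, feature_sds = feature_sds,
    subject_sd = subject_sd, time_effect = time_effect,
    gamma_sd = gamma_sd, delta2_sdlog = delta2_sdlog,
    residual_df = residual_df,
    single_timepoint_frac = single_timepoint_frac,
    seed = as.integer(seed)
  ), class = "synth_design")
}

feature_names_for <- function(n_features) {
  if (n_features == 42L) feature_registry()$name else sprintf("F%03d", seq_len(n_features))
}

# realized per-batch x per-feature effects and per-feature scale parameters
realize_parameters <- function(design) {
  g <- design$n_features
  k <- nrow(design$batches)
  alpha <- design$feature_means %||%
    with_seed(child_seed(design$seed, "feature_means"), runif(g, -10, 10))
  sigma <- design$feature_sds %||%
    with_seed(child_seed(design$seed, "feature_sds"), runif(g, 0.5, 3))
  alpha <- rep_len(alpha, g)
  sigma <- rep_len(sigma, g)
  gamma <- with_seed(child_seed(design$seed, "gamma"), {
    design$batches$gamma + matrix(rnorm(k * g, 0, design$gamma_sd), k, g)
  })
  delta2 <- with_seed(child_seed(design$seed, "delta2"), {
    exp(log(design$batches$delta2) + matrix(rnorm(k * g, 0, design$delta2_sdlog), k, g))
  })
  fn <- feature_names_for(g)
  dimnames(gamma) <- dimnames(delta2) <- list(design$batches$batch_id, fn)
  list(alpha = setNames(alpha, fn), sigma = setNames(sigma, fn),
       gamma = gamma, delta2 = delta2)
}

# unit-variance residuals, Gaussian or scaled Student-t
draw_residuals <- function(n, df) {
  if (is.infinite(df)) return(rnorm(n))
  if (df <= 2) abort("`residual_df` must be > 2 (finite residual variance)")
  rt(n, df) * sqrt((df - 2) / df)
}

# acquisition metadata columns shared by both table generators
draw_metadata <- function(design, batch_idx, n) {
  b <- design$batches
  with_seed(child_seed(design$seed, "metadata"), {
    tibble::tibble(
      scanner = kernel_scanner(b$kernel[batch_idx]),
      kvp = b$kvp[batch_idx],
      kernel = b$kernel[batch_idx],
      exposure_time_ms = sample(c(350, 500, 600, 698, 1000), n, replace = TRUE),
      tube_current_ma = round(runif(n, 56, 581)),
      contrast_agent = ifelse(runif(n) < 0.55, NA_character_,
                              sample(c("Iobitridol", "Iomeprol"), n, replace = TRUE)),
      slice_thickness_mm = sample(c(0.5, 1, 1.25, 1.5, 2, 2.5, 3), n, replace = TRUE)
    )
  })
}

#' Generate a cross-sectional synthetic feature table
#'
#' Draws one row per lesion under the L/S batch model of [synth_design()]
#' and records every realized parameter in a ground-truth object, so that
#' downstream estimates (ComBat gamma/delta2) can be checked against the
#' values actually injected. Output is bit-identical for identical designs
#' (one master seed, deterministic child streams).
#'
#' @param design A [synth_design()].
#' @return A list with `table` (tibble: metadata columns then one column per
#'   feature) and `truth` (list: `alpha`, `sigma`, `gamma` and `delta2`
#'   matrices (batch x feature), `seed`).
#' @examples
#' out <- gen_feature_table(synth_design(n_features = 4, seed = 7))
#' dim(out$table)
#' @export
gen_feature_table <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  par <- realize_parameters(design)
  b <- design$batches
  batch_idx <- rep(seq_len(nrow(b)), b$n_lesions)
  n <- length(batch_idx)
  g <- design$n_features
  eps <- with_seed(child_seed(design$seed, "residuals"),
                   matrix(draw_residuals(n * g, design$residual_df), n, g))
  y <- matrix(par$alpha, n, g, byrow = TRUE) +
    matrix(par$sigma, n, g, byrow = TRUE) *
      (par$gamma[batch_idx, , drop = FALSE] +
         sqrt(par$delta2[batch_idx, , drop = FALSE]) * eps)
  colnames(y) <- names(par$alpha)
  n_patients <- max(1L, round(n * 23 / 124))
  table <- dplyr::bind_cols(
    tibble::tibble(
      obs_id = sprintf("obs%04d", seq_len(n)),
      patient_id = sprintf("P%03d", ((seq_len(n) - 1L) %% n_patients) + 1L),
      lesion_id = sprintf("L%04d", seq_len(n)),
      timepoint = "baseline"
    ),
    draw_metadata(design, batch_idx, n),
    tibble::as_tibble(y)
  )
  truth <- list(alpha = par$alpha, sigma = par$sigma, gamma = par$gamma,
                delta2 = par$delta2, batch_id = b$batch_id[batch_idx],
                seed = design$seed)
  list(table = table, truth = truth)
}

#' Generate a longitudinal synthetic feature table
#'
#' Like [gen_feature_table()] but with repeated measures: subjects carry a
#' shared random intercept `b_s ~ N(0, subject_sd^2)` (raw feature units,
#' common to all their rows) and follow-up rows are shifted by
#' `time_effect` feature SDs. Each observation (subject x timepoint image)
#' is assigned its own acquisition batch, mirroring re-scanning under a
#' different protocol. A fraction of subjects can be generated with a single
#' timepoint; these are flagged ineligible for longitudinal harmonization in
#' the ground truth.
#'
#' @inheritParams gen_feature_table
#' @return A list with `table` and `truth`; `truth` additionally contains
#'   `subject_intercepts` (tibble) and `ineligible_subjects`.
#' @export
gen_longitudinal_table <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  par <- realize_parameters(design)
  b <- design$batches
  n <- sum(b$n_lesions)
  f <- design$single_timepoint_frac
  n_subj <- max(1L, round(n / (2 - f)))
  n_single <- round(f * n_subj)
  n_double <- n_subj - n_single
  # adjust so 2*n_double + n_single == n exactly
  slack <- n - (2L * n_double + n_single)
  if (slack != 0L) {
    if (slack %% 2L != 0L) { n_single <- n_single + 1L; slack <- slack - 1L }
    n_double <- n_double + slack %/% 2L
    if (n_double < 0L) { n_single <- n_single + 2L * n_double; n_double <- 0L }
  }
  n_subj <- n_double + n_single
  subj <- sprintf("P%03d", seq_len(n_subj))
  rows <- tibble::tibble(
    patient_id = c(rep(subj[seq_len(n_double)], each = 2L),
                   subj[n_double + seq_len(n_single)]),
    timepoint = c(rep(c("baseline", "follow-up"), n_double),
                  rep("baseline", n_single))
  )
  stopifnot(nrow(rows) == n)
  batch_slots <- rep(seq_len(nrow(b)), b$n_lesions)
  batch_idx <- with_seed(child_seed(design$seed, "batch_assignment"),
                         sample(batch_slots))
  g <- design$n_features
  intercepts <- with_seed(child_seed(design$seed, "subject_intercepts"),
                          rnorm(n_subj, 0, design$subject_sd))
  eps <- with_seed(child_seed(design$seed, "residuals"),
                   matrix(draw_residuals(n * g, design$residual_df), n, g))
  sidx <- match(rows$patient_id, subj)
  y <- matrix(par$alpha, n, g, byrow = TRUE) + intercepts[sidx] +
    matrix(par$sigma, n, g, byrow = TRUE) *
      (design$time_effect * (rows$timepoint == "follow-up") +
         par$gamma[batch_idx, , drop = FALSE] +
         sqrt(par$delta2[batch_idx, , drop = FALSE]) * eps)
  colnames(y) <- names(par$alpha)
  table <- dplyr::bind_cols(
    tibble::tibble(
      obs_id = sprintf("obs%04d", seq_len(n)),
      patient_id = rows$patient_id,
      lesion_id = paste0(rows$patient_id, "_L1"),
      timepoint = rows$timepoint
    ),
    draw_metadata(design, batch_idx, n),
    tibble::as_tibble(y)
  )
  truth <- list(
    alpha = par$alpha, sigma = par$sigma, gamma = par$gamma,
    delta2 = par$delta2, batch_id = b$batch_id[batch_idx],
    subject_intercepts = tibble::tibble(patient_id = subj, intercept = intercepts),
    ineligible_subjects = subj[n_double + seq_len(n_single)],
    time_effect = design$time_effect, subject_sd = design$subject_sd,
    seed = design$seed
  )
  list(table = table, truth = truth)
}

#' Write a synthetic table and its ground truth to disk
#'
#' The table is written as CSV (metadata columns first, then feature
#' columns) and the ground truth as a JSON side-car next to it.
#'
#' @param x Result of [gen_feature_table()] or [gen_longitudinal_table()].
#' @param path CSV path; the JSON side-car gets extension `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  write.csv(x$table, path, row.names = FALSE, na = "")
  truth <- x$truth
  truth$gamma <- as.data.frame(truth$gamma)
  truth$delta2 <- as.data.frame(truth$delta2)
  jsonlite::write_json(truth, sub("\\.csv$", ".truth.json", path),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path CSV path written by [write_feature_table()] or following the
#'   same header convention.
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    na.strings = c("NA", "")))
}
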