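#' Longitudinal ComBat configuration
#'
#' @param eb_tol,eb_max_iter Parametric-EB fixed-point controls.
#' @param delta2_denominator Within-batch variance convention for the
#'   standardized residuals (`"n-1"` default, `"n"`); singleton batches
#'   carry no scale information and get `delta2_hat = 1`.
#' @return A list of class `longcombat_config`.
#' @export
longcombat_config <- function(eb_tol = 1e-4, eb_max_iter = 100L,
                              delta2_denominator = c("n-1", "n")) {
  structure(list(eb_tol = eb_tol, eb_max_iter = as.integer(eb_max_iter),
                 delta2_denominator = match.arg(delta2_denominator)),
            class = "longcombat_config")
}

#' Fit the longitudinal batch-effect model per feature
#'
#' For each feature fits the linear mixed model
#' \deqn{y = \alpha + \beta_{time} I(\text{follow-up}) + \gamma_{batch} +
#'   b_{subject} + \varepsilon}
#' by REML ([lme4::lmer()]), with a subject random intercept (intercept-only:
#' two timepoints cannot support random slopes). Batch coefficients are
#' re-expressed under the size-weighted sum-to-zero constraint
#' \eqn{\sum_i (n_i/N)\gamma_i = 0}; per-feature scale is the REML residual
#' SD, and per-batch scale effects are variances of within-batch
#' standardized residuals. Features whose fit is rank-deficient (e.g. batch
#' confounded with subject) are flagged and later passed through
#' unharmonized.
#'
#' @param table Feature table that passed [filter_longitudinal()].
#' @param assignment A [assign_batches()] result.
#' @param subject,time Column names; `time` must have levels
#'   `baseline`/`follow-up`.
#' @param features Optional feature column names.
#' @param config A [longcombat_config()].
#' @return An object of class `longcombat_model`.
#' @export
longcombat_fit <- function(table, assignment,
                           subject = "patient_id", time = "timepoint",
                           features = NULL, config = longcombat_config()) {
  stopifnot(inherits(assignment, "batch_assignment"),
            inherits(config, "longcombat_config"))
  joined <- with_batches(table, assignment)
  feats <- feature_columns(joined, features)
  ids <- sort(unique(joined$batch_id))
  if (length(ids) < 2L) abort("longitudinal fitting needs >= 2 batches")
  dat <- data.frame(
    y = 0,
    time_fu = as.numeric(joined[[time]] == "follow-up"),
    batch = factor(joined$batch_id, levels = ids),
    subject = factor(joined[[subject]])
  )
  n_i <- as.vector(table(dat$batch))
  w_i <- n_i / sum(n_i)
  k <- length(ids)
  g <- length(feats)
  subj_levels <- levels(dat$subject)
  fits <- vector("list", g)
  names(fits) <- feats
  for (f in feats) {
    dat$y <- joined[[f]]
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(y ~ time_fu + batch + (1 | subject), data = dat,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
      )),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      fits[[f]] <- list(flagged = TRUE, reason = conditionMessage(fit))
      next
    }
    fe <- lme4::fixef(fit)
    theta <- setNames(rep(0, k), paste0("batch", ids))
    found <- intersect(names(theta), names(fe))
    theta[found] <- fe[found]
    rank_deficient <- length(found) < k - 1L ||
      anyNA(fe[grep("^batch", names(fe))])
    if (rank_deficient) {
      fits[[f]] <- list(flagged = TRUE, reason = "rank-deficient batch effects")
      next
    }
    wmean <- sum(w_i * theta)
    gamma_raw <- theta - wmean            # size-weighted sum-to-zero
    intercept <- fe[["(Intercept)"]] + wmean
    beta_time <- fe[["time_fu"]]
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_var <- vc$vcov[vc$grp == "subject"]
    sigma <- stats::sigma(fit)
    b_hat <- setNames(rep(0, length(subj_levels)), subj_levels)
    re <- lme4::ranef(fit)$subject
    b_hat[rownames(re)] <- re[["(Intercept)"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    fits[[f]] <- list(
      flagged = FALSE, intercept = intercept, beta_time = beta_time,
      beta_time_se = unname(se["time_fu"]), re_var = re_var,
      sigma2 = sigma^2, gamma_raw = gamma_raw, b_hat = b_hat,
      converged = is.null(fit@optinfo$conv$lme4$messages)
    )
  }
  ok <- !vapply(fits, function(x) x$flagged, logical(1))
  if (!any(ok)) abort("all features failed the mixed-model fit")
  # standardized residuals including the batch effect: z = (y - fixed(no
  # batch) - b_hat)/sigma, whose batch means are the standardized gamma_hat
  gamma_hat <- matrix(NA_real_, k, g, dimnames = list(ids, feats))
  delta2_hat <- gamma_hat
  z_mat <- matrix(NA_real_, nrow(dat), g, dimnames = list(NULL, feats))
  for (f in feats[ok]) {
    ft <- fits[[f]]
    fixed_nb <- ft$intercept + ft$beta_time * dat$time_fu
    z <- (joined[[f]] - fixed_nb - ft$b_hat[as.character(dat$subject)]) /
      sqrt(ft$sigma2)
    z_mat[, f] <- z
    gamma_hat[, f] <- ft$gamma_raw / sqrt(ft$sigma2)
    resid_std <- z - gamma_hat[match(joined$batch_id, ids), f]
    d2 <- vapply(seq_len(k), function(i) {
      ri <- resid_std[joined$batch_id == ids[i]]
      if (length(ri) < 2L) return(1)
      batch_var(ri, config$delta2_denominator)
    }, numeric(1))
    delta2_hat[, f] <- pmax(d2, 1e-8)
  }
  structure(list(
    fits = fits, features = feats, flagged = feats[!ok],
    batch_ids = ids, n_per_batch = setNames(n_i, ids),
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = NULL, delta2_star = NULL,
    Z = z_mat, batch = joined$batch_id, obs_id = joined$obs_id,
    subject = as.character(dat$subject), time_fu = dat$time_fu,
    config = config
  ), class = "longcombat_model")
}

#' Empirical-Bayes shrinkage of longitudinal batch effects
#'
#' Parametric EB across features within each batch, with the same
#' conditional-posterior fixed point as the cross-sectional module, applied
#' to the standardized residuals of the mixed-model fits. (The longitudinal
#' variant has no nonparametric or non-EB mode.)
#'
#' @param model A [longcombat_fit()] result.
#' @return The model with `gamma_star`, `delta2_star` and `hyper` filled in.
#' @export
longcombat_shrink <- function(model) {
  stopifnot(inherits(model, "longcombat_model"))
  ok <- setdiff(model$features, model$flagged)
  if (length(ok) < 2L) abort("parametric EB needs >= 2 fitted features")
  k <- length(model$batch_ids)
  gamma_star <- model$gamma_hat
  delta2_star <- model$delta2_hat
  hyper <- vector("list", k)
  for (i in seq_len(k)) {
    zi <- model$Z[model$batch == model$batch_ids[i], ok, drop = FALSE]
    g_hat <- model$gamma_hat[i, ok]
    d2_hat <- model$delta2_hat[i, ok]
    g_bar <- mean(g_hat)
    tau2 <- var(g_hat)
    ig <- ig_moments(d2_hat)
    sol <- eb_fixed_point(zi, g_hat, d2_hat, nrow(zi), g_bar, tau2,
                          ig$lambda, ig$theta,
                          model$config$eb_tol, model$config$eb_max_iter)
    gamma_star[i, ok] <- sol$gamma_star
    delta2_star[i, ok] <- sol$delta2_star
    hyper[[i]] <- list(gamma_bar = g_bar, tau2 = tau2,
                       lambda = ig$lambda, theta = ig$theta)
  }
  names(hyper) <- model$batch_ids
  model$gamma_star <- gamma_star
  model$delta2_star <- delta2_star
  model$hyper <- hyper
  model
}

#' Longitudinal ComBat harmonization
#'
#' Fits the per-feature mixed model, shrinks batch effects with parametric
#' EB, and removes them while preserving subject trajectories and the time
#' effect:
#' \deqn{y^* = \frac{\sigma}{\delta^*_i}(z - \gamma^*_i) + \text{fixed} +
#'   \hat b_s, \qquad z = \frac{y - \text{fixed} - \hat b_s}{\sigma}}
#' where "fixed" is the batch-free fixed part (intercept + time effect).
#' Flagged features are passed through unchanged.
#'
#' @inheritParams longcombat_fit
#' @return A list with `table` (harmonized tibble) and `model`
#'   (`longcombat_model`).
#' @export
longcombat_harmonize <- function(table, assignment,
                                 subject = "patient_id", time = "timepoint",
                                 features = NULL,
                                 config = longcombat_config()) {
  model <- longcombat_fit(table, assignment, subject, time, features, config)
  model <- longcombat_shrink(model)
  joined <- with_batches(table, assignment)
  stopifnot(identical(joined$obs_id, model$obs_id))
  out <- joined
  bidx <- match(model$batch, model$batch_ids)
  for (f in setdiff(model$features, model$flagged)) {
    ft <- model$fits[[f]]
    fixed_nb <- ft$intercept + ft$beta_time * model$time_fu
    base <- fixed_nb + ft$b_hat[model$subject]
    z <- model$Z[, f]
    out[[f]] <- sqrt(ft$sigma2) / sqrt(model$delta2_star[cbind(bidx, match(f, colnames(model$delta2_star)))]) *
      (z - model$gamma_star[cbind(bidx, match(f, colnames(model$gamma_star)))]) + base
  }
  out$batch_id <- NULL
  list(table = out, model = model)
}

#' @export
print.longcombat_model <- function(x, ...) {
  cat("<longcombat_model> ", length(x$batch_ids), " batches, ",
      length(x$features), " features",
      if (length(x$flagged)) paste0(" (", length(x$flagged), " flagged)"),
      if (!is.null(x$gamma_star)) ", EB-shrunk", "\n", sep = "")
  invisible(x)
}

#' Tidy a longitudinal ComBat model
#'
#' @param x A `longcombat_model`.
#' @param ... Unused.
#' @return A tibble with one row per (batch, feature).
#' @export
tidy.longcombat_model <- function(x, ...) {
  feats <- colnames(x$gamma_hat)
  out <- tidyr::expand_grid(batch_id = x$batch_ids, feature = feats) |>
    dplyr::mutate(
      gamma_hat = as.vector(t(x$gamma_hat)),
      delta2_hat = as.vector(t(x$delta2_hat))
    )
  if (!is.null(x$gamma_star)) {
    out$gamma_star <- as.vector(t(x$gamma_star))
    out$delta2_star <- as.vector(t(x$delta2_star))
  }
  out
}

#' Summarize a longitudinal ComBat model
#'
#' @param x A `longcombat_model`.
#' @param ... Unused.
#' @return A one-row tibble with fit counts and median variance components.
#' @export
glance.longcombat_model <- function(x, ...) {
  ok <- setdiff(x$features, x$flagged)
  tibble::tibble(
    n_batches = length(x$batch_ids),
    n_features = length(x$features),
    n_flagged = length(x$flagged),
    median_re_var = median(vapply(x$fits[ok], function(f) f$re_var, numeric(1))),
    median_sigma2 = median(vapply(x$fits[ok], function(f) f$sigma2, numeric(1))),
    eb_shrunk = !is.null(x$gamma_star)
  )
}
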