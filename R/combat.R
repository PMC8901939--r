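#' ComBat configuration
#'
#' Variance-denominator conventions and empirical-Bayes solver settings.
#' At the small batch sizes typical of protocol harmonization these
#' conventions visibly change the result, so they are explicit:
#' `sigma2_denominator` divides the pooled squared residuals (after batch
#' means) by `N` (`"n"`, default) or `N - K` (`"n-k"`, df-corrected);
#' `delta2_denominator` controls the within-batch variance of standardized
#' data (`"n-1"` default, or `"n"`).
#'
#' @param delta2_denominator `"n-1"` or `"n"`.
#' @param sigma2_denominator `"n"` or `"n-k"`.
#' @param eb_tol Convergence tolerance (max absolute change) of the
#'   parametric-EB fixed point.
#' @param eb_max_iter Iteration cap for the parametric-EB fixed point.
#' @return A list of class `combat_config`.
#' @export
combat_config <- function(delta2_denominator = c("n-1", "n"),
                          sigma2_denominator = c("n", "n-k"),
                          eb_tol = 1e-4, eb_max_iter = 100L) {
  structure(list(delta2_denominator = match.arg(delta2_denominator),
                 sigma2_denominator = match.arg(sigma2_denominator),
                 eb_tol = eb_tol, eb_max_iter = as.integer(eb_max_iter)),
            class = "combat_config")
}

# within-batch variance under the configured convention
batch_var <- function(x, denom) {
  n <- length(x)
  ss <- sum((x - mean(x))^2)
  if (denom == "n-1") ss / (n - 1) else ss / n
}

#' Standardize a feature table across batches
#'
#' First stage of the location/scale model without biological covariates:
#' per feature, the grand mean is the batch-size-weighted mean of batch
#' means and the pooled variance is the mean squared residual after
#' removing batch means; standardized data are
#' `Z = (Y - alpha_hat) / sigma_hat`, under which the batch-size-weighted
#' mean of per-batch location effects is zero by construction.
#' Zero-variance features are skipped with a warning and flagged.
#'
#' @param table Feature table.
#' @param assignment A [assign_batches()] result.
#' @param features Optional feature column names.
#' @param config A [combat_config()].
#' @return A list of class `combat_standardized`: `Z` (n x G matrix),
#'   `batch` (integer vector of batch ids per row), `obs_id`, `n_per_batch`,
#'   `alpha_hat`, `sigma2_hat`, `gamma_hat` (K x G batch means of Z),
#'   `delta2_hat` (K x G batch variances of Z), `skipped`, `config`.
#' @export
combat_standardize <- function(table, assignment, features = NULL,
                               config = combat_config()) {
  stopifnot(inherits(assignment, "batch_assignment"),
            inherits(config, "combat_config"))
  joined <- with_batches(table, assignment)
  feats <- feature_columns(joined, features)
  y <- as.matrix(joined[feats])
  batch <- joined$batch_id
  ids <- sort(unique(batch))
  k <- length(ids)
  bidx <- match(batch, ids)
  n_i <- tabulate(bidx, k)
  n <- nrow(y)
  m <- rowsum(y, bidx) / n_i
  alpha_hat <- colSums(m * (n_i / n))
  resid <- y - m[bidx, , drop = FALSE]
  denom <- if (config$sigma2_denominator == "n") n else n - k
  sigma2_hat <- colSums(resid^2) / denom
  skipped <- feats[sigma2_hat <= 0 | !is.finite(sigma2_hat)]
  if (length(skipped) > 0) {
    warn(paste0("zero-variance feature(s) skipped: ",
                paste(skipped, collapse = ", ")))
  }
  keep <- setdiff(feats, skipped)
  z <- sweep(sweep(y[, keep, drop = FALSE], 2, alpha_hat[keep]), 2,
             sqrt(sigma2_hat[keep]), "/")
  gamma_hat <- rowsum(z, bidx) / n_i
  delta2_hat <- do.call(rbind, lapply(seq_len(k), function(i) {
    apply(z[bidx == i, , drop = FALSE], 2, batch_var,
          denom = config$delta2_denominator)
  }))
  rownames(gamma_hat) <- rownames(delta2_hat) <- ids
  structure(list(Z = z, batch = batch, batch_ids = ids, obs_id = joined$obs_id,
                 n_per_batch = setNames(n_i, ids),
                 alpha_hat = alpha_hat, sigma2_hat = sigma2_hat,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 features = feats, skipped = skipped, config = config),
            class = "combat_standardized")
}

#' Batch-effect estimators
#'
#' Three estimators of the per-batch location (`gamma_star`) and scale
#' (`delta2_star`) effects on standardized data:
#'
#' * `combat_estimate_no_eb()`: raw within-batch moments, no shrinkage.
#' * `combat_estimate_parametric_eb()`: empirical Bayes with a normal prior
#'   on location and an inverse-gamma prior on scale; hyperparameters by
#'   method of moments across features within each batch, then the coupled
#'   conditional-posterior updates
#'   \deqn{\gamma^* = \frac{n_i \tau^2 \hat\gamma + \delta^{*2} \bar\gamma}
#'     {n_i \tau^2 + \delta^{*2}}, \qquad
#'     \delta^{*2} = \frac{\theta + \tfrac12 \sum_j (Z_{ijg} - \gamma^*)^2}
#'     {n_i/2 + \lambda - 1}}
#'   iterated to a fixed point (max absolute change below `tol`).
#' * `combat_estimate_nonparametric_eb()`: distribution-free empirical
#'   Bayes; the posterior estimate for feature `g` in batch `i` is the
#'   likelihood-weighted average of the other features' moment estimates,
#'   with weights \eqn{w_{g'} = \prod_j N(Z_{ijg};\hat\gamma_{ig'},
#'   \hat\delta^2_{ig'})} computed in the log domain. Deterministic: the
#'   full sum over features is used, never a Monte-Carlo subsample.
#'
#' @param std A [combat_standardize()] result.
#' @param tol,max_iter Parametric fixed-point controls (defaults from the
#'   config stored in `std`).
#' @return A list with `gamma_star`, `delta2_star` (K x G matrices),
#'   `method`, and for the parametric method `hyper` (per-batch
#'   `gamma_bar`, `tau2`, `lambda`, `theta`) and `iterations`.
#' @name combat_estimators
NULL

#' @rdname combat_estimators
#' @export
combat_estimate_no_eb <- function(std) {
  stopifnot(inherits(std, "combat_standardized"))
  if (any(std$n_per_batch < 2L)) {
    abort("no-EB estimation needs >= 2 observations per batch")
  }
  list(gamma_star = std$gamma_hat, delta2_star = std$delta2_hat,
       method = "no_eb")
}

# method-of-moments inverse-gamma hyperparameters
ig_moments <- function(d2) {
  m <- mean(d2)
  s2 <- max(var(d2), 1e-12)
  list(lambda = (m^2 + 2 * s2) / s2, theta = (m^3 + m * s2) / s2)
}

#' @rdname combat_estimators
#' @export
combat_estimate_parametric_eb <- function(std, tol = NULL, max_iter = NULL) {
  stopifnot(inherits(std, "combat_standardized"))
  tol <- tol %||% std$config$eb_tol
  max_iter <- max_iter %||% std$config$eb_max_iter
  if (ncol(std$Z) < 2L) abort("parametric EB needs >= 2 features")
  k <- length(std$batch_ids)
  gamma_star <- std$gamma_hat
  delta2_star <- std$delta2_hat
  hyper <- vector("list", k)
  iterations <- integer(k)
  bidx <- match(std$batch, std$batch_ids)
  for (i in seq_len(k)) {
    zi <- std$Z[bidx == i, , drop = FALSE]
    n_i <- nrow(zi)
    g_hat <- std$gamma_hat[i, ]
    d2_hat <- std$delta2_hat[i, ]
    g_bar <- mean(g_hat)
    tau2 <- var(g_hat)
    ig <- ig_moments(d2_hat)
    sol <- eb_fixed_point(zi, g_hat, d2_hat, n_i, g_bar, tau2,
                          ig$lambda, ig$theta, tol, max_iter)
    gamma_star[i, ] <- sol$gamma_star
    delta2_star[i, ] <- sol$delta2_star
    iterations[i] <- sol$iterations
    hyper[[i]] <- list(gamma_bar = g_bar, tau2 = tau2,
                       lambda = ig$lambda, theta = ig$theta)
  }
  names(hyper) <- std$batch_ids
  list(gamma_star = gamma_star, delta2_star = delta2_star,
       method = "parametric_eb", hyper = hyper, iterations = iterations)
}

# coupled conditional-posterior fixed point for one batch (all features)
eb_fixed_point <- function(zi, g_hat, d2_hat, n_i, g_bar, tau2,
                           lambda, theta, tol, max_iter) {
  g_star <- g_hat
  d2_star <- d2_hat
  for (it in seq_len(max_iter)) {
    g_new <- (n_i * tau2 * g_hat + d2_star * g_bar) / (n_i * tau2 + d2_star)
    sum2 <- colSums(sweep(zi, 2, g_new)^2)
    d2_new <- (theta + 0.5 * sum2) / (n_i / 2 + lambda - 1)
    change <- max(abs(g_new - g_star), abs(d2_new - d2_star))
    g_star <- g_new
    d2_star <- d2_new
    if (change < tol) {
      return(list(gamma_star = g_star, delta2_star = d2_star, iterations = it))
    }
  }
  abort(sprintf(
    "parametric EB did not converge in %d iterations (last change %.3g)",
    max_iter, change))
}

#' @rdname combat_estimators
#' @export
combat_estimate_nonparametric_eb <- function(std) {
  stopifnot(inherits(std, "combat_standardized"))
  g <- ncol(std$Z)
  if (g < 2L) abort("nonparametric EB needs >= 2 features")
  k <- length(std$batch_ids)
  gamma_star <- std$gamma_hat
  delta2_star <- std$delta2_hat
  bidx <- match(std$batch, std$batch_ids)
  for (i in seq_len(k)) {
    zi <- std$Z[bidx == i, , drop = FALSE]
    g_hat <- std$gamma_hat[i, ]
    d2_hat <- std$delta2_hat[i, ]
    # lw[g', g]: summed log-likelihood of feature g's data under the moment
    # estimates of feature g'
    lw <- vapply(seq_len(g), function(gp) {
      colSums(dnorm(zi, mean = g_hat[gp], sd = sqrt(d2_hat[gp]), log = TRUE))
    }, numeric(g))
    lw <- t(lw)
    diag(lw) <- -Inf  # leave-one-out
    for (gg in seq_len(g)) {
      l <- lw[, gg]
      mx <- max(l)
      if (!is.finite(mx)) {
        warn("all nonparametric-EB weights underflowed; using unweighted mean")
        w <- rep(1 / (g - 1), g)
        w[gg] <- 0
      } else {
        w <- exp(l - mx)
        w <- w / sum(w)
      }
      gamma_star[i, gg] <- sum(w * g_hat)
      delta2_star[i, gg] <- sum(w * d2_hat)
    }
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star,
       method = "nonparametric_eb")
}

#' Remove estimated batch effects from a feature table
#'
#' Applies the location/scale correction
#' \deqn{Y^*_{ijg} = \frac{\sigma_g}{\delta^*_{ig}} (Z_{ijg} -
#'   \gamma^*_{ig}) + \hat\alpha_g,}
#' leaving zero-variance-flagged features unchanged.
#'
#' @param table Feature table.
#' @param model A `combat_model` from [combat_harmonize()].
#' @param assignment A [assign_batches()] result.
#' @return The harmonized table (same shape and row order as `table`
#'   restricted to assigned observations).
#' @export
combat_adjust <- function(table, model, assignment) {
  stopifnot(inherits(model, "combat_model"))
  joined <- with_batches(table, assignment)
  feats <- setdiff(model$features, model$skipped)
  missing <- setdiff(feats, names(joined))
  if (length(missing) > 0) {
    abort(paste0("table lacks model features: ", paste(missing, collapse = ", ")))
  }
  y <- as.matrix(joined[feats])
  bidx <- match(joined$batch_id, model$batch_ids)
  if (anyNA(bidx)) abort("table contains batches absent from the model")
  z <- sweep(sweep(y, 2, model$alpha_hat[feats]), 2,
             sqrt(model$sigma2_hat[feats]), "/")
  zc <- z - model$gamma_star[bidx, , drop = FALSE]
  ystar <- sweep(zc / sqrt(model$delta2_star[bidx, , drop = FALSE]), 2,
                 sqrt(model$sigma2_hat[feats]), "*")
  ystar <- sweep(ystar, 2, model$alpha_hat[feats], "+")
  out <- joined
  out[feats] <- ystar
  out$batch_id <- NULL
  out
}

#' Cross-sectional ComBat harmonization
#'
#' Composition of [combat_standardize()], one of the three batch-effect
#' estimators, and [combat_adjust()]. The configuration used in the CT
#' protocol-harmonization study is `method = "nonparametric_eb"` with no
#' biological covariates. All methods are deterministic.
#'
#' @param table Feature table.
#' @param assignment A [assign_batches()] result.
#' @param method `"nonparametric_eb"` (default), `"parametric_eb"` or
#'   `"no_eb"`.
#' @param features Optional feature column names.
#' @param config A [combat_config()].
#' @return A list with `table` (harmonized tibble) and `model`
#'   (`combat_model`: estimates, hyperparameters, conventions).
#' @examples
#' sim <- gen_feature_table(synth_design(seed = 42))
#' asg <- assign_batches(sim$table)
#' fit <- combat_harmonize(sim$table, asg)
#' fit$model
#' @export
combat_harmonize <- function(table, assignment,
                             method = c("nonparametric_eb", "parametric_eb",
                                        "no_eb"),
                             features = NULL, config = combat_config()) {
  method <- match.arg(method)
  std <- combat_standardize(table, assignment, features, config)
  est <- switch(method,
    no_eb = combat_estimate_no_eb(std),
    parametric_eb = combat_estimate_parametric_eb(std),
    nonparametric_eb = combat_estimate_nonparametric_eb(std)
  )
  model <- structure(list(
    method = method, alpha_hat = std$alpha_hat, sigma2_hat = std$sigma2_hat,
    gamma_hat = std$gamma_hat, delta2_hat = std$delta2_hat,
    gamma_star = est$gamma_star, delta2_star = est$delta2_star,
    hyper = est$hyper, iterations = est$iterations,
    batch_ids = std$batch_ids, n_per_batch = std$n_per_batch,
    features = std$features, skipped = std$skipped, config = std$config
  ), class = "combat_model")
  list(table = combat_adjust(table, model, assignment), model = model)
}

#' @export
print.combat_model <- function(x, ...) {
  cat("<combat_model> method ", x$method, ": ", length(x$batch_ids),
      " batches, ", length(x$features), " features",
      if (length(x$skipped)) paste0(" (", length(x$skipped), " skipped)"),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return A tibble with one row per (batch, feature): raw and EB-adjusted
#'   location/scale estimates.
#' @export
tidy.combat_model <- function(x, ...) {
  feats <- colnames(x$gamma_hat)
  tidyr::expand_grid(batch_id = x$batch_ids, feature = feats) |>
    dplyr::mutate(
      gamma_hat = as.vector(t(x$gamma_hat)),
      delta2_hat = as.vector(t(x$delta2_hat)),
      gamma_star = as.vector(t(x$gamma_star)),
      delta2_star = as.vector(t(x$delta2_star))
    )
}

#' Summarize a ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return A one-row tibble: method, batch/feature counts, conventions.
#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_batches = length(x$batch_ids),
    n_features = length(x$features),
    n_skipped = length(x$skipped),
    delta2_denominator = x$config$delta2_denominator,
    sigma2_denominator = x$config$sigma2_denominator
  )
}

#' Serialize a harmonization model to JSON
#'
#' @param model A `combat_model` or `longcombat_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- lapply(unclass(model), function(el) {
    if (is.matrix(el)) as.data.frame(el) else el
  })
  obj$class <- class(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
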