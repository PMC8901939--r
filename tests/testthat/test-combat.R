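# small helper: a feature table from an explicit value matrix
table_from_matrix <- function(y, batch_labels) {
  colnames(y) <- sprintf("F%03d", seq_len(ncol(y)))
  dplyr::bind_cols(
    tibble::tibble(obs_id = sprintf("o%03d", seq_len(nrow(y))),
                   kernel = sprintf("K%02d", batch_labels), kvp = 120),
    tibble::as_tibble(y)
  )
}

std_of <- function(y, batch_labels, config = combat_config()) {
  tab <- table_from_matrix(y, batch_labels)
  asg <- assign_batches(tab)
  combat_standardize(tab, asg, config = config)
}

test_that("standardization recovers hand-computed grand mean and batch moments", {
  y <- matrix(c(0, 2, 10, 14), ncol = 1)
  std <- std_of(y, c(1, 1, 2, 2))
  # batch means 1 and 12, equal sizes: weighted grand mean 6.5
  expect_equal(unname(std$alpha_hat), 6.5)
  # pooled residual variance (denominator N): (1+1+4+4)/4
  expect_equal(unname(std$sigma2_hat), 2.5)
  expect_equal(unname(std$gamma_hat[, 1]),
               c((1 - 6.5), (12 - 6.5)) / sqrt(2.5))
  # weighted mean of gamma_hat is zero by construction
  w <- std$n_per_batch / sum(std$n_per_batch)
  expect_equal(sum(w * std$gamma_hat[, 1]), 0, tolerance = 1e-12)
})

test_that("zero-variance features are skipped and passed through", {
  set.seed(3)
  y <- cbind(rnorm(8), 7)
  tab <- table_from_matrix(y, rep(1:2, each = 4))
  asg <- assign_batches(tab)
  expect_warning(std <- combat_standardize(tab, asg), "zero-variance")
  expect_equal(std$skipped, "F002")
  fit <- suppressWarnings(combat_harmonize(tab, asg, method = "no_eb"))
  expect_equal(fit$table$F002, rep(7, 8))
  expect_false(identical(fit$table$F001, tab$F001))
})

test_that("no-EB estimates are the raw batch moments", {
  y <- matrix(c(-1, 1, -1, 1, 2, 4), ncol = 1)
  std <- std_of(y, c(1, 1, 2, 2, 3, 3))
  est <- combat_estimate_no_eb(std)
  # two-point batches: per-batch variance of Z with the n-1 convention
  z <- std$Z[, 1]
  for (i in 1:3) {
    rows <- std$batch == std$batch_ids[i]
    expect_equal(est$gamma_star[i, 1], mean(z[rows]))
    expect_equal(est$delta2_star[i, 1], var(z[rows]))
  }
  # batch of size one is rejected
  y1 <- matrix(rnorm(5), ncol = 1)
  expect_error(combat_estimate_no_eb(std_of(y1, c(1, 1, 2, 2, 3))),
               ">= 2 observations")
})

test_that("no-EB adjustment equalizes per-batch moments exactly", {
  set.seed(11)
  sim <- gen_feature_table(synth_design(n_features = 5, seed = 91))
  asg <- assign_batches(sim$table)
  fit <- combat_harmonize(sim$table, asg, method = "no_eb")
  joined <- with_batches(fit$table, asg)
  model <- fit$model
  for (f in model$features) {
    ms <- as.vector(tapply(joined[[f]], joined$batch_id, mean))
    vs <- as.vector(tapply(joined[[f]], joined$batch_id, var))
    expect_equal(ms, rep(unname(model$alpha_hat[f]), length(ms)),
                 tolerance = 1e-9)
    expect_equal(vs, rep(unname(model$sigma2_hat[f]), length(vs)),
                 tolerance = 1e-9)
  }
})

test_that("single-batch no-EB harmonization is the identity under matched conventions", {
  set.seed(21)
  y <- matrix(rnorm(30), ncol = 3)
  tab <- table_from_matrix(y, rep(1, 10))
  asg <- assign_batches(tab)
  cfg <- combat_config(delta2_denominator = "n-1", sigma2_denominator = "n-k")
  fit <- combat_harmonize(tab, asg, method = "no_eb", config = cfg)
  for (f in c("F001", "F002", "F003")) {
    expect_equal(fit$table[[f]], tab[[f]], tolerance = 1e-12)
  }
})

test_that("parametric EB is a convex combination and matches the damped oracle", {
  set.seed(31)
  y <- matrix(rnorm(25 * 10, sd = 2), 25, 10) +
    rep(c(0, 1.5, -1), c(8, 9, 8))
  std <- std_of(y, rep(1:3, c(8, 9, 8)))
  est <- combat_estimate_parametric_eb(std, tol = 1e-12, max_iter = 2000)
  for (i in 1:3) {
    h <- est$hyper[[i]]
    lo <- pmin(std$gamma_hat[i, ], h$gamma_bar)
    hi <- pmax(std$gamma_hat[i, ], h$gamma_bar)
    expect_true(all(est$gamma_star[i, ] >= lo - 1e-9 &
                      est$gamma_star[i, ] <= hi + 1e-9))
    zi <- std$Z[std$batch == std$batch_ids[i], , drop = FALSE]
    orc <- oracle_eb_fixed_point(zi, std$gamma_hat[i, ], std$delta2_hat[i, ],
                                 h$gamma_bar, h$tau2, h$lambda, h$theta,
                                 tol = 1e-12)
    expect_equal(unname(est$gamma_star[i, ]), unname(orc$gamma_star),
                 tolerance = 1e-8)
    expect_equal(unname(est$delta2_star[i, ]), unname(orc$delta2_star),
                 tolerance = 1e-8)
  }
})

test_that("identical batch moments across features yield no shrinkage", {
  # every feature has the same batch moments, so the prior mean equals each
  # raw estimate and gamma_star = gamma_hat
  z <- c(-2, -1, 0, 1, 2)
  y <- cbind(c(z, z + 4), c(2 * z, 2 * z + 8), c(3 * z, 3 * z + 12))
  std <- std_of(y, rep(1:2, each = 5))
  expect_equal(var(std$gamma_hat[1, ]), 0, tolerance = 1e-20)
  est <- combat_estimate_parametric_eb(std, tol = 1e-10, max_iter = 1000)
  expect_equal(est$gamma_star, std$gamma_hat, tolerance = 1e-6)
})

test_that("nonparametric EB: swap identity and log-domain correctness", {
  # two features with identical data in each batch: the leave-one-out
  # weighted average has a single term, the other feature's raw estimate
  set.seed(41)
  base <- rnorm(12)
  y <- cbind(base, base)
  std <- std_of(y, rep(1:2, each = 6))
  est <- combat_estimate_nonparametric_eb(std)
  expect_equal(est$gamma_star[, 1], std$gamma_hat[, 2], tolerance = 1e-12)
  expect_equal(est$delta2_star[, 2], std$delta2_hat[, 1], tolerance = 1e-12)

  # tiny fixture: log-domain weights equal the direct product computation
  set.seed(42)
  y3 <- matrix(rnorm(3 * 4), 3, 4)
  tab3 <- table_from_matrix(rbind(y3, y3 + 1), rep(1:2, each = 3))
  asg3 <- assign_batches(tab3)
  std3 <- combat_standardize(tab3, asg3)
  est3 <- combat_estimate_nonparametric_eb(std3)
  for (i in 1:2) {
    zi <- std3$Z[std3$batch == std3$batch_ids[i], , drop = FALSE]
    for (g in 1:4) {
      w <- vapply(1:4, function(gp) {
        prod(dnorm(zi[, g], std3$gamma_hat[i, gp],
                   sqrt(std3$delta2_hat[i, gp])))
      }, numeric(1))
      w[g] <- 0
      w <- w / sum(w)
      expect_equal(est3$gamma_star[i, g],
                   sum(w * std3$gamma_hat[i, ]), tolerance = 1e-10)
      expect_equal(est3$delta2_star[i, g],
                   sum(w * std3$delta2_hat[i, ]), tolerance = 1e-10)
    }
  }
})

test_that("nonparametric and parametric posteriors agree on Gaussian data", {
  # under Gaussian batch effects both EB flavours estimate the same
  # posterior mean; with many features the median gap is small
  set.seed(43)
  g <- 200
  n_i <- c(25, 30)
  gamma_true <- rbind(rnorm(g, 0.8, 0.4), rnorm(g, -0.6, 0.4))
  y <- matrix(rnorm(sum(n_i) * g), sum(n_i), g)
  y[1:25, ] <- y[1:25, ] + matrix(gamma_true[1, ], 25, g, byrow = TRUE)
  y[26:55, ] <- y[26:55, ] + matrix(gamma_true[2, ], 30, g, byrow = TRUE)
  std <- std_of(y, rep(1:2, n_i))
  par <- combat_estimate_parametric_eb(std, tol = 1e-10, max_iter = 2000)
  np <- combat_estimate_nonparametric_eb(std)
  expect_lt(median(abs(par$gamma_star - np$gamma_star)), 0.1)
})

test_that("our nonparametric ComBat matches the reference implementation", {
  skip_if_not_installed("sva")
  set.seed(51)
  g <- 10
  y <- matrix(rnorm(30 * g), 30, g) + rep(c(0, 2, -1), c(10, 8, 12))
  batch <- rep(1:3, c(10, 8, 12))
  tab <- table_from_matrix(y, batch)
  asg <- assign_batches(tab)
  ours <- combat_harmonize(tab, asg, method = "nonparametric_eb")
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(y), batch = batch, mod = NULL, par.prior = FALSE)
  ))
  got <- as.matrix(ours$table[sprintf("F%03d", 1:g)])
  expect_equal(unname(got), unname(ref), tolerance = 1e-6)

  # parametric flavour: same fixed point up to convergence tolerance
  ours_p <- combat_harmonize(tab, asg, method = "parametric_eb",
                             config = combat_config(eb_tol = 1e-10,
                                                    eb_max_iter = 5000))
  ref_p <- t(suppressMessages(
    sva::ComBat(dat = t(y), batch = batch, mod = NULL, par.prior = TRUE)
  ))
  got_p <- as.matrix(ours_p$table[sprintf("F%03d", 1:g)])
  expect_equal(unname(got_p), unname(ref_p), tolerance = 1e-4)
})

test_that("batch relabeling permutes the model but not the output", {
  sim <- gen_feature_table(synth_design(n_features = 4, seed = 61))
  asg <- assign_batches(sim$table)
  fit1 <- combat_harmonize(sim$table, asg, method = "nonparametric_eb")
  # relabel: reverse the batch ids
  relab <- asg
  old <- relab$batches$batch_id
  newid <- rev(old)
  relab$batches$batch_id <- newid
  relab$batches <- dplyr::arrange(relab$batches, batch_id)
  relab$observations$batch_id <- newid[match(relab$observations$batch_id, old)]
  fit2 <- combat_harmonize(sim$table, relab, method = "nonparametric_eb")
  feats <- fit1$model$features
  expect_equal(fit2$table[feats], fit1$table[feats], tolerance = 1e-10)
  # each old batch's estimates reappear under its new label
  for (k in seq_along(old)) {
    o <- as.character(old[k])
    n <- as.character(newid[k])
    expect_equal(fit2$model$gamma_star[n, ], fit1$model$gamma_star[o, ],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("injected location effects are recovered on the default design", {
  sim <- gen_feature_table(synth_design(seed = 71))
  asg <- assign_batches(sim$table)
  std <- combat_standardize(sim$table, asg)
  truth <- sim$truth
  # align truth batches (generator batch ids) with assignment batch ids
  key <- unique(tibble::tibble(gen = truth$batch_id,
                               asg = with_batches(sim$table, asg)$batch_id))
  big <- asg$batches$batch_id[asg$batches$frequency >= 5]
  est <- c(); tru <- c()
  for (b in big) {
    gen_b <- key$gen[key$asg == b]
    est <- c(est, std$gamma_hat[as.character(b), ])
    tru <- c(tru, truth$gamma[gen_b, ])
  }
  expect_gte(cor(est, tru), 0.9)
})

test_that("model tidiers expose estimates and metadata", {
  sim <- gen_feature_table(synth_design(n_features = 5, seed = 81))
  asg <- assign_batches(sim$table)
  fit <- combat_harmonize(sim$table, asg)
  td <- tidy(fit$model)
  expect_equal(nrow(td), 14L * 5L)
  expect_true(all(c("gamma_hat", "gamma_star", "delta2_star") %in% names(td)))
  gl <- glance(fit$model)
  expect_equal(gl$method, "nonparametric_eb")
  expect_equal(gl$n_batches, 14L)
  # round-trip estimates: tidy values match the matrices
  row <- td[td$batch_id == td$batch_id[20] & td$feature == td$feature[20], ]
  expect_equal(row$gamma_hat,
               fit$model$gamma_hat[as.character(row$batch_id), row$feature])
  # JSON serialization runs
  p <- tempfile(fileext = ".json")
  write_model_json(fit$model, p)
  expect_true(jsonlite::validate(readChar(p, file.size(p))))
})
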