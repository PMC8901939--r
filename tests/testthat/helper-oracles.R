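# Brute-force oracles, deliberately written as plain loops over voxels /
# matrix cells so they share no code path with the package implementations.

oracle_dirs13 <- function() {
  dirs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    nz <- v[v != 0]
    if (nz[1] > 0) dirs[[length(dirs) + 1]] <- v
  }
  dirs
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric pooled GLCM by voxel-pair enumeration
oracle_glcm <- function(L) {
  d <- dim(L)
  lv <- sort(unique(L[!is.na(L)]))
  m <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- L[x, y, z]
    if (is.na(a)) next
    for (dir in oracle_dirs13()) {
      q <- c(x, y, z) + dir
      if (!in_grid(q, d)) next
      b <- L[q[1], q[2], q[3]]
      if (is.na(b)) next
      i <- match(a, lv); j <- match(b, lv)
      m[i, j] <- m[i, j] + 1
      m[j, i] <- m[j, i] + 1
    }
  }
  m / sum(m)
}

# pooled GLRLM by walking each line from its run starts
oracle_glrlm <- function(L) {
  d <- dim(L)
  runs_lev <- integer(0); runs_len <- integer(0)
  for (dir in oracle_dirs13()) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- L[x, y, z]
      if (is.na(a)) next
      p_prev <- c(x, y, z) - dir
      prev <- if (in_grid(p_prev, d)) L[p_prev[1], p_prev[2], p_prev[3]] else NA
      if (!is.na(prev) && prev == a) next  # not a run start
      len <- 1L
      q <- c(x, y, z) + dir
      while (in_grid(q, d) && !is.na(L[q[1], q[2], q[3]]) &&
             L[q[1], q[2], q[3]] == a) {
        len <- len + 1L
        q <- q + dir
      }
      runs_lev <- c(runs_lev, a); runs_len <- c(runs_len, len)
    }
  }
  lv <- sort(unique(runs_lev))
  m <- matrix(0, length(lv), max(runs_len),
              dimnames = list(lv, seq_len(max(runs_len))))
  for (r in seq_along(runs_lev)) {
    m[match(runs_lev[r], lv), runs_len[r]] <-
      m[match(runs_lev[r], lv), runs_len[r]] + 1
  }
  m
}

# GLZLM via igraph connected components over the 26-neighborhood graph
oracle_glzlm <- function(L) {
  skip_if_not_installed("igraph")
  d <- dim(L)
  idx <- which(!is.na(L))
  pos <- arrayInd(idx, d)
  key <- function(p) paste(p, collapse = ",")
  lookup <- setNames(seq_along(idx), apply(pos, 1, key))
  edges <- integer(0)
  for (r in seq_along(idx)) {
    for (dir in oracle_dirs13()) {
      q <- pos[r, ] + dir
      if (!in_grid(q, d)) next
      s <- lookup[key(q)]
      if (is.na(s)) next
      if (L[idx[r]] == L[idx[s]]) edges <- c(edges, r, s)
    }
  }
  gph <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(gph)
  lev <- vapply(seq_len(comp$no),
                function(cc) L[idx[comp$membership == cc][1]], numeric(1))
  sz <- comp$csize
  lv <- sort(unique(lev))
  m <- matrix(0, length(lv), max(sz), dimnames = list(lv, seq_len(max(sz))))
  for (cc in seq_len(comp$no)) {
    m[match(lev[cc], lv), sz[cc]] <- m[match(lev[cc], lv), sz[cc]] + 1
  }
  m
}

# NGLDM summary by per-voxel neighborhood enumeration
oracle_ngldm <- function(L) {
  d <- dim(L)
  lev_all <- numeric(0); diff_all <- numeric(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- L[x, y, z]
    if (is.na(a)) next
    nb <- numeric(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!in_grid(q, d)) next
      b <- L[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    lev_all <- c(lev_all, a)
    diff_all <- c(diff_all, abs(a - mean(nb)))
  }
  lv <- sort(unique(lev_all))
  m <- cbind(n = vapply(lv, function(l) sum(lev_all == l), numeric(1)),
             s = vapply(lv, function(l) sum(diff_all[lev_all == l]), numeric(1)))
  rownames(m) <- lv
  m
}

# feature formulas re-derived with explicit cell loops
oracle_glcm_features <- function(m) {
  lv <- as.numeric(rownames(m))
  hom <- en <- con <- dis <- e10 <- e2 <- 0
  mu <- 0; s2 <- 0
  for (i in seq_along(lv)) mu <- mu + lv[i] * sum(m[i, ])
  for (i in seq_along(lv)) s2 <- s2 + (lv[i] - mu)^2 * sum(m[i, ])
  cr <- 0
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    p <- m[i, j]
    hom <- hom + p / (1 + abs(lv[i] - lv[j]))
    en <- en + p^2
    con <- con + (lv[i] - lv[j])^2 * p
    dis <- dis + abs(lv[i] - lv[j]) * p
    if (p > 0) { e10 <- e10 - p * log10(p); e2 <- e2 - p * log2(p) }
    cr <- cr + lv[i] * lv[j] * p
  }
  corr <- if (s2 > 0) (cr - mu^2) / s2 else 1
  c(hom, en, con, corr, e10, e2, dis)
}

oracle_rl_features <- function(m, n_units) {
  lv <- as.numeric(rownames(m)); ln <- as.numeric(colnames(m))
  nr <- sum(m)
  acc <- numeric(8)
  gl <- numeric(length(lv)); rl <- numeric(length(ln))
  for (i in seq_along(lv)) for (l in seq_along(ln)) {
    r <- m[i, l]
    acc <- acc + r * c(1 / ln[l]^2, ln[l]^2, 1 / lv[i]^2, lv[i]^2,
                       1 / (lv[i]^2 * ln[l]^2), lv[i]^2 / ln[l]^2,
                       ln[l]^2 / lv[i]^2, lv[i]^2 * ln[l]^2)
    gl[i] <- gl[i] + r; rl[l] <- rl[l] + r
  }
  c(acc / nr, sum(gl^2) / nr, sum(rl^2) / nr, nr / n_units)
}

oracle_ngldm_features <- function(nd) {
  lv <- as.numeric(rownames(nd))
  n_tot <- sum(nd[, "n"])
  p <- nd[, "n"] / n_tot
  ps <- sum(p * nd[, "s"])
  ng <- sum(p > 0)
  ctr <- 0; busy_den <- 0
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    ctr <- ctr + p[i] * p[j] * (lv[i] - lv[j])^2
    busy_den <- busy_den + abs(lv[i] * p[i] - lv[j] * p[j])
  }
  c(if (ps > 0) 1 / ps else 0,
    if (ng > 1) ctr / (ng * (ng - 1)) * sum(nd[, "s"]) / n_tot else 0,
    if (busy_den > 0) ps / busy_den else 0)
}

oracle_histo_features <- function(levels_vec) {
  x <- levels_vec
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  if (m2 > 0) {
    sk <- m3 / m2^1.5; ku <- m4 / m2^2; ek <- ku - 3
  } else sk <- ku <- ek <- 0
  ux <- sort(unique(x))
  p <- vapply(ux, function(u) sum(x == u) / n, numeric(1))
  c(sk, ku, ek, -sum(p * log10(p)), -sum(p * log2(p)), sum(p^2))
}

oracle_shape_features <- function(mask, spacing) {
  d <- dim(mask)
  n_vox <- sum(mask)
  vol <- n_vox * prod(spacing)
  area <- 0
  faces <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  fa <- c(spacing[2] * spacing[3], spacing[2] * spacing[3],
          spacing[1] * spacing[3], spacing[1] * spacing[3],
          spacing[1] * spacing[2], spacing[1] * spacing[2])
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    for (f in 1:6) {
      q <- c(x, y, z) + faces[f, ]
      outside <- !in_grid(q, d) || !mask[q[1], q[2], q[3]]
      if (outside) area <- area + fa[f]
    }
  }
  c(vol / 1000, n_vox, pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    vol / (sqrt(pi) * area^1.5))
}

# independent damped fixed-point solver for the parametric-EB posterior
oracle_eb_fixed_point <- function(zi, g_hat, d2_hat, g_bar, tau2,
                                  lambda, theta, tol = 1e-10) {
  n_i <- nrow(zi)
  g_star <- g_hat; d2_star <- d2_hat
  for (it in 1:10000) {
    g_new <- (n_i * tau2 * g_hat + d2_star * g_bar) / (n_i * tau2 + d2_star)
    sum2 <- vapply(seq_along(g_new),
                   function(g) sum((zi[, g] - g_new[g])^2), numeric(1))
    d2_new <- (theta + 0.5 * sum2) / (n_i / 2 + lambda - 1)
    g_damp <- 0.5 * g_star + 0.5 * g_new
    d2_damp <- 0.5 * d2_star + 0.5 * d2_new
    if (max(abs(g_damp - g_star), abs(d2_damp - d2_star)) < tol) {
      return(list(gamma_star = g_damp, delta2_star = d2_damp))
    }
    g_star <- g_damp; d2_star <- d2_damp
  }
  stop("oracle solver did not converge")
}

# hand rank-formula Kruskal-Wallis H with tie correction
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  gl <- unique(groups)
  h <- 0
  for (g in gl) {
    rg <- r[groups == g]
    h <- h + sum(rg)^2 / length(rg)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# discretize a gray_volume by the direct formula (for pipeline oracle)
oracle_discretize <- function(vol, mask, min_hu = -1000, max_hu = 3000,
                              n_bins = 400) {
  w <- (max_hu - min_hu) / n_bins
  L <- floor((vol - min_hu) / w) + 1
  L[vol == max_hu] <- n_bins
  L <- pmin(pmax(L, 1), n_bins)
  L[!mask] <- NA
  array(L, dim(vol))
}

# small synthetic feature table with effects only through kvp
kvp_effect_table <- function(n_per_level = 30, seed = 5) {
  set.seed(seed)
  kvp <- rep(c(100, 120, 130), each = n_per_level)
  n <- length(kvp)
  tibble::tibble(
    obs_id = sprintf("o%03d", seq_len(n)),
    patient_id = sprintf("P%02d", seq_len(n) %% 10 + 1),
    lesion_id = sprintf("L%03d", seq_len(n)),
    timepoint = "baseline",
    scanner = sample(c("A", "B"), n, replace = TRUE),
    kvp = kvp,
    kernel = sample(c("B30f", "FC08"), n, replace = TRUE),
    exposure_time_ms = sample(c(350, 500), n, replace = TRUE),
    tube_current_ma = runif(n, 56, 581),
    contrast_agent = NA_character_,
    slice_thickness_mm = 1,
    FA = rnorm(n) + 2 * (kvp == 100) - 1.5 * (kvp == 130),
    FB = rnorm(n) + 1.0 * (kvp == 120),
    FC = rnorm(n) - 2 * (kvp == 100)
  )
}

# one-row-per-lesion table following the reference protocol profile
profile_table <- function(profile = ct_protocol_profile()) {
  rows <- profile[rep(seq_len(nrow(profile)), profile$frequency), ]
  n <- nrow(rows)
  tibble::tibble(
    obs_id = sprintf("o%03d", seq_len(n)),
    patient_id = sprintf("P%02d", ((seq_len(n) - 1) %% 23) + 1),
    lesion_id = sprintf("L%03d", seq_len(n)),
    timepoint = "baseline",
    kernel = rows$kernel,
    kvp = rows$kvp,
    FA = seq_len(n) / 10
  )
}
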