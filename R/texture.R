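# Gray-level texture matrices in 3D.
#
# All builders take a `gray_volume` (integer levels inside the ROI, NA
# outside) and work on the actual discretized level values, not compressed
# ranks: matrices are indexed by the levels present, with dimnames carrying
# the level values used by the feature formulas.

# the 13 unique 3D directions (26-neighborhood up to sign)
directions13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  unname(d[keep, , drop = FALSE])
}

check_roi_size <- function(gray, min_voxels = 64L) {
  n <- sum(!is.na(gray$levels))
  if (n < min_voxels) {
    abort(paste0("ROI has ", n, " voxels; at least ", min_voxels,
                 " are required for extraction"))
  }
  n
}

# slice index ranges so that src + offset stays in bounds
offset_ranges <- function(d, off) {
  lapply(1:3, function(a) seq(max(1L, 1L - off[a]), min(d[a], d[a] - off[a])))
}

#' Build the pooled gray-level co-occurrence matrix (GLCM)
#'
#' Co-occurrences of in-ROI gray-level pairs at Chebyshev distance 1 are
#' counted symmetrically over the 13 unique 3D directions, pooled into a
#' single matrix and normalized to sum 1. Rows/columns are the gray levels
#' present in the ROI (dimnames carry the level values).
#'
#' @param gray A `gray_volume` from [discretize_absolute()].
#' @param min_voxels Minimum in-ROI voxel count (default 64).
#' @return Normalized symmetric matrix with attribute `n_pairs` (raw count).
#' @export
build_glcm <- function(gray, min_voxels = 64L) {
  check_roi_size(gray, min_voxels)
  L <- gray$levels
  d <- dim(L)
  lv <- sort(unique(L[!is.na(L)]))
  p <- length(lv)
  code <- array(match(L, lv), d)
  counts <- numeric(p * p)
  for (k in seq_len(nrow(directions13()))) {
    off <- directions13()[k, ]
    rg <- offset_ranges(d, off)
    a <- code[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
    b <- code[rg[[1]] + off[1], rg[[2]] + off[2], rg[[3]] + off[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- counts + tabulate((a[ok] - 1L) * p + b[ok], p * p) +
      tabulate((b[ok] - 1L) * p + a[ok], p * p)
  }
  m <- matrix(counts, p, p, dimnames = list(lv, lv))
  total <- sum(m)
  out <- if (total > 0) m / total else m
  attr(out, "n_pairs") <- total
  out
}

#' Build the pooled gray-level run-length matrix (GLRLM)
#'
#' Maximal runs of equal gray level are enumerated along each of the 13
#' unique 3D directions (runs break at ROI boundaries) and pooled into one
#' counts matrix: rows are the gray levels present, columns run lengths
#' 1..max.
#'
#' @inheritParams build_glcm
#' @return Counts matrix with attributes `n_runs` and `n_directions`.
#' @export
build_glrlm <- function(gray, min_voxels = 64L) {
  check_roi_size(gray, min_voxels)
  L <- gray$levels
  d <- dim(L)
  n <- length(L)
  ix <- ((seq_len(n) - 1L) %% d[1]) + 1L
  iy <- (((seq_len(n) - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((seq_len(n) - 1L) %/% (d[1] * d[2])) + 1L
  big <- as.numeric(max(d) + 2L)  # double keys avoid integer overflow
  levels_all <- integer(0)
  lengths_all <- integer(0)
  dirs <- directions13()
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    # step parameter increases by 1 per move along the direction
    t <- if (off[1] == 1L) ix else if (off[2] == 1L) iy else iz
    a1 <- ix - t * off[1]
    a2 <- iy - t * off[2]
    a3 <- iz - t * off[3]
    key <- (a1 + big) + (a2 + 3L * big) * (5L * big) +
      (a3 + 3L * big) * (25L * big * big)
    ord <- order(key, t)
    lv <- as.vector(L)[ord]
    kk <- key[ord]
    newline <- c(TRUE, kk[-1] != kk[-n])
    prev <- c(NA_integer_, lv[-n])
    change <- newline | (is.na(lv) != is.na(prev)) |
      (!is.na(lv) & !is.na(prev) & lv != prev)
    run_id <- cumsum(change)
    first <- !duplicated(run_id)
    run_lev <- lv[first]
    run_len <- tabulate(run_id, max(run_id))
    keep <- !is.na(run_lev)
    levels_all <- c(levels_all, run_lev[keep])
    lengths_all <- c(lengths_all, run_len[keep])
  }
  lv <- sort(unique(levels_all))
  maxlen <- max(lengths_all)
  m <- matrix(0, length(lv), maxlen, dimnames = list(lv, seq_len(maxlen)))
  idx <- cbind(match(levels_all, lv), lengths_all)
  for (r in seq_len(nrow(idx))) m[idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + 1
  attr(m, "n_runs") <- sum(m)
  attr(m, "n_directions") <- nrow(dirs)
  m
}

#' Build the gray-level zone-length matrix (GLZLM)
#'
#' Zones are 26-connected components of equal gray level inside the ROI;
#' the matrix counts zones by (level, zone size).
#'
#' @inheritParams build_glcm
#' @return Counts matrix with attribute `n_zones`.
#' @export
build_glzlm <- function(gray, min_voxels = 64L) {
  check_roi_size(gray, min_voxels)
  zones <- label_zones(gray$levels)
  lv <- sort(unique(zones$level))
  maxsz <- max(zones$size)
  m <- matrix(0, length(lv), maxsz, dimnames = list(lv, seq_len(maxsz)))
  for (r in seq_along(zones$level)) {
    i <- match(zones$level[r], lv)
    m[i, zones$size[r]] <- m[i, zones$size[r]] + 1
  }
  attr(m, "n_zones") <- sum(m)
  m
}

# 26-connected flood fill over equal-level in-ROI voxels;
# returns per-zone level and size
label_zones <- function(L) {
  d <- dim(L)
  n <- length(L)
  offs <- directions13()
  offs <- rbind(offs, -offs)  # full 26-neighborhood
  # distinct linear shifts (offsets alias when an axis has length 1)
  lin_off <- unique(offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2])
  ix <- ((seq_len(n) - 1L) %% d[1]) + 1L
  iy <- (((seq_len(n) - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((seq_len(n) - 1L) %/% (d[1] * d[2])) + 1L
  visited <- is.na(as.vector(L))
  Lv <- as.vector(L)
  zone_level <- integer(0)
  zone_size <- integer(0)
  for (seed in which(!visited)) {
    if (visited[seed]) next
    lev <- Lv[seed]
    stack <- seed
    visited[seed] <- TRUE
    size <- 0L
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      w <- v + lin_off
      okb <- abs(ix[pmin(pmax(w, 1L), n)] - ix[v]) <= 1L &
        abs(iy[pmin(pmax(w, 1L), n)] - iy[v]) <= 1L &
        abs(iz[pmin(pmax(w, 1L), n)] - iz[v]) <= 1L &
        w >= 1L & w <= n
      w <- w[okb]
      w <- w[!visited[w] & Lv[w] == lev]
      if (length(w) > 0L) {
        visited[w] <- TRUE
        stack <- c(stack, w)
      }
    }
    zone_level <- c(zone_level, lev)
    zone_size <- c(zone_size, size)
  }
  list(level = zone_level, size = zone_size)
}

#' Build the neighborhood gray-level difference summary (NGLDM)
#'
#' For every in-ROI voxel the 26-neighborhood (restricted to in-ROI
#' neighbors) is summarized: per gray level `i`, `n_i` counts voxels of
#' level `i` with at least one in-ROI neighbor and `s_i` accumulates
#' `|i - mean(neighbor levels)|` over those voxels.
#'
#' @inheritParams build_glcm
#' @return A matrix with one row per present level and columns `n` and `s`;
#'   attribute `n_voxels` is the total of `n`.
#' @export
build_ngldm <- function(gray, min_voxels = 64L) {
  check_roi_size(gray, min_voxels)
  L <- gray$levels
  d <- dim(L)
  present <- !is.na(L)
  V <- L
  V[!present] <- 0L
  sumN <- array(0, d)
  cntN <- array(0, d)
  offs <- directions13()
  offs <- rbind(offs, -offs)
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    rg <- offset_ranges(d, off)
    dst <- lapply(1:3, function(a) rg[[a]] + off[a])
    sumN[rg[[1]], rg[[2]], rg[[3]]] <-
      sumN[rg[[1]], rg[[2]], rg[[3]]] +
      V[dst[[1]], dst[[2]], dst[[3]]]
    cntN[rg[[1]], rg[[2]], rg[[3]]] <-
      cntN[rg[[1]], rg[[2]], rg[[3]]] +
      present[dst[[1]], dst[[2]], dst[[3]]]
  }
  use <- present & cntN > 0
  lev <- L[use]
  diffs <- abs(lev - sumN[use] / cntN[use])
  lv <- sort(unique(lev))
  n_i <- tabulate(match(lev, lv), length(lv))
  s_i <- vapply(seq_along(lv), function(i) sum(diffs[lev == lv[i]]), numeric(1))
  m <- cbind(n = n_i, s = s_i)
  rownames(m) <- lv
  attr(m, "n_voxels") <- sum(n_i)
  m
}
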