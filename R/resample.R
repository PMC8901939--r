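#' Resample a volume and mask to isotropic voxels
#'
#' Resamples the HU volume to a fixed isotropic voxel size (default
#' 1 x 1 x 1 mm) by trilinear interpolation; the ROI mask is resampled by
#' nearest-neighbor lookup and re-binarized. The output grid starts at the
#' first input voxel center and covers the input physical extent
#' (`n_out = floor((n - 1) * spacing / target) + 1` per axis), so a volume
#' already at the target spacing is returned unchanged.
#'
#' @param volume A [voxel_volume()].
#' @param mask A [roi_mask()] on the same grid.
#' @param target_mm Target isotropic spacing in mm (default 1).
#' @return A list with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, target_mm = 1.0) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "roi_mask"))
  d <- dim(volume$values)
  if (!identical(d, dim(mask$mask))) abort("volume and mask grids differ")
  if (any(d < 2L)) {
    abort("3D extraction requires >= 2 voxels per axis; got a degenerate axis")
  }
  check_positive(target_mm, "target_mm")
  sp <- volume$spacing
  # continuous input index coordinates (1-based) of the output voxel centers
  coords <- lapply(1:3, function(a) {
    n_out <- floor((d[a] - 1) * sp[a] / target_mm) + 1
    (seq_len(n_out) - 1) * target_mm / sp[a] + 1
  })
  vol_out <- trilinear_interp(volume$values, coords)
  # nearest neighbour for the mask, then re-binarize
  nn <- lapply(1:3, function(a) pmin(pmax(round(coords[[a]]), 1L), d[a]))
  mask_out <- mask$mask[as.matrix(expand.grid(nn[[1]], nn[[2]], nn[[3]]))]
  dim(mask_out) <- lengths(coords)
  list(volume = voxel_volume(vol_out, rep(target_mm, 3), volume$origin),
       mask = roi_mask(mask_out, rep(target_mm, 3)))
}

# vectorized trilinear interpolation of arr at the grid spanned by coords
# (list of per-axis continuous 1-based indices); edge-clamped
trilinear_interp <- function(arr, coords) {
  d <- dim(arr)
  lo <- lapply(1:3, function(a) pmin(pmax(floor(coords[[a]]), 1L), d[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
  fr <- lapply(1:3, function(a) coords[[a]] - lo[[a]])
  n <- lengths(coords)
  out <- array(0, n)
  grid <- expand.grid(gx = 0:1, gy = 0:1, gz = 0:1)
  for (k in seq_len(nrow(grid))) {
    ix <- if (grid$gx[k] == 0) lo[[1]] else hi[[1]]
    iy <- if (grid$gy[k] == 0) lo[[2]] else hi[[2]]
    iz <- if (grid$gz[k] == 0) lo[[3]] else hi[[3]]
    wx <- if (grid$gx[k] == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (grid$gy[k] == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (grid$gz[k] == 0) 1 - fr[[3]] else fr[[3]]
    vals <- arr[as.matrix(expand.grid(ix, iy, iz))]
    dim(vals) <- n
    w <- outer(outer(wx, wy), wz)
    out <- out + vals * w
  }
  out
}

#' Discretization configuration
#'
#' Absolute gray-level discretization settings: HU values are binned into
#' `n_bins` equal-width, half-open bins `[lo, hi)` spanning
#' `[min_hu, max_hu]`, with the top edge closed. The defaults
#' (-1000 to 3000 HU, 400 bins) give a 10 HU bin width.
#'
#' @param min_hu,max_hu HU range (`max_hu > min_hu`).
#' @param n_bins Number of bins (>= 2).
#' @return A list of class `discretization_config` with an extra
#'   `bin_width` element.
#' @export
discretization_config <- function(min_hu = -1000, max_hu = 3000, n_bins = 400L) {
  if (max_hu <= min_hu) abort("`max_hu` must exceed `min_hu`")
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  structure(list(min_hu = min_hu, max_hu = max_hu, n_bins = as.integer(n_bins),
                 bin_width = (max_hu - min_hu) / n_bins),
            class = "discretization_config")
}

#' Absolute gray-level discretization
#'
#' Maps in-ROI HU values to integer gray levels 1..`n_bins` with the rule
#' `level = floor((v - min_hu) / bin_width) + 1`, clamped to `[1, n_bins]`
#' (so `v = max_hu` maps to `n_bins`, and out-of-range HU are clamped to
#' the boundary levels rather than rejected). The number of clamped voxels
#' is recorded in the `n_clamped` attribute and reported as a message.
#'
#' @param volume A [voxel_volume()].
#' @param mask A [roi_mask()] on the same grid.
#' @param cfg A [discretization_config()].
#' @return An object of class `gray_volume`: integer levels inside the ROI
#'   (`NA` outside), plus the mask, spacing and `n_bins`.
#' @export
discretize_absolute <- function(volume, mask, cfg = discretization_config()) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "roi_mask"),
            inherits(cfg, "discretization_config"))
  if (!identical(dim(volume$values), dim(mask$mask))) {
    abort("volume and mask grids differ")
  }
  v <- volume$values
  lev <- floor((v - cfg$min_hu) / cfg$bin_width) + 1
  lev[v == cfg$max_hu] <- cfg$n_bins  # top edge closed
  n_clamped <- sum((lev[mask$mask] < 1) | (lev[mask$mask] > cfg$n_bins))
  lev <- pmin(pmax(lev, 1), cfg$n_bins)
  lev[!mask$mask] <- NA_integer_
  if (n_clamped > 0) {
    inform(paste0(n_clamped, " in-ROI voxels outside [", cfg$min_hu, ", ",
                  cfg$max_hu, "] HU were clamped"))
  }
  structure(list(levels = array(as.integer(lev), dim(v)),
                 mask = mask$mask, spacing = volume$spacing,
                 n_bins = cfg$n_bins),
            class = "gray_volume", n_clamped = n_clamped)
}
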