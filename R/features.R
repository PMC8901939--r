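# The 42 radiomic features (shape, discretized histogram, GLCM, GLRLM,
# NGLDM, GLZLM), computed from the matrices built in texture.R. Degenerate
# conventions (single gray level, texture-free ROI) are chosen so that
# valid input never yields NaN: GLCM correlation of a single-level ROI is
# 1, histogram skewness/kurtosis of a zero-variance ROI are 0, and NGLDM
# coarseness/busyness/contrast of a texture-free ROI are 0.

#' Shape features of an ROI mask
#'
#' Volume in mL and voxels, plus sphericity and compacity computed from the
#' exposed-voxel-face surface estimate: every face between an in-mask voxel
#' and a non-mask (or out-of-grid) voxel contributes its physical area.
#' Sphericity is \eqn{\pi^{1/3} (6V)^{2/3} / A} (1 for a perfect sphere);
#' compacity is \eqn{V / (\sqrt{\pi} A^{3/2})}.
#'
#' @param mask A [roi_mask()].
#' @param spacing Optional spacing override (mm per axis).
#' @return Named numeric vector of the four `SHAPE_*` features.
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  sp <- spacing %||% mask$spacing
  m <- mask$mask
  d <- dim(m)
  n_vox <- sum(m)
  vox_vol <- prod(sp)
  volume_mm3 <- n_vox * vox_vol
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  for (a in 1:3) {
    pad_dim <- d
    pad_dim[a] <- d[a] + 2L
    padded <- array(FALSE, pad_dim)
    idx <- lapply(1:3, function(b) seq_len(d[b]))
    idx[[a]] <- idx[[a]] + 1L
    padded[idx[[1]], idx[[2]], idx[[3]]] <- m
    lo <- idx
    lo[[a]] <- lo[[a]] - 1L
    hi <- idx
    hi[[a]] <- hi[[a]] + 1L
    exposed <- sum(m & !padded[lo[[1]], lo[[2]], lo[[3]]]) +
      sum(m & !padded[hi[[1]], hi[[2]], hi[[3]]])
    area <- area + exposed * face_area[a]
  }
  sphericity <- pi^(1 / 3) * (6 * volume_mm3)^(2 / 3) / area
  compacity <- volume_mm3 / (sqrt(pi) * area^1.5)
  c(SHAPE_Volume_mL = volume_mm3 / 1000,
    SHAPE_Volume_voxels = as.numeric(n_vox),
    SHAPE_Sphericity = sphericity,
    SHAPE_Compacity = compacity)
}

#' First-order features of the discretized in-ROI histogram
#'
#' Skewness, kurtosis (and excess kurtosis), entropies (log10 and log2) and
#' energy computed on the distribution of discretized gray levels inside
#' the ROI. Moments are population moments; entropy/energy sum over
#' occupied bins.
#'
#' @param gray A `gray_volume`.
#' @return Named numeric vector of the six `DISCRETIZED_HISTO_*` features.
#' @export
histo_features <- function(gray) {
  x <- gray$levels[!is.na(gray$levels)]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
    exkurt <- kurt - 3
  } else {
    skew <- kurt <- exkurt <- 0
  }
  p <- tabulate(match(x, sort(unique(x)))) / n
  c(DISCRETIZED_HISTO_Skewness = skew,
    DISCRETIZED_HISTO_Kurtosis = kurt,
    DISCRETIZED_HISTO_ExcessKurtosis = exkurt,
    DISCRETIZED_HISTO_Entropy_log10 = -sum(p * log10(p)),
    DISCRETIZED_HISTO_Entropy_log2 = -sum(p * log2(p)),
    DISCRETIZED_HISTO_Energy = sum(p^2))
}

glcm_features <- function(m) {
  lv <- as.numeric(rownames(m))
  i <- matrix(lv, length(lv), length(lv))
  j <- t(i)
  pm <- rowSums(m)
  mu <- sum(lv * pm)
  s2 <- sum((lv - mu)^2 * pm)
  corr <- if (s2 > 0) (sum(i * j * m) - mu^2) / s2 else 1
  pos <- m[m > 0]
  c(GLCM_Homogeneity = sum(m / (1 + abs(i - j))),
    GLCM_Energy = sum(m^2),
    GLCM_Contrast = sum((i - j)^2 * m),
    GLCM_Correlation = corr,
    GLCM_Entropy_log10 = -sum(pos * log10(pos)),
    GLCM_Entropy_log2 = -sum(pos * log2(pos)),
    GLCM_Dissimilarity = sum(abs(i - j) * m))
}

# shared run-length / zone-length feature kernel; prefix selects naming
rl_features <- function(m, n_units, prefix, emphasis_names) {
  lv <- as.numeric(rownames(m))
  ln <- as.numeric(colnames(m))
  i <- matrix(lv, length(lv), length(ln))
  l <- matrix(ln, length(lv), length(ln), byrow = TRUE)
  nr <- sum(m)
  f <- c(
    sum(m / l^2) / nr,            # short emphasis
    sum(m * l^2) / nr,            # long emphasis
    sum(m / i^2) / nr,            # low gray-level
    sum(m * i^2) / nr,            # high gray-level
    sum(m / (i^2 * l^2)) / nr,    # short + low
    sum(m * i^2 / l^2) / nr,      # short + high
    sum(m * l^2 / i^2) / nr,      # long + low
    sum(m * i^2 * l^2) / nr,      # long + high
    sum(rowSums(m)^2) / nr,       # gray-level non-uniformity
    sum(colSums(m)^2) / nr,       # length non-uniformity
    nr / n_units                  # run/zone percentage
  )
  setNames(f, paste0(prefix, "_", emphasis_names))
}

glrlm_features <- function(m, n_voxels) {
  rl_features(m, n_units = attr(m, "n_directions") * n_voxels, "GLRLM",
              c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE",
                "LRLGE", "LRHGE", "GLNU", "RLNU", "RP"))
}

glzlm_features <- function(m, n_voxels) {
  rl_features(m, n_units = n_voxels, "GLZLM",
              c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                "LZLGE", "LZHGE", "GLNU", "ZLNU", "ZP"))
}

ngldm_features <- function(nd) {
  lv <- as.numeric(rownames(nd))
  n_i <- nd[, "n"]
  s_i <- nd[, "s"]
  n_tot <- sum(n_i)
  p_i <- n_i / n_tot
  ps <- sum(p_i * s_i)
  ng <- sum(p_i > 0)
  coarseness <- if (ps > 0) 1 / ps else 0
  contrast <- if (ng > 1) {
    (sum(outer(p_i, p_i) * outer(lv, lv, "-")^2) / (ng * (ng - 1))) *
      (sum(s_i) / n_tot)
  } else 0
  busy_den <- sum(abs(outer(lv * p_i, lv * p_i, "-")))
  busyness <- if (busy_den > 0) ps / busy_den else 0
  c(NGLDM_Coarseness = coarseness,
    NGLDM_Contrast = contrast,
    NGLDM_Busyness = busyness)
}

#' Texture features from pre-built matrices
#'
#' @param glcm,glrlm,glzlm,ngldm Matrices from the corresponding builders.
#' @param n_voxels In-ROI voxel count (needed for run/zone percentages).
#' @return Named numeric vector of the 7 + 11 + 3 + 11 texture features.
#' @export
texture_features <- function(glcm, glrlm, ngldm, glzlm, n_voxels) {
  c(glcm_features(glcm),
    glrlm_features(glrlm, n_voxels),
    ngldm_features(ngldm),
    glzlm_features(glzlm, n_voxels))
}

#' Extraction configuration
#'
#' @param target_mm Isotropic resampling target (mm); `NA` disables
#'   resampling (the volume must then already be isotropic).
#' @param discretization A [discretization_config()].
#' @param min_voxels Minimum in-ROI voxel count after resampling.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(target_mm = 1.0,
                              discretization = discretization_config(),
                              min_voxels = 64L) {
  structure(list(target_mm = target_mm, discretization = discretization,
                 min_voxels = as.integer(min_voxels)),
            class = "extraction_config")
}

#' Extract the 42 radiomic features from a volume and ROI
#'
#' Full 3D extraction pipeline: isotropic resampling (trilinear for HU,
#' nearest-neighbor for the mask), absolute gray-level discretization,
#' texture-matrix construction, then all 42 registry features. Deterministic;
#' rejects ROIs below the minimum voxel count.
#'
#' @param volume A [voxel_volume()].
#' @param mask A [roi_mask()] on the same grid.
#' @param config An [extraction_config()].
#' @return A one-row tibble with the 42 feature columns in registry order.
#' @examples
#' ph <- gen_phantom_volume("noisy_sphere", size = 9, seed = 3)
#' extract_all(ph$volume, ph$mask)
#' @export
extract_all <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  if (!is.na(config$target_mm)) {
    rs <- resample_isotropic(volume, mask, config$target_mm)
    volume <- rs$volume
    mask <- rs$mask
  }
  n_vox <- sum(mask$mask)
  if (n_vox < config$min_voxels) {
    abort(paste0("ROI has ", n_vox, " voxels after resampling; at least ",
                 config$min_voxels, " are required"))
  }
  gray <- discretize_absolute(volume, mask, config$discretization)
  vals <- c(
    shape_features(mask),
    histo_features(gray),
    texture_features(build_glcm(gray, config$min_voxels),
                     build_glrlm(gray, config$min_voxels),
                     build_ngldm(gray, config$min_voxels),
                     build_glzlm(gray, config$min_voxels),
                     n_voxels = n_vox)
  )
  reg <- feature_registry()$name
  stopifnot(setequal(names(vals), reg))
  tibble::as_tibble(as.list(vals[reg]))
}
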