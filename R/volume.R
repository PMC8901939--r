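#' Construct a voxel volume
#'
#' A minimal container for a 3D CT volume: an array of Hounsfield-Unit
#' values plus physical voxel spacing (mm per axis) and an origin offset.
#'
#' @param values 3D numeric array of HU values (finite).
#' @param spacing Numeric length-3, mm per axis, all > 0.
#' @param origin Numeric length-3, mm; position of the first voxel center.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array")
  }
  if (any(!is.finite(values))) abort("`values` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm)")
  }
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' Construct an ROI mask
#'
#' Binary region-of-interest mask on the same grid as its volume. Extraction
#' requires at least 64 in-mask voxels; smaller masks are allowed here but
#' will be rejected by the feature extractor.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param spacing Numeric length-3, mm per axis.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, spacing = c(1, 1, 1)) {
  if (!is.array(mask) || length(dim(mask)) != 3L) abort("`mask` must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (any(is.na(mask))) abort("`mask` must be binary (0/1)")
  structure(list(mask = mask, spacing = as.numeric(spacing)),
            class = "roi_mask")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$values), collapse = "x"),
      " voxels, spacing ", paste(x$spacing, collapse = "x"), " mm, HU range [",
      round(min(x$values), 1), ", ", round(max(x$values), 1), "]\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$mask), collapse = "x"),
      " voxels, ", sum(x$mask), " in mask\n", sep = "")
  invisible(x)
}

#' Read / write volumes and masks as NIfTI
#'
#' Volumes are stored as floating-point HU with spacing in the header;
#' masks as unsigned 8-bit 0/1.
#'
#' @param x A [voxel_volume()] or [roi_mask()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `write_*` return `path` invisibly; `read_*` return the object.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "voxel_volume"))
  img <- RNifti::asNifti(x$values)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim(img)[1:3]),
               spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname nifti_io
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(x$mask), dim(x$mask)))
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3])
}

#' Generate a digital phantom volume and ROI mask
#'
#' Tiny deterministic 3D phantoms used to exercise the feature-extraction
#' pipeline: `uniform` (constant HU, cuboid ROI), `sphere` (digital ball
#' ROI in a two-level background/foreground volume), `checkerboard`
#' (alternating two HU levels by voxel parity, cuboid ROI) and
#' `noisy_sphere` (ball ROI with Gaussian HU noise). Masks smaller than 64
#' voxels are allowed but flagged with a warning, since extraction rejects
#' them.
#'
#' @param kind One of `"uniform"`, `"sphere"`, `"checkerboard"`,
#'   `"noisy_sphere"`.
#' @param size Voxels per axis (scalar or length-3); sphere kinds require
#'   >= 4 per axis.
#' @param spacing mm per axis.
#' @param hu Foreground HU level (`uniform`, sphere kinds).
#' @param hu_background Background HU level.
#' @param levels Two HU levels for `checkerboard`.
#' @param noise_sd Gaussian HU noise SD for `noisy_sphere`.
#' @param radius Ball radius in voxels for sphere kinds (default: largest
#'   ball fitting the grid with a 1-voxel margin).
#' @param seed Seed for the noise stream.
#' @return A list with `volume` ([voxel_volume()]) and `mask`
#'   ([roi_mask()]); the in-mask voxel count is attached as attribute
#'   `n_voxels`.
#' @examples
#' ph <- gen_phantom_volume("sphere", size = 9)
#' sum(ph$mask$mask)
#' @export
gen_phantom_volume <- function(kind = c("uniform", "sphere", "checkerboard",
                                        "noisy_sphere"),
                               size = 8, spacing = c(1, 1, 1),
                               hu = 50, hu_background = -1000,
                               levels = c(-50, 50), noise_sd = 20,
                               radius = NULL, seed = 1L) {
  kind <- match.arg(kind)
  size <- rep_len(as.integer(size), 3L)
  if (kind %in% c("sphere", "noisy_sphere") && any(size < 4L)) {
    abort("sphere phantoms require `size` >= 4 per axis")
  }
  vol <- array(hu_background, size)
  if (kind %in% c("uniform", "checkerboard")) {
    mask <- array(TRUE, size)
    if (kind == "uniform") {
      vol[] <- hu
    } else {
      idx <- expand.grid(x = seq_len(size[1]), y = seq_len(size[2]),
                         z = seq_len(size[3]))
      vol[] <- ifelse((idx$x + idx$y + idx$z) %% 2 == 0, levels[1], levels[2])
    }
  } else {
    ctr <- (size + 1) / 2
    r <- radius %||% (min(size) / 2 - 1)
    idx <- expand.grid(x = seq_len(size[1]), y = seq_len(size[2]),
                       z = seq_len(size[3]))
    inside <- (idx$x - ctr[1])^2 + (idx$y - ctr[2])^2 + (idx$z - ctr[3])^2 <= r^2
    mask <- array(inside, size)
    vol[mask] <- hu
    if (kind == "noisy_sphere") {
      vol <- vol + with_seed(seed, array(rnorm(prod(size), 0, noise_sd), size))
    }
  }
  n_vox <- sum(mask)
  if (n_vox < 64L) {
    warn(paste0("phantom ROI has ", n_vox,
                " voxels (< 64); feature extraction will reject it"))
  }
  out <- list(volume = voxel_volume(vol, spacing),
              mask = roi_mask(mask, spacing))
  attr(out, "n_voxels") <- n_vox
  out
}
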