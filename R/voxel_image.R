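#' Voxel image container
#'
#' A minimal 3D scalar grid with isotropic spacing, used for activity maps
#' (kBq/ml) and SUV images. Voxel centres sit at
#' `origin + (index - 0.5) * spacing` along each axis (1-based indices), so
#' `origin` is the world coordinate of the grid's lower corner.
#'
#' @param values 3D numeric array of non-negative values.
#' @param spacing voxel edge length in mm (isotropic scalar or length-3).
#' @param origin world coordinate (mm) of the lower grid corner.
#' @param unit `"kBq/ml"` or `"SUV"`.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(values, spacing, origin = NULL, unit = "kBq/ml") {
  if (length(dim(values)) != 3L) stopf("`values` must be a 3D array")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stopf("spacing must be positive")
  if (length(unique(spacing)) != 1L) stopf("spacing must be isotropic")
  if (any(values < 0, na.rm = TRUE)) stopf("image values must be non-negative")
  if (is.null(origin)) origin <- -dim(values) * spacing / 2
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         unit = unit),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_image> %d x %d x %d voxels @ %.4g mm [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$unit))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Binary volume-of-interest mask
#'
#' A boolean grid aligned to a [voxel_image()]. `volume_ml` is by definition
#' `voxel_count * spacing^3 / 1000`.
#'
#' @param values 3D logical array.
#' @param spacing,origin grid geometry, shared with the source image.
#' @param allow_empty permit an all-`FALSE` mask.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, spacing, origin = NULL, allow_empty = FALSE) {
  if (length(dim(values)) != 3L) stopf("`values` must be a 3D array")
  storage.mode(values) <- "logical"
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (is.null(origin)) origin <- -dim(values) * spacing / 2
  n <- sum(values)
  if (n == 0L && !allow_empty) stopf("mask is empty")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         voxel_count = n,
         volume_ml = n * prod(spacing) / 1000),
    class = "voi_mask"
  )
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %d voxels, %.3f ml @ %.4g mm\n",
              x$voxel_count, x$volume_ml, x$spacing[1]))
  invisible(x)
}

#' Mask/image volume in ml
#' @param x a `voi_mask` or `voxel_image`.
#' @return volume of the mask (or full grid) in millilitres.
#' @export
volume_ml <- function(x) {
  if (inherits(x, "voi_mask")) return(x$volume_ml)
  prod(dim(x$values)) * prod(x$spacing) / 1000
}

# World coordinates of voxel centres along one axis.
axis_coords <- function(x, axis) {
  n <- dim(x$values)[axis]
  x$origin[axis] + (seq_len(n) - 0.5) * x$spacing[axis]
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Write an image or mask to NIfTI
#'
#' Writes a `.nii.gz` with an affine carrying the isotropic spacing, and a
#' JSON sidecar recording grid geometry and any provenance fields supplied.
#'
#' @param x a `voxel_image` or `voi_mask`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param sidecar named list of extra provenance fields, or `NULL` to skip
#'   the sidecar.
#' @return `path`, invisibly.
#' @export
write_voxel_nifti <- function(x, path, sidecar = list()) {
  vals <- x$values
  if (inherits(x, "voi_mask")) storage.mode(vals) <- "integer"
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) {
    meta <- c(list(spacing_mm = x$spacing, origin_mm = x$origin,
                   dim = dim(x$values),
                   unit = if (inherits(x, "voi_mask")) "mask" else x$unit),
              sidecar)
    jsonlite::write_json(meta, sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a NIfTI volume as a voxel image
#'
#' @param path NIfTI file.
#' @param unit unit tag to attach (NIfTI itself does not carry one).
#' @return a [voxel_image()].
#' @export
read_voxel_nifti <- function(path, unit = "SUV") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  voxel_image(array(as.numeric(img), dim = dim(img)), spacing = sp[1],
              origin = c(0, 0, 0), unit = unit)
}

#' Separable Gaussian blur of a voxel image
#'
#' Zero-padded separable convolution with an isotropic Gaussian of the given
#' FWHM. The discrete kernel is normalised to unit sum, so total signal is
#' conserved up to boundary truncation.
#'
#' @param img a [voxel_image()].
#' @param fwhm_mm full width at half maximum in mm; `0` returns the input.
#' @return blurred [voxel_image()].
#' @export
gaussian_blur <- function(img, fwhm_mm) {
  if (fwhm_mm < 0) stopf("psf_fwhm must be >= 0")
  if (fwhm_mm == 0) return(img)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / img$spacing[1]
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  a <- img$values
  for (axis in 1:3) a <- convolve_axis(a, k, axis)
  voxel_image(a, img$spacing, img$origin, img$unit)
}

# 1D zero-padded convolution along one axis of a 3D array.
convolve_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  dims <- dim(a)
  out <- array(0, dims)
  for (j in seq_along(k)) {
    d <- j - r - 1L
    off <- c(0L, 0L, 0L); off[axis] <- d
    ov <- shift_overlap(dims, off)
    if (is.null(ov)) next
    out[ov$src[[1]], ov$src[[2]], ov$src[[3]]] <-
      slice3(out, ov$src) + k[j] * slice3(a, ov$dst)
  }
  out
}
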