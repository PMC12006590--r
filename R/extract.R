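#' Extract the full 67-feature vector for one image and mask
#'
#' Computes every catalogue feature for the (image, mask) pair: conventional
#' SUV statistics on the raw SUVs, discretised/histogram/texture families on
#' the fixed-bin-width levels, and the shape family on the mask. Texture
#' matrices are built inside the mask's bounding box only, which leaves
#' every feature unchanged (translation invariance) while keeping matrices
#' small.
#'
#' Features that are undefined on (near-)constant regions — skewness-type
#' moments and GLCM correlation — are returned as `NA` and their names are
#' listed in the `degenerate` attribute; they are never silently dropped.
#'
#' @param image SUV [voxel_image()].
#' @param mask nonempty [voi_mask()] on the same grid.
#' @param scheme a [discretisation_scheme()].
#' @return named numeric vector of length 67 (catalogue order) with
#'   attribute `degenerate` (character vector of flagged names).
#' @export
extract_features <- function(image, mask, scheme = discretisation_scheme()) {
  if (!same_grid(image, mask)) stopf("image and mask grids differ")
  if (mask$voxel_count == 0L) stopf("mask is empty")
  bb <- mask_bbox(mask$values, margin = 1L)
  sub_m <- crop_arr(mask$values, bb)
  sub_v <- crop_arr(image$values, bb)
  lev <- array(NA_integer_, dim(sub_m))
  lev[sub_m] <- discretise(sub_v[sub_m], scheme)
  nl <- scheme$n_bins

  # single-voxel masks cannot form pairs/neighbourhoods: those families are
  # flagged degenerate rather than erroring
  safe <- function(expr, nms) {
    tryCatch(expr,
             error = function(e) stats::setNames(rep(NA_real_, length(nms)),
                                                 nms))
  }
  cat <- feature_catalog()
  vals <- c(
    intensity_features(image, mask),
    discretised_features(image, mask, scheme),
    histogram_features(lev[sub_m], scheme),
    shape_features(mask),
    safe(glcm_features(lev, nl), cat$name[cat$family == "glcm"]),
    glrlm_features(lev, nl),
    glzlm_features(lev, nl),
    safe(ngldm_features(lev, nl), cat$name[cat$family == "ngldm"])
  )
  out <- vals[feature_names()]
  names(out) <- feature_names()
  attr(out, "degenerate") <- names(out)[is.na(out)]
  out
}

#' Feature table over a VOI series
#'
#' Runs [extract_features()] for every mask of a [spherical_voi_series()]
#' (or any list of `list(diameter, mask)` elements) and assembles the
#' one-row-per-VOI table with provenance columns.
#'
#' @param image SUV [voxel_image()].
#' @param series a `voi_series`.
#' @param scheme a [discretisation_scheme()].
#' @return data.frame with columns `diameter_mm`, `volume_ml` and the 67
#'   features.
#' @export
extract_series <- function(image, series, scheme = discretisation_scheme()) {
  rows <- lapply(series, function(el) {
    fv <- extract_features(image, el$mask, scheme)
    cbind(data.frame(diameter_mm = el$diameter,
                     volume_ml = el$mask$volume_ml),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}
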