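# Conventional SUV, discretised-SUV and histogram feature families.

# Bounding box of a mask, expanded by `margin` voxels and clipped to the grid.
mask_bbox <- function(mask_arr, margin = 0L) {
  w <- which(mask_arr, arr.ind = TRUE)
  dims <- dim(mask_arr)
  lo <- pmax(1L, apply(w, 2L, min) - margin)
  hi <- pmin(dims, apply(w, 2L, max) + margin)
  list(lo = lo, hi = hi)
}

crop_arr <- function(arr, bb) {
  arr[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

#' Peak SUV over a spherical neighbourhood
#'
#' `SUVpeak(v)` is the maximum, over in-mask voxels, of the mean image value
#' within a sphere of volume `v` ml centred on the voxel centre. The sphere
#' may extend outside the mask but is clipped at the image bounds.
#'
#' @param image a [voxel_image()].
#' @param mask a [voi_mask()].
#' @param vol_ml sphere volume in ml.
#' @return scalar peak value.
#' @export
suv_peak <- function(image, mask, vol_ml) {
  s <- image$spacing[1]
  r_mm <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
  rv <- ceiling(r_mm / s)
  off <- as.matrix(expand.grid(dx = -rv:rv, dy = -rv:rv, dz = -rv:rv))
  off <- off[sqrt(rowSums((off * s)^2)) <= r_mm, , drop = FALSE]
  bb <- mask_bbox(mask$values, margin = rv)
  a <- crop_arr(image$values, bb)
  m <- crop_arr(mask$values, bb)
  dims <- dim(a)
  acc <- array(0, dims); cnt <- array(0L, dims)
  for (i in seq_len(nrow(off))) {
    ov <- shift_overlap(dims, off[i, ])
    if (is.null(ov)) next
    acc[ov$src[[1]], ov$src[[2]], ov$src[[3]]] <-
      slice3(acc, ov$src) + slice3(a, ov$dst)
    cnt[ov$src[[1]], ov$src[[2]], ov$src[[3]]] <-
      slice3(cnt, ov$src) + 1L
  }
  max((acc / cnt)[m])
}

# Shared summary block: min/mean/std(pop)/max/quartiles/moments over values,
# named with the given prefix conventions.
intensity_block <- function(vals, names_map) {
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  mom <- population_moments(vals)
  out <- c(min(vals), mom$mean, sqrt(mom$var), max(vals), q[1], q[2], q[3],
           mom$skew, mom$kurt,
           if (is.na(mom$kurt)) NA_real_ else mom$kurt - 3)
  stats::setNames(out, names_map)
}

#' Conventional SUV statistics
#'
#' Min/mean/std (population)/max, quartiles, skewness, kurtosis and excess
#' kurtosis of the in-mask SUVs, the two SUVpeak variants (0.5 and 1.0 ml)
#' and TLSRE (`SUVmean x volume` in SUV*ml). Moment features of a constant
#' region are degenerate and returned as `NA`.
#'
#' @param image SUV [voxel_image()].
#' @param mask nonempty [voi_mask()].
#' @return named numeric vector over the conventional family.
#' @export
intensity_features <- function(image, mask) {
  if (mask$voxel_count == 0L) stopf("mask is empty")
  vals <- image$values[mask$values]
  out <- intensity_block(vals, c("SUVmin", "SUVmean", "SUVstd", "SUVmax",
                                 "SUVQ1", "SUVQ2", "SUVQ3", "SUV_Skewness",
                                 "SUV_Kurtosis", "SUV_ExcessKurtosis"))
  c(out,
    `SUVpeak_0.5ml` = suv_peak(image, mask, 0.5),
    `SUVpeak_1.0ml` = suv_peak(image, mask, 1.0),
    TLSRE = unname(out["SUVmean"]) * mask$volume_ml)
}

#' Discretised SUV statistics
#'
#' The conventional statistics recomputed on bin-centre SUVs
#' (`lower + (level - 1/2) * bin width`), keeping the discretised family in
#' SUV units; peaks are taken on the bin-centre image.
#'
#' @param image SUV [voxel_image()].
#' @param mask nonempty [voi_mask()].
#' @param scheme a [discretisation_scheme()].
#' @return named numeric vector over the discretised family.
#' @export
discretised_features <- function(image, mask, scheme = discretisation_scheme()) {
  if (mask$voxel_count == 0L) stopf("mask is empty")
  dimg <- image
  dimg$values <- array(bin_centres(discretise(image$values, scheme), scheme),
                       dim(image$values))
  vals <- dimg$values[mask$values]
  out <- intensity_block(vals, paste0("Discretised_",
    c("SUVmin", "SUVmean", "SUVstd", "SUVmax", "SUVQ1", "SUVQ2", "SUVQ3",
      "SUV_Skewness", "SUV_Kurtosis", "SUV_ExcessKurtosis")))
  # Discretised SUVmax is computed for completeness but is not part of the
  # shipped 67-name catalogue (see the catalogue provenance note).
  c(out,
    `Discretised_SUVpeak_0.5ml` = suv_peak(dimg, mask, 0.5),
    `Discretised_SUVpeak_1.0ml` = suv_peak(dimg, mask, 1.0),
    Discretised_TLSRE = unname(out["Discretised_SUVmean"]) * mask$volume_ml)
}

#' Histogram features of the discretised grey levels
#'
#' Bin probabilities `p(i)` over the `n_bins` levels; energy `sum p^2`,
#' Shannon entropy in bits and in decimal digits (`0 log 0 = 0`), and the
#' skewness/kurtosis/excess kurtosis of the discretised values (moments are
#' affine-invariant, so levels and bin centres give identical values).
#'
#' @param levels integer levels from [discretise()].
#' @param scheme the [discretisation_scheme()].
#' @return named numeric vector over the histogram family.
#' @export
histogram_features <- function(levels, scheme = discretisation_scheme()) {
  p <- tabulate(levels, nbins = scheme$n_bins) / length(levels)
  pp <- p[p > 0]
  mom <- population_moments(as.numeric(levels))
  c(Histogram_Skewness = mom$skew,
    Histogram_Kurtosis = mom$kurt,
    Histogram_ExcessKurtosis = if (is.na(mom$kurt)) NA_real_ else mom$kurt - 3,
    Histogram_Entropy_log10 = -sum(pp * log10(pp)),
    Histogram_Entropy_log2 = -sum(pp * log2(pp)),
    Histogram_Energy = sum(pp^2))
}
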