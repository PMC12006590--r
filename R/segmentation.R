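#' Rasterise a spherical VOI
#'
#' A voxel belongs to the sphere iff its centre lies within `diameter/2` of
#' the sphere centre (voxel-centre inclusion rule).
#'
#' @param center sphere centre, world mm (length 3).
#' @param diameter sphere diameter (mm).
#' @param grid a [voxel_image()] defining the grid.
#' @return a [voi_mask()].
#' @export
rasterize_sphere <- function(center, diameter, grid) {
  r <- diameter / 2
  lo <- center - r; hi <- center + r
  gx <- axis_coords(grid, 1); gy <- axis_coords(grid, 2); gz <- axis_coords(grid, 3)
  s <- grid$spacing[1]
  if (any(lo < grid$origin - s / 2) ||
      any(hi > grid$origin + dim(grid$values) * grid$spacing + s / 2))
    stopf("sphere of diameter %.3g mm at (%g, %g, %g) extends outside the grid",
          diameter, center[1], center[2], center[3])
  m <- array(FALSE, dim(grid$values))
  dz2 <- (gz - center[3])^2
  dxy2 <- outer((gx - center[1])^2, (gy - center[2])^2, `+`)
  keep_z <- which(dz2 <= r^2)
  for (k in keep_z) {
    m[, , k] <- dxy2 <= r^2 - dz2[k]
  }
  voi_mask(m, grid$spacing, grid$origin, allow_empty = TRUE)
}

#' Spherical VOI series for volume-dependency testing
#'
#' The series of concentric spherical VOIs of increasing diameter (default
#' 10 to 122 mm in 4 mm steps, 29 masks) placed at the phantom centre.
#'
#' @param center common centre (mm).
#' @param grid a [voxel_image()].
#' @param d_min,d_max,step diameters (mm).
#' @param interior a function of world coordinates returning TRUE inside the
#'   admissible phantom interior, or `NULL` to skip the boundary check; used
#'   to refuse series whose largest sphere crosses the phantom edge.
#' @return An object of class `voi_series`: list of elements
#'   `list(diameter, mask)` ordered by diameter, with the centre as an
#'   attribute.
#' @export
spherical_voi_series <- function(center, grid, d_min = 10, d_max = 122,
                                 step = 4, interior = NULL) {
  if (d_max < d_min || step <= 0) stopf("invalid diameter series")
  diams <- seq(d_min, d_max, by = step)
  if (!is.null(interior)) {
    r <- d_max / 2
    probe <- rbind(center + c(r, 0, 0), center - c(r, 0, 0),
                   center + c(0, r, 0), center - c(0, r, 0),
                   center + c(0, 0, r), center - c(0, 0, r))
    if (!all(apply(probe, 1L, function(p) isTRUE(interior(p))))) {
      admissible <- diams[vapply(diams, function(d) {
        r <- d / 2
        pr <- rbind(center + c(r, 0, 0), center - c(r, 0, 0),
                    center + c(0, r, 0), center - c(0, r, 0),
                    center + c(0, 0, r), center - c(0, 0, r))
        all(apply(pr, 1L, function(p) isTRUE(interior(p))))
      }, logical(1))]
      stopf("largest sphere crosses the phantom boundary; maximum admissible diameter is %s mm",
            if (length(admissible)) max(admissible) else "< d_min")
    }
  }
  out <- lapply(diams, function(d)
    list(diameter = d, mask = rasterize_sphere(center, d, grid)))
  structure(out, center = center, class = "voi_series")
}

#' @export
print.voi_series <- function(x, ...) {
  cat(sprintf("<voi_series> %d spherical VOIs, %g-%g mm\n", length(x),
              x[[1]]$diameter, x[[length(x)]]$diameter))
  invisible(x)
}

#' Mean SUV over a background region
#'
#' @param image a [voxel_image()] in SUV.
#' @param region a nonempty [voi_mask()] placed in the body background.
#' @return mean SUV (scalar).
#' @export
measure_background <- function(image, region) {
  if (region$voxel_count == 0L) stopf("background region is empty")
  mean(image$values[region$values])
}

#' Segmentation parameters
#'
#' @param method `"adaptive_background"` (threshold = factor x background
#'   SUV, the guideline protocol, default factor 2.5) or `"percent_max"`
#'   (threshold = factor x SUVmax within the search region, default 0.40).
#' @param factor threshold factor (> 0; in (0,1) for `percent_max`).
#' @param background_region [voi_mask()] for the adaptive method.
#' @param search_radius_mm radius around the seed within which SUVmax is
#'   taken for `percent_max`.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(method = c("adaptive_background", "percent_max"),
                                factor = NULL, background_region = NULL,
                                search_radius_mm = 50) {
  method <- match.arg(method)
  factor <- factor %||% if (method == "adaptive_background") 2.5 else 0.40
  if (factor <= 0) stopf("factor must be > 0")
  if (method == "percent_max" && factor >= 1)
    stopf("percent_max factor must be in (0, 1)")
  structure(list(method = method, factor = factor,
                 background_region = background_region,
                 search_radius_mm = search_radius_mm),
            class = "segmentation_params")
}

# 26-connected component of `sel` containing the voxel linear index `seed`.
connected_component_26 <- function(sel, seed_idx) {
  dims <- dim(sel)
  idx <- which(sel)
  if (!sel[seed_idx]) return(integer(0))
  pos <- match(seed_idx, idx)
  vid <- array(0L, dims)
  vid[idx] <- seq_along(idx)
  offs <- direction_offsets_13()
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    ov <- shift_overlap(dims, offs[i, ])
    if (is.null(ov)) next
    a <- slice3(vid, ov$src); b <- slice3(vid, ov$dst)
    keep <- a > 0L & b > 0L
    edges[[i]] <- cbind(a[keep], b[keep])
  }
  em <- do.call(rbind, edges)
  if (is.null(em) || nrow(em) == 0L) return(idx[pos])
  g <- igraph::make_graph(as.vector(t(em)), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  idx[comp == comp[pos]]
}

#' Threshold-based VOI segmentation
#'
#' Computes the threshold (`factor x background SUV` for the adaptive method,
#' `factor x SUVmax` within the search region for percent-max), then returns
#' the 26-connected component of `{SUV >= threshold}` containing the seed
#' point. The seed voxel is snapped to the hottest voxel within
#' `snap_radius_mm` of the given point, so that a noise-depressed voxel at
#' the exact seed position does not abort an otherwise valid segmentation;
#' snapping is deterministic.
#'
#' @param image a [voxel_image()] in SUV.
#' @param params a [segmentation_params()].
#' @param seed_point world coordinate (mm) inside the target object.
#' @param snap_radius_mm radius for seed snapping (0 disables).
#' @return a [voi_mask()] with attributes `threshold` and `method`.
#' @export
segment_voi <- function(image, params, seed_point, snap_radius_mm = 6) {
  dims <- dim(image$values)
  ijk <- pmin(pmax(1L, as.integer(ceiling((seed_point - image$origin) /
                                            image$spacing))), dims)
  if (snap_radius_mm > 0) {
    rv <- ceiling(snap_radius_mm / image$spacing[1])
    lo <- pmax(1L, ijk - rv); hi <- pmin(dims, ijk + rv)
    sub <- image$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ijk <- lo + w - 1L
  }
  seed_idx <- ijk[1] + (ijk[2] - 1L) * dims[1] +
    (ijk[3] - 1L) * dims[1] * dims[2]
  if (params$method == "adaptive_background") {
    if (is.null(params$background_region))
      stopf("adaptive segmentation requires a background region")
    thr <- params$factor * measure_background(image, params$background_region)
  } else {
    if (max(image$values) == min(image$values))
      stopf("percent_max segmentation needs a non-constant image")
    x <- axis_coords(image, 1); y <- axis_coords(image, 2); z <- axis_coords(image, 3)
    d2 <- outer(outer((x - seed_point[1])^2, (y - seed_point[2])^2, `+`),
                (z - seed_point[3])^2, `+`)
    thr <- params$factor * max(image$values[d2 <= params$search_radius_mm^2])
  }
  sel <- image$values >= thr
  if (!any(sel)) stopf("empty segmentation: threshold %.4g exceeds image maximum", thr)
  if (!sel[seed_idx])
    stopf("empty segmentation: seed point below threshold %.4g", thr)
  comp <- connected_component_26(sel, seed_idx)
  m <- array(FALSE, dims)
  m[comp] <- TRUE
  out <- voi_mask(m, image$spacing, image$origin)
  attr(out, "threshold") <- thr
  attr(out, "method") <- params$method
  out
}
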