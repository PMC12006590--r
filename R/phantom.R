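#' Phantom geometry description
#'
#' Describes one of the two phantom designs: a uniform water-filled cylinder
#' (volume-dependency testing) or a seven-syringe "Revolver" insert mounted in
#' a NEMA-IQ-style elliptical body (repeatability testing). Syringes are
#' modelled as cylinders of typical barrel inner diameter (10 / 12 / 16 mm
#' for 2.5 / 5 / 10 ml), length set by volume, packed hexagonally and
#' touching, with axes along the phantom's long axis.
#'
#' @param kind `"uniform_cylinder"` or `"revolver_body"`.
#' @param cylinder_height,cylinder_diameter nominal cylinder dimensions (mm).
#' @param fill_volume_ml water fill volume (ml); authoritative for
#'   concentration and SUV mass. The rendered fill height is
#'   `fill_volume / cross-section`, capped at `cylinder_height`.
#' @param syringe_volume_ml syringe size: 2.5, 5 or 10 ml.
#' @param syringe_inner_diameter mm; default looked up from the volume.
#' @param insert_center world position (mm) of the central syringe's centre.
#' @param body_axes half-axes (mm) of the elliptical body cross-section.
#' @param body_length axial length (mm) of the body.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(kind = c("uniform_cylinder", "revolver_body"),
                             cylinder_height = 200, cylinder_diameter = 220,
                             fill_volume_ml = 6244,
                             syringe_volume_ml = 2.5,
                             syringe_inner_diameter = NULL,
                             insert_center = c(0, 0, 0),
                             body_axes = c(150, 110), body_length = 180) {
  kind <- match.arg(kind)
  if (kind == "revolver_body") {
    if (!syringe_volume_ml %in% c(2.5, 5, 10))
      stopf("syringe_volume_ml must be 2.5, 5 or 10")
    if (is.null(syringe_inner_diameter)) {
      syringe_inner_diameter <-
        c(`2.5` = 10, `5` = 12, `10` = 16)[[as.character(syringe_volume_ml)]]
    }
    syringe_length <- syringe_volume_ml * 1000 /
      (pi * (syringe_inner_diameter / 2)^2)
    vol_check <- syringe_length * pi * (syringe_inner_diameter / 2)^2 / 1000
    stopifnot(abs(vol_check - syringe_volume_ml) / syringe_volume_ml < 0.005)
    fill_volume_ml <- pi * body_axes[1] * body_axes[2] * body_length / 1000
  } else {
    syringe_length <- NULL
  }
  g <- structure(
    list(kind = kind, cylinder_height = cylinder_height,
         cylinder_diameter = cylinder_diameter,
         fill_volume_ml = fill_volume_ml,
         syringe_volume_ml = syringe_volume_ml,
         syringe_inner_diameter = syringe_inner_diameter,
         syringe_length = syringe_length,
         insert_center = insert_center,
         body_axes = body_axes, body_length = body_length),
    class = "phantom_geometry"
  )
  if (kind == "revolver_body") check_syringes_in_body(g)
  g
}

# Centres (x, y) of the 7 syringes: one central, six hexagonally packed and
# touching (centre distance = inner diameter).
syringe_centres <- function(geometry) {
  d <- geometry$syringe_inner_diameter
  ang <- (0:5) * pi / 3
  rbind(c(0, 0), cbind(d * cos(ang), d * sin(ang))) +
    rep(geometry$insert_center[1:2], each = 7L)
}

check_syringes_in_body <- function(geometry) {
  a <- geometry$body_axes[1]; b <- geometry$body_axes[2]
  rs <- geometry$syringe_inner_diameter / 2
  cz <- geometry$insert_center[3]
  if (abs(cz) + geometry$syringe_length / 2 > geometry$body_length / 2)
    stopf("syringes exceed body bounds axially")
  cc <- syringe_centres(geometry)
  # conservative: the syringe circle's outermost point must stay in the ellipse
  ok <- ((abs(cc[, 1]) + rs) / a)^2 + ((abs(cc[, 2]) + rs) / b)^2 <= 1
  if (!all(ok)) stopf("syringes exceed body bounds in the transaxial plane")
  invisible(TRUE)
}

#' Activity specification
#'
#' Total activity, per-syringe concentration ratios, background concentration
#' and phantom mass (1 g/ml water equivalence), the quantities that fix
#' concentration maps and the SUV normalisation.
#'
#' @param total_activity_MBq total activity in the phantom (MBq).
#' @param ratios 7 per-syringe multipliers of the background concentration
#'   (Revolver only). The first entry is the central syringe.
#' @param background_concentration_kBq_ml background concentration (kBq/ml).
#' @param fill_volume_ml water volume (ml).
#' @param phantom_mass_g defaults to `fill_volume_ml` (1 g/ml).
#' @return An object of class `activity_spec`.
#' @export
activity_spec <- function(total_activity_MBq, ratios = NULL,
                          background_concentration_kBq_ml = NULL,
                          fill_volume_ml, phantom_mass_g = fill_volume_ml) {
  if (!is.null(ratios)) {
    if (length(ratios) != 7L || any(ratios <= 0))
      stopf("`ratios` must be 7 positive multipliers")
  }
  structure(
    list(total_activity_MBq = total_activity_MBq, ratios = ratios,
         background_concentration_kBq_ml = background_concentration_kBq_ml,
         fill_volume_ml = fill_volume_ml, phantom_mass_g = phantom_mass_g),
    class = "activity_spec"
  )
}

#' Revolver activity specification from a background fill activity
#'
#' Computes the background concentration from the activity dispensed into the
#' body (total minus the syringe volumes) and the implied total activity
#' including the hot syringes, completing an [activity_spec()].
#'
#' @param geometry a revolver [phantom_geometry()].
#' @param background_activity_MBq activity dispensed into the body background.
#' @param ratios 7 syringe:background concentration ratios drawn from
#'   {4, 8, 16}; default places 16:1 centrally with 4:1/8:1 alternating on
#'   the ring.
#' @return an [activity_spec()].
#' @export
revolver_activity_spec <- function(geometry, background_activity_MBq,
                                   ratios = c(16, 4, 8, 4, 8, 4, 8)) {
  stopifnot(geometry$kind == "revolver_body")
  v_body <- geometry$fill_volume_ml
  v_syr <- 7 * geometry$syringe_volume_ml
  bg <- background_activity_MBq * 1000 / (v_body - v_syr)  # kBq/ml
  total <- background_activity_MBq +
    sum(ratios) * bg * geometry$syringe_volume_ml / 1000
  activity_spec(total_activity_MBq = total, ratios = ratios,
                background_concentration_kBq_ml = bg,
                fill_volume_ml = v_body)
}

#' Per-radionuclide imaging profile
#'
#' Image-domain surrogate parameters for the two acquisition set-ups:
#' system resolution as a Gaussian PSF FWHM and a count scale fixing the
#' Poisson noise level. Defaults reproduce the reconstructed-image noise
#' ordering between the radionuclides (uniform-phantom voxel CoV of about
#' 14% for 99mTc-LEHR and 20% for 177Lu-MEGP at the protocol activities);
#' see the methods vignette for the derivation.
#'
#' @param radionuclide `"tc99m"` or `"lu177"`.
#' @return list with `psf_fwhm` (mm), `count_scale` (expected counts per
#'   kBq/ml per voxel), `uniform_activity_MBq`, `background_activity_MBq`.
#' @export
radionuclide_profile <- function(radionuclide = c("tc99m", "lu177")) {
  radionuclide <- match.arg(radionuclide)
  switch(radionuclide,
    tc99m = list(radionuclide = "tc99m", psf_fwhm = 8,  count_scale = 1.10,
                 uniform_activity_MBq = 278, background_activity_MBq = 472),
    lu177 = list(radionuclide = "lu177", psf_fwhm = 12, count_scale = 0.23,
                 uniform_activity_MBq = 670, background_activity_MBq = 386)
  )
}

#' Imaging model
#'
#' @param radionuclide optional; fills `psf_fwhm`/`count_scale` defaults from
#'   [radionuclide_profile()].
#' @param psf_fwhm Gaussian PSF full width at half maximum (mm), >= 0.
#' @param count_scale expected counts per kBq/ml per voxel (> 0); larger
#'   means less Poisson noise.
#' @param voxel_size isotropic voxel edge (mm).
#' @param seed integer seed making the scan reproducible.
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(radionuclide = NULL, psf_fwhm = NULL,
                          count_scale = NULL, voxel_size = 1.95, seed = 1L) {
  if (!is.null(radionuclide)) {
    prof <- radionuclide_profile(radionuclide)
    psf_fwhm <- psf_fwhm %||% prof$psf_fwhm
    count_scale <- count_scale %||% prof$count_scale
  }
  if (is.null(psf_fwhm) || is.null(count_scale))
    stopf("supply `radionuclide` or both `psf_fwhm` and `count_scale`")
  if (psf_fwhm < 0) stopf("psf_fwhm must be >= 0")
  if (count_scale <= 0) stopf("count_scale must be > 0")
  if (voxel_size <= 0) stopf("voxel_size must be > 0")
  structure(
    list(radionuclide = radionuclide, psf_fwhm = psf_fwhm,
         count_scale = count_scale, voxel_size = voxel_size,
         seed = as.integer(seed)),
    class = "imaging_model"
  )
}

# Centred grid covering [-half_xy, half_xy]^2 x [-half_z, half_z] plus a
# margin wide enough that the PSF blur loses negligible signal off-grid.
make_grid <- function(half_xy, half_z, voxel, margin_voxels = 6L) {
  nxy <- ceiling(2 * half_xy / voxel) + 2L * margin_voxels
  nz <- ceiling(2 * half_z / voxel) + 2L * margin_voxels
  list(dims = c(nxy, nxy, nz),
       origin = c(-nxy, -nxy, -nz) * voxel / 2)
}

#' Build the uniform cylindrical phantom activity map
#'
#' Constant concentration `total_activity / fill_volume` inside the water
#' volume, zero outside, voxelised by voxel-centre inclusion. The cylinder is
#' rendered at the nominal diameter with the fill height implied by the fill
#' volume, so that the integrated activity matches the dispensed activity up
#' to rasterisation error.
#'
#' @param geometry a `uniform_cylinder` [phantom_geometry()].
#' @param spec an [activity_spec()].
#' @param voxel voxel edge (mm).
#' @return a [voxel_image()] in kBq/ml.
#' @export
build_uniform_phantom <- function(geometry, spec, voxel = 1.95) {
  stopifnot(geometry$kind == "uniform_cylinder")
  r <- geometry$cylinder_diameter / 2
  if (voxel > r) stopf("voxel size %.3g mm exceeds cylinder radius: degenerate grid", voxel)
  h_fill <- min(geometry$cylinder_height,
                spec$fill_volume_ml * 1000 / (pi * r^2))
  conc <- spec$total_activity_MBq * 1000 / spec$fill_volume_ml  # kBq/ml
  g <- make_grid(r, h_fill / 2, voxel)
  x <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * voxel
  z <- g$origin[3] + (seq_len(g$dims[3]) - 0.5) * voxel
  r2 <- outer(x^2, x^2, `+`)           # transaxial squared radius
  inside_xy <- r2 <= r^2
  inside_z <- abs(z) <= h_fill / 2
  vals <- array(0, g$dims)
  vals[] <- conc * as.numeric(inside_xy)[] * rep(as.numeric(inside_z),
                                                 each = prod(g$dims[1:2]))
  voxel_image(vals, voxel, g$origin, "kBq/ml")
}

#' Build the Revolver phantom activity map
#'
#' Background concentration throughout the elliptical body, with each of the
#' seven syringe cylinders set to `ratio * background`; zero outside the body.
#'
#' @param geometry a `revolver_body` [phantom_geometry()].
#' @param spec an [activity_spec()] with 7 `ratios` and a background
#'   concentration (see [revolver_activity_spec()]).
#' @param voxel voxel edge (mm).
#' @return a [voxel_image()] in kBq/ml.
#' @export
build_revolver_phantom <- function(geometry, spec, voxel = 1.95) {
  stopifnot(geometry$kind == "revolver_body")
  if (is.null(spec$ratios) || length(spec$ratios) != 7L)
    stopf("7 syringe ratios required")
  if (is.null(spec$background_concentration_kBq_ml))
    stopf("background concentration required (see revolver_activity_spec())")
  check_syringes_in_body(geometry)
  a <- geometry$body_axes[1]; b <- geometry$body_axes[2]
  g <- make_grid(max(a, b), geometry$body_length / 2, voxel)
  x <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * voxel
  z <- g$origin[3] + (seq_len(g$dims[3]) - 0.5) * voxel
  inside_body_xy <- outer((x / a)^2, (x / b)^2, `+`) <= 1
  inside_z <- abs(z) <= geometry$body_length / 2
  bg <- spec$background_concentration_kBq_ml
  vals <- array(0, g$dims)
  vals[] <- bg * as.numeric(inside_body_xy)[] *
    rep(as.numeric(inside_z), each = prod(g$dims[1:2]))

  rs <- geometry$syringe_inner_diameter / 2
  half_len <- geometry$syringe_length / 2
  cz <- geometry$insert_center[3]
  in_syr_z <- abs(z - cz) <= half_len
  cc <- syringe_centres(geometry)
  for (i in 1:7) {
    d2 <- outer((x - cc[i, 1])^2, (x - cc[i, 2])^2, `+`)
    sel_xy <- d2 <= rs^2
    plane <- which(sel_xy)
    for (k in which(in_syr_z)) {
      vals[plane + (k - 1L) * prod(g$dims[1:2])] <- spec$ratios[i] * bg
    }
  }
  voxel_image(vals, voxel, g$origin, "kBq/ml")
}

#' Convert a concentration map to SUV
#'
#' `SUV = concentration (kBq/ml) * phantom mass (g) / total activity (kBq)`;
#' a uniform phantom at exact fill maps to SUV 1 inside.
#'
#' @param concentration a [voxel_image()] in kBq/ml.
#' @param spec an [activity_spec()] with positive mass and activity.
#' @return a [voxel_image()] in SUV.
#' @export
to_suv <- function(concentration, spec) {
  if (is.null(spec$total_activity_MBq) || spec$total_activity_MBq <= 0)
    stopf("total activity must be positive for SUV conversion")
  if (is.null(spec$phantom_mass_g) || spec$phantom_mass_g <= 0)
    stopf("phantom mass must be positive for SUV conversion")
  f <- spec$phantom_mass_g / (spec$total_activity_MBq * 1000)
  voxel_image(concentration$values * f, concentration$spacing,
              concentration$origin, "SUV")
}

#' Simulate one quantitative SPECT scan
#'
#' Image-domain surrogate of acquisition plus reconstruction: the activity
#' map is blurred with the isotropic Gaussian PSF, scaled to expected counts
#' (`count_scale` per kBq/ml per voxel), Poisson-sampled with the model seed,
#' rescaled to concentration and converted to SUV. Deterministic given the
#' seed. With `noise = FALSE` (the infinite-count limit) sampling is skipped
#' and the output is exactly `to_suv(blurred input)`.
#'
#' @param activity a [voxel_image()] in kBq/ml.
#' @param model an [imaging_model()].
#' @param spec the [activity_spec()] used for the SUV conversion.
#' @param noise Poisson-sample the expected counts?
#' @return a [voxel_image()] in SUV.
#' @export
simulate_scan <- function(activity, model, spec, noise = TRUE) {
  if (!identical(activity$unit, "kBq/ml"))
    stopf("simulate_scan expects an activity map in kBq/ml")
  blurred <- gaussian_blur(activity, model$psf_fwhm)
  if (noise) {
    lambda <- blurred$values * model$count_scale
    counts <- withr::with_seed(model$seed,
                               stats::rpois(length(lambda), lambda))
    blurred$values[] <- counts / model$count_scale
  }
  to_suv(blurred, spec)
}

#' Generate a repeat-scan series
#'
#' `n_repeats` scans of the same ground-truth activity map with independent
#' noise (seeds `seed, seed + 1, ...`), emulating consecutive acquisitions.
#'
#' @param geometry a [phantom_geometry()] of either kind.
#' @param spec an [activity_spec()].
#' @param model an [imaging_model()].
#' @param n_repeats number of scans (default 4, the repeat protocol).
#' @param noise Poisson noise on/off.
#' @param voxel voxel edge (mm).
#' @return list of `n_repeats` SUV [voxel_image()]s.
#' @export
generate_repeat_series <- function(geometry, spec, model, n_repeats = 4L,
                                   noise = TRUE, voxel = NULL) {
  if (n_repeats < 1L) stopf("n_repeats must be >= 1")
  voxel <- voxel %||% model$voxel_size
  act <- switch(geometry$kind,
    uniform_cylinder = build_uniform_phantom(geometry, spec, voxel),
    revolver_body = build_revolver_phantom(geometry, spec, voxel)
  )
  lapply(seq_len(n_repeats) - 1L, function(k) {
    mk <- model
    mk$seed <- model$seed + k
    simulate_scan(act, mk, spec, noise = noise)
  })
}

#' Uniform-phantom voxel noise (CoV)
#'
#' Simulates one uniform-phantom scan at the protocol activity for the given
#' radionuclide and returns the coefficient of variation (percent) across
#' voxels of the eroded interior, the quantity used to compare image noise
#' between radionuclides.
#'
#' @param radionuclide `"tc99m"` or `"lu177"`.
#' @param seed scan seed.
#' @param voxel voxel edge (mm).
#' @param interior_margin_mm margin excluded from the phantom boundary.
#' @return list with `cov_pct` and `n_voxels`.
#' @export
uniform_noise_cov <- function(radionuclide, seed = 1L, voxel = 1.95,
                              interior_margin_mm = 25) {
  prof <- radionuclide_profile(radionuclide)
  geom <- phantom_geometry("uniform_cylinder")
  spec <- activity_spec(prof$uniform_activity_MBq, fill_volume_ml = 6244)
  model <- imaging_model(radionuclide, voxel_size = voxel, seed = seed)
  img <- simulate_scan(build_uniform_phantom(geom, spec, voxel), model, spec)
  r <- geom$cylinder_diameter / 2 - interior_margin_mm
  h_fill <- min(geom$cylinder_height,
                spec$fill_volume_ml * 1000 / (pi * (geom$cylinder_diameter / 2)^2))
  hz <- h_fill / 2 - interior_margin_mm
  x <- axis_coords(img, 1); y <- axis_coords(img, 2); z <- axis_coords(img, 3)
  inside_xy <- as.vector(outer(x^2, y^2, `+`) <= r^2)
  sel <- array(FALSE, dim(img$values))
  sel[] <- inside_xy & rep(abs(z) <= hz, each = length(x) * length(y))
  v <- img$values[sel]
  list(cov_pct = 100 * stats::sd(v) / mean(v), n_voxels = length(v))
}
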