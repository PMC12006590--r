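# Phantom construction, SUV conversion and the imaging surrogate.

test_that("uniform phantom has the protocol concentration and conserves activity", {
  geom <- phantom_geometry("uniform_cylinder")
  spec <- activity_spec(278, fill_volume_ml = 6244)
  img <- build_uniform_phantom(geom, spec, voxel = 1.95)
  expect_equal(max(img$values), 278000 / 6244, tolerance = 1e-10)
  integral_MBq <- sum(img$values) * prod(img$spacing) / 1e6
  expect_lt(abs(integral_MBq - 278) / 278, 0.02)

  zero <- build_uniform_phantom(geom, activity_spec(0, fill_volume_ml = 6244))
  expect_true(all(zero$values == 0))
  expect_error(build_uniform_phantom(geom, spec, voxel = 150), "degenerate")
})

test_that("revolver phantom places ratio-scaled syringes inside the body", {
  sr <- small_revolver()
  img <- build_revolver_phantom(sr$geom, sr$spec, voxel = 1.95)
  bg <- sr$spec$background_concentration_kBq_ml
  vals <- sort(unique(round(as.vector(img$values) / bg, 6)))
  expect_equal(vals, c(0, 1, 4, 8, 16))

  integral_MBq <- sum(img$values) * prod(img$spacing) / 1e6
  expect_lt(abs(integral_MBq - sr$spec$total_activity_MBq) /
              sr$spec$total_activity_MBq, 0.02)

  # nominal hot volume: voxels above background recover 7 x syringe volume
  # within a voxel shell
  hot_ml <- sum(img$values > bg * 1.001) * prod(img$spacing) / 1000
  r <- sr$geom$syringe_inner_diameter / 2
  shell_ml <- 7 * (pi * ((r + 1.95)^2 - r^2) * sr$geom$syringe_length +
                     2 * pi * r^2 * 1.95) / 1000
  expect_lt(abs(hot_ml - 17.5), shell_ml)

  # all ratios equal -> indistinguishable from a uniform body
  spec1 <- sr$spec; spec1$ratios <- rep(1, 7)
  img1 <- build_revolver_phantom(sr$geom, spec1, voxel = 1.95)
  inside <- img1$values > 0
  expect_equal(max(img1$values[inside]) / min(img1$values[inside]), 1)

  expect_error(
    phantom_geometry("revolver_body", syringe_volume_ml = 10,
                     body_axes = c(20, 20), body_length = 70),
    "exceed body bounds")
})

test_that("SUV conversion is a mass-over-activity rescaling", {
  geom <- phantom_geometry("uniform_cylinder")
  spec <- activity_spec(278, fill_volume_ml = 6244)
  suv <- to_suv(build_uniform_phantom(geom, spec), spec)
  expect_equal(max(suv$values), 1.0, tolerance = 1e-12)

  sr <- small_revolver()
  rsuv <- to_suv(build_revolver_phantom(sr$geom, sr$spec), sr$spec)
  b <- sr$spec$background_concentration_kBq_ml * sr$spec$phantom_mass_g /
    (sr$spec$total_activity_MBq * 1000)
  expect_equal(max(rsuv$values), 16 * b, tolerance = 1e-12)

  bad <- spec; bad$total_activity_MBq <- 0
  expect_error(to_suv(build_uniform_phantom(geom, spec), bad), "positive")
})

test_that("simulate_scan is deterministic, has an exact no-noise limit, and Poisson noise scale", {
  su <- small_uniform()
  act <- build_uniform_phantom(su$geom, su$spec)
  model <- imaging_model(psf_fwhm = 0, count_scale = 1, seed = 11)
  noiseless <- simulate_scan(act, model, su$spec, noise = FALSE)
  expect_identical(noiseless$values, to_suv(act, su$spec)$values)

  a <- simulate_scan(act, model, su$spec)
  b <- simulate_scan(act, model, su$spec)
  expect_identical(a$values, b$values)
  model2 <- model; model2$seed <- 12
  expect_false(identical(a$values,
                         simulate_scan(act, model2, su$spec)$values))

  # no blur, lambda = count_scale * conc = 100 -> voxel CoV ~ 10%
  conc <- max(act$values)
  m100 <- imaging_model(psf_fwhm = 0, count_scale = 100 / conc, seed = 5)
  scan <- simulate_scan(act, m100, su$spec)
  interior <- act$values == conc
  cv <- stats::sd(scan$values[interior]) / mean(scan$values[interior])
  expect_equal(cv, 0.1, tolerance = 0.05)

  expect_error(imaging_model(psf_fwhm = -1, count_scale = 1), "psf_fwhm")
})

test_that("PSF blur conserves total signal on a padded grid", {
  su <- small_uniform()
  act <- build_uniform_phantom(su$geom, su$spec)
  for (fwhm in c(8, 12)) {
    bl <- gaussian_blur(act, fwhm)
    expect_lt(abs(sum(bl$values) - sum(act$values)) / sum(act$values), 1e-3)
  }
})

test_that("repeat series gives independent repeats with shared ground truth", {
  su <- small_uniform()
  model <- imaging_model("tc99m", seed = 3)
  scans <- generate_repeat_series(su$geom, su$spec, model, n_repeats = 4)
  expect_length(scans, 4)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(scans[[i]]$values, scans[[j]]$values))

  expect_length(generate_repeat_series(su$geom, su$spec, model,
                                       n_repeats = 1), 1)
  quiet <- generate_repeat_series(su$geom, su$spec, model, n_repeats = 2,
                                  noise = FALSE)
  expect_identical(quiet[[1]]$values, quiet[[2]]$values)
})

test_that("voxelwise mean over many repeats converges to the noise-free image", {
  su <- small_uniform()
  act <- build_uniform_phantom(su$geom, su$spec)
  model <- imaging_model("tc99m", seed = 101)
  truth <- simulate_scan(act, model, su$spec, noise = FALSE)
  n <- 150
  acc <- array(0, dim(act$values))
  for (k in seq_len(n)) {
    mk <- model; mk$seed <- model$seed + k
    acc <- acc + simulate_scan(act, mk, su$spec)$values
  }
  avg <- acc / n
  lambda <- gaussian_blur(act, model$psf_fwhm)$values * model$count_scale
  f <- su$spec$phantom_mass_g / (su$spec$total_activity_MBq * 1000) /
    model$count_scale
  sig <- sqrt(lambda) * f          # per-voxel SUV noise sd
  sel <- lambda > 5
  z <- (avg[sel] - truth$values[sel]) / (sig[sel] / sqrt(n))
  # max |z| over ~1e5 voxels: expect ~4.3; 6 is a comfortable LLN bound
  expect_lt(max(abs(z)), 6)
  expect_lt(abs(mean(z)), 0.05)
})

test_that("noise decreases monotonically with count scale", {
  su <- small_uniform()
  act <- build_uniform_phantom(su$geom, su$spec)
  interior <- act$values == max(act$values)
  cov_at <- function(cs_mult) {
    model <- imaging_model("tc99m", seed = 42)
    model$count_scale <- model$count_scale * cs_mult
    reps <- lapply(1:20, function(k) {
      mk <- model; mk$seed <- model$seed + k
      simulate_scan(act, mk, su$spec)$values[interior]
    })
    stack <- do.call(cbind, reps)
    mean(apply(stack, 1L, stats::sd) / rowMeans(stack))
  }
  covs <- vapply(c(0.25, 1, 4), cov_at, numeric(1))
  expect_true(all(diff(covs) < 0))
})

test_that("uniform cylinder image is symmetric under 90-degree rotation", {
  su <- small_uniform()
  act <- build_uniform_phantom(su$geom, su$spec)
  model <- imaging_model("tc99m", seed = 1)
  img <- simulate_scan(act, model, su$spec, noise = FALSE)$values
  rot <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , ]  # (x,y) -> (-y,x)
  expect_equal(rot, img, tolerance = 1e-10)
})

test_that("uniform-phantom noise matches the per-radionuclide calibration", {
  tc <- uniform_noise_cov("tc99m", seed = 2)
  lu <- uniform_noise_cov("lu177", seed = 2)
  expect_equal(tc$cov_pct, 14.3, tolerance = 0.05)
  expect_equal(lu$cov_pct, 20.2, tolerance = 0.05)
  expect_gt(lu$cov_pct, tc$cov_pct)
})
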