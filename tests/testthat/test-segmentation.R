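# Sphere rasterisation, the VOI series, and threshold segmentation.

test_that("sphere rasterisation follows the voxel-centre rule", {
  grid <- tiny_image(array(1, c(21, 21, 21)), spacing = 1)
  # centred on the grid centre voxel: a sub-voxel sphere is exactly 1 voxel
  ctr <- grid$origin + 10.5 * grid$spacing
  one <- rasterize_sphere(ctr, 0.9, grid)
  expect_equal(one$voxel_count, 1L)

  # symmetric under reflection through the centre plane
  m <- rasterize_sphere(ctr, 7, grid)$values
  expect_identical(m, m[dim(m)[1]:1, , ])
  expect_identical(m, m[, dim(m)[2]:1, ])

  expect_error(rasterize_sphere(ctr, 50, grid), "outside the grid")
})

test_that("large rasterised sphere volume approaches the analytic volume", {
  su <- small_uniform()
  img <- build_uniform_phantom(phantom_geometry("uniform_cylinder"),
                               activity_spec(278, fill_volume_ml = 6244),
                               voxel = 1.95)
  m122 <- rasterize_sphere(c(0, 0, 0), 122, img)
  analytic <- pi / 6 * 12.2^3  # ml; 950.8
  expect_lt(abs(m122$volume_ml - analytic) / analytic, 0.015)
  expect_equal(m122$volume_ml, m122$voxel_count * 1.95^3 / 1000)
})

test_that("spherical VOI series has the protocol count and increasing volumes", {
  img <- build_uniform_phantom(phantom_geometry("uniform_cylinder"),
                               activity_spec(278, fill_volume_ml = 6244),
                               voxel = 1.95)
  series <- spherical_voi_series(c(0, 0, 0), img)
  expect_length(series, 29)
  vols <- vapply(series, function(el) el$mask$volume_ml, numeric(1))
  expect_true(all(diff(vols) > 0))

  expect_length(spherical_voi_series(c(0, 0, 0), img, d_min = 10,
                                     d_max = 10), 1)

  # relative rasterisation error of the volume shrinks along the series
  analytic <- pi / 6 * vapply(series, `[[`, numeric(1), "diameter")^3 / 1000
  rel <- abs(vols - analytic) / analytic
  expect_lt(rel[29], rel[1])
  expect_lt(suppressWarnings(cor(seq_along(rel), rel, method = "spearman")),
            -0.7)

  inside_small <- function(p) sqrt(sum(p[1:2]^2)) <= 20 && abs(p[3]) <= 20
  expect_error(
    spherical_voi_series(c(0, 0, 0), img, interior = inside_small),
    "maximum admissible diameter")
})

test_that("background measurement is the regional mean", {
  img <- tiny_image(array(2.5, c(10, 10, 10)))
  reg <- voi_mask(array(TRUE, c(10, 10, 10)), 1)
  expect_equal(measure_background(img, reg), 2.5)
  one <- array(FALSE, c(10, 10, 10)); one[3, 4, 5] <- TRUE
  img$values[3, 4, 5] <- 7
  expect_equal(measure_background(img, voi_mask(one, 1)), 7)
  expect_error(measure_background(img, voi_mask(array(FALSE, c(10, 10, 10)),
                                                1, allow_empty = TRUE)),
               "empty")
})

test_that("adaptive threshold recovers a binary hot object exactly", {
  vals <- array(1, c(20, 20, 20))
  vals[8:12, 8:12, 5:15] <- 10
  img <- tiny_image(vals)
  bgm <- array(FALSE, c(20, 20, 20)); bgm[1:3, 1:3, 1:3] <- TRUE
  params <- segmentation_params("adaptive_background",
                                background_region = voi_mask(bgm, 1))
  ctr <- img$origin + c(10, 10, 10) * img$spacing
  m <- segment_voi(img, params, ctr)
  expect_equal(attr(m, "threshold"), 2.5)
  expect_identical(m$values, vals == 10)

  # scale invariance: multiplying the image scales the threshold with it
  img2 <- img; img2$values <- img$values * 17
  m2 <- segment_voi(img2, params, ctr)
  expect_identical(m2$values, m$values)

  # threshold above the maximum
  p9 <- segmentation_params("adaptive_background", factor = 99,
                            background_region = voi_mask(bgm, 1))
  expect_error(segment_voi(img, p9, ctr), "empty segmentation")
})

test_that("segmentation returns one 26-connected component", {
  vals <- array(1, c(24, 24, 8))
  vals[3:6, 3:6, 3:5] <- 10     # target blob
  vals[18:21, 18:21, 3:5] <- 10 # decoy blob, not connected to the seed
  img <- tiny_image(vals)
  seed <- img$origin + c(4.5, 4.5, 4) * img$spacing
  m <- segment_voi(img, segmentation_params("percent_max", factor = 0.5),
                   seed, snap_radius_mm = 0)
  expect_equal(m$voxel_count, 4L * 4L * 3L)
  expect_true(all(which(m$values) %in% which(vals == 10)))
  # decoy excluded
  expect_false(m$values[19, 19, 4])
})

test_that("noiseless 2.5 ml insert segmentations are single components over the syringe pack", {
  sr <- small_revolver()
  act <- build_revolver_phantom(sr$geom, sr$spec)
  model <- imaging_model("tc99m", seed = 1)
  suv <- simulate_scan(act, model, sr$spec, noise = FALSE)
  cc <- syringe_centres(sr$geom)

  # adaptive 2.5 x background: all 7 syringe axes inside one mask
  bgm <- rasterize_sphere(c(35, 0, 0), 16, suv)
  m_ad <- segment_voi(suv,
                      segmentation_params("adaptive_background",
                                          background_region = bgm),
                      c(0, 0, 0))
  for (i in 1:7) {
    ijk <- as.integer(ceiling((c(cc[i, 1], cc[i, 2], 0) - suv$origin) /
                                suv$spacing))
    expect_true(m_ad$values[ijk[1], ijk[2], ijk[3]])
  }
  expect_gt(m_ad$volume_ml, 17.5)   # partial-volume inflation

  # percent-max 0.40 sits above the blurred 4:1 syringe profile at this
  # PSF, so it yields a smaller (still connected, central) mask
  m_pm <- segment_voi(suv, segmentation_params("percent_max"), c(0, 0, 0))
  ijk0 <- as.integer(ceiling((c(cc[1, 1], cc[1, 2], 0) - suv$origin) /
                               suv$spacing))
  expect_true(m_pm$values[ijk0[1], ijk0[2], ijk0[3]])
  expect_lt(m_pm$volume_ml, m_ad$volume_ml)
})
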