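# Texture families: worked examples, invariants, and brute-force oracle
# equivalence (the full 50-array sweep runs in the acceptance suite).

dir_x <- matrix(c(1L, 0L, 0L), 1, 3)

test_that("GLCM worked example: 2x2 grid, x-direction, symmetric pooling", {
  lev <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  p <- glcm_matrix(lev, n_levels = 2L, directions = dir_x)
  expect_equal(p[1, 1], 0.5)
  expect_equal(p[1, 2], 0.25)
  expect_equal(p[2, 1], 0.25)
  f <- glcm_features(lev, n_levels = 2L, directions = dir_x)
  expect_equal(unname(f["GLCM_Contrast"]), 0.5)
  expect_equal(unname(f["GLCM_Dissimilarity"]), 0.5)
  expect_equal(unname(f["GLCM_Homogeneity"]),
               0.5 + 0.25 / 2 + 0.25 / 2)  # sum p / (1 + (i-j)^2)
})

test_that("GLCM of a constant region is maximally homogeneous and degenerate in correlation", {
  lev <- array(5L, c(3, 3, 3))
  f <- glcm_features(lev, n_levels = 8L)
  expect_equal(unname(f["GLCM_Contrast"]), 0)
  expect_equal(unname(f["GLCM_Homogeneity"]), 1)
  expect_equal(unname(f["GLCM_Energy"]), 1)
  expect_true(is.na(f["GLCM_Correlation"]))
})

test_that("GLCM distance features are invariant to level-label reflection", {
  set.seed(2)
  lev <- oracle_random_levels(c(5, 5, 5), n_levels = 6L)
  flip <- 7L - lev
  f1 <- glcm_features(lev, n_levels = 6L)
  f2 <- glcm_features(flip, n_levels = 6L)
  for (nm in c("GLCM_Contrast", "GLCM_Homogeneity", "GLCM_Energy",
               "GLCM_Entropy_log2", "GLCM_Dissimilarity"))
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-12)
})

test_that("GLRLM worked examples on 1D rows", {
  lev <- array(c(1L, 1L, 2L), c(3, 1, 1))
  f <- glrlm_features(lev, n_levels = 2L, directions = dir_x)
  expect_equal(unname(f["GLRLM_SRE"]), 0.625)
  expect_equal(unname(f["GLRLM_RP"]), 2 / 3)

  n <- 7L
  g <- glrlm_features(array(1L, c(n, 1, 1)), n_levels = 2L,
                      directions = dir_x)
  expect_equal(unname(g["GLRLM_LRE"]), as.numeric(n^2))
  expect_equal(unname(g["GLRLM_RP"]), 1 / n)
})

test_that("GLZLM worked examples", {
  z <- glzlm_features(array(c(1L, 2L, 1L), c(3, 1, 1)), n_levels = 2L)
  expect_equal(unname(z["GLZLM_SZE"]), 1)
  expect_equal(unname(z["GLZLM_ZP"]), 1)

  z2 <- glzlm_features(array(3L, c(2, 3, 1)), n_levels = 4L)
  expect_equal(unname(z2["GLZLM_ZP"]), 1 / 6)
  expect_equal(unname(z2["GLZLM_LZE"]), 36)
})

test_that("zone sizes partition the mask", {
  set.seed(9)
  for (rep in 1:5) {
    lev <- oracle_random_levels(c(6, 5, 4), n_levels = 3L)
    m <- glzlm_matrix(lev, n_levels = 3L)
    expect_equal(sum(m * col(m)), sum(!is.na(lev)))
  }
})

test_that("NGLDM: constant region degenerate values and checkerboard maximality", {
  f0 <- ngldm_features(array(2L, c(4, 4, 1)), n_levels = 4L)
  expect_equal(unname(f0["NGLDM_Contrast"]), 0)
  expect_equal(unname(f0["NGLDM_Busyness"]), 0)
  expect_equal(unname(f0["NGLDM_Coarseness"]), 1e6)

  # fine-grained alternation produces larger neighbourhood differences than
  # coarse segregation of the same two levels at the same 50/50 proportion
  board <- array(0L, c(4, 4, 1))
  board[] <- (outer(1:4, 1:4, `+`) %% 2L) + 1L
  block <- array(1L, c(4, 4, 1)); block[3:4, , 1] <- 2L
  f_cb <- ngldm_features(board, n_levels = 2L)
  f_bl <- ngldm_features(block, n_levels = 2L)
  expect_gt(f_cb[["NGLDM_Contrast"]], f_bl[["NGLDM_Contrast"]])
})

test_that("masking a voxel removes it from all neighbourhood averages", {
  lev <- array(c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L), c(3, 3, 1))
  f_full <- ngldm_features(lev, n_levels = 2L)
  lev2 <- lev; lev2[2, 2, 1] <- NA_integer_   # mask out the odd voxel
  f_masked <- ngldm_features(lev2, n_levels = 2L)
  # with the hot voxel removed the region is constant
  expect_equal(unname(f_masked["NGLDM_Contrast"]), 0)
  expect_gt(f_full[["NGLDM_Contrast"]], 0)
})

test_that("all four families equal their brute-force oracles on random arrays", {
  set.seed(31)
  for (rep in 1:10) {
    nlev <- sample(2:5, 1)
    lev <- oracle_random_levels(c(5, 5, 5), n_levels = nlev)
    expect_equal(glcm_features(lev, nlev), oracle_glcm(lev, nlev),
                 tolerance = 1e-10)
    expect_equal(glrlm_features(lev, nlev), oracle_glrlm(lev),
                 tolerance = 1e-10)
    expect_equal(glzlm_features(lev, nlev), oracle_glzlm(lev),
                 tolerance = 1e-10)
    expect_equal(ngldm_features(lev, nlev), oracle_ngldm(lev, nlev),
                 tolerance = 1e-10)
  }
})

test_that("texture features are translation invariant", {
  set.seed(5)
  lev <- oracle_random_levels(c(4, 4, 4), n_levels = 3L)
  pad <- array(NA_integer_, c(7, 7, 7))
  pad[2:5, 3:6, 2:5] <- lev
  for (fn in list(glcm_features, glrlm_features,
                  function(l, n) glzlm_features(l, n),
                  function(l, n) ngldm_features(l, n))) {
    expect_equal(fn(lev, 3L), fn(pad, 3L), tolerance = 1e-12)
  }
})

test_that("GLCM normalisation and percentage bounds hold on random inputs", {
  set.seed(8)
  for (rep in 1:10) {
    lev <- oracle_random_levels(c(5, 4, 3), n_levels = 4L)
    expect_equal(sum(glcm_matrix(lev, 4L)), 1, tolerance = 1e-12)
    rp <- glrlm_features(lev, 4L)[["GLRLM_RP"]]
    zp <- glzlm_features(lev, 4L)[["GLZLM_ZP"]]
    expect_true(rp > 0 && rp <= 1)
    expect_true(zp > 0 && zp <= 1)
  }
})
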