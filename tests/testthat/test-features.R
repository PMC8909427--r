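test_that("fixed-bin discretization follows the floor formula", {
  img <- image_volume(array(c(0, 24.9, 25, 49, 0, 0, 0, 0), c(2, 2, 2)))
  msk <- binary_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
  d <- discretize(img, msk, 25)
  expect_equal(sort(d$levels[d$levels > 0]), c(1, 1, 2, 2))
  expect_equal(d$n_levels, 2L)

  const <- image_volume(array(7, c(2, 2, 2)))
  dc <- discretize(const, msk, 25)
  expect_equal(unique(dc$levels[dc$levels > 0]), 1L)
  expect_equal(dc$n_levels, 1L)

  expect_error(discretize(img, msk, 0), "bin_width")
})

test_that("first-order statistics match hand arithmetic", {
  img <- image_volume(array(c(1, 2, 3, 4, 9, 9, 9, 9), c(2, 2, 2)))
  msk <- binary_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
  f <- first_order_features(img, msk, bin_width = 1)
  expect_equal(unname(f["firstorder_Maximum"]), 4)
  expect_equal(unname(f["firstorder_Minimum"]), 1)
  expect_equal(unname(f["firstorder_Mean"]), 2.5)
  expect_equal(unname(f["firstorder_Variance"]), 1.25)  # population
  expect_equal(unname(f["firstorder_Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["firstorder_Entropy"]), 2)  # 4 equal bins -> log2(4)

  cimg <- image_volume(array(5, c(2, 2, 2)))
  fc <- first_order_features(cimg, msk)
  expect_equal(unname(fc["firstorder_Variance"]), 0)
  expect_equal(unname(fc["firstorder_Entropy"]), 0)
  expect_equal(unname(fc["firstorder_Skewness"]), 0)
})

test_that("first-order moments agree with independent formulas on random ROIs", {
  set.seed(3)
  vals <- rnorm(40, 50, 12)
  img <- image_volume(array(c(vals, rep(0, 24)), c(4, 4, 4)))
  msk <- binary_mask(array(c(rep(TRUE, 40), rep(FALSE, 24)), c(4, 4, 4)))
  f <- first_order_features(img, msk)
  n <- length(vals); m <- mean(vals)
  expect_equal(unname(f["firstorder_Median"]), median(vals))
  expect_equal(unname(f["firstorder_RootMeanSquared"]),
               sqrt(mean(vals^2)), tolerance = 1e-12)
  expect_equal(unname(f["firstorder_Skewness"]),
               (sum((vals - m)^3) / n) / (sum((vals - m)^2) / n)^1.5,
               tolerance = 1e-12)
  expect_equal(unname(f["firstorder_Kurtosis"]),
               (sum((vals - m)^4) / n) / (sum((vals - m)^2) / n)^2,
               tolerance = 1e-12)
})

test_that("shape features match unit-cube geometry", {
  single <- binary_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)))
  s <- shape_features(single)
  expect_equal(unname(s["shape_VoxelVolume"]), 1)
  expect_equal(unname(s["shape_SurfaceAreaApprox"]), 6)

  cube <- binary_mask(array(TRUE, c(3, 3, 3)))
  pad <- array(FALSE, c(5, 5, 5)); pad[2:4, 2:4, 2:4] <- TRUE
  s3 <- shape_features(binary_mask(pad))
  expect_equal(unname(s3["shape_VoxelVolume"]), 27)
  expect_equal(unname(s3["shape_SurfaceAreaApprox"]), 54)
  expect_equal(unname(s3["shape_Maximum3DDiameter"]), sqrt(12),
               tolerance = 1e-12)

  # cube sphericity matches the closed form pi^(1/3) (6 V)^(2/3) / A
  expect_equal(unname(s3["shape_Sphericity"]),
               pi^(1 / 3) * (6 * 27)^(2 / 3) / 54, tolerance = 1e-12)
  # sphericity never exceeds 1 for face-counted surfaces
  ballm <- make_phantom(grid_shape = c(32, 32, 32), radius_mm = 8,
                        seed = 1)$mask
  expect_lt(unname(shape_features(ballm)["shape_Sphericity"]), 1)
})

test_that("GLCM features match brute-force counting and conventions", {
  # 3x3x1 checkerboard of two levels
  lv <- array(0L, c(3, 3, 1))
  lv[, , 1] <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2, 1), 3, 3)
  img <- image_volume(array(as.numeric(lv) * 25 - 12, c(3, 3, 1)))
  msk <- binary_mask(array(TRUE, c(3, 3, 1)))
  d <- discretize(img, msk, 25)
  expect_equal(d$levels, lv)
  g <- glcm_features(d)
  expect_lte(unname(g["glcm_Correlation"]), 0)  # anti-correlated neighbors

  const <- discretize(image_volume(array(1, c(3, 3, 2))),
                      binary_mask(array(TRUE, c(3, 3, 2))), 25)
  expect_message(gc <- glcm_features(const), "single-level")
  expect_equal(unname(gc["glcm_Contrast"]), 0)
  expect_equal(unname(gc["glcm_MCC"]), 1)
  expect_equal(unname(gc["glcm_Correlation"]), 1)
})

test_that("all texture matrices equal their enumeration oracles", {
  set.seed(77)
  for (i in 1:25) {
    d <- random_roi(c(sample(2:4, 1), sample(2:4, 1), sample(1:2, 1)),
                    n_levels = sample(2:4, 1))
    lv <- d$levels; ng <- d$n_levels; dm <- dim(lv)
    glcm <- segstab:::.cpp_glcm_counts(as.vector(lv), dm, ng)
    dim(glcm) <- c(ng, ng, 13)
    expect_equal(glcm, oracle_glcm(lv, ng), ignore_attr = TRUE)

    glrlm <- segstab:::.cpp_glrlm_counts(as.vector(lv), dm, ng)
    dim(glrlm) <- c(ng, max(dm), 13)
    expect_equal(glrlm, oracle_glrlm(lv, ng), ignore_attr = TRUE)

    gldm <- segstab:::.cpp_gldm_counts(as.vector(lv), dm, ng, 0L)
    expect_equal(unclass(gldm), oracle_gldm(lv, ng), ignore_attr = TRUE)

    ngt <- segstab:::.cpp_ngtdm_sums(as.vector(lv), dm, ng)
    want <- oracle_ngtdm(lv, ng)
    expect_equal(ngt$s, want$s, tolerance = 1e-12)
    expect_equal(ngt$n, want$n)

    zones <- segstab:::glszm_zones(d)
    want_z <- oracle_glszm_zones(lv)
    key <- function(z) sort(paste(z$level, z$size))
    expect_equal(key(zones), key(want_z))
  }
})

test_that("GLRLM features follow run arithmetic on tiny fixtures", {
  img <- image_volume(array(c(10, 10, 10), c(3, 1, 1)))
  msk <- binary_mask(array(TRUE, c(3, 1, 1)))
  d <- discretize(img, msk, 25)
  f <- glrlm_features(d)
  # single run of length 3 along the row direction: GLN = 1, entropy 0
  # (other directions see three runs of length 1: GLN = 3)
  counts <- segstab:::.cpp_glrlm_counts(as.vector(d$levels), dim(d$levels), 1L)
  dim(counts) <- c(1, 3, 13)
  expect_equal(counts[1, , 1], c(0, 0, 1))      # x direction: one run of 3
  expect_equal(counts[1, , 2], c(3, 0, 0))      # y direction: three runs of 1
  expect_equal(unname(f["glrlm_RunEntropy"]), 0)
})

test_that("GLSZM and GLDM degenerate fixtures follow the definitions", {
  const <- discretize(image_volume(array(1, c(3, 3, 3))),
                      binary_mask(array(TRUE, c(3, 3, 3))), 25)
  z <- glszm_features(const)
  expect_equal(unname(z["glszm_GrayLevelVariance"]), 0)
  expect_equal(unname(z["glszm_GrayLevelNonUniformityNormalized"]), 1)
  # constant ROI: GLDM GLN equals the voxel count
  expect_equal(unname(gldm_features(const)["gldm_GrayLevelNonUniformity"]), 27)
  # constant ROI: NGTDM coarseness capped
  expect_message(ng <- ngtdm_features(const), "capped")
  expect_equal(unname(ng["ngtdm_Coarseness"]), 1e6)

  # two equal-size blobs of distinct levels, far apart -> GLNN = 0.5
  a <- array(0, c(7, 3, 1))
  a[1:2, 1, 1] <- 10; a[6:7, 1, 1] <- 60
  img <- image_volume(a)
  msk <- binary_mask(array(a != 0, dim(a)))
  dz <- discretize(img, msk, 25)
  zz <- glszm_features(dz)
  expect_equal(unname(zz["glszm_GrayLevelNonUniformityNormalized"]), 0.5)

  single <- discretize(image_volume(array(c(5, 0), c(2, 1, 1))),
                       binary_mask(array(c(TRUE, FALSE), c(2, 1, 1))), 25)
  dep <- segstab:::.cpp_gldm_counts(as.vector(single$levels),
                                    dim(single$levels), 1L, 0L)
  expect_equal(unclass(dep)[1, 1], 1)  # one voxel with dependence 0
})

test_that("NGTDM coarseness matches a hand-computed 3x3x1 grid", {
  lv <- array(0L, c(3, 3, 1))
  lv[, , 1] <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2, 1), 3, 3)
  s <- numeric(2); n <- numeric(2)
  for (i in 1:3) for (j in 1:3) {
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 3 && jj >= 1 && jj <= 3) nb <- c(nb, lv[ii, jj, 1])
    }
    g <- lv[i, j, 1]
    s[g] <- s[g] + abs(g - mean(nb))
    n[g] <- n[g] + 1
  }
  want <- 1 / sum(n / 9 * s)
  img <- image_volume(array(as.numeric(lv) * 25 - 12, c(3, 3, 1)))
  d <- discretize(img, binary_mask(array(TRUE, c(3, 3, 1))), 25)
  expect_equal(unname(ngtdm_features(d)["ngtdm_Coarseness"]), want,
               tolerance = 1e-12)
})

test_that("extract_all emits the full schema deterministically", {
  ph <- make_phantom(grid_shape = c(32, 32, 32), radius_mm = 8, seed = 12)
  cfg <- run_config()
  f1 <- extract_all(ph$image, ph$mask, cfg)
  f2 <- extract_all(ph$image, ph$mask, cfg)
  expect_identical(f1, f2)
  expect_true(all(core_feature_names() %in% names(f1)))
  expect_true(all(is.finite(f1)))

  sel <- run_config(feature_list = c("glcm_MCC", "firstorder_Mean"))
  expect_named(extract_all(ph$image, ph$mask, sel),
               c("glcm_MCC", "firstorder_Mean"))
  bad <- run_config(feature_list = "not_a_feature")
  expect_error(extract_all(ph$image, ph$mask, bad), "unsupported")
})

test_that("firstorder Maximum survives perturbations that keep the argmax", {
  ph <- make_phantom(grid_shape = c(32, 32, 32), radius_mm = 8,
                     texture_sd_hu = 20, seed = 44)
  # plant the global maximum well inside the core (deeper than tau)
  img <- ph$image
  img$voxels[16, 16, 16] <- 500
  cfg <- perturbation_config(n_realizations = 5, seed = 9)
  reals <- generate_realizations(ph$mask, cfg)
  vals <- vapply(reals, function(m)
    unname(first_order_features(img, m)["firstorder_Maximum"]), 0)
  expect_true(all(vals == 500))
})
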