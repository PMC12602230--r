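test_that("bias correction is near-identity on a flat image", {
  vol <- hb_volume(array(100, c(20, 20, 20)))
  out <- correct_bias(vol)
  rms <- sqrt(mean((out$bias_field$values - 1)^2))
  expect_lt(rms, 0.01)
  expect_equal(out$corrected$values, vol$values / out$bias_field$values)
})

test_that("bias correction recovers the generator's known 20% field", {
  co <- generate_cohort(cohort_config(n_patients = 3, seed = 11))
  for (p in co$patients) {
    est <- correct_bias(p$volume, p$mask, positivity = "shift")
    inside <- p$mask$values == 1L
    r <- cor(est$bias_field$values[inside], p$bias_field$values[inside])
    expect_gte(r, 0.9)
  }
})

test_that("non-positive voxels are rejected in strict mode and shifted otherwise", {
  vol <- hb_volume(array(c(0, rep(50, 26)), c(3, 3, 3)))
  expect_error(correct_bias(vol, positivity = "error"), "non-positive")
  expect_warning(out <- correct_bias(vol, positivity = "shift"), "shifting")
  expect_true(all(is.finite(out$corrected$values)))
})

test_that("isotropic resampling preserves extent, binarity and mask volume", {
  # 10 voxels at 2 mm -> 20 +/- 1 voxels at 1 mm
  vol <- hb_volume(array(rnorm(10 * 8 * 6, 100, 5), c(10, 8, 6)),
                   spacing = c(2, 2, 2))
  msk <- hb_mask(array(1L, c(10, 8, 6)), spacing = c(2, 2, 2))
  out <- resample_isotropic(vol, msk, 1)
  expect_true(abs(dim(out$volume$values)[1] - 20) <= 1)
  expect_equal(out$volume$spacing, c(1, 1, 1))
  expect_true(all(out$mask$values %in% c(0L, 1L)))
  expect_identical(dim(out$volume$values), dim(out$mask$values))

  # physical mask volume conserved within 5% on spheres
  sph <- make_sphere_mask(6, spacing = c(0.9, 0.9, 3))
  img <- hb_volume(array(1.0, dim(sph$values)), spacing = sph$spacing)
  rs <- resample_isotropic(img, sph, 1)
  expect_lt(abs(mask_volume_mm3(rs$mask) - mask_volume_mm3(sph)) /
              mask_volume_mm3(sph), 0.05)

  tiny <- hb_mask(array(0L, c(10, 8, 6)), spacing = c(2, 2, 2))
  expect_error(resample_isotropic(vol, tiny, 1), "empty")
})

test_that("dominant-lesion selection picks the largest with a deterministic tie-break", {
  small <- make_sphere_mask(3)
  large <- make_sphere_mask(5)
  expect_identical(select_dominant_lesion(list(small, large)), large)
  expect_identical(select_dominant_lesion(list(small)), small)

  # exact tie: one-voxel masks at different positions
  a <- hb_mask(array(0L, c(5, 5, 5))); a$values[4, 4, 4] <- 1L
  b <- hb_mask(array(0L, c(5, 5, 5))); b$values[2, 2, 2] <- 1L
  expect_identical(select_dominant_lesion(list(a, b)), b)
  empty <- hb_mask(array(0L, c(4, 4, 4)))
  expect_error(select_dominant_lesion(list(empty)), "empty")
})

test_that("ICC(2,1) matches the ANOVA mean-squares decomposition", {
  r <- matrix(rep(1:6, 2), ncol = 2)
  expect_equal(icc_agreement(r), 1.0)

  set.seed(31)
  subj <- rnorm(50, sd = 3)
  ratings <- cbind(subj + rnorm(50), subj + rnorm(50), subj + rnorm(50))
  # oracle: mean squares from aov on the long-format two-way layout
  long <- data.frame(y = as.vector(ratings),
                     subject = factor(rep(1:50, 3)),
                     rater = factor(rep(1:3, each = 50)))
  ms <- summary(aov(y ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 3; n <- 50
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_agreement(ratings), oracle, tolerance = 1e-9)

  expect_error(icc_agreement(matrix(1:2, nrow = 1)), "subjects")
  expect_error(icc_agreement(matrix(rep(2, 10), ncol = 2)), "degenerate")
})

test_that("the reproducibility filter keeps only concordant features", {
  set.seed(8)
  base <- matrix(rnorm(40 * 3, sd = 4), 40, 3,
                 dimnames = list(NULL, c("f1", "f2", "f3")))
  a <- as.data.frame(base + rnorm(120, sd = 0.2))   # highly reproducible
  b <- as.data.frame(base + rnorm(120, sd = 0.2))
  b$f3 <- rnorm(40, sd = 4)                         # rater-discordant
  keep <- icc_filter_features(a, b, threshold = 0.75)
  expect_true(all(c("f1", "f2") %in% keep))
  expect_false("f3" %in% keep)
})

test_that("image and mask geometry stay in lockstep through preprocessing", {
  co <- generate_cohort(cohort_config(n_patients = 2, seed = 13))
  pp <- preprocess_patient(co$patients[[1]], normalize_intensity = "tissue")
  expect_identical(dim(pp$volume$values), dim(pp$mask$values))
  expect_equal(pp$volume$spacing, pp$mask$spacing)
  expect_equal(pp$volume$spacing, c(1, 1, 1))
  expect_gt(mask_count(pp$mask), 0)
})
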