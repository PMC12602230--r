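test_that("fixed-bin-width discretization follows the floor rule", {
  expect_identical(discretize(rep(3.7, 10), bin_width = 25), rep(1L, 10))
  expect_identical(discretize(c(0, 1, 2, 3), bin_width = 1), 1:4)
  set.seed(1)
  x <- runif(40000, 0, 100 - 1e-9)
  lv <- discretize(x, bin_width = 25)
  counts <- tabulate(lv, 4)
  expect_true(all(abs(counts / 10000 - 1) < 0.05))   # histogram oracle
  expect_error(discretize(x, bin_width = 0), "bin_width")
  expect_error(discretize(numeric(0), bin_width = 1), "empty")
})

test_that("texture matrices reduce correctly on a constant block", {
  lv <- array(0L, c(4, 4, 4))
  lv[2:3, 2:3, 2:3] <- 1L
  tm <- texture_matrices(lv)
  p <- tm$glcm / sum(tm$glcm)
  expect_equal(sum(p^2), 1.0)                      # joint energy
  expect_equal(-sum(p[p > 0] * log2(p[p > 0])), 0) # joint entropy
  expect_equal(nrow(tm$glszm), 1L)                 # one zone
  expect_equal(tm$glszm[1, 2], 8L)
  expect_error(texture_matrices(array(0L, c(3, 3, 3))), "empty")
})

test_that("GLCM counts equal brute-force pair enumeration on a checkerboard", {
  lv <- array(0L, c(4, 4, 1))
  lv[, , 1] <- (outer(1:4, 1:4, "+") %% 2) + 1L
  tm <- texture_matrices(lv)
  # exhaustive enumeration over the 13 unique directions, symmetrized
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0), c(1,0,1),
                c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1), c(1,1,-1),
                c(1,-1,1), c(1,-1,-1))
  oracle <- matrix(0, 2, 2)
  d <- dim(lv)
  for (x in 1:4) for (y in 1:4) for (dd in seq_len(nrow(dirs))) {
    xx <- x + dirs[dd, 1]; yy <- y + dirs[dd, 2]; zz <- 1 + dirs[dd, 3]
    if (xx < 1 || xx > 4 || yy < 1 || yy > 4 || zz != 1) next
    a <- lv[x, y, 1]; b <- lv[xx, yy, 1]
    oracle[a, b] <- oracle[a, b] + 1
    oracle[b, a] <- oracle[b, a] + 1
  }
  expect_equal(unname(tm$glcm), oracle)
})

test_that("GLRLM runs equal hand enumeration on a 1D strip", {
  lv <- array(0L, c(5, 1, 1))
  lv[, 1, 1] <- c(1L, 1L, 2L, 2L, 2L)
  R <- texture_matrices(lv)$glrlm
  # along x: runs (level 1, len 2) and (level 2, len 3); every other
  # direction contributes only unit-length runs (2 of level 1, 3 of level 2
  # per direction, 12 directions)
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 3], 1)
  expect_equal(R[1, 1], 2 * 12)
  expect_equal(R[2, 1], 3 * 12)
  expect_equal(sum(R), 2 + 5 * 12)
})

test_that("first-order and GLCM features match brute force on a 4x4 phantom", {
  set.seed(7)
  vals <- sample(1:4, 16, replace = TRUE)
  lv <- array(0L, c(4, 4, 1)); lv[, , 1] <- vals
  x <- as.numeric(vals)
  fo <- habitatbm:::first_order_features(x, as.integer(vals), 1)
  p <- tabulate(vals, 4) / 16
  expect_equal(unname(fo["Mean"]), mean(x), tolerance = 1e-9)
  expect_equal(unname(fo["Energy"]), sum(x^2), tolerance = 1e-9)
  expect_equal(unname(fo["Entropy"]), -sum(p[p > 0] * log2(p[p > 0])),
               tolerance = 1e-9)
  expect_equal(unname(fo["Variance"]), mean((x - mean(x))^2), tolerance = 1e-9)

  g <- habitatbm:::glcm_features(texture_matrices(lv)$glcm)
  P <- texture_matrices(lv)$glcm; P <- P / sum(P)
  i <- matrix(1:4, 4, 4); j <- t(i)
  expect_equal(unname(g["Contrast"]), sum((i - j)^2 * P), tolerance = 1e-9)
  expect_equal(unname(g["JointEnergy"]), sum(P^2), tolerance = 1e-9)
  expect_equal(unname(g["Autocorrelation"]), sum(i * j * P), tolerance = 1e-9)
  expect_equal(unname(g["MaximumProbability"]), max(P), tolerance = 1e-9)
})

test_that("the default inventory is 1834 features with the printed family counts", {
  cfg <- feature_config()
  nms <- feature_names(cfg)
  expect_length(nms, 1834L)
  expect_equal(sum(grepl("__firstorder__", nms)), 360L)
  expect_equal(sum(grepl("^shape__", nms)), 14L)
  expect_equal(sum(grepl("__glcm__", nms)), 20L * 22L)
  expect_equal(sum(grepl("__glrlm__", nms)), 20L * 16L)
  expect_equal(sum(grepl("__glszm__", nms)), 20L * 16L)
  expect_equal(sum(grepl("__gldm__", nms)), 20L * 14L)
  expect_equal(sum(grepl("__ngtdm__", nms)), 20L * 5L)
  expect_length(habitatbm:::filter_type_names(cfg), 20L)
  expect_false(any(duplicated(nms)))
})

test_that("shape features are accurate on analytic phantoms", {
  sph <- make_sphere_mask(5)
  sf <- habitatbm:::shape_features(sph)
  expect_gt(sf[["Sphericity"]], 0.95)
  expect_lt(abs(sf[["MeshVolume"]] - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.05)
  expect_equal(sf[["VoxelVolume"]], mask_count(sph))
  expect_equal(sf[["Elongation"]], 1, tolerance = 0.05)

  cube <- hb_mask(array(0L, c(14, 14, 14)))
  cube$values[3:12, 3:12, 3:12] <- 1L
  sfc <- habitatbm:::shape_features(cube)
  # orientation-corrected facet area; sharp 90-degree edges are partially
  # smoothed by any local estimator, hence the 7% band
  expect_lt(abs(sfc[["SurfaceArea"]] - 600) / 600, 0.07)
  # the mesh surface sits half a voxel outside the outer voxel centres, so
  # the diameter is the space diagonal of the 10 mm cube
  expect_equal(sfc[["Maximum3DDiameter"]], sqrt(3) * 10, tolerance = 0.02)
})

test_that("shape ignores intensity and first-order mean shifts with the image", {
  p <- make_test_patient()
  cfg <- feature_config()
  f1 <- extract_region_features(p$volume, p$mask, cfg)
  shifted <- hb_volume(p$volume$values + 500, p$volume$spacing)
  f2 <- extract_region_features(shifted, p$mask, cfg)
  sh <- grepl("^shape__", names(f1))
  expect_equal(f1[sh], f2[sh], tolerance = 1e-9)
  expect_equal(f2[["original__firstorder__Mean"]],
               f1[["original__firstorder__Mean"]] + 500, tolerance = 1e-6)
})

test_that("small regions yield a recorded missing row", {
  p <- make_test_patient()
  tiny <- hb_mask(array(0L, dim(p$mask$values)), p$mask$spacing)
  idx <- which(p$mask$values == 1L)[1:5]
  tiny$values[idx] <- 1L
  f <- extract_region_features(p$volume, tiny, feature_config())
  expect_true(all(is.na(f)))
  expect_match(attr(f, "reason"), "voxels")
})

test_that("habitat fusion yields 5502 columns with documented imputation", {
  cfg <- feature_config()
  nms <- feature_names(cfg)
  v <- setNames(rnorm(length(nms)), nms)
  fused <- fuse_habitat_features(list(v, v * 2, v * 3), k = 3)
  expect_length(fused, 5502L)
  expect_true(all(grepl("^habitat[123]__", names(fused))))

  single <- fuse_habitat_features(list(v), k = 1)
  expect_equal(as.numeric(single), as.numeric(v))

  miss <- fuse_habitat_features(list(v, v, NULL), k = 3)
  expect_equal(attr(miss, "missing_habitats"), 3L)
  expect_true(all(miss[grepl("^habitat3__", names(miss))] == 0))

  bad <- v; names(bad) <- rev(names(bad))
  expect_error(fuse_habitat_features(list(v, bad, v), k = 3), "inconsistent")
})
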