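test_that("local feature maps have 19 named channels and sane degenerate values", {
  vol <- hb_volume(array(7, c(9, 9, 9)))
  msk <- hb_mask(array(1L, c(9, 9, 9)))
  lf <- local_features(vol, msk)
  expect_equal(ncol(lf$features), 19L)
  expect_identical(colnames(lf$features), local_feature_names())
  # constant image: location channels equal the constant, dispersion zero
  expect_true(all(abs(lf$features[, "mean"] - 7) < 1e-12))
  expect_true(all(abs(lf$features[, "median"] - 7) < 1e-12))
  expect_true(all(lf$features[, "range"] == 0))
  expect_true(all(lf$features[, "entropy"] == 0))
  expect_error(local_features(vol, msk, window = 4), "odd")
  expect_error(local_features(vol, msk, window = 1), "odd")
})

test_that("each channel equals a direct formula evaluation on an enumerated window", {
  set.seed(99)
  d <- c(7, 7, 7)
  vol <- hb_volume(array(rnorm(prod(d), 100, 20), d))
  msk <- hb_mask(array(1L, d))
  lf <- local_features(vol, msk, window = 5)
  centre <- which(lf$voxels == sub2ind_r(4, 4, 4, d))
  w <- as.vector(vol$values[2:6, 2:6, 2:6])  # the 125 window values
  q <- quantile(w, c(.05, .10, .25, .40, .60, .75, .90, .95), names = FALSE)
  expected <- c(mean(w), median(w), min(w), max(w), max(w) - min(w),
                q, mean(w[w >= q[2] & w <= q[7]]),
                mean(w[w >= q[3] & w <= q[6]]),
                (q[3] + q[6]) / 2, (min(w) + max(w)) / 2,
                sqrt(mean(w^2)),
                local({
                  b <- pmin(floor(32 * (w - min(w)) / (max(w) - min(w))), 31)
                  p <- table(b) / length(w)
                  -sum(p * log2(p))
                }))
  expect_equal(unname(lf$features[centre, ]), expected, tolerance = 1e-12)
})

test_that("masked windows ignore out-of-lesion voxels", {
  d <- c(7, 7, 7)
  arr <- array(1000, d)               # poison value outside the mask
  arr[3:5, 3:5, 3:5] <- 50
  msk <- hb_mask(array(0L, d)); msk$values[3:5, 3:5, 3:5] <- 1L
  lf <- local_features(hb_volume(arr), msk, window = 5)
  expect_true(all(lf$features[, "maximum"] == 50))
})

test_that("validity indices select the generating component count on separated blobs", {
  set.seed(21)
  n <- 200
  X <- rbind(matrix(rnorm(n * 19), ncol = 19),
             matrix(rnorm(n * 19, mean = 10), ncol = 19),
             matrix(rnorm(n * 19, mean = -10), ncol = 19))
  sk <- select_k(X, 3:8, n_seeds = 5, seed = 1)
  expect_equal(sk$k, 3L)
  expect_gt(max(sk$diagnostics$silhouette), 0.8)
  expect_false(sk$weak_structure)
  # all three indices agree at the same k
  d <- sk$diagnostics
  expect_equal(d$k[which.max(d$silhouette)], 3)
  expect_equal(d$k[which.max(d$calinski_harabasz)], 3)
  expect_equal(d$k[which.min(d$davies_bouldin)], 3)
})

test_that("structureless data is flagged as weakly clustered", {
  set.seed(22)
  X <- matrix(runif(500 * 6), ncol = 6)
  sk <- select_k(X, 3:6, n_seeds = 3, seed = 1)
  expect_true(sk$weak_structure)
  expect_true(all(sk$diagnostics$silhouette <= 0.5))
})

test_that("k-range preconditions are enforced", {
  X <- matrix(rnorm(40 * 3), ncol = 3)
  expect_error(select_k(X, 1:5), "k_range")
  expect_error(select_k(X, 3:60), "k_range")
  expect_error(select_k(matrix(rep(1:3, each = 3), ncol = 1), 2:4), "distinct")
})

test_that("silhouette implementation matches the brute-force pairwise oracle", {
  set.seed(23)
  X <- matrix(rnorm(60 * 4), ncol = 4)
  labels <- sample(1:3, 60, replace = TRUE)
  # brute-force oracle
  D <- as.matrix(dist(X))
  s_oracle <- vapply(1:60, function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_equal(silhouette_mean(X, labels), mean(s_oracle), tolerance = 1e-12)
  # independent cross-check against cluster::silhouette
  sil <- cluster::silhouette(labels, dist(X))
  expect_equal(silhouette_mean(X, labels), mean(sil[, "sil_width"]),
               tolerance = 1e-9)
})

test_that("Hungarian label matching equals exhaustive permutation search", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1); out <- NULL
    for (i in 1:n) out <- rbind(out, cbind(i, p + (p >= i)))
    out
  }
  set.seed(24)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    a <- sample(1:k, 40, replace = TRUE)
    b <- sample(1:k, 40, replace = TRUE)
    C <- as.matrix(table(factor(a, 1:k), factor(b, 1:k)))
    best <- max(apply(perms(k), 1, function(p) sum(C[cbind(1:k, p)]))) / 40
    expect_equal(matched_agreement(a, b, k), best)
  }
})

test_that("matched agreement is invariant under relabeling", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(matched_agreement(a, c(3, 3, 1, 1, 2, 2)), 1.0)
  set.seed(25)
  b <- sample(1:3, 6, replace = TRUE)
  perm <- c(2, 3, 1)
  expect_equal(matched_agreement(a, b), matched_agreement(a, perm[b]))
})

test_that("habitat models are stable across seeds on separable data and honest on noise", {
  set.seed(26)
  X <- rbind(matrix(rnorm(300 * 19), ncol = 19),
             matrix(rnorm(300 * 19, mean = 8), ncol = 19),
             matrix(rnorm(300 * 19, mean = -8), ncol = 19))
  colnames(X) <- local_feature_names()
  hm <- fit_habitats(X, 3, n_seeds = 5, seed = 1)
  expect_gt(hm$consistency, 0.9)

  # independent uniform-random labelings: Monte-Carlo expectation oracle
  set.seed(27)
  mc <- replicate(50, matched_agreement(sample(1:3, 300, TRUE),
                                        sample(1:3, 300, TRUE), 3))
  expect_gt(mean(mc), 1 / 3)         # matching inflates chance agreement
  expect_lt(mean(mc), 0.45)
})

test_that("degenerate channels are dropped with a warning", {
  set.seed(28)
  X <- cbind(matrix(rnorm(100 * 18), ncol = 18), const = 1)
  colnames(X) <- local_feature_names()
  expect_warning(hm <- fit_habitats(X, 2, n_seeds = 2, seed = 1), "degenerate")
  expect_equal(length(hm$scaler$channels), 18L)
})

test_that("assignment is nearest-center, deterministic, and recovers separable phenotypes", {
  set.seed(29)
  X <- rbind(matrix(rnorm(200 * 19), ncol = 19),
             matrix(rnorm(200 * 19, mean = 8), ncol = 19))
  colnames(X) <- local_feature_names()
  hm <- fit_habitats(X, 2, n_seeds = 3, seed = 1)
  # a synthetic map whose first voxel sits exactly on a model center
  centre_raw <- hm$centers[2, ] * hm$scaler$sd + hm$scaler$mean
  map <- list(features = rbind(centre_raw, X[1:5, ]), voxels = 1:6,
              dim = c(6, 1, 1), spacing = c(1, 1, 1))
  class(map) <- "local_feature_map"
  lab <- assign_habitats(hm, map)
  expect_equal(lab$values[1], 2L)

  # channel mismatch is an error
  bad <- map; colnames(bad$features) <- paste0("x", 1:19)
  expect_error(assign_habitats(hm, bad), "channel mismatch")

  # separable-phenotype recovery (best-permutation oracle): sharp-edged
  # phenotypes, mild bias, lesions large enough that interface partial
  # volume does not dominate
  co <- generate_cohort(cohort_config(n_patients = 4,
                                      native_spacing = c(1, 1, 1),
                                      diameter_range_mm = c(22, 28),
                                      blend_sigma_mm = 0,
                                      bias_amplitude = 0.05,
                                      seed = 77))
  prep <- lapply(co$patients, preprocess_patient,
                 normalize_intensity = "tissue")
  maps <- lapply(prep, function(p) local_features(p$volume, p$mask))
  hm2 <- fit_habitats(pool_voxel_features(maps, 1500, 1), 3, n_seeds = 5,
                      seed = 1)
  accs <- vapply(seq_along(maps), function(i) {
    hl <- assign_habitats(hm2, maps[[i]])
    inside <- prep[[i]]$mask$values == 1L
    tv <- prep[[i]]$truth$values[inside]
    tv[tv < 1L] <- 1L; tv[tv > 3L] <- 3L
    matched_agreement(as.integer(tv), as.integer(hl$values[inside]), 3)
  }, 0)
  expect_gt(mean(accs), 0.9)
})

test_that("equidistant voxels break ties toward the lowest label", {
  hm <- structure(list(k = 2,
                       centers = rbind(c(1, 0), c(-1, 0)),
                       scaler = list(mean = c(a = 0, b = 0),
                                     sd = c(a = 1, b = 1),
                                     channels = c("a", "b"))),
                  class = "habitat_model")
  map <- list(features = matrix(0, 1, 2, dimnames = list(NULL, c("a", "b"))),
              voxels = 1L, dim = c(1, 1, 1), spacing = c(1, 1, 1))
  class(map) <- "local_feature_map"
  expect_equal(assign_habitats(hm, map)$values[1], 1L)
})
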