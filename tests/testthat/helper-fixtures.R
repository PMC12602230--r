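# Shared fixtures, built in code.

# Binary sphere mask of radius r_mm centred in a cubic grid.
make_sphere_mask <- function(r_mm, spacing = c(1, 1, 1), pad_mm = 3) {
  d <- as.integer(ceiling((2 * r_mm + 2 * pad_mm) / spacing)) + 1L
  ctr <- (d + 1) / 2
  cx <- (seq_len(d[1]) - ctr[1]) * spacing[1]
  cy <- (seq_len(d[2]) - ctr[2]) * spacing[2]
  cz <- (seq_len(d[3]) - ctr[3]) * spacing[3]
  E <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  hb_mask(array(as.integer(E <= r_mm^2), d), spacing)
}

# Small deterministic image/mask pair for feature tests.
make_test_patient <- function(seed = 42, diameter = 14) {
  cfg <- cohort_config(n_patients = 2, native_spacing = c(1, 1, 1),
                       diameter_range_mm = c(diameter, diameter), seed = seed)
  generate_cohort(cfg)$patients[[1]]
}

# Cached small isotropic cohort used by several habitat/pipeline tests.
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      cohort_config(n_patients = 8, native_spacing = c(1, 1, 1),
                    diameter_range_mm = c(12, 20), seed = 202))
  }
  .fixture_env$cohort
}

# Exhaustive Shapley values for a model function f over p features,
# single-row x, background mean b: 2^p coalition enumeration.
exact_shapley <- function(f, x, b) {
  p <- length(x)
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  vals <- apply(subsets, 1, function(s) {
    z <- b; z[as.logical(s)] <- x[as.logical(s)]
    f(z)
  })
  for (j in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      s <- as.logical(subsets[r, ])
      if (s[j]) next
      size <- sum(s)
      w <- factorial(size) * factorial(p - size - 1) / factorial(p)
      s_with <- s; s_with[j] <- TRUE
      idx_with <- which(apply(subsets, 1, function(q) all(as.logical(q) == s_with)))
      phi[j] <- phi[j] + w * (vals[idx_with] - vals[r])
    }
  }
  phi
}

# 1-based linear index into a column-major 3D array.
sub2ind_r <- function(x, y, z, d) x + (y - 1) * d[1] + (z - 1) * d[1] * d[2]
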