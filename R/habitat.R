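# Voxel-wise local feature maps and population-level K-means habitat
# discovery with validity-index model selection and multi-seed stability.

#' Channel names of the local feature map
#'
#' The 19 per-voxel statistics computed on the moving window: a robust
#' quantile profile of the neighbourhood intensity distribution (mean,
#' median, extremes, eight percentiles, two trimmed means, midhinge,
#' midrange, RMS) plus range and a 32-bin entropy. Moment statistics
#' beyond the mean are deliberately absent: skewness/kurtosis-type
#' channels are unstable in 125-voxel windows and spread-type channels
#' flag subregion interfaces rather than phenotypes, which distorts
#' population clustering.
#' @return character vector of length 19.
#' @export
local_feature_names <- function() {
  c("mean", "median", "minimum", "maximum", "range", "p5", "p10", "p25",
    "p40", "p60", "p75", "p90", "p95", "trimmed_mean10", "trimmed_mean25",
    "midhinge", "midrange", "rms", "entropy")
}

#' Voxel-wise local feature map
#'
#' For every lesion voxel, computes the 19 statistics listed by
#' [local_feature_names()] on the `window^3` neighbourhood (default
#' 5x5x5). Neighbourhood statistics are computed over the in-mask window
#' voxels only (so boundary voxels are characterized by lesion tissue,
#' not by background), and the window is truncated at image borders.
#'
#' @param volume a preprocessed (isotropic) [hb_volume()].
#' @param mask an aligned nonempty [hb_mask()].
#' @param window odd window edge length >= 3, in voxels.
#' @return A `local_feature_map`: list with `features` (voxels x 19 matrix),
#'   `voxels` (linear indices into the grid), `dim`, and `spacing`.
#' @export
local_features <- function(volume, mask, window = 5) {
  check_aligned(volume, mask)
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  vox <- which(mask$values != 0L)
  if (!length(vox)) stop("mask is empty")
  f <- cpp_local_features(as.numeric(volume$values),
                          as.integer(mask$values != 0L), dim(volume$values),
                          as.integer(vox - 1L), as.integer(window))
  colnames(f) <- local_feature_names()
  structure(list(features = f, voxels = vox, dim = dim(volume$values),
                 spacing = volume$spacing),
            class = "local_feature_map")
}

#' Pool voxel features across patients
#'
#' Subsamples up to `per_patient` voxels from each patient's local feature
#' map (seeded) and stacks them so habitats are defined at the population
#' level and comparable across patients.
#'
#' @param maps list of `local_feature_map` objects (training cohort only).
#' @param per_patient maximum voxels retained per patient.
#' @param seed RNG seed for the subsample.
#' @return numeric matrix, pooled voxels x 19.
#' @export
pool_voxel_features <- function(maps, per_patient = 2000, seed = 1L) {
  with_seed(seed, function() {
    do.call(rbind, lapply(maps, function(m) {
      n <- nrow(m$features)
      if (n > per_patient) m$features[sort(sample.int(n, per_patient)), ,
                                      drop = FALSE]
      else m$features
    }))
  })
}

# ---- K-means machinery ------------------------------------------------------

# k-means++ seeding followed by Lloyd refinement.
kmeanspp <- function(X, k, seed) {
  with_seed(seed, function() {
    n <- nrow(X)
    centers <- matrix(0, k, ncol(X))
    centers[1, ] <- X[sample.int(n, 1), ]
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in seq_len(k)[-1]) {
      pr <- d2 / sum(d2)
      centers[j, ] <- X[sample.int(n, 1, prob = pr), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
    stats::kmeans(X, centers = centers, iter.max = 100)
  })
}

# squared Euclidean distances rows of X to rows of C
dist2_to_centers <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

#' Calinski-Harabasz index
#' @param X numeric matrix (rows = observations).
#' @param labels integer cluster labels.
#' @return variance-ratio criterion (higher = better separation).
#' @export
calinski_harabasz <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  grand <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    ci <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * sum((ci - grand)^2)
    ssw <- ssw + sum(sweep(Xi, 2, ci)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Davies-Bouldin index
#' @inheritParams calinski_harabasz
#' @return mean worst-pair scatter-to-separation ratio (lower = better).
#' @export
davies_bouldin <- function(X, labels) {
  gs <- sort(unique(labels)); k <- length(gs)
  C <- t(vapply(gs, function(g) colMeans(X[labels == g, , drop = FALSE]),
                numeric(ncol(X))))
  S <- vapply(seq_len(k), function(i) {
    Xi <- X[labels == gs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, C[i, ])^2)))
  }, 0)
  M <- as.matrix(stats::dist(C))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (S[i] + S[j]) / M[i, j], 0))
  }, 0))
}

#' Mean silhouette width
#' @inheritParams calinski_harabasz
#' @return mean silhouette over all observations (singletons score 0).
#' @export
silhouette_mean <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  gs <- sort(unique(labels))
  n <- nrow(X)
  s <- numeric(n)
  # mean distance of every point to every cluster
  md <- vapply(gs, function(g) rowMeans(D[, labels == g, drop = FALSE]), numeric(n))
  sizes <- vapply(gs, function(g) sum(labels == g), 0L)
  for (i in seq_len(n)) {
    gi <- match(labels[i], gs)
    if (sizes[gi] == 1) { s[i] <- 0; next }
    a <- md[i, gi] * sizes[gi] / (sizes[gi] - 1)   # exclude self
    b <- min(md[i, -gi])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the cluster count via validity indices
#'
#' For each k in `k_range`, K-means (k-means++ seeding) is repeated
#' `n_seeds` times; the best-inertia fit per k is scored by the
#' Calinski-Harabasz, Davies-Bouldin and Silhouette indices. k* is the best
#' mean rank (Silhouette and Calinski-Harabasz maximal, Davies-Bouldin
#' minimal), ties going to the smaller k.
#'
#' @param X pooled, standardized voxel-feature matrix.
#' @param k_range candidate cluster counts (default 3:10).
#' @param n_seeds K-means restarts per k.
#' @param seed base RNG seed.
#' @return list with `k` (selected count), `diagnostics` (per-k data.frame
#'   of the three indices and inertia, for validity-curve plots), and
#'   `weak_structure` (TRUE when no k reaches silhouette 0.5).
#' @export
select_k <- function(X, k_range = 3:10, n_seeds = 10, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(unique(X))
  if (min(k_range) < 2 || max(k_range) > nrow(X) - 1)
    stop("k_range must lie within [2, n_rows - 1]")
  if (n < max(k_range))
    stop("need at least max(k_range) distinct rows")
  diag_df <- data.frame(k = k_range, calinski_harabasz = NA_real_,
                        davies_bouldin = NA_real_, silhouette = NA_real_,
                        inertia = NA_real_)
  for (r in seq_along(k_range)) {
    k <- k_range[r]
    fits <- lapply(seq_len(n_seeds), function(s) kmeanspp(X, k, seed + s - 1L))
    best <- fits[[which.min(vapply(fits, function(f) f$tot.withinss, 0))]]
    diag_df$inertia[r] <- best$tot.withinss
    diag_df$calinski_harabasz[r] <- calinski_harabasz(X, best$cluster)
    diag_df$davies_bouldin[r] <- davies_bouldin(X, best$cluster)
    diag_df$silhouette[r] <- silhouette_mean(X, best$cluster)
  }
  rk <- rank(-diag_df$silhouette) + rank(-diag_df$calinski_harabasz) +
    rank(diag_df$davies_bouldin)
  kstar <- k_range[which(rk == min(rk))[1]]   # ties -> smaller k
  list(k = kstar, diagnostics = diag_df,
       weak_structure = max(diag_df$silhouette) <= 0.5)
}

# ---- label matching (Hungarian) --------------------------------------------

# Minimal-cost square assignment via shortest augmenting paths.
# Returns match[i] = column assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  match
}

#' Agreement of two labelings after optimal label matching
#'
#' Matches the label sets with the Hungarian algorithm on the contingency
#' table and returns the fraction of observations whose matched labels
#' agree. Invariant under any relabeling of either input.
#'
#' @param a,b integer label vectors of equal length (labels in 1..k).
#' @param k number of labels (default: max observed).
#' @return agreement fraction in `[0, 1]`.
#' @export
matched_agreement <- function(a, b, k = max(a, b)) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  C <- matrix(0, k, k)
  tb <- table(factor(a, levels = 1:k), factor(b, levels = 1:k))
  C[, ] <- as.numeric(tb)
  m <- solve_assignment(-C)
  sum(C[cbind(seq_len(k), m)]) / length(a)
}

#' Fit a population habitat model
#'
#' Standardizes the pooled training voxels per channel, runs K-means with
#' `n_seeds` k-means++ restarts, keeps the best-inertia centers, and scores
#' stability as the mean pairwise voxel agreement between runs after
#' Hungarian label matching.
#'
#' @param pooled pooled voxel-feature matrix (training cohort only), e.g.
#'   from [pool_voxel_features()].
#' @param k cluster count (e.g. from [select_k()]).
#' @param n_seeds number of seeded restarts.
#' @param seed base RNG seed.
#' @return A `habitat_model`: centers (k x channels, standardized space),
#'   scaler, per-run inertia, `consistency` in `[0, 1]`, `seeds_used`.
#' @export
fit_habitats <- function(pooled, k, n_seeds = 10, seed = 1L) {
  X <- as.matrix(pooled)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- sdv > 1e-12
  if (!all(keep))
    warning("dropping degenerate channels: ",
            paste(colnames(X)[!keep], collapse = ", "))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  seeds <- seed + seq_len(n_seeds) - 1L
  fits <- lapply(seeds, function(s) kmeanspp(Xs, k, s))
  inertia <- vapply(fits, function(f) f$tot.withinss, 0)
  best <- fits[[which.min(inertia)]]
  pairs <- utils::combn(n_seeds, 2)
  cons <- mean(vapply(seq_len(ncol(pairs)), function(j) {
    matched_agreement(fits[[pairs[1, j]]]$cluster,
                      fits[[pairs[2, j]]]$cluster, k)
  }, 0))
  structure(list(k = k, centers = best$centers,
                 scaler = list(mean = mu[keep], sd = sdv[keep],
                               channels = colnames(X)[keep]),
                 inertia = inertia, consistency = cons, seeds_used = seeds),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("<habitat_model> k = %d, %d channels, consistency %.3f\n",
              x$k, length(x$scaler$channels), x$consistency))
  invisible(x)
}

#' Assign habitat labels to a patient
#'
#' Nearest-center assignment in the model's standardized feature space.
#' Deterministic; equidistant voxels take the lowest label index. Applies a
#' frozen training-cohort model to any patient without refitting.
#'
#' @param model a fitted `habitat_model`.
#' @param map the patient's `local_feature_map`.
#' @return A `HabitatLabelMap` as an [hb_mask()] with labels 1..k on lesion
#'   voxels and 0 outside.
#' @export
assign_habitats <- function(model, map) {
  ch <- model$scaler$channels
  if (!all(ch %in% colnames(map$features)))
    stop("channel mismatch: map lacks ",
         paste(setdiff(ch, colnames(map$features)), collapse = ", "))
  X <- map$features[, ch, drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$scaler$mean), 2, model$scaler$sd, "/")
  D2 <- dist2_to_centers(Xs, model$centers)
  lab <- max.col(-D2, ties.method = "first")
  arr <- array(0L, dim = map$dim)
  arr[map$voxels] <- lab
  hb_mask(arr, map$spacing)
}
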