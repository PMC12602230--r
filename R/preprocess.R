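# Image normalization: bias-field correction, isotropic resampling,
# dominant-lesion selection, and observer-agreement ICC.

#' Log-domain bias field correction
#'
#' Estimates a smooth multiplicative intensity inhomogeneity field and
#' divides it out. The log image is decomposed into a piecewise-constant
#' tissue component (intensity classes re-estimated each iteration) plus a
#' smooth residual field obtained by heavy Gaussian smoothing; removing the
#' class structure first keeps anatomy out of the estimated field.
#'
#' @param volume a strictly positive [hb_volume()] (or see `positivity`).
#' @param mask optional [hb_mask()]; the field is normalized to unit
#'   geometric mean over the mask support (whole volume when `NULL`).
#' @param n_classes number of intensity classes used to absorb tissue
#'   contrast before smoothing.
#' @param sigma_mm Gaussian smoothing scale of the field estimate in mm;
#'   the estimated field carries no energy above this scale.
#' @param n_iter class/field alternations.
#' @param positivity `"error"` rejects non-positive voxels; `"shift"` adds
#'   an offset (with a warning) so the log transform is defined.
#' @return list with `corrected` and `bias_field`, both [hb_volume()];
#'   `corrected = volume / bias_field` elementwise.
#' @export
correct_bias <- function(volume, mask = NULL, n_classes = 4, sigma_mm = 10,
                         n_iter = 2, positivity = c("error", "shift")) {
  positivity <- match.arg(positivity)
  x <- volume$values
  if (any(x <= 0)) {
    if (positivity == "error")
      stop("volume contains non-positive intensities; log-domain correction undefined")
    shift <- abs(min(x)) + 1e-3 * diff(range(x))
    warning(sprintf("shifting intensities by %.4g to enforce positivity", shift))
    x <- x + shift
  }
  if (!is.null(mask)) check_aligned(volume, mask)
  support <- if (is.null(mask)) rep(TRUE, length(x)) else mask$values != 0L

  l <- log(x)
  field_log <- array(0, dim = dim(x))
  for (it in seq_len(n_iter)) {
    resid_tissue <- l - field_log
    # deterministic k-means on intensities: quantile-seeded Lloyd iterations
    centers <- unique(quantile(resid_tissue[support],
                               probs = seq(0.5, n_classes - 0.5) / n_classes,
                               names = FALSE))
    if (length(centers) > 1) {
      for (ll in 1:10) {
        assign_c <- apply(abs(outer(as.vector(resid_tissue), centers, "-")),
                          1, which.min)
        centers <- vapply(seq_along(centers), function(j) {
          v <- resid_tissue[assign_c == j]
          if (length(v)) mean(v) else centers[j]
        }, 0)
      }
      tissue <- array(centers[assign_c], dim = dim(x))
    } else {
      tissue <- array(centers, dim = dim(x))
    }
    field_log <- gaussian_smooth(l - tissue, volume$spacing, sigma_mm)
    field_log <- field_log - mean(field_log[support])
  }
  field <- exp(field_log)
  list(corrected = hb_volume(volume$values / field, volume$spacing,
                             volume$origin),
       bias_field = hb_volume(field, volume$spacing, volume$origin))
}

# Catmull-Rom (3rd-order) interpolation operator for one axis.
resample_op <- function(n_old, old_mm, new_mm, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  n_new <- max(1L, round(n_old * old_mm / new_mm))
  W <- matrix(0, n_new, n_old)
  for (j in seq_len(n_new)) {
    u <- ((j - 0.5) * new_mm) / old_mm - 0.5   # 0-based input coordinate
    if (method == "nearest") {
      i <- min(max(round(u), 0), n_old - 1)
      W[j, i + 1] <- 1
    } else {
      i0 <- floor(u); t <- u - i0
      w <- c((-t^3 + 2 * t^2 - t) / 2,
             (3 * t^3 - 5 * t^2 + 2) / 2,
             (-3 * t^3 + 4 * t^2 + t) / 2,
             (t^3 - t^2) / 2)
      idx <- pmin(pmax(i0 + (-1:2), 0), n_old - 1)
      for (m in 1:4) W[j, idx[m] + 1] <- W[j, idx[m] + 1] + w[m]
    }
  }
  W
}

#' Resample an image/mask pair to an isotropic grid
#'
#' The image is interpolated with a separable Catmull-Rom cubic kernel, the
#' mask with nearest-neighbour so it stays binary. Physical extent is
#' preserved within one voxel.
#'
#' @param volume a [hb_volume()].
#' @param mask an aligned [hb_mask()].
#' @param target_mm target isotropic spacing (default 1 mm).
#' @return list with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, target_mm = 1.0) {
  check_aligned(volume, mask)
  if (target_mm <= 0) stop("target_mm must be positive")
  img <- volume$values
  msk <- mask$values
  for (ax in 1:3) {
    Wc <- resample_op(dim(img)[ax], volume$spacing[ax], target_mm, "cubic")
    Wn <- resample_op(dim(msk)[ax], volume$spacing[ax], target_mm, "nearest")
    img <- axis_matmul(img, ax, Wc)
    msk <- axis_matmul(msk * 1.0, ax, Wn)
  }
  msk <- array(as.integer(round(msk)), dim = dim(msk))
  if (sum(msk != 0L) == 0)
    stop("mask is empty after resampling (lesion too small for the target grid)")
  list(volume = hb_volume(img, rep(target_mm, 3), volume$origin),
       mask = hb_mask(msk, rep(target_mm, 3), volume$origin))
}

#' Select the dominant lesion
#'
#' Returns the mask with the largest physical volume. Exact ties are broken
#' deterministically by the lexicographically smallest foreground centroid
#' (physical coordinates).
#'
#' @param masks list of [hb_mask()] objects, one per lesion.
#' @return The dominant [hb_mask()].
#' @export
select_dominant_lesion <- function(masks) {
  if (!length(masks)) stop("no masks supplied")
  vols <- vapply(masks, mask_volume_mm3, 0)
  if (all(vols == 0)) stop("all masks are empty")
  best <- which(vols == max(vols))
  if (length(best) > 1) {
    cents <- lapply(best, function(i) {
      m <- masks[[i]]
      idx <- which(m$values != 0L, arr.ind = TRUE)
      colMeans(sweep(idx - 1, 2, m$spacing, "*") +
                 matrix(m$origin, nrow(idx), 3, byrow = TRUE))
    })
    ord <- do.call(order, as.data.frame(do.call(rbind, cents)))
    best <- best[ord[1]]
  }
  masks[[best[1]]]
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure, from the
#' standard ANOVA mean-squares decomposition.
#'
#' @param ratings numeric matrix, subjects in rows and raters in columns;
#'   at least 2 x 2, no missing cells.
#' @return ICC value in `[-1, 1]`.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2) stop("need at least 2 subjects")
  if (k < 2) stop("need at least 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must be complete and finite")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-12 * max(1, grand^2))
    stop("zero between-subject variance: ICC undefined on degenerate input")
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Reproducibility filter on features between two raters
#'
#' Optional stage: keeps features whose between-rater ICC(2,1) meets the
#' excellent-reliability threshold.
#'
#' @param table_a,table_b numeric data.frames with identical feature columns,
#'   one row per patient, from two independent delineations.
#' @param threshold minimum ICC (default 0.75).
#' @return character vector of surviving feature names.
#' @export
icc_filter_features <- function(table_a, table_b, threshold = 0.75) {
  common <- intersect(names(table_a), names(table_b))
  keep <- vapply(common, function(nm) {
    r <- cbind(table_a[[nm]], table_b[[nm]])
    if (any(!is.finite(r)) || var(rowMeans(r)) < 1e-24) return(FALSE)
    icc_agreement(r) >= threshold
  }, TRUE)
  common[keep]
}
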