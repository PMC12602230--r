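# Image filter bank: original, 8 stationary-Haar wavelet sub-bands,
# Laplacian-of-Gaussian at 5 scales, intensity transforms, and gradient.

# 1D stationary Haar operators (replicate boundary), taps at i-1 and i.
haar_op <- function(n, high = FALSE) {
  W <- matrix(0, n, n)
  s <- 1 / sqrt(2)
  for (i in seq_len(n)) {
    j <- max(i - 1, 1)
    if (high) { W[i, i] <- W[i, i] + s; W[i, j] <- W[i, j] - s }
    else { W[i, i] <- W[i, i] + s; W[i, j] <- W[i, j] + s }
  }
  W
}

# All 8 single-level 3D stationary wavelet sub-bands, sharing partial passes.
wavelet_bands <- function(arr) {
  d <- dim(arr)
  ops <- lapply(1:3, function(ax) list(L = haar_op(d[ax], FALSE),
                                       H = haar_op(d[ax], TRUE)))
  pass1 <- list(L = axis_matmul(arr, 1, ops[[1]]$L),
                H = axis_matmul(arr, 1, ops[[1]]$H))
  out <- list()
  for (b1 in c("L", "H")) for (b2 in c("L", "H")) {
    p2 <- axis_matmul(pass1[[b1]], 2, ops[[2]][[b2]])
    for (b3 in c("L", "H")) {
      out[[paste0("wavelet_", b1, b2, b3)]] <-
        axis_matmul(p2, 3, ops[[3]][[b3]])
    }
  }
  out
}

# Laplacian of Gaussian at physical scale sigma_mm.
log_filter <- function(arr, spacing, sigma_mm) {
  sm <- gaussian_smooth(arr, spacing, sigma_mm)
  d <- dim(sm)
  lap <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      ip <- min(i + 1, n); im <- max(i - 1, 1)
      W[i, ip] <- W[i, ip] + 1
      W[i, im] <- W[i, im] + 1
      W[i, i] <- W[i, i] - 2
    }
    lap <- lap + axis_matmul(sm, ax, W) / spacing[ax]^2
  }
  sigma_mm^2 * lap   # scale-normalized
}

#' Compute the image filter bank
#'
#' Materializes the 20 image types used for feature extraction: the
#' original image, 8 stationary-Haar wavelet sub-bands, Laplacian-of-
#' Gaussian at `log_sigmas_mm`, square, square-root, logarithm and
#' exponential intensity transforms, and the gradient magnitude. Intensity
#' transforms are range-stabilized: square is `x^2 / max|x|`, square-root
#' is `sign(x) sqrt(|x| max|x|)`, logarithm is `sign(x) log(1 + |x|)`
#' rescaled to the input range, exponential is `exp(3 x / max|x|)` scaled
#' back to the input magnitude.
#'
#' @param volume a [hb_volume()].
#' @param config a [feature_config()].
#' @return named list of 3D arrays (class `hb_filter_bank`), with the
#'   spacing attached.
#' @export
filter_bank <- function(volume, config = feature_config()) {
  arr <- volume$values
  sp <- volume$spacing
  bank <- list(original = arr)
  if ("wavelet" %in% config$image_filters)
    bank <- c(bank, wavelet_bands(arr))
  if ("log" %in% config$image_filters) {
    for (s in config$log_sigmas_mm)
      bank[[sprintf("log_sigma_%g", s)]] <- log_filter(arr, sp, s)
  }
  mx <- max(abs(arr), 1e-12)
  if ("square" %in% config$image_filters)
    bank$square <- arr^2 / mx
  if ("squareroot" %in% config$image_filters)
    bank$squareroot <- sign(arr) * sqrt(abs(arr) * mx)
  if ("logarithm" %in% config$image_filters)
    bank$logarithm <- sign(arr) * log1p(abs(arr)) * mx / log1p(mx)
  if ("exponential" %in% config$image_filters)
    bank$exponential <- exp(3 * arr / mx) * mx / exp(3)
  if ("gradient" %in% config$image_filters)
    bank$gradient <- gradient_magnitude(arr, sp)
  attr(bank, "spacing") <- sp
  attr(bank, "vol_dim") <- dim(arr)
  class(bank) <- "hb_filter_bank"
  bank
}
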