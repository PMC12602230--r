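#' @useDynLib habitatbm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans sd var quantile median rnorm runif rbinom rpois
#'   rlnorm pnorm qnorm pchisq pt wilcox.test t.test shapiro.test glm binomial
#'   coef predict cor uniroot setNames aggregate p.adjust plogis qlogis
#'   complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

# ---- Volume / LabelMask containers -----------------------------------------

#' Create a 3D scalar volume
#'
#' A `hb_volume` couples a 3D numeric array with its physical geometry
#' (voxel spacing and origin, in mm). All pipeline stages keep image and
#' mask geometry in lockstep.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, position of the first voxel centre in mm.
#' @return An object of class `hb_volume`.
#' @export
hb_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers (mm)")
  if (any(!is.finite(values)))
    stop("volume values must be finite")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "hb_volume")
}

#' Create a label mask aligned to a volume grid
#'
#' @param values 3D integer array (0 = background). Binary ROIs use {0,1};
#'   habitat label maps use {0,1..k}.
#' @param spacing,origin geometry, as in [hb_volume()].
#' @return An object of class `hb_mask`.
#' @export
hb_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  v <- values
  storage.mode(v) <- "integer"
  if (any(is.na(v)) || any(v < 0)) stop("mask values must be non-negative integers")
  out <- hb_volume(v * 1.0, spacing, origin)
  out$values <- v
  class(out) <- c("hb_mask", "hb_volume")
  out
}

#' @export
print.hb_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask a [hb_mask()].
#' @return integer count.
#' @export
mask_count <- function(mask) sum(mask$values != 0L)

#' Physical volume (mm^3) of a mask
#' @param mask a [hb_mask()].
#' @return numeric, foreground voxel count times voxel volume.
#' @export
mask_volume_mm3 <- function(mask) mask_count(mask) * prod(mask$spacing)

# Geometry agreement check used by every stage that pairs image and mask.
check_aligned <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grids are not aligned: dimensions differ")
  if (max(abs(a$spacing - b$spacing)) > tol)
    stop("grids are not aligned: spacing differs")
  if (max(abs(a$origin - b$origin)) > tol)
    stop("grids are not aligned: origin differs")
  invisible(TRUE)
}

# ---- separable axis operations ---------------------------------------------

# Apply a linear operator W (n_new x n_old) along one axis of a 3D array.
axis_matmul <- function(arr, axis, W) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- W %*% m
  d2 <- d; d2[axis] <- nrow(W)
  aperm(array(out, dim = d2[perm]), order(perm))
}

# Row-normalized truncated Gaussian smoothing matrix (replicating the kernel
# mass lost at the borders back onto the retained taps).
gauss_op <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  idx <- seq_len(n)
  W <- matrix(0, n, n)
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  for (i in idx) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= n
    w <- k[keep]
    W[i, j[keep]] <- w / sum(w)
  }
  W
}

# Smooth a 3D array with a separable Gaussian of physical width sigma_mm.
gaussian_smooth <- function(arr, spacing, sigma_mm) {
  for (ax in 1:3) {
    arr <- axis_matmul(arr, ax, gauss_op(dim(arr)[ax], sigma_mm / spacing[ax]))
  }
  arr
}

# Central-difference gradient magnitude in physical units (1/mm scaling).
gradient_magnitude <- function(arr, spacing) {
  d <- dim(arr)
  g2 <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * spacing[ax]
    W <- matrix(0, n, n)
    W[cbind(seq_len(n), ip)] <- W[cbind(seq_len(n), ip)] + 1 / denom
    W[cbind(seq_len(n), im)] <- W[cbind(seq_len(n), im)] - 1 / denom
    g2 <- g2 + axis_matmul(arr, ax, W)^2
  }
  sqrt(g2)
}

# ---- NIfTI I/O --------------------------------------------------------------

#' Read a NIfTI volume
#' @param path path to a .nii or .nii.gz file.
#' @param mask logical; read as an integer label mask.
#' @return A [hb_volume()] or [hb_mask()].
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  if (mask) hb_mask(round(vals), spacing = sp) else hb_volume(vals, spacing = sp)
}

#' Write a volume or mask to NIfTI
#' @param vol a [hb_volume()] or [hb_mask()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
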