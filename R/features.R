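# IBSI-style radiomic feature bank: shape, first-order, and five texture
# families over the filter bank, with a fixed default inventory of
# 14 + 20 x 91 = 1834 features per region.

#' Configure feature extraction
#'
#' The default configuration yields exactly 1834 features per region:
#' 14 shape + 20 image types x (18 first-order + 22 GLCM + 16 GLRLM +
#' 16 GLSZM + 14 GLDM + 5 NGTDM) = 14 + 20 x 91.
#'
#' @param image_filters filter families to enable (the default set realizes
#'   the 20 image types: original, 8 wavelet sub-bands, 5 LoG scales,
#'   square, squareroot, logarithm, exponential, gradient).
#' @param log_sigmas_mm LoG scales in mm.
#' @param bin_width fixed bin width for discretizing original-intensity
#'   images.
#' @param bin_count_filtered fixed bin count for derived (filtered) images,
#'   whose intensity scales differ from the original.
#' @param max_levels cap on discretized gray levels (memory guard).
#' @param min_voxels minimum region size; smaller regions yield an
#'   all-missing row with a recorded reason.
#' @param gldm_alpha GLDM dependence tolerance on gray-level difference.
#' @return A `feature_config` list.
#' @export
feature_config <- function(image_filters = c("wavelet", "log", "square",
                                             "squareroot", "logarithm",
                                             "exponential", "gradient"),
                           log_sigmas_mm = c(0.5, 1, 2, 3, 4, 5),
                           bin_width = 25,
                           bin_count_filtered = 32,
                           max_levels = 256,
                           min_voxels = 10,
                           gldm_alpha = 0) {
  if (!is.null(bin_width) && bin_width <= 0) stop("bin_width must be > 0")
  structure(list(image_filters = image_filters,
                 log_sigmas_mm = log_sigmas_mm,
                 bin_width = bin_width,
                 bin_count_filtered = bin_count_filtered,
                 max_levels = max_levels,
                 min_voxels = min_voxels,
                 gldm_alpha = gldm_alpha),
            class = "feature_config")
}

filter_type_names <- function(config) {
  out <- "original"
  if ("wavelet" %in% config$image_filters)
    out <- c(out, paste0("wavelet_", c("LLL", "LLH", "LHL", "LHH",
                                       "HLL", "HLH", "HHL", "HHH")))
  if ("log" %in% config$image_filters)
    out <- c(out, sprintf("log_sigma_%g", config$log_sigmas_mm))
  for (f in c("square", "squareroot", "logarithm", "exponential", "gradient"))
    if (f %in% config$image_filters) out <- c(out, f)
  out
}

first_order_names <- function() {
  c("Energy", "TotalEnergy", "Entropy", "Minimum", "P10", "P90", "Maximum",
    "Mean", "Median", "InterquartileRange", "Range", "MeanAbsoluteDeviation",
    "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness", "Kurtosis",
    "Variance", "Uniformity")
}

glcm_names <- function() {
  c("Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
    "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
    "MaximumProbability", "SumEntropy", "SumSquares")
}

rl_family_names <- function(prefixes) {
  # shared naming scheme for run-length / size-zone families
  c(paste0("Short", prefixes, "Emphasis"), paste0("Long", prefixes, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(prefixes, "NonUniformity"),
    paste0(prefixes, "NonUniformityNormalized"),
    paste0(prefixes, "Percentage"), "GrayLevelVariance",
    paste0(prefixes, "Variance"), paste0(prefixes, "Entropy"),
    paste0("LowGrayLevel", prefixes, "Emphasis"),
    paste0("HighGrayLevel", prefixes, "Emphasis"),
    paste0("Short", prefixes, "LowGrayLevelEmphasis"),
    paste0("Short", prefixes, "HighGrayLevelEmphasis"),
    paste0("Long", prefixes, "LowGrayLevelEmphasis"),
    paste0("Long", prefixes, "HighGrayLevelEmphasis"))
}

glrlm_names <- function() rl_family_names("Run")
glszm_names <- function() {
  c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
    "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
    "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LargeAreaHighGrayLevelEmphasis")
}
gldm_names <- function() {
  c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "GrayLevelVariance",
    "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis")
}
ngtdm_names <- function() {
  c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
}
shape_names <- function() {
  c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
    "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
    "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness")
}

#' Names of all features under a configuration
#' @param config a [feature_config()].
#' @return character vector (`filter__family__feature`; 1834 by default).
#' @export
feature_names <- function(config = feature_config()) {
  per_type <- c(paste0("firstorder__", first_order_names()),
                paste0("glcm__", glcm_names()),
                paste0("glrlm__", glrlm_names()),
                paste0("glszm__", glszm_names()),
                paste0("gldm__", gldm_names()),
                paste0("ngtdm__", ngtdm_names()))
  c(paste0("shape__", shape_names()),
    as.vector(t(outer(filter_type_names(config), per_type,
                      function(a, b) paste0(a, "__", b)))))
}

# ---- discretization ---------------------------------------------------------

#' Discretize region intensities to gray levels
#'
#' Fixed-bin-width mapping `level = floor((x - min) / w) + 1` (levels start
#' at 1); alternatively a fixed bin count over the region's range.
#'
#' @param x numeric intensities of the region (nonempty).
#' @param bin_width bin width (> 0); mutually exclusive with `bin_count`.
#' @param bin_count number of equal-width bins over the observed range.
#' @return integer vector of levels >= 1.
#' @export
discretize <- function(x, bin_width = NULL, bin_count = NULL) {
  if (!length(x)) stop("empty region")
  if (!is.null(bin_width)) {
    if (bin_width <= 0) stop("bin_width must be > 0")
    as.integer(floor((x - min(x)) / bin_width) + 1)
  } else if (!is.null(bin_count)) {
    if (bin_count < 1) stop("bin_count must be >= 1")
    r <- range(x)
    if (r[2] - r[1] <= 0) return(rep(1L, length(x)))
    lv <- floor((x - r[1]) / ((r[2] - r[1]) / bin_count)) + 1
    as.integer(pmin(lv, bin_count))
  } else stop("supply bin_width or bin_count")
}

discretize_for <- function(x, type, config) {
  if (type == "original" && !is.null(config$bin_width)) {
    lv <- discretize(x, bin_width = config$bin_width)
    if (max(lv) > config$max_levels)
      lv <- discretize(x, bin_count = config$max_levels)
    lv
  } else {
    discretize(x, bin_count = config$bin_count_filtered)
  }
}

# ---- texture matrices -------------------------------------------------------

#' Texture matrices of a discretized region
#'
#' Computes the 3D texture matrices per IBSI conventions: a symmetric GLCM
#' aggregated over the 13 unique directions at distance 1, a GLRLM over the
#' same 13 directions, a GLSZM from 26-connected equal-level zones, an
#' NGTDM over the in-region 26-neighbourhood, and a GLDM with dependence
#' tolerance `alpha`.
#'
#' @param levels 3D integer array; 0 outside the region, 1..Ng inside.
#' @param alpha GLDM gray-level difference tolerance.
#' @return list with `glcm`, `glrlm`, `glszm` (zones x (level, size)),
#'   `ngtdm` (level x (count, sum-abs-diff)), `gldm`, and `n_voxels`.
#' @export
texture_matrices <- function(levels, alpha = 0) {
  stopifnot(is.array(levels), length(dim(levels)) == 3)
  storage.mode(levels) <- "integer"
  n <- sum(levels > 0L)
  if (n == 0) stop("empty region")
  ng <- max(levels)
  d <- dim(levels)
  list(glcm = cpp_glcm(levels, d, ng),
       glrlm = cpp_glrlm(levels, d, ng),
       glszm = cpp_glszm_zones(levels, d),
       ngtdm = cpp_ngtdm(levels, d, ng),
       gldm = cpp_gldm(levels, d, ng, as.integer(alpha)),
       n_voxels = n)
}

# ---- per-family feature formulas -------------------------------------------

first_order_features <- function(x, levels, voxel_volume) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p <- tabulate(levels) / n
  p <- p[p > 0]
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  rob <- x[x >= q[1] & x <= q[5]]
  setNames(c(
    sum(x^2), voxel_volume * sum(x^2), -sum(p * log2(p)),
    min(x), q[1], q[5], max(x), mu, q[3], q[4] - q[2], max(x) - min(x),
    mean(abs(x - mu)),
    if (length(rob)) mean(abs(rob - mean(rob))) else 0,
    sqrt(mean(x^2)),
    if (m2 > 1e-24) mean((x - mu)^3) / m2^1.5 else 0,
    if (m2 > 1e-24) mean((x - mu)^4) / m2^2 else 0,
    m2, sum(p^2)
  ), first_order_names())
}

glcm_features <- function(P) {
  ng <- nrow(P)
  s <- sum(P)
  if (s == 0) return(setNames(rep(0, 22), glcm_names()))
  p <- P / s
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  ux <- sum(seq_len(ng) * px)
  sx2 <- sum((seq_len(ng) - ux)^2 * px)
  # difference and sum marginals
  k_d <- 0:(ng - 1)
  pd <- vapply(k_d, function(k) sum(p[abs(i - j) == k]), 0)
  k_s <- 2:(2 * ng)
  ps <- vapply(k_s, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(k_d * pd)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pij_marg <- outer(px, px)
  hxy1 <- -sum(p[pij_marg > 0] * log2(pij_marg[pij_marg > 0]))
  hxy2 <- -sum(pij_marg[pij_marg > 0] * log2(pij_marg[pij_marg > 0]))
  corr <- if (sx2 > 1e-24) (sum(i * j * p) - ux^2) / sx2 else 1
  imc1 <- if (hx > 1e-24) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  off <- abs(i - j) > 0
  setNames(c(
    sum(i * j * p), ux,
    sum((i + j - 2 * ux)^4 * p), sum((i + j - 2 * ux)^3 * p),
    sum((i + j - 2 * ux)^2 * p), sum((i - j)^2 * p),
    corr, da,
    -sum(pd[pd > 0] * log2(pd[pd > 0])), sum((k_d - da)^2 * pd),
    sum(p^2), hxy, imc1, imc2,
    sum(p / (1 + (i - j)^2)), sum(p / (1 + ((i - j) / ng)^2)),
    sum(p / (1 + abs(i - j))), sum(p / (1 + abs(i - j) / ng)),
    sum(p[off] / (i - j)[off]^2), max(p),
    -sum(ps[ps > 0] * log2(ps[ps > 0])), sum((i - ux)^2 * p)
  ), glcm_names())
}

# shared formulas for GLRLM (j = run length), GLSZM (j = zone size) and
# GLDM (j = dependence size); M is level x size counts, denom_vox the
# normalizer of the percentage feature.
size_family_features <- function(M, denom_vox, names_out) {
  N <- sum(M)
  if (N == 0) return(setNames(rep(0, length(names_out)), names_out))
  ng <- nrow(M); nl <- ncol(M)
  iv <- seq_len(ng); jv <- seq_len(nl)
  ri <- rowSums(M); rj <- colSums(M)
  p <- M / N
  mu_i <- sum(iv * ri) / N
  mu_j <- sum(jv * rj) / N
  pe <- p[p > 0]
  setNames(c(
    sum(rj / jv^2) / N, sum(rj * jv^2) / N,
    sum(ri^2) / N, sum(ri^2) / N^2,
    sum(rj^2) / N, sum(rj^2) / N^2,
    N / denom_vox,
    sum(sweep(p, 1, (iv - mu_i)^2, "*")),
    sum(sweep(p, 2, (jv - mu_j)^2, "*")),
    -sum(pe * log2(pe)),
    sum(ri / iv^2) / N, sum(ri * iv^2) / N,
    sum(M / outer(iv^2, jv^2)) / N, sum(M * outer(iv^2, 1 / jv^2)) / N,
    sum(M * outer(1 / iv^2, jv^2)) / N, sum(M * outer(iv^2, jv^2)) / N
  ), names_out)
}

glrlm_features <- function(R, n_vox, n_dir = 13) {
  size_family_features(R, n_vox * n_dir, glrlm_names())
}

glszm_features <- function(zones, n_vox) {
  if (nrow(zones) == 0) return(setNames(rep(0, 16), glszm_names()))
  ng <- max(zones[, 1]); mx <- max(zones[, 2])
  S <- matrix(0, ng, mx)
  for (r in seq_len(nrow(zones)))
    S[zones[r, 1], zones[r, 2]] <- S[zones[r, 1], zones[r, 2]] + 1
  size_family_features(S, n_vox, glszm_names())
}

gldm_features <- function(D, n_vox) {
  # column d+1 holds dependence d, so sizes are j = d+1 >= 1; the generic
  # 16-slot family is reduced to the 14 dependence features
  v <- size_family_features(D, n_vox, paste0("f", 1:16))
  setNames(v[c(1:3, 5:6, 8:16)], gldm_names())
}

ngtdm_features <- function(M) {
  ni <- M[, 1]; si <- M[, 2]
  nvp <- sum(ni)
  out <- setNames(rep(0, 5), ngtdm_names())
  if (nvp == 0) return(out)
  pi_ <- ni / nvp
  act <- which(ni > 0)
  ngp <- length(act)
  iv <- seq_len(nrow(M))
  coars_den <- sum(pi_ * si)
  out["Coarseness"] <- if (coars_den > 1e-24) 1 / coars_den else 1e6
  if (ngp > 1) {
    cc <- 0
    for (a in act) for (b in act) cc <- cc + pi_[a] * pi_[b] * (a - b)^2
    out["Contrast"] <- cc / (ngp * (ngp - 1)) * sum(si) / nvp
    bden <- 0
    for (a in act) for (b in act) bden <- bden + abs(a * pi_[a] - b * pi_[b])
    out["Busyness"] <- if (bden > 1e-24) sum(pi_ * si) / bden else 0
    cx <- 0; st <- 0
    for (a in act) for (b in act) {
      cx <- cx + abs(a - b) * (pi_[a] * si[a] + pi_[b] * si[b]) /
        (pi_[a] + pi_[b])
      st <- st + (pi_[a] + pi_[b]) * (a - b)^2
    }
    out["Complexity"] <- cx / nvp
    out["Strength"] <- if (sum(si) > 1e-24) st / sum(si) else 0
  }
  out
}

# ---- shape ------------------------------------------------------------------

max2d_diameter <- function(coords, ax_drop) {
  planes <- split(seq_len(nrow(coords)), coords[, ax_drop])
  keep_ax <- setdiff(1:3, ax_drop)
  best <- 0
  for (idx in planes) {
    pts <- coords[idx, keep_ax, drop = FALSE]
    if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(pts) == 1) next
    best <- max(best, max(stats::dist(pts)))
  }
  best
}

shape_features <- function(mask) {
  sp <- mask$spacing
  voxvol <- prod(sp)
  idx <- which(mask$values != 0L, arr.ind = TRUE)
  n <- nrow(idx)
  coords <- sweep(idx - 1, 2, sp, "*")
  # Mesh the sharp binary 0.5-isosurface (accurate enclosed volume), then
  # correct the stair-stepped facet areas by projecting each facet onto the
  # local surface orientation estimated from a smoothed-indicator gradient.
  d <- dim(mask$values)
  sig <- 0.8 * min(sp)
  padv <- as.integer(ceiling(3 * sig / sp) + 1)
  padded <- array(0, d + 2L * padv)
  padded[padv[1] + 1:d[1], padv[2] + 1:d[2], padv[3] + 1:d[3]] <-
    as.numeric(mask$values != 0L)
  nfield <- gaussian_smooth(padded, sp, sig)
  surf <- cpp_mt_surface(padded, dim(padded), sp, 0.5, nfield)
  A <- surf$area_corrected
  V <- abs(surf$volume)
  ev <- eigen(stats::cov(coords) * (n - 1) / n, symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  verts <- unique(round(surf$vertices, 4))
  if (nrow(verts) > 4000) verts <- verts[seq(1, nrow(verts), length.out = 4000), ]
  setNames(c(
    V, n * voxvol, A, A / V,
    pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    cpp_max_pairwise_dist(as.matrix(verts)),
    max2d_diameter(coords, 3), max2d_diameter(coords, 2),
    max2d_diameter(coords, 1),
    4 * sqrt(ev[1]), 4 * sqrt(ev[2]), 4 * sqrt(ev[3]),
    if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  ), shape_names())
}

# ---- region-level extraction ------------------------------------------------

crop_bbox <- function(arr, idx_arr, margin = 0L) {
  d <- dim(arr)
  lo <- pmax(apply(idx_arr, 2, min) - margin, 1L)
  hi <- pmin(apply(idx_arr, 2, max) + margin, d)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

#' Extract the radiomic feature vector of one region
#'
#' Shape features come from the binary mask alone; first-order and the five
#' texture families are computed on every image type of the filter bank.
#' The default configuration yields 1834 named features.
#'
#' @param bank a [filter_bank()] (or a [hb_volume()], from which the bank
#'   is computed).
#' @param mask the region [hb_mask()], aligned with the bank's grid.
#' @param config a [feature_config()].
#' @return named numeric vector; regions below `min_voxels` return
#'   all-`NA` with a `reason` attribute.
#' @export
extract_region_features <- function(bank, mask, config = feature_config()) {
  if (inherits(bank, "hb_volume")) bank <- filter_bank(bank, config)
  stopifnot(inherits(bank, "hb_filter_bank"))
  nms <- feature_names(config)
  if (!identical(attr(bank, "vol_dim"), dim(mask$values)))
    stop("bank and mask grids are not aligned")
  vox <- which(mask$values != 0L)
  if (length(vox) < config$min_voxels) {
    out <- setNames(rep(NA_real_, length(nms)), nms)
    attr(out, "reason") <- sprintf("region has %d voxels (< %d)",
                                   length(vox), config$min_voxels)
    return(out)
  }
  sp <- attr(bank, "spacing")
  voxvol <- prod(sp)
  idx_arr <- which(mask$values != 0L, arr.ind = TRUE)
  mask_crop <- crop_bbox(mask$values, idx_arr) != 0L
  out <- numeric(0)
  out <- c(out, setNames(shape_features(mask),
                         paste0("shape__", shape_names())))
  types <- filter_type_names(config)
  for (ty in types) {
    img <- bank[[ty]]
    x <- img[vox]
    lv_vec <- discretize_for(x, ty, config)
    fo <- first_order_features(x, lv_vec, voxvol)
    img_crop <- crop_bbox(img, idx_arr)
    lv_arr <- array(0L, dim(img_crop))
    xin <- img_crop[mask_crop]
    lv_arr[mask_crop] <- discretize_for(xin, ty, config)
    tm <- texture_matrices(lv_arr, alpha = config$gldm_alpha)
    fv <- c(fo,
            glcm_features(tm$glcm),
            glrlm_features(tm$glrlm, tm$n_voxels),
            glszm_features(tm$glszm, tm$n_voxels),
            gldm_features(tm$gldm, tm$n_voxels),
            ngtdm_features(tm$ngtdm))
    names(fv) <- paste0(ty, "__", c(paste0("firstorder__", first_order_names()),
                                    paste0("glcm__", glcm_names()),
                                    paste0("glrlm__", glrlm_names()),
                                    paste0("glszm__", glszm_names()),
                                    paste0("gldm__", gldm_names()),
                                    paste0("ngtdm__", ngtdm_names())))
    out <- c(out, fv)
  }
  stopifnot(identical(names(out), nms))
  out
}

#' Fuse per-habitat feature vectors (early fusion)
#'
#' Concatenates the k habitat vectors with habitat-id prefixes; for k = 3
#' under the default configuration this yields 5502 imaging features. A
#' missing habitat is imputed with zeros and flagged.
#'
#' @param habitat_vectors list of k named vectors (or `NULL` / all-`NA` for
#'   a habitat absent in this patient), all with identical name sets.
#' @param k number of habitats.
#' @return named vector of length `k * length(vector)`, with attribute
#'   `missing_habitats` listing imputed habitat ids.
#' @export
fuse_habitat_features <- function(habitat_vectors, k = length(habitat_vectors)) {
  if (length(habitat_vectors) != k)
    stop("expected ", k, " habitat vectors")
  proto <- NULL
  for (v in habitat_vectors) if (!is.null(v) && !all(is.na(v))) {
    proto <- names(v); break
  }
  if (is.null(proto)) stop("all habitat vectors are missing")
  missing_h <- integer(0)
  pieces <- vector("list", k)
  for (h in seq_len(k)) {
    v <- habitat_vectors[[h]]
    if (is.null(v) || all(is.na(v))) {
      v <- setNames(rep(0, length(proto)), proto)
      missing_h <- c(missing_h, h)
    } else if (!identical(names(v), proto)) {
      stop("inconsistent per-habitat feature names")
    }
    names(v) <- paste0("habitat", h, "__", names(v))
    pieces[[h]] <- v
  }
  out <- do.call(c, pieces)
  attr(out, "missing_habitats") <- missing_h
  out
}
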