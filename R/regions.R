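# Peritumoral ring construction by physical-distance dilation.

#' Peritumoral ring at a physical radius
#'
#' The ring is the set of voxels whose exact Euclidean distance (in mm,
#' computed by distance transform on the physical grid) to the tumor lies
#' in `(0, radius_mm]`, optionally intersected with a brain/field-of-view
#' mask. Radii are honest physical distances on any spacing.
#'
#' @param tumor a nonempty binary [hb_mask()].
#' @param radius_mm outer ring radius in mm.
#' @param brain_mask optional [hb_mask()] to clip the ring.
#' @return A binary [hb_mask()], disjoint from the tumor.
#' @export
peritumoral_ring <- function(tumor, radius_mm, brain_mask = NULL) {
  if (mask_count(tumor) == 0) stop("tumor mask is empty")
  d <- dim(tumor$values)
  if (radius_mm <= 0) {
    warning("radius_mm <= 0: returning an empty ring")
    return(hb_mask(array(0L, d), tumor$spacing, tumor$origin))
  }
  dist_mm <- sqrt(cpp_edt_sq(as.integer(tumor$values != 0L), d, tumor$spacing))
  ring <- array(as.integer(dist_mm > 0 & dist_mm <= radius_mm + 1e-9), d)
  if (!is.null(brain_mask)) {
    check_aligned(tumor, brain_mask)
    ring <- ring * as.integer(brain_mask$values != 0L)
    if (sum(ring) == 0) stop("ring is empty after brain-mask clipping")
  }
  hb_mask(ring, tumor$spacing, tumor$origin)
}

#' Build the full region set for one patient
#'
#' Materializes the tumor mask, peritumoral rings at each radius, and one
#' mask per habitat label. Habitat masks partition the tumor exactly.
#'
#' @param tumor binary [hb_mask()].
#' @param habitat_label_map [hb_mask()] with labels 1..k on tumor voxels.
#' @param radii ring radii in mm (default 1, 2, 3).
#' @param brain_mask optional clip mask passed to [peritumoral_ring()].
#' @return A `region_set`: list with `tumor`, `rings` (named by radius),
#'   and `habitats` (named by label).
#' @export
build_region_set <- function(tumor, habitat_label_map, radii = c(1, 2, 3),
                             brain_mask = NULL) {
  check_aligned(tumor, habitat_label_map)
  tv <- tumor$values != 0L
  hv <- habitat_label_map$values
  if (any(tv & hv == 0L) || any(!tv & hv != 0L))
    stop("habitat map does not partition the tumor")
  rings <- lapply(radii, function(r) peritumoral_ring(tumor, r, brain_mask))
  names(rings) <- paste0("peri", radii, "mm")
  ks <- sort(unique(hv[hv > 0L]))
  habitats <- lapply(ks, function(k) {
    hb_mask(array(as.integer(hv == k), dim(hv)), tumor$spacing, tumor$origin)
  })
  names(habitats) <- paste0("habitat", ks)
  structure(list(tumor = tumor, rings = rings, habitats = habitats),
            class = "region_set")
}
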