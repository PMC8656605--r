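#' Whole-prostate mask from a zonal label map
#'
#' The whole prostate is the union of the PZ and CG labels.
#'
#' @param zones Label [voxel_grid()] (0 background, 1 PZ, 2 CG).
#' @return Binary [voxel_grid()].
#' @export
whole_prostate_mask <- function(zones) {
  stopifnot(is_voxel_grid(zones))
  voxel_grid(array(as.integer(zones$data %in% c(1L, 2L)), dim(zones$data)),
             zones$spacing, zones$origin, kind = "label",
             label_set = c(0L, 1L))
}

#' Maximum extents of the prostate, in cm
#'
#' Lengths along the transverse (x), anterior-posterior (y) and
#' cranio-caudal (z) axes from the maximum extents of the whole-prostate
#' mask. The voxel-footprint convention is used: length =
#' `(max_index - min_index + 1) * spacing`, so a single voxel has the
#' length of its footprint.
#'
#' @param wp Binary [voxel_grid()], non-empty.
#' @return Named numeric: `transverse_cm`, `anterior_posterior_cm`,
#'   `cranio_caudal_cm`.
#' @export
prostate_lengths <- function(wp) {
  stopifnot(is_voxel_grid(wp))
  idx <- which(wp$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("whole-prostate mask is empty", call. = FALSE)
  ext <- apply(idx, 2L, range)
  len_mm <- (ext[2, ] - ext[1, ] + 1) * wp$spacing
  c(transverse_cm = len_mm[1] / 10,
    anterior_posterior_cm = len_mm[2] / 10,
    cranio_caudal_cm = len_mm[3] / 10)
}

#' Mask volume in cm^3
#'
#' Voxel count multiplied by voxel volume.
#'
#' @param mask Binary [voxel_grid()].
#' @return Volume in cm^3 (0 for an empty mask).
#' @export
mask_volume <- function(mask) {
  stopifnot(is_voxel_grid(mask))
  sum(mask$data > 0) * prod(mask$spacing) / 1000
}

#' PSA density
#'
#' PSA divided by whole-prostate volume, reported in ng/mL^2
#' (numerically ng/mL divided by cm^3).
#'
#' @param psa PSA in ng/mL.
#' @param wp_volume_cm3 Whole-prostate volume in cm^3, > 0.
#' @return PSA density.
#' @export
psa_density <- function(psa, wp_volume_cm3) {
  if (!is.finite(wp_volume_cm3) || wp_volume_cm3 <= 0)
    stop("whole-prostate volume must be > 0", call. = FALSE)
  psa / wp_volume_cm3
}

#' Prostate region (base / midgland / apex) of a z position
#'
#' The whole-prostate z extent is split into thirds of equal physical
#' length: the caudal-most third is the apex, the cranial-most third the
#' base, the remainder the midgland (z increases cranially). Positions
#' exactly on a boundary are assigned to the midgland.
#'
#' @param centroid_z Z voxel index (1-based, may be fractional).
#' @param wp Binary [voxel_grid()], non-empty.
#' @return One of `"apex"`, `"midgland"`, `"base"`.
#' @export
centroid_region <- function(centroid_z, wp) {
  stopifnot(is_voxel_grid(wp))
  zs <- which(apply(wp$data > 0, 3L, any))
  if (length(zs) == 0L) stop("whole-prostate mask is empty", call. = FALSE)
  z_min <- min(zs); z_max <- max(zs)
  if (centroid_z < z_min - 0.5 || centroid_z > z_max + 0.5)
    stop("centroid lies outside the prostate z extent", call. = FALSE)
  sp <- wp$spacing[3]
  zc <- centroid_z * sp
  b1 <- (z_min + (z_max - z_min) / 3) * sp
  b2 <- (z_min + 2 * (z_max - z_min) / 3) * sp
  if (zc < b1) "apex" else if (zc > b2) "base" else "midgland"
}

#' Characterize a lesion candidate
#'
#' Derives the reportable quantities of one candidate component: volume,
#' centroid (voxel-coordinate mean rounded to the nearest voxel), centroid
#' slice (1-based, counted from the most caudal slice), centroid zone (the
#' zonal label at the centroid; a background centroid is resolved to the
#' nearest in-prostate zone by physical distance), centroid region
#' (base/midgland/apex thirds rule), minimum ADC inside the contour, and
#' the extracapsular flag (true if any lesion voxel lies outside the
#' whole-prostate mask).
#'
#' @param component `list(mask, score)` as produced by
#'   [extract_candidates()].
#' @param zones Zonal label [voxel_grid()].
#' @param wp Binary whole-prostate [voxel_grid()].
#' @param adc ADC map [voxel_grid()] (mm^2/s).
#' @return An object of class `lesion_candidate`.
#' @export
characterize_lesion <- function(component, zones, wp, adc) {
  mask <- component$mask
  stop_if_geometry_mismatch(mask, zones, "lesion mask and zones")
  stop_if_geometry_mismatch(mask, wp, "lesion mask and whole prostate")
  stop_if_geometry_mismatch(mask, adc, "lesion mask and ADC")
  idx <- which(mask$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty lesion component", call. = FALSE)
  centroid <- colMeans(idx)
  cvox <- pmin(pmax(round(centroid), 1L), dim(mask$data))
  zone_lab <- zones$data[cvox[1], cvox[2], cvox[3]]
  if (zone_lab == 0L) {
    # nearest non-background zone voxel by physical distance
    zidx <- which(zones$data > 0, arr.ind = TRUE)
    if (nrow(zidx) == 0L) {
      zone_lab <- 1L
    } else {
      d2 <- colSums((t(zidx) - as.numeric(cvox))^2 * zones$spacing^2)
      zone_lab <- zones$data[matrix(zidx[which.min(d2), ], 1L)]
    }
  }
  structure(
    list(mask = mask,
         probability = component$score,
         volume_cm3 = mask_volume(mask),
         centroid_voxel = as.numeric(centroid),
         centroid_slice = as.integer(cvox[3]),
         centroid_zone = if (zone_lab == 2L) "CG" else "PZ",
         centroid_region = centroid_region(centroid[3], wp),
         min_adc = min(adc$data[mask$data > 0]),
         extracapsular = any(mask$data > 0 & wp$data == 0)),
    class = "lesion_candidate")
}

#' Sort lesion candidates for reporting
#'
#' Stable sort in descending order of probability of CSPCa; ties keep
#' their extraction order.
#'
#' @param candidates List of `lesion_candidate` objects.
#' @return The sorted list.
#' @export
rank_lesions <- function(candidates) {
  if (length(candidates) <= 1L) return(candidates)
  p <- vapply(candidates, `[[`, numeric(1), "probability")
  candidates[order(-p)]   # order() is stable
}

#' All prostate-level measurements for a report
#'
#' @param zones Zonal label [voxel_grid()].
#' @param psa PSA (ng/mL), may be `NA`.
#' @return An object of class `prostate_measurements`: lengths (cm), PZ /
#'   CG / whole-prostate volumes (cm^3), PSA density (or `NA` when PSA is
#'   missing).
#' @export
prostate_measurements <- function(zones, psa = NA_real_) {
  wp <- whole_prostate_mask(zones)
  lens <- prostate_lengths(wp)
  pz_vol <- sum(zones$data == 1L) * prod(zones$spacing) / 1000
  cg_vol <- sum(zones$data == 2L) * prod(zones$spacing) / 1000
  wp_vol <- mask_volume(wp)
  psad <- if (is.na(psa)) NA_real_ else psa_density(psa, wp_vol)
  structure(
    list(transverse_cm = unname(lens[1]),
         anterior_posterior_cm = unname(lens[2]),
         cranio_caudal_cm = unname(lens[3]),
         wp_volume_cm3 = wp_vol, pz_volume_cm3 = pz_vol,
         cg_volume_cm3 = cg_vol, psa_density = psad),
    class = "prostate_measurements")
}
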