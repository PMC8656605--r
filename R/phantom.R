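#' Specification of a synthetic prostate bpMRI phantom
#'
#' The phantom is a nested-ellipsoid model of the prostate: a whole-prostate
#' (WP) ellipsoid containing a central-gland (CG) ellipsoid; the peripheral
#' zone (PZ) is WP minus CG. Lesions are small ellipsoids of depressed ADC,
#' each labelled clinically significant (CSPCa) or not. Diffusion-weighted
#' images at the configured b-values are generated from the monoexponential
#' signal model \eqn{s(b) = s(0) \exp(-b \cdot ADC)} with optional additive
#' zero-mean Gaussian noise clipped at zero.
#'
#' Default tissue parameters are plausible 3T values: PZ ADC 1.6e-3, CG ADC
#' 1.3e-3, lesion ADC 0.8e-3 mm^2/s (ordering lesion < tissue is what
#' matters), b-values {0, 150, 500, 1000} s/mm^2 as in multi-b prostate DWI
#' protocols.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing Voxel spacing (mm).
#' @param wp_semi_axes,cg_semi_axes Ellipsoid semi-axes (mm); the CG
#'   ellipsoid must lie strictly inside the WP ellipsoid (both are centred
#'   at `center`).
#' @param center Physical centre of the prostate (mm); default grid centre.
#' @param lesions List of lesions, each
#'   `list(center = mm, semi_axes = mm, adc = mm^2/s, is_cspca = logical)`.
#' @param tissue_adc Named list, ADC of `pz` and `cg` tissue (mm^2/s).
#' @param background_adc ADC outside the prostate.
#' @param tissue_t2 Named list of T2WI intensities for `pz`, `cg`,
#'   `background`.
#' @param s0 Named list of b=0 DWI signal for `prostate` and `background`.
#' @param b_values Acquired b-values (s/mm^2); at least two distinct values,
#'   one below 100.
#' @param noise_sigma SD of additive Gaussian noise on DWI magnitude.
#' @param psa Serum PSA (ng/mL) for the synthetic patient.
#' @param age Patient age (years).
#' @param seed Integer seed; the phantom is bit-reproducible given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 40L),
                         spacing = c(0.6, 0.6, 1.5),
                         wp_semi_axes = c(20, 15, 22),
                         cg_semi_axes = c(12, 9, 14),
                         center = NULL,
                         lesions = list(
                           list(center = c(15, 0, 5), semi_axes = c(4, 4, 4),
                                adc = 0.8e-3, is_cspca = TRUE)),
                         tissue_adc = list(pz = 1.6e-3, cg = 1.3e-3),
                         background_adc = 2.5e-3,
                         tissue_t2 = list(pz = 500, cg = 400, background = 150),
                         s0 = list(prostate = 400, background = 100),
                         b_values = c(0, 150, 500, 1000),
                         noise_sigma = 0,
                         psa = 8, age = 65, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(unique(b_values)) < 2L || min(b_values) >= 100)
    stop("b_values needs >= 2 distinct values including one < 100",
         call. = FALSE)
  if (any(cg_semi_axes >= wp_semi_axes))
    stop("CG ellipsoid must lie strictly inside the WP ellipsoid",
         call. = FALSE)
  if (is.null(center))
    center <- (grid_shape - 1) / 2 * spacing
  for (les in lesions) {
    if (les$adc >= min(unlist(tissue_adc)))
      stop("lesion ADC must be below surrounding tissue ADC", call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, spacing = as.numeric(spacing),
         wp_semi_axes = as.numeric(wp_semi_axes),
         cg_semi_axes = as.numeric(cg_semi_axes),
         center = as.numeric(center), lesions = lesions,
         tissue_adc = tissue_adc, background_adc = background_adc,
         tissue_t2 = tissue_t2, s0 = s0, b_values = as.numeric(b_values),
         noise_sigma = noise_sigma, psa = psa, age = age,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# Rasterize an ellipsoid: voxel belongs iff its CENTER satisfies the
# ellipsoid inequality (matches the voxel-centre convention of voxel_grid).
rasterize_ellipsoid <- function(grid_shape, spacing, origin, center,
                                semi_axes) {
  cx <- (origin[1] + (seq_len(grid_shape[1]) - 1) * spacing[1] - center[1]) /
    semi_axes[1]
  cy <- (origin[2] + (seq_len(grid_shape[2]) - 1) * spacing[2] - center[2]) /
    semi_axes[2]
  cz <- (origin[3] + (seq_len(grid_shape[3]) - 1) * spacing[3] - center[3]) /
    semi_axes[3]
  q <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  array(q <= 1, grid_shape)
}

ellipsoid_volume_mm3 <- function(semi_axes) 4 / 3 * pi * prod(semi_axes)

#' Generate a synthetic prostate bpMRI case
#'
#' Deterministic given `spec$seed`. Returns T2WI, multi-b DWI, the
#' ground-truth ADC map, zonal labels (0 background, 1 PZ, 2 CG), per-lesion
#' masks with CSPCa labels, a synthetic patient record, and the analytic
#' ellipsoid volumes and diameters the rasterized masks converge to as
#' spacing shrinks.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_case` with elements `t2`, `dwi`
#'   (named list, one grid per b-value), `adc_gt`, `zones_gt`, `lesions_gt`
#'   (list of `list(mask, is_cspca)`), `patient`, `analytic`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; sp <- spec$spacing
  origin <- c(0, 0, 0)
  wp <- rasterize_ellipsoid(gs, sp, origin, spec$center, spec$wp_semi_axes)
  if (!any(wp)) stop("whole-prostate ellipsoid rasterizes to nothing",
                     call. = FALSE)
  cg <- rasterize_ellipsoid(gs, sp, origin, spec$center, spec$cg_semi_axes)
  if (any(cg & !wp))
    stop("CG rasterization escapes the WP mask", call. = FALSE)
  zones <- array(0L, gs)
  zones[wp] <- 1L
  zones[cg] <- 2L

  t2 <- array(spec$tissue_t2$background, gs)
  t2[zones == 1L] <- spec$tissue_t2$pz
  t2[zones == 2L] <- spec$tissue_t2$cg
  adc <- array(spec$background_adc, gs)
  adc[zones == 1L] <- spec$tissue_adc$pz
  adc[zones == 2L] <- spec$tissue_adc$cg
  s0 <- array(spec$s0$background, gs)
  s0[wp] <- spec$s0$prostate

  lesions_gt <- list()
  for (les in spec$lesions) {
    lc <- spec$center + les$center
    m <- rasterize_ellipsoid(gs, sp, origin, lc, les$semi_axes)
    adc[m] <- les$adc
    lesions_gt[[length(lesions_gt) + 1L]] <- list(
      mask = voxel_grid(array(as.integer(m), gs), sp, origin,
                        kind = "label", label_set = c(0L, 1L)),
      is_cspca = isTRUE(les$is_cspca),
      analytic_volume_mm3 = ellipsoid_volume_mm3(les$semi_axes))
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  dwi <- list()
  for (b in spec$b_values) {
    sig <- s0 * exp(-b * adc)
    if (spec$noise_sigma > 0)
      sig <- pmax(sig + array(stats::rnorm(prod(gs), 0, spec$noise_sigma),
                              gs), 0)
    dwi[[as.character(b)]] <- voxel_grid(sig, sp, origin)
  }

  dob <- as.Date("2026-01-01") - round(spec$age * 365.25)
  patient <- patient_record(
    name = sprintf("Phantom %03d", spec$seed),
    hospital_number = sprintf("PH%05d", spec$seed),
    date_of_birth = dob, scan_date = as.Date("2026-01-01"),
    age = spec$age, psa = spec$psa)

  wp_mm3 <- ellipsoid_volume_mm3(spec$wp_semi_axes)
  cg_mm3 <- ellipsoid_volume_mm3(spec$cg_semi_axes)
  analytic <- list(
    wp_volume_cm3 = wp_mm3 / 1000,
    cg_volume_cm3 = cg_mm3 / 1000,
    pz_volume_cm3 = (wp_mm3 - cg_mm3) / 1000,
    lengths_cm = 2 * spec$wp_semi_axes / 10)

  structure(
    list(t2 = voxel_grid(t2, sp, origin),
         dwi = dwi,
         adc_gt = voxel_grid(adc, sp, origin),
         s0_gt = voxel_grid(s0, sp, origin),
         zones_gt = voxel_grid(zones, sp, origin, kind = "label",
                               label_set = c(0L, 1L, 2L)),
         lesions_gt = lesions_gt,
         patient = patient,
         analytic = analytic,
         spec = spec),
    class = "phantom_case")
}

#' Generate a cohort of phantom cases
#'
#' Varies prostate size, lesion placement and PSA across cases in a seeded,
#' reproducible way. Roughly half the cases carry one or two CSPCa lesions
#' (biopsy-positive); the rest carry at most a non-significant lesion and
#' are flagged biopsy-negative for false-positive accounting.
#'
#' @param n Number of cases.
#' @param seed Integer master seed.
#' @param grid_shape,spacing Passed to [phantom_spec()].
#' @param noise_sigma DWI noise SD.
#' @return A list of `phantom_case` objects; each has
#'   `$biopsy_negative` set.
#' @export
generate_cohort <- function(n, seed = 1L, grid_shape = c(64L, 64L, 24L),
                            spacing = c(0.9, 0.9, 2.4), noise_sigma = 0) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    wp <- c(stats::runif(1, 17, 21), stats::runif(1, 13, 16),
            stats::runif(1, 16, 20))
    cg <- wp * stats::runif(3, 0.55, 0.65)
    positive <- (i %% 2L) == 1L
    lesions <- list()
    n_cs <- if (positive) sample(1:2, 1) else 0L
    n_ncs <- sample(0:1, 1)
    place <- function() {
      # place lesion centre inside the PZ band, mid-gland
      ang <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 0.7, 0.85)
      c(r * wp[1] * cos(ang), r * wp[2] * sin(ang), stats::runif(1, -4, 4))
    }
    for (k in seq_len(n_cs))
      lesions[[length(lesions) + 1L]] <- list(
        center = place(), semi_axes = stats::runif(3, 3.2, 4.5),
        adc = 0.8e-3, is_cspca = TRUE)
    for (k in seq_len(n_ncs))
      lesions[[length(lesions) + 1L]] <- list(
        center = place(), semi_axes = stats::runif(3, 3.0, 4.0),
        adc = 1.0e-3, is_cspca = FALSE)
    spec <- phantom_spec(
      grid_shape = grid_shape, spacing = spacing,
      wp_semi_axes = wp, cg_semi_axes = cg, lesions = lesions,
      noise_sigma = noise_sigma,
      psa = round(stats::runif(1, 4, 15), 2),
      age = sample(55:75, 1),
      seed = seed * 1000L + i)
    case <- generate_phantom(spec)
    case$biopsy_negative <- !positive
    cases[[i]] <- case
  }
  cases
}

#' Perturb a binary mask to a target Dice overlap
#'
#' Used by the oracle segmentation backend to emulate an imperfect
#' segmenter with a controlled accuracy. The perturbation swaps `k` voxels
#' from the mask's inner boundary for `k` voxels on its outer boundary,
#' where `k = round(|mask| * (1 - dice_target))`; the resulting mask keeps
#' the input's voxel count, so its Dice with the input is exactly
#' `1 - k/|mask|` (within rounding, well inside the +-0.05 contract).
#' Deterministic given `seed`.
#'
#' @param mask A binary `voxel_grid` (or 3D 0/1 array).
#' @param dice_target Target Dice in (0, 1].
#' @param seed Integer seed.
#' @return A perturbed mask of the same class as the input.
#' @export
perturb_mask <- function(mask, dice_target, seed = 1L) {
  grid <- NULL
  if (is_voxel_grid(mask)) { grid <- mask; m <- mask$data > 0 }
  else m <- mask > 0
  if (!any(m)) stop("mask is empty", call. = FALSE)
  if (!is.numeric(dice_target) || dice_target <= 0 || dice_target > 1)
    stop("dice_target must be in (0, 1]", call. = FALSE)
  v <- sum(m)
  k <- round(v * (1 - dice_target))
  if (k == 0L) return(mask)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  gs <- dim(m)
  # peel k voxels from successive inner-boundary layers of the mask
  kept <- m
  to_remove <- k
  while (to_remove > 0L) {
    inner <- which(kept & !erode6(kept))
    if (length(inner) == 0L) break
    take <- if (length(inner) <= to_remove) inner
            else sample(inner, to_remove)
    kept[take] <- FALSE
    to_remove <- to_remove - length(take)
  }
  # grow k voxels on successive outer-dilation layers of the mask
  grown <- m
  to_add <- k
  while (to_add > 0L) {
    layer <- which(dilate6(grown) & !grown & !m)
    if (length(layer) == 0L) break
    take <- if (length(layer) <= to_add) layer
            else sample(layer, to_add)
    grown[take] <- TRUE
    to_add <- to_add - length(take)
  }
  out <- kept | (grown & !m)
  res <- array(as.integer(out), gs)
  if (!is.null(grid))
    voxel_grid(res, grid$spacing, grid$origin, kind = "label",
               label_set = c(0L, 1L))
  else res
}

# 6-neighbour binary erosion/dilation via array shifts (no padding wrap)
shift3 <- function(m, d) {
  gs <- dim(m); out <- array(FALSE, gs)
  src <- lapply(1:3, function(a) {
    i <- seq_len(gs[a]) + d[a]
    i[i < 1L | i > gs[a]] <- NA_integer_
    i
  })
  ok <- lapply(src, function(i) !is.na(i))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    m[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

erode6 <- function(m) {
  out <- m
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1),
                 c(0,0,-1)))
    out <- out & shift3(m, d)
  out
}

dilate6 <- function(m) {
  out <- m
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1),
                 c(0,0,-1)))
    out <- out | shift3(m, d)
  out
}
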