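#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the computed high b-value.
#'
#' @param preprocess A [preprocess_config()].
#' @param postprocess A [postprocess_config()].
#' @param backend A [backend_config()].
#' @param bc Computed high b-value (s/mm^2), default 2000.
#' @param detection_cutoff Score cut-off used when summarizing detections
#'   at lesion level.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            postprocess = postprocess_config(),
                            backend = backend_config(),
                            bc = 2000, detection_cutoff = 0.5) {
  structure(list(preprocess = preprocess, postprocess = postprocess,
                 backend = backend, bc = bc,
                 detection_cutoff = detection_cutoff),
            class = "pipeline_config")
}

#' Pipeline configuration for phantom studies
#'
#' Phantom evaluations run at the phantom's native resolution (the
#' resample step becomes the identity) with in-plane crops sized to the
#' phantom grid, no test-time augmentation and a single forward pass:
#' with a deterministic oracle backend, augmentation averaging has no
#' meaning and native resolution keeps geometric closure exact.
#'
#' @param case A `phantom_case` (defines native spacing and grid shape).
#' @param crop Optional in-plane crop shape; defaults to the grid's own
#'   in-plane shape.
#' @return A `pipeline_config`.
#' @export
phantom_pipeline_config <- function(case, crop = NULL) {
  gs <- dim(case$t2$data)
  if (is.null(crop)) crop <- gs[1:2]
  pipeline_config(
    preprocess = preprocess_config(target_spacing = case$t2$spacing[1],
                                   zone_crop_shape = crop,
                                   lesion_crop_shape = crop),
    backend = backend_config(tta_transforms = list(), ttd_passes = 1L))
}

# Transform an original-grid volume into preprocessed (resampled +
# cropped) space; used both for input channels and to give oracle
# backends their ground truth on the grid they will be asked about.
preprocess_transform <- function(target_spacing, crop_shape,
                                 center = NULL) {
  function(grid) {
    rs <- resample_inplane(grid, target_spacing)
    ctr <- center
    if (!is.null(ctr)) {
      # physical centre -> voxel coords of the resampled grid
      ctr <- (ctr[1:2] - rs$grid$origin[1:2]) / rs$grid$spacing[1:2] + 1
    }
    cr <- crop_or_pad_inplane(rs$grid, crop_shape, center = ctr)
    list(grid = cr$grid, records = list(rs$record, cr$record))
  }
}

restore_chain <- function(grid, records) {
  for (rec in rev(records)) grid <- restore_geometry(grid, rec)
  grid
}

#' Oracle zone-segmentation backend builder
#'
#' Returns a builder for [assess_case()]: given the pipeline's transform
#' into preprocessed space, it perturbs the case's ground-truth zonal
#' labels to the requested Dice and serves them as one-hot probability
#' channels.
#'
#' @param case A `phantom_case` (or any case with `zones_gt`).
#' @param dice_target Dice of the emulated segmenter against ground
#'   truth (1 = perfect).
#' @param seed Integer seed for the perturbation.
#' @return A builder function `(transform) -> slice_predictor`.
#' @export
oracle_zone_builder <- function(case, dice_target = 1, seed = 1L) {
  force(case); force(dice_target); force(seed)
  function(transform) {
    zones <- case$zones_gt
    if (dice_target < 1) {
      pz <- perturb_mask(with_data(zones,
              array(as.integer(zones$data == 1L), dim(zones$data)),
              kind = "label", label_set = c(0L, 1L)), dice_target, seed)
      cg <- perturb_mask(with_data(zones,
              array(as.integer(zones$data == 2L), dim(zones$data)),
              kind = "label", label_set = c(0L, 1L)), dice_target,
              seed + 1L)
      lab <- array(0L, dim(zones$data))
      lab[pz$data > 0] <- 1L
      lab[cg$data > 0] <- 2L   # CG wins where perturbations overlap
      zones <- with_data(zones, lab, kind = "label",
                         label_set = c(0L, 1L, 2L))
    }
    tz <- transform(zones)$grid
    oracle_backend(zone_channels_from_labels(tz))
  }
}

#' Oracle lesion-segmentation backend builder
#'
#' Serves a CSPCa probability map built from the case's (optionally
#' perturbed) ground-truth lesion masks: CSPCa lesions get a high raw
#' probability, non-significant lesions an intermediate one, background
#' a low floor — emulating a segmenter that sees every annotated lesion
#' but ranks them by suspicion.
#'
#' @param case A `phantom_case`.
#' @param dice_target Per-lesion mask Dice against ground truth.
#' @param seed Integer seed.
#' @param p_cspca,p_ncspca,p_background Raw probabilities emitted inside
#'   CSPCa lesions, non-significant lesions, and elsewhere.
#' @return A builder function `(transform) -> slice_predictor`.
#' @export
oracle_lesion_builder <- function(case, dice_target = 1, seed = 1L,
                                  p_cspca = 0.95, p_ncspca = 0.35,
                                  p_background = 0.01) {
  force(case); force(dice_target); force(seed)
  function(transform) {
    base <- case$zones_gt
    prob <- array(p_background, dim(base$data))
    i <- 0L
    for (les in case$lesions_gt) {
      i <- i + 1L
      m <- les$mask
      if (dice_target < 1) m <- perturb_mask(m, dice_target, seed + i)
      prob[m$data > 0] <- if (les$is_cspca) p_cspca else p_ncspca
    }
    pg <- voxel_grid(prob, base$spacing, base$origin, kind = "probability")
    tp <- transform(pg)$grid
    oracle_backend(list(lesion = with_data(tp, clip01(tp$data),
                                           kind = "probability")))
  }
}

#' Run the full assessment pipeline on one case
#'
#' Zone pathway: T2WI is resampled to the common in-plane resolution,
#' cropped, whitened, segmented slice-wise by the zone backend (with the
#' configured ensemble/TTA/TTD aggregation), restored to the original
#' grid and converted to a zonal label map by per-voxel argmax. Lesion
#' pathway: the computed high b-value volume is derived from the multi-b
#' DWI stack, ADC and computed DWI are aligned to T2WI, all channels are
#' resampled and cropped centred on the prostate, T2WI and computed DWI
#' are normalized by the CG interquartile mean (ADC is not), the
#' five-channel stack is segmented by the lesion backend, restored,
#' calibrated, thresholded at the cut-off and size-filtered into
#' candidates. Measurements and the report are derived from the results.
#'
#' @param case A case list with `t2`, `dwi`, optional `adc`, `patient`
#'   (e.g. a `phantom_case`; its `adc_gt` is used as the supplied ADC
#'   map).
#' @param zone_builder,lesion_builder Backend builders
#'   `(transform) -> slice_predictor` (see [oracle_zone_builder()]).
#' @param config A `pipeline_config`.
#' @param calibrator Optional fitted [fit_calibrator()] output; `NULL`
#'   applies no calibration (identity).
#' @param seed Integer seed forwarded to stochastic backends.
#' @return List: `zones`, `measurements`, `raw_prob`, `cal_prob`,
#'   `candidates` (characterized, ranked), `report`.
#' @export
assess_case <- function(case, zone_builder, lesion_builder,
                        config = pipeline_config(), calibrator = NULL,
                        seed = 1L) {
  pp <- config$preprocess
  ## ---- zone pathway ----
  zone_tf <- preprocess_transform(pp$target_spacing, pp$zone_crop_shape)
  t2p <- zone_tf(case$t2)
  t2w <- whiten(t2p$grid)
  zone_pred <- zone_builder(zone_tf)
  zprob <- predict_volume(zone_pred, list(t2w), config$backend, seed)
  zprob_orig <- lapply(zprob, restore_chain, records = t2p$records)
  zones <- zones_argmax(zprob_orig)
  wp <- whole_prostate_mask(zones)
  meas <- prostate_measurements(zones, psa = case$patient$psa)

  ## ---- lesion pathway ----
  adc <- if (!is.null(case$adc)) case$adc else case$adc_gt
  cb <- compute_high_b_volume(case$dwi, config$bc)
  adc_al <- align_to_reference(adc, case$t2)
  cb_al <- align_to_reference(cb, case$t2)
  # crop centred on the prostate (WP centroid, physical coordinates)
  wp_idx <- which(wp$data > 0, arr.ind = TRUE)
  center_phys <- if (nrow(wp_idx) > 0)
    voxel_to_physical(wp, colMeans(wp_idx)) else NULL
  les_tf <- preprocess_transform(pp$target_spacing, pp$lesion_crop_shape,
                                 center = center_phys)
  t2c <- les_tf(case$t2)
  adcc <- les_tf(adc_al)
  cbc <- les_tf(cb_al)
  zonesc <- les_tf(zones)
  cg_mask <- with_data(zonesc$grid,
                       array(as.integer(zonesc$grid$data == 2L),
                             dim(zonesc$grid$data)),
                       kind = "label", label_set = c(0L, 1L))
  t2n <- normalize_by_cg(t2c$grid, cg_mask)
  cbn <- normalize_by_cg(cbc$grid, cg_mask)
  pzp <- with_data(zonesc$grid,
                   array(as.numeric(zonesc$grid$data == 1L),
                         dim(zonesc$grid$data)), kind = "probability")
  cgp <- with_data(zonesc$grid,
                   array(as.numeric(zonesc$grid$data == 2L),
                         dim(zonesc$grid$data)), kind = "probability")
  les_pred <- lesion_builder(les_tf)
  lprob <- predict_volume(les_pred, list(t2n, adcc$grid, cbn, pzp, cgp),
                          config$backend, seed)[[1]]
  raw_prob <- restore_chain(lprob, t2c$records)
  cal_prob <- if (is.null(calibrator)) raw_prob
              else apply_calibrator(calibrator, raw_prob)
  comps <- extract_candidates(cal_prob, config$postprocess)
  cands <- lapply(comps, characterize_lesion, zones = zones, wp = wp,
                  adc = adc_al)
  cands <- rank_lesions(cands)
  report <- build_report(case$patient, meas, cands,
                         config_hash = rlang::hash(unclass(config)),
                         timestamp = "1970-01-01T00:00:00Z")
  list(zones = zones, measurements = meas, raw_prob = raw_prob,
       cal_prob = cal_prob, candidates = cands, report = report)
}

#' Fit an isotonic calibrator on a training cohort
#'
#' Runs the lesion pathway on each training case, pools voxel-level
#' (raw score, in-CSPCa-lesion) pairs across cases — subsampled to at
#' most `max_voxels_per_case` voxels per case for memory — and fits the
#' pool-adjacent-violators calibrator.
#'
#' @param cases List of cases.
#' @param zone_builder_fn,lesion_builder_fn Functions `(case) -> builder`
#'   (see [oracle_zone_builder()]).
#' @param config_fn Function `(case) -> pipeline_config`.
#' @param max_voxels_per_case Subsample cap per case.
#' @param seed Integer seed.
#' @return A fitted `calibrator`.
#' @export
fit_cohort_calibrator <- function(cases, zone_builder_fn, lesion_builder_fn,
                                  config_fn = phantom_pipeline_config,
                                  max_voxels_per_case = 20000L, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  xs <- list(); ys <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    res <- assess_case(case, zone_builder_fn(case), lesion_builder_fn(case),
                       config = config_fn(case), calibrator = NULL,
                       seed = seed + ci)
    gt <- array(0L, dim(case$t2$data))
    for (les in case$lesions_gt)
      if (les$is_cspca) gt[les$mask$data > 0] <- 1L
    sc <- as.numeric(res$raw_prob$data)
    lb <- as.numeric(gt)
    n <- length(sc)
    if (n > max_voxels_per_case) {
      keep <- sample.int(n, max_voxels_per_case)
      sc <- sc[keep]; lb <- lb[keep]
    }
    xs[[ci]] <- sc; ys[[ci]] <- lb
  }
  fit_calibrator(unlist(xs), unlist(ys))
}

#' Evaluate the pipeline over a phantom cohort
#'
#' Runs [assess_case()] on every case, matches candidates to
#' ground-truth lesions, and aggregates segmentation and detection
#' metrics.
#'
#' @param cases List of `phantom_case`s (with `biopsy_negative` flags).
#' @param zone_builder_fn,lesion_builder_fn Functions `(case) -> builder`.
#' @param config_fn Function `(case) -> pipeline_config`.
#' @param calibrator Optional fitted calibrator applied to every case.
#' @param seed Integer seed.
#' @return List: `per_case` (zone Dice, volume errors, outcome per
#'   case), `detection` ([detection_metrics()] output at the configured
#'   cut-off), `mean_dice` (named: pz, cg, wp).
#' @export
evaluate_cohort <- function(cases, zone_builder_fn, lesion_builder_fn,
                            config_fn = phantom_pipeline_config,
                            calibrator = NULL, seed = 1L) {
  per_case <- list()
  outcomes <- list()
  cutoff <- NULL
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    cfg <- config_fn(case)
    if (is.null(cutoff)) cutoff <- cfg$detection_cutoff
    res <- assess_case(case, zone_builder_fn(case), lesion_builder_fn(case),
                       config = cfg, calibrator = calibrator,
                       seed = seed + ci)
    gt <- case$zones_gt
    d_pz <- dice(res$zones$data == 1L, gt$data == 1L)
    d_cg <- dice(res$zones$data == 2L, gt$data == 2L)
    d_wp <- dice(res$zones$data > 0L, gt$data > 0L)
    comp_list <- lapply(res$candidates, function(l)
      list(mask = l$mask, score = l$probability))
    out <- match_detections(comp_list, case$lesions_gt,
                            prob = res$cal_prob,
                            biopsy_negative = isTRUE(case$biopsy_negative))
    outcomes[[ci]] <- out
    per_case[[ci]] <- list(
      dice_pz = d_pz, dice_cg = d_cg, dice_wp = d_wp,
      wp_volume_cm3 = res$measurements$wp_volume_cm3,
      wp_volume_abs_pct_err = abs_pct_err(res$measurements$wp_volume_cm3,
                                          case$analytic$wp_volume_cm3),
      psa_density = res$measurements$psa_density,
      n_candidates = length(res$candidates))
  }
  det <- detection_metrics(outcomes, cutoff)
  list(per_case = per_case, outcomes = outcomes, detection = det,
       mean_dice = c(
         pz = mean(vapply(per_case, `[[`, numeric(1), "dice_pz")),
         cg = mean(vapply(per_case, `[[`, numeric(1), "dice_cg")),
         wp = mean(vapply(per_case, `[[`, numeric(1), "dice_wp"))))
}
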