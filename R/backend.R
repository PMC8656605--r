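#' Slice-wise segmentation predictor contract
#'
#' A predictor wraps any slice-wise segmentation model behind a uniform
#' interface so that the aggregation machinery (ensembling, test-time
#' augmentation, test-time dropout) is independent of the model. The
#' network itself is not part of this package; predictors adapt external
#' models or, for testing, the ground-truth oracle.
#'
#' @param predict Function `(channels, z, seed)` where `channels` is a list
#'   of 2D matrices (one per input channel) and `z` the slice index;
#'   returns a list of per-class 2D probability matrices. For zone
#'   predictors the per-pixel class probabilities must sum to 1; lesion
#'   predictors return a single foreground probability map.
#' @param classes Character vector of class names emitted.
#' @param stochastic `TRUE` if repeated calls with different seeds give
#'   different stochastic passes (test-time dropout support).
#' @return An object of class `slice_predictor`.
#' @export
slice_predictor <- function(predict, classes, stochastic = FALSE) {
  stopifnot(is.function(predict), length(classes) >= 1L)
  structure(list(predict = predict, classes = as.character(classes),
                 stochastic = isTRUE(stochastic)),
            class = "slice_predictor")
}

#' Backend aggregation configuration
#'
#' @param tta_transforms List of TTA transform names from
#'   `"hflip"`, `"rot+10"`, `"rot-10"`, `"scale0.9"`, `"scale1.1"`; each
#'   has an exact or near-exact inverse for probability maps. Empty list
#'   disables TTA.
#' @param ttd_passes Number of stochastic forward passes (test-time
#'   dropout); 1 disables TTD averaging.
#' @param dropout_p Dropout probability used by stochastic predictors
#'   (default 0.2).
#' @param ensemble_members Number of ensemble members a multi-model
#'   backend should aggregate (informational; the predictor list passed to
#'   [predict_volume()] is what is actually averaged).
#' @return An object of class `backend_config`.
#' @export
backend_config <- function(tta_transforms = list(), ttd_passes = 1L,
                           dropout_p = 0.2, ensemble_members = 1L) {
  ttd_passes <- as.integer(ttd_passes)
  if (ttd_passes < 1L) stop("ttd_passes must be >= 1", call. = FALSE)
  known <- c("hflip", "rot+10", "rot-10", "scale0.9", "scale1.1")
  for (tr in tta_transforms)
    if (!tr %in% known)
      stop(sprintf("unknown TTA transform '%s'", tr), call. = FALSE)
  structure(list(tta_transforms = tta_transforms, ttd_passes = ttd_passes,
                 dropout_p = dropout_p,
                 ensemble_members = as.integer(ensemble_members)),
            class = "backend_config")
}

#' Average probability maps voxelwise
#'
#' Arithmetic per-voxel mean of probability volumes or slices; the result
#' is order-invariant and bounded by the voxelwise min/max of the inputs.
#'
#' @param maps List of [voxel_grid()]s (or plain arrays/matrices) with
#'   identical geometry.
#' @return The mean, of the same type as the inputs.
#' @export
ensemble_average <- function(maps) {
  if (length(maps) < 1L) stop("need at least one map", call. = FALSE)
  if (is_voxel_grid(maps[[1]])) {
    ref <- maps[[1]]
    for (m in maps) stop_if_geometry_mismatch(ref, m, "probability maps")
    acc <- array(0, dim(ref$data))
    for (m in maps) acc <- acc + m$data
    return(with_data(ref, acc / length(maps), kind = "probability"))
  }
  ref_dim <- dim(maps[[1]])
  acc <- array(0, ref_dim)
  for (m in maps) {
    if (!identical(dim(m), ref_dim))
      stop("probability maps do not share shape", call. = FALSE)
    acc <- acc + m
  }
  acc / length(maps)
}

# --- invertible 2D TTA transforms -------------------------------------------

tta_forward <- function(mat, name) {
  switch(name,
    "hflip"    = mat[rev(seq_len(nrow(mat))), , drop = FALSE],
    "rot+10"   = EBImage::rotate(mat, 10, output.dim = dim(mat), bg.col = 0),
    "rot-10"   = EBImage::rotate(mat, -10, output.dim = dim(mat), bg.col = 0),
    "scale0.9" = tta_scale(mat, 0.9),
    "scale1.1" = tta_scale(mat, 1.1),
    stop(sprintf("unknown TTA transform '%s'", name), call. = FALSE))
}

tta_inverse <- function(mat, name) {
  switch(name,
    "hflip"    = mat[rev(seq_len(nrow(mat))), , drop = FALSE],
    "rot+10"   = EBImage::rotate(mat, -10, output.dim = dim(mat), bg.col = 0),
    "rot-10"   = EBImage::rotate(mat, 10, output.dim = dim(mat), bg.col = 0),
    "scale0.9" = tta_scale(mat, 1 / 0.9),
    "scale1.1" = tta_scale(mat, 1 / 1.1),
    stop(sprintf("unknown TTA transform '%s'", name), call. = FALSE))
}

# isotropic scale about the image centre, output shape preserved
tta_scale <- function(mat, s) {
  d <- dim(mat)
  big <- EBImage::resize(mat, w = max(1L, round(d[1] * s)),
                         h = max(1L, round(d[2] * s)))
  db <- dim(big)
  out <- matrix(0, d[1], d[2])
  # centre-aligned copy
  off <- (db - d) %/% 2L
  src_lo <- pmax(off + 1L, 1L); src_hi <- pmin(off + d, db)
  dst_lo <- src_lo - off; dst_hi <- src_hi - off
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2]] <-
    big[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2]]
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Predict one slice with test-time augmentation
#'
#' For each configured transform the input channels are transformed, the
#' predictor is run, and the output probabilities are mapped back through
#' the inverse transform; the untransformed prediction and all
#' inverse-transformed predictions are combined by [ensemble_average()].
#'
#' @param predictor A [slice_predictor()].
#' @param channels List of 2D matrices (input channels).
#' @param transforms List of TTA transform names (see [backend_config()]).
#' @param z Slice index forwarded to the predictor.
#' @param seed Seed forwarded to stochastic predictors.
#' @return List of per-class 2D probability matrices.
#' @export
tta_predict <- function(predictor, channels, transforms = list(), z = 1L,
                        seed = 1L) {
  preds <- list(predictor$predict(channels, z, seed))
  for (tr in transforms) {
    tch <- lapply(channels, tta_forward, name = tr)
    p <- predictor$predict(tch, z, seed)
    preds[[length(preds) + 1L]] <-
      lapply(p, function(m) clip01(tta_inverse(m, tr)))
  }
  ncls <- length(preds[[1]])
  out <- vector("list", ncls)
  names(out) <- names(preds[[1]])
  for (k in seq_len(ncls))
    out[[k]] <- ensemble_average(lapply(preds, `[[`, k))
  out
}

#' Predict one slice with test-time dropout
#'
#' Mean over `passes` stochastic forward passes of a stochastic predictor;
#' deterministic given `seed` (pass `i` uses seed `seed + i`).
#'
#' @param predictor A [slice_predictor()] with `stochastic = TRUE` when
#'   `passes > 1`.
#' @param channels List of 2D channel matrices.
#' @param passes Number of passes (>= 1).
#' @param z Slice index.
#' @param seed Integer base seed.
#' @return List of per-class 2D probability matrices.
#' @export
ttd_predict <- function(predictor, channels, passes = 10L, z = 1L,
                        seed = 1L) {
  passes <- as.integer(passes)
  if (passes < 1L) stop("passes must be >= 1", call. = FALSE)
  if (passes > 1L && !predictor$stochastic)
    stop("predictor is not stochastic; cannot run test-time dropout",
         call. = FALSE)
  preds <- lapply(seq_len(passes), function(i)
    predictor$predict(channels, z, seed + i))
  ncls <- length(preds[[1]])
  out <- vector("list", ncls)
  names(out) <- names(preds[[1]])
  for (k in seq_len(ncls))
    out[[k]] <- ensemble_average(lapply(preds, `[[`, k))
  out
}

#' Run a backend over a volume, slice by slice
#'
#' Applies each predictor to every axial slice with the configured
#' test-time augmentation and test-time dropout, averages predictors
#' voxelwise (ensembling), and restacks slices along z into per-class
#' probability volumes.
#'
#' @param predictors A [slice_predictor()] or list of them (the ensemble).
#' @param channels List of [voxel_grid()]s, the input channels; all must
#'   share geometry.
#' @param config A [backend_config()].
#' @param seed Integer seed for stochastic passes.
#' @return Named list of probability [voxel_grid()]s, one per class.
#' @export
predict_volume <- function(predictors, channels, config = backend_config(),
                           seed = 1L) {
  if (inherits(predictors, "slice_predictor")) predictors <- list(predictors)
  ref <- channels[[1]]
  for (ch in channels)
    stop_if_geometry_mismatch(ref, ch, "input channels")
  gs <- dim(ref$data)
  classes <- predictors[[1]]$classes
  vols <- lapply(classes, function(cl) array(0, gs))
  names(vols) <- classes
  for (z in seq_len(gs[3])) {
    sl <- lapply(channels, function(ch) ch$data[, , z])
    per_model <- lapply(predictors, function(pr) {
      if (config$ttd_passes > 1L && pr$stochastic) {
        # pooled average over all dropout passes and TTA transforms
        passes <- lapply(seq_len(config$ttd_passes), function(i)
          tta_predict(pr, sl, config$tta_transforms, z = z,
                      seed = seed + 1000L * i))
        ncls <- length(passes[[1]])
        out <- vector("list", ncls); names(out) <- names(passes[[1]])
        for (k in seq_len(ncls))
          out[[k]] <- ensemble_average(lapply(passes, `[[`, k))
        out
      } else {
        tta_predict(pr, sl, config$tta_transforms, z = z, seed = seed)
      }
    })
    for (k in seq_along(classes)) {
      avg <- ensemble_average(lapply(per_model, `[[`, k))
      vols[[k]][, , z] <- avg
    }
  }
  lapply(vols, function(v)
    voxel_grid(clip01(v), ref$spacing, ref$origin, kind = "probability"))
}

#' Oracle segmentation backend
#'
#' A predictor that ignores its input channels and returns stored
#' probability maps derived from (optionally perturbed) ground truth. It
#' stands in for a trained network in tests and phantom studies: at
#' `dice_target = 1` the pipeline around it must reproduce the ground
#' truth exactly, and degrading `dice_target` degrades downstream metrics
#' in a controlled way.
#'
#' @param prob_channels Named list of probability [voxel_grid()]s on the
#'   grid the predictor will be asked about (one per class).
#' @param noise_sd If > 0, each stochastic pass adds seeded Gaussian noise
#'   of this SD (clipped to `[0,1]`), for exercising test-time dropout.
#' @return A [slice_predictor()].
#' @export
oracle_backend <- function(prob_channels, noise_sd = 0) {
  classes <- names(prob_channels)
  force(prob_channels); force(noise_sd)
  pred <- function(channels, z, seed) {
    out <- lapply(prob_channels, function(g) g$data[, , z])
    if (noise_sd > 0) {
      old_seed <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                             envir = globalenv()))
      set.seed(seed)
      out <- lapply(out, function(m)
        clip01(m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))))
    }
    out
  }
  slice_predictor(pred, classes, stochastic = noise_sd > 0)
}

#' One-hot zone probability channels from a label map
#'
#' @param zones Label [voxel_grid()] with 0 = background, 1 = PZ, 2 = CG.
#' @return Named list of probability grids `background`, `pz`, `cg`.
#' @export
zone_channels_from_labels <- function(zones) {
  stopifnot(is_voxel_grid(zones))
  lab <- zones$data
  mk <- function(v) with_data(zones, array(as.numeric(lab == v), dim(lab)),
                              kind = "probability")
  list(background = mk(0L), pz = mk(1L), cg = mk(2L))
}
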