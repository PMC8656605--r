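#' Post-processing configuration for lesion candidates
#'
#' Defaults are the pipeline's standard operating point: probability
#' cut-off C = 4.5% and removal of connected components smaller than
#' 40 mm^3 (one fifth of the 200 mm^3 guideline minimum for clinically
#' significant lesions, allowing for partial segmentations).
#'
#' @param cutoff_C Probability cut-off in (0, 1); voxels with calibrated
#'   probability `>= cutoff_C` are foreground.
#' @param min_size_mm3 Minimum component volume in mm^3; components
#'   strictly smaller are removed (a component of exactly this volume is
#'   kept).
#' @param connectivity 3D neighbourhood: 6, 18 or 26 (default 26).
#' @return An object of class `postprocess_config`.
#' @export
postprocess_config <- function(cutoff_C = 0.045, min_size_mm3 = 40,
                               connectivity = 26L) {
  if (cutoff_C <= 0 || cutoff_C >= 1)
    stop("cutoff_C must be in (0, 1)", call. = FALSE)
  if (min_size_mm3 < 0) stop("min_size_mm3 must be >= 0", call. = FALSE)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(cutoff_C = cutoff_C, min_size_mm3 = min_size_mm3,
                 connectivity = connectivity),
            class = "postprocess_config")
}

#' Zonal label map by per-voxel argmax
#'
#' Assigns each voxel the class of highest probability among background,
#' PZ and CG channels. Exact ties are broken by the fixed priority
#' background < PZ < CG (the prostate classes win against background, CG
#' against PZ).
#'
#' @param channels Named list of probability [voxel_grid()]s with elements
#'   `background`, `pz`, `cg`, sharing geometry.
#' @return A label [voxel_grid()] with 0 = background, 1 = PZ, 2 = CG.
#' @export
zones_argmax <- function(channels) {
  need <- c("background", "pz", "cg")
  if (!all(need %in% names(channels)))
    stop("channels must contain background, pz, cg", call. = FALSE)
  bg <- channels$background; pz <- channels$pz; cg <- channels$cg
  stop_if_geometry_mismatch(bg, pz, "zone channels")
  stop_if_geometry_mismatch(bg, cg, "zone channels")
  lab <- array(0L, dim(bg$data))
  # priority on ties: cg beats pz beats background
  lab[pz$data >= bg$data] <- 1L
  lab[cg$data >= pz$data & cg$data >= bg$data] <- 2L
  voxel_grid(lab, bg$spacing, bg$origin, kind = "label",
             label_set = c(0L, 1L, 2L))
}

#' Fit an isotonic probability calibrator
#'
#' Solves the isotonic least-squares problem by pool-adjacent-violators:
#' the fitted values minimize \eqn{\sum_i w_i (y_i - f(x_i))^2} over all
#' non-decreasing \eqn{f}, where `x` are raw scores and `y` binary labels.
#' Tied scores are pooled before fitting. The calibrator maps raw to
#' calibrated probability by linear interpolation between the fitted
#' knots (constant beyond the outermost knots).
#'
#' @param raw_scores Numeric vector of raw probabilities/scores.
#' @param labels Binary vector (0/1) of the same length; both classes must
#'   be present.
#' @return An object of class `calibrator` with `breakpoints` (increasing
#'   score knots) and `values` (non-decreasing calibrated probabilities).
#' @export
fit_calibrator <- function(raw_scores, labels) {
  x <- as.numeric(raw_scores); y <- as.numeric(labels)
  if (length(x) != length(y) || length(x) < 2L)
    stop("need >= 2 (score, label) pairs", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit a calibrator", call. = FALSE)
  # pool tied scores
  agg <- stats::aggregate(list(y = y, w = rep(1, length(y))),
                          by = list(x = x), FUN = sum)
  agg <- agg[order(agg$x), ]
  ybar <- agg$y / agg$w
  fit <- pava(ybar, agg$w)
  structure(list(breakpoints = agg$x, values = fit), class = "calibrator")
}

# weighted pool-adjacent-violators for non-decreasing least squares
pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; size <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tw <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / tw
      wt[m - 1L] <- tw
      size[m - 1L] <- size[m - 1L] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = size[seq_len(m)])
}

#' Apply a calibrator pointwise
#'
#' Monotone piecewise-linear transform of raw probabilities; the voxelwise
#' rank ordering is preserved (non-strictly).
#'
#' @param cal A `calibrator` from [fit_calibrator()].
#' @param x A [voxel_grid()] or numeric vector/array of raw scores.
#' @return Calibrated values of the same type, in `[0, 1]`.
#' @export
apply_calibrator <- function(cal, x) {
  stopifnot(inherits(cal, "calibrator"))
  f <- function(v) {
    if (length(cal$breakpoints) == 1L)
      return(rep(cal$values, length(v)))
    stats::approx(cal$breakpoints, cal$values, xout = v, rule = 2,
                  ties = "ordered")$y
  }
  if (is_voxel_grid(x)) {
    out <- array(clip01(f(as.numeric(x$data))), dim(x$data))
    return(with_data(x, out, kind = "probability"))
  }
  out <- clip01(f(as.numeric(x)))
  if (is.array(x)) out <- array(out, dim(x))
  out
}

# 3D connected-component labelling under 6/18/26-connectivity.
# Returns an integer array of component ids (0 = background).
label_components <- function(mask, connectivity = 26L) {
  gs <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(array(0L, gs))
  id <- array(0L, gs)
  id[fg] <- seq_along(fg)
  offsets <- component_offsets(connectivity)
  edges <- list()
  coord <- arrayInd(fg, gs)
  for (k in seq_len(nrow(offsets))) {
    d <- offsets[k, ]
    nb <- sweep(coord, 2L, d, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] & nb[, 2] >= 1 &
      nb[, 2] <= gs[2] & nb[, 3] >= 1 & nb[, 3] <= gs[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * gs[1] * gs[2] + (nb[ok, 2] - 1L) * gs[1] +
      nb[ok, 1]
    nb_id <- id[nb_lin]
    src_id <- id[fg[ok]]
    keep <- nb_id > 0L
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(src_id[keep], nb_id[keep])
  }
  n <- length(fg)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  out <- array(0L, gs)
  out[fg] <- as.integer(comp)
  out
}

# positive half-neighbourhood offsets for the requested connectivity
component_offsets <- function(connectivity) {
  all_off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all_off <- all_off[rowSums(abs(all_off)) > 0, ]
  deg <- rowSums(abs(all_off))
  sel <- switch(as.character(connectivity),
                "6" = deg == 1, "18" = deg <= 2, "26" = deg <= 3)
  half <- all_off[sel, , drop = FALSE]
  # keep one direction of each pair; components does not need both
  half[half[, 1] > 0 | (half[, 1] == 0 & half[, 2] > 0) |
         (half[, 1] == 0 & half[, 2] == 0 & half[, 3] > 0), , drop = FALSE]
}

#' Extract lesion candidates from a calibrated probability volume
#'
#' Thresholds the map at the cut-off (voxels with probability `>=
#' cutoff_C` are positive), labels connected components under the
#' configured connectivity, removes components with physical volume
#' strictly below `min_size_mm3`, and scores each surviving component by
#' its maximum calibrated voxel probability.
#'
#' @param prob A probability [voxel_grid()] in `[0, 1]`.
#' @param config A [postprocess_config()].
#' @return List of candidates, each `list(mask, score, volume_mm3,
#'   n_voxels)`; empty list if nothing survives. Candidates are ordered by
#'   decreasing score.
#' @export
extract_candidates <- function(prob, config = postprocess_config()) {
  stopifnot(is_voxel_grid(prob))
  fg <- prob$data >= config$cutoff_C
  comp <- label_components(fg, config$connectivity)
  ncomp <- max(comp)
  if (ncomp == 0L) return(list())
  vox_mm3 <- prod(prob$spacing)
  out <- list()
  for (k in seq_len(ncomp)) {
    sel <- comp == k
    vol <- sum(sel) * vox_mm3
    if (vol < config$min_size_mm3) next   # strictly smaller => removed
    m <- array(as.integer(sel), dim(sel))
    out[[length(out) + 1L]] <- list(
      mask = voxel_grid(m, prob$spacing, prob$origin, kind = "label",
                        label_set = c(0L, 1L)),
      score = max(prob$data[sel]),
      volume_mm3 = vol,
      n_voxels = sum(sel))
  }
  if (length(out) > 1L) {
    ord <- order(vapply(out, `[[`, numeric(1), "score"),
                 decreasing = TRUE)
    out <- out[ord]
  }
  out
}
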