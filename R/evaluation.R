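#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; two empty masks are defined to have
#' Dice 1.
#'
#' @param a,b Binary [voxel_grid()]s (or logical/0-1 arrays) of identical
#'   geometry.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (is_voxel_grid(a) && is_voxel_grid(b))
    stop_if_geometry_mismatch(a, b, "masks")
  av <- if (is_voxel_grid(a)) a$data > 0 else a > 0
  bv <- if (is_voxel_grid(b)) b$data > 0 else b > 0
  if (!identical(dim(av), dim(bv)))
    stop("masks do not share shape", call. = FALSE)
  denom <- sum(av) + sum(bv)
  if (denom == 0) return(1)
  2 * sum(av & bv) / denom
}

#' Dice restricted to ground-truth contoured slices
#'
#' Dice computed only over z slices on which the ground truth has at
#' least one voxel; slices without a contour (where no ground truth was
#' drawn) are excluded from both masks.
#'
#' @param pred,gt Binary [voxel_grid()]s; `gt` must be non-empty.
#' @return Dice coefficient on contoured slices.
#' @export
lesion_dice_contoured_slices <- function(pred, gt) {
  stop_if_geometry_mismatch(pred, gt, "masks")
  gtv <- gt$data > 0
  zs <- which(apply(gtv, 3L, any))
  if (length(zs) == 0L)
    stop("ground-truth mask is empty", call. = FALSE)
  dice(pred$data[, , zs, drop = FALSE] > 0, gtv[, , zs, drop = FALSE])
}

#' Absolute percentage error
#'
#' @param est Estimate.
#' @param truth Reference value, non-zero.
#' @return `100 * |est - truth| / truth` (%).
#' @export
abs_pct_err <- function(est, truth) {
  if (truth == 0) stop("truth must be non-zero", call. = FALSE)
  100 * abs(est - truth) / truth
}

#' Ellipsoid-formula prostate volume
#'
#' The clinical comparator: volume estimated from three orthogonal
#' diameters as \eqn{l_1 l_2 l_3 \pi / 6}.
#'
#' @param l1,l2,l3 Diameters in cm, > 0.
#' @return Volume in cm^3.
#' @export
ellipsoid_volume <- function(l1, l2, l3) {
  if (any(c(l1, l2, l3) <= 0))
    stop("lengths must be positive", call. = FALSE)
  l1 * l2 * l3 * pi / 6
}

#' Match predicted candidates to ground-truth lesions
#'
#' A candidate matches a ground-truth lesion iff their masks share at
#' least one voxel; each candidate is assigned to the single lesion of
#' greatest overlap (ties to the larger lesion). A lesion's detection
#' score is the maximum probability over its matching candidates; an
#' unmatched lesion falls back to the maximum calibrated voxel
#' probability under its contour (if a probability map is supplied), else
#' 0. Unmatched candidates are false positives.
#'
#' @param candidates List of `list(mask, score)` (e.g. from
#'   [extract_candidates()]).
#' @param gt_lesions List of `list(mask, is_cspca)`.
#' @param prob Optional calibrated probability [voxel_grid()] for the
#'   unmatched-lesion score fallback.
#' @param biopsy_negative Logical flag for the patient (used downstream
#'   for false-positive averaging).
#' @return An object of class `detection_outcome`: per-lesion `matched`,
#'   `score`, `is_cspca`; per-candidate `matched_gt` (index or `NA`);
#'   `fp_count`; `biopsy_negative`.
#' @export
match_detections <- function(candidates, gt_lesions, prob = NULL,
                             biopsy_negative = FALSE) {
  n_gt <- length(gt_lesions)
  gt_masks <- lapply(gt_lesions, function(l)
    if (is_voxel_grid(l$mask)) l$mask$data > 0 else l$mask > 0)
  gt_sizes <- vapply(gt_masks, sum, numeric(1))
  matched_gt <- rep(NA_integer_, length(candidates))
  lesion_score <- rep(0, n_gt)
  lesion_matched <- rep(FALSE, n_gt)
  for (i in seq_along(candidates)) {
    cm <- candidates[[i]]$mask
    cmv <- if (is_voxel_grid(cm)) cm$data > 0 else cm > 0
    ov <- vapply(gt_masks, function(g) sum(cmv & g), numeric(1))
    if (n_gt > 0L && any(ov > 0)) {
      best <- which(ov == max(ov))
      if (length(best) > 1L) best <- best[which.max(gt_sizes[best])]
      matched_gt[i] <- best
      lesion_matched[best] <- TRUE
      lesion_score[best] <- max(lesion_score[best], candidates[[i]]$score)
    }
  }
  if (!is.null(prob)) {
    for (j in seq_len(n_gt)) {
      if (!lesion_matched[j]) {
        under <- prob$data[gt_masks[[j]]]
        if (length(under)) lesion_score[j] <- max(under)
      }
    }
  }
  structure(
    list(lesions = data.frame(
           matched = lesion_matched,
           score = lesion_score,
           is_cspca = vapply(gt_lesions, function(l)
             isTRUE(l$is_cspca), logical(1))),
         matched_gt = matched_gt,
         fp_count = sum(is.na(matched_gt)),
         biopsy_negative = isTRUE(biopsy_negative)),
    class = "detection_outcome")
}

#' Lesion-level detection metrics over a cohort
#'
#' Sensitivity = detected CSPCa lesions (score >= cutoff) / all CSPCa
#' lesions; specificity = nCSPCa lesions with score < cutoff / all nCSPCa
#' lesions; precision = detected CSPCa / (detected CSPCa + nCSPCa scored
#' >= cutoff); mean false positives are averaged over biopsy-negative
#' patients only (ground-truth limitations prevent false-positive
#' determination in positive patients).
#'
#' @param outcomes List of `detection_outcome`s, one per patient.
#' @param cutoff Detection score cut-off.
#' @return Named list: `sensitivity_pct`, `specificity_pct`,
#'   `precision_pct`, `fp_per_negative_patient`, plus raw counts.
#' @export
detection_metrics <- function(outcomes, cutoff) {
  les <- do.call(rbind, lapply(outcomes, `[[`, "lesions"))
  if (is.null(les) || sum(les$is_cspca) == 0L || sum(!les$is_cspca) == 0L)
    stop("cohort must contain both CSPCa and nCSPCa lesions", call. = FALSE)
  pos <- les[les$is_cspca, ]; neg <- les[!les$is_cspca, ]
  tp <- sum(pos$score >= cutoff)
  fp_les <- sum(neg$score >= cutoff)
  negp <- vapply(outcomes, `[[`, logical(1), "biopsy_negative")
  fps <- vapply(outcomes[negp], `[[`, numeric(1), "fp_count")
  list(sensitivity_pct = 100 * tp / nrow(pos),
       specificity_pct = 100 * sum(neg$score < cutoff) / nrow(neg),
       precision_pct = if (tp + fp_les == 0) NA_real_
                       else 100 * tp / (tp + fp_les),
       fp_per_negative_patient = if (length(fps)) mean(fps) else NA_real_,
       n_cspca = nrow(pos), n_ncspca = nrow(neg),
       n_negative_patients = length(fps))
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Equals the probability that a random positive outranks a random
#' negative, ties counting one half; invariant under strictly monotone
#' score transforms.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC by the step integral
#'
#' Area under the precision-recall curve computed as the
#' interpolation-free sum of precision at each recall increment
#' (average-precision form).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); both classes required.
#' @return PR AUC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  n <- length(ys)
  tp <- cumsum(ys)
  prec <- tp / seq_len(n)
  # handle ties: evaluate at the last index of each distinct score
  last_of_tie <- c(ss[-n] != ss[-1], TRUE)
  npos <- sum(ys)
  auc <- 0; prev_tp <- 0
  for (i in which(last_of_tie)) {
    d_tp <- tp[i] - prev_tp
    if (d_tp > 0) auc <- auc + d_tp * prec[i]
    prev_tp <- tp[i]
  }
  auc / npos
}

#' Select a detection cut-off matching target operating points
#'
#' Among thresholds at the observed score values, chooses the one
#' minimizing the absolute sensitivity gap to the target, breaking ties
#' by the specificity gap, then by the larger threshold. Used to fix the
#' operating point on training data.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); both classes required.
#' @param target_sensitivity,target_specificity Targets in percent
#'   (defaults 93 and 37, a reference-reader operating point).
#' @return The selected cut-off value.
#' @export
select_cutoff <- function(scores, labels, target_sensitivity = 93,
                          target_specificity = 37) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) 100 * mean(scores[y == 1] >= t),
                 numeric(1))
  spec <- vapply(thr, function(t) 100 * mean(scores[y == 0] < t),
                 numeric(1))
  d_sens <- abs(sens - target_sensitivity)
  d_spec <- abs(spec - target_specificity)
  ord <- order(d_sens, d_spec, -thr)
  thr[ord[1]]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences; zero differences are dropped.
#' The exact signed-rank distribution is used for n <= 25 with untied
#' ranks, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Paired numeric vectors; at least 5 non-zero differences.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  d <- as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all paired differences are zero", call. = FALSE)
  if (length(d) < 5L)
    stop("need at least 5 non-zero differences", call. = FALSE)
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value)
}

#' McNemar's test on discordant pairs
#'
#' Exact two-sided binomial test on the discordant counts; both counts
#' zero returns p = 1 by convention.
#'
#' @param b01 Pairs where only the second rater is correct/positive.
#' @param b10 Pairs where only the first rater is correct/positive.
#' @return Two-sided exact p-value.
#' @export
mcnemar_exact <- function(b01, b10) {
  if (b01 < 0 || b10 < 0) stop("counts must be >= 0", call. = FALSE)
  n <- b01 + b10
  if (n == 0L) return(1)
  stats::binom.test(b01, n, p = 0.5)$p.value
}

#' DeLong's test for paired ROC AUCs
#'
#' Compares the ROC AUCs of two score vectors over the same labelled
#' lesions using the structural-components covariance estimator for
#' paired, correlated AUCs.
#'
#' @param scores_1,scores_2 Paired scores over identical items.
#' @param labels Binary labels (0/1); both classes required.
#' @return List: `auc_1`, `auc_2`, `p_value` (two-sided).
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  r1 <- pROC::roc(response = y, predictor = as.numeric(scores_1),
                  quiet = TRUE, direction = "<", levels = c(0, 1))
  r2 <- pROC::roc(response = y, predictor = as.numeric(scores_2),
                  quiet = TRUE, direction = "<", levels = c(0, 1))
  a1 <- as.numeric(pROC::auc(r1)); a2 <- as.numeric(pROC::auc(r2))
  if (abs(a1 - a2) < .Machine$double.eps^0.5)
    return(list(auc_1 = a1, auc_2 = a2, p_value = 1))
  tst <- tryCatch(
    pROC::roc.test(r1, r2, method = "delong", paired = TRUE),
    error = function(e)
      stop(sprintf("DeLong test failed: %s", conditionMessage(e)),
           call. = FALSE))
  p <- as.numeric(tst$p.value)
  if (!is.finite(p))
    stop("degenerate variance in DeLong test", call. = FALSE)
  list(auc_1 = a1, auc_2 = a2, p_value = p)
}

#' Weighted generalized score test for paired predictive fractions
#'
#' Compares the positive predictive fraction (precision) of two raters
#' whose calls are paired by lesion. Each positive call contributes one
#' observation (truth of the called lesion); the score statistic for the
#' rater effect is computed under the pooled null estimate of the common
#' predictive value, with a cluster-robust (per-lesion) variance so
#' lesions called by both raters are not treated as independent.
#'
#' @param truth Binary vector: true status of each lesion.
#' @param calls_1,calls_2 Binary vectors: each rater's positive calls.
#' @return List: `ppv_1`, `ppv_2`, `p_value` (two-sided, chi-square with
#'   1 df).
#' @export
wgs_precision_test <- function(truth, calls_1, calls_2) {
  truth <- as.numeric(truth)
  c1 <- as.numeric(calls_1); c2 <- as.numeric(calls_2)
  if (length(truth) != length(c1) || length(truth) != length(c2))
    stop("inputs must have equal length", call. = FALSE)
  n1 <- sum(c1); n2 <- sum(c2)
  if (n1 == 0 && n2 == 0)
    stop("no positive calls by either rater", call. = FALSE)
  ppv1 <- if (n1 > 0) sum(truth * c1) / n1 else NA_real_
  ppv2 <- if (n2 > 0) sum(truth * c2) / n2 else NA_real_
  # long form: one row per (lesion, rater) positive call
  idx1 <- which(c1 == 1); idx2 <- which(c2 == 1)
  cl <- c(idx1, idx2)                       # cluster = lesion
  xx <- c(rep(0, length(idx1)), rep(1, length(idx2)))  # rater indicator
  yy <- c(truth[idx1], truth[idx2])
  if (identical(ppv1, ppv2) &&
      isTRUE(all.equal(sort(idx1), sort(idx2))) &&
      isTRUE(all.equal(truth[idx1], truth[idx2])))
    return(list(ppv_1 = ppv1, ppv_2 = ppv2, p_value = 1))
  p0 <- mean(yy)                            # pooled null predictive value
  xbar <- mean(xx)
  u <- sum((xx - xbar) * (yy - p0))         # score for the rater effect
  # cluster-robust variance of the score
  contrib <- tapply((xx - xbar) * (yy - p0), cl, sum)
  v <- sum(contrib^2)
  if (v <= 0)
    stop("degenerate variance in weighted generalized score test",
         call. = FALSE)
  stat <- u^2 / v
  list(ppv_1 = ppv1, ppv_2 = ppv2,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Agreement between two binary call vectors
#'
#' @param calls_a,calls_b Equal-length vectors.
#' @return List: `pct` (agreement rounded to the nearest integer
#'   percent), `numerator`, `denominator`.
#' @export
concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b) || length(calls_a) == 0L)
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  num <- sum(calls_a == calls_b)
  den <- length(calls_a)
  list(pct = round(100 * num / den), numerator = num, denominator = den)
}
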