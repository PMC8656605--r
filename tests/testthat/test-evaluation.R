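test_that("Dice handles identity, disjoint and partial overlap", {
  a <- array(0L, c(10, 10, 3)); a[1:5, 1:5, 1] <- 1L
  b <- a
  expect_equal(dice(a, b), 1)
  d <- array(0L, c(10, 10, 3)); d[6:10, 6:10, 2] <- 1L
  expect_equal(dice(a, d), 0)
  # |A| = |B| = 100, overlap 50
  a2 <- array(0L, c(20, 20, 1)); a2[1:10, 1:10, 1] <- 1L
  b2 <- array(0L, c(20, 20, 1)); b2[6:15, 1:10, 1] <- 1L
  expect_equal(sum(a2), 100); expect_equal(sum(b2), 100)
  expect_equal(sum(a2 & b2), 50)
  expect_equal(dice(a2, b2), 0.5)
  expect_equal(dice(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), 1)
  g1 <- voxel_grid(a); g2 <- voxel_grid(array(0L, c(9, 10, 3)))
  expect_error(dice(g1, g2), "geometry|shape")
})

test_that("contoured-slice Dice ignores slices without ground truth", {
  gt <- array(0L, c(8, 8, 4)); gt[2:5, 2:5, 2] <- 1L
  pred <- gt
  g_gt <- voxel_grid(gt, kind = "label", label_set = 0:1)
  expect_equal(lesion_dice_contoured_slices(voxel_grid(pred,
    kind = "label", label_set = 0:1), g_gt), 1)
  # extra prediction on a non-contoured slice does not change the score
  pred2 <- gt; pred2[1:4, 1:4, 4] <- 1L
  expect_equal(lesion_dice_contoured_slices(voxel_grid(pred2,
    kind = "label", label_set = 0:1), g_gt), 1)
  # hand-built 2-slice example: slice 2 overlap 8 of (16, 8); slice 3
  # gt 4 pred 0
  gt3 <- array(0L, c(8, 8, 4)); gt3[2:5, 2:5, 2] <- 1L
  gt3[2:5, 2, 3] <- 1L
  pr3 <- array(0L, c(8, 8, 4)); pr3[2:5, 2:3, 2] <- 1L
  expected <- 2 * 8 / ((16 + 4) + 8)
  expect_equal(lesion_dice_contoured_slices(
    voxel_grid(pr3, kind = "label", label_set = 0:1),
    voxel_grid(gt3, kind = "label", label_set = 0:1)), expected)
  expect_error(lesion_dice_contoured_slices(g_gt,
    voxel_grid(array(0L, c(8, 8, 4)), kind = "label", label_set = 0:1)),
    "empty")
})

test_that("absolute percentage error and the ellipsoid formula evaluate", {
  expect_equal(abs_pct_err(50, 50), 0)
  expect_equal(abs_pct_err(45, 50), 10)
  expect_equal(abs_pct_err(100, 50), 100)
  expect_error(abs_pct_err(1, 0), "non-zero")
  expect_equal(ellipsoid_volume(4, 3, 5), 31.41593, tolerance = 1e-5)
  expect_equal(ellipsoid_volume(1, 1, 1), pi / 6)
  expect_error(ellipsoid_volume(0, 1, 1), "positive")
  # closed loop: true diameters of a phantom reproduce its analytic volume
  ph <- tiny_phantom()
  lens_cm <- 2 * ph$spec$wp_semi_axes / 10
  expect_equal(ellipsoid_volume(lens_cm[1], lens_cm[2], lens_cm[3]),
               ph$analytic$wp_volume_cm3, tolerance = 1e-9)
})

test_that("detection matching follows the any-overlap greatest-overlap rule", {
  mk_mask <- function(ix) {
    m <- array(0L, c(12, 12, 3)); m[ix] <- 1L
    voxel_grid(m, kind = "label", label_set = 0:1)
  }
  gt <- list(list(mask = mk_mask(1:20), is_cspca = TRUE),
             list(mask = mk_mask(101:140), is_cspca = FALSE))
  # candidate overlapping lesion 1 only
  out <- match_detections(list(list(mask = mk_mask(10:30), score = 0.9)),
                          gt)
  expect_true(out$lesions$matched[1])
  expect_false(out$lesions$matched[2])
  expect_equal(out$lesions$score[1], 0.9)
  expect_equal(out$fp_count, 0)
  # unmatched candidate is a false positive
  out2 <- match_detections(list(list(mask = mk_mask(300:320),
                                     score = 0.5)), gt)
  expect_equal(out2$fp_count, 1)
  expect_true(all(!out2$lesions$matched))
  # two candidates on the same lesion: detected once, no FP
  out3 <- match_detections(list(
    list(mask = mk_mask(1:10), score = 0.6),
    list(mask = mk_mask(11:20), score = 0.8)), gt)
  expect_equal(sum(out3$lesions$matched), 1)
  expect_equal(out3$fp_count, 0)
  expect_equal(out3$lesions$score[1], 0.8)  # max over matching candidates
  # candidate overlapping both lesions goes to the greater overlap
  out4 <- match_detections(list(list(mask = mk_mask(c(1:5, 101:130)),
                                     score = 0.7)), gt)
  expect_identical(out4$matched_gt, 2L)
  # unmatched lesion falls back to max probability under its contour
  prob <- voxel_grid(array(0.2, c(12, 12, 3)), kind = "probability")
  out5 <- match_detections(list(), gt, prob = prob)
  expect_equal(out5$lesions$score, c(0.2, 0.2))
})

test_that("detection metrics match brute-force counting on a toy cohort", {
  mk_out <- function(scores, cspca, fp, bneg) {
    structure(list(
      lesions = data.frame(matched = scores > 0, score = scores,
                           is_cspca = cspca),
      matched_gt = integer(0), fp_count = fp, biopsy_negative = bneg),
      class = "detection_outcome")
  }
  outs <- list(
    mk_out(c(1.0, 0.2), c(TRUE, FALSE), 2, FALSE),
    mk_out(c(0.8, 0.6, 0.1), c(TRUE, TRUE, FALSE), 1, TRUE),
    mk_out(c(0.4), c(TRUE), 3, TRUE),
    mk_out(c(0.7, 0.0), c(FALSE, FALSE), 0, TRUE))
  m <- detection_metrics(outs, cutoff = 0.5)
  # brute force: CSPCa scores {1.0, 0.8, 0.6, 0.4}; >= 0.5 -> 3/4
  expect_equal(m$sensitivity_pct, 75)
  # nCSPCa scores {0.2, 0.1, 0.7, 0.0}; < 0.5 -> 3/4
  expect_equal(m$specificity_pct, 75)
  # precision: 3 detected CSPCa, 1 nCSPCa over threshold
  expect_equal(m$precision_pct, 75)
  # FP mean over biopsy-negative patients only: (1 + 3 + 0) / 3
  expect_equal(m$fp_per_negative_patient, 4 / 3)
  # boundary cut-offs
  expect_equal(detection_metrics(outs, 0)$sensitivity_pct, 100)
  expect_equal(detection_metrics(outs, 0)$specificity_pct, 0)
  expect_equal(detection_metrics(outs, 2)$sensitivity_pct, 0)
})

test_that("perfect and degenerate score sets give the expected AUCs", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUC equals pairwise enumeration on toy sets", {
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  set.seed(17)
  for (i in 1:10) {
    y <- c(1, 1, 1, 0, 0, 0)
    s <- sample(seq(0, 1, 0.1), 6, replace = TRUE)
    expect_equal(roc_auc(s, y), pair_auc(s, y))
  }
  # invariance under strictly monotone transforms
  s <- runif(30); y <- rbinom(30, 1, 0.5); if (sum(y) %in% c(0, 30)) y[1] <- 1 - y[1]
  expect_equal(roc_auc(exp(3 * s) + 2, y), roc_auc(s, y))
})

test_that("PR AUC matches a step-integral oracle and is 1 for separation", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # average-precision oracle by direct summation
  ap_oracle <- function(s, y) {
    ord <- order(-s); y <- y[ord]
    tp <- cumsum(y); prec <- tp / seq_along(y)
    sum(prec * y) / sum(y)
  }
  set.seed(19)
  s <- runif(40); y <- rbinom(40, 1, 0.4)
  if (sum(y) %in% c(0, 40)) y[1] <- 1 - y[1]
  expect_equal(pr_auc(s, y), ap_oracle(s, y), tolerance = 1e-12)
})

test_that("cut-off selection recovers target operating points", {
  # a threshold hitting the targets exactly is returned
  s <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  # at t = 0.4: sens = 100, spec = 75
  expect_equal(select_cutoff(s, y, 100, 75), 0.4)
  # monotone scores: requested sensitivity reproduced within 1/n_pos
  set.seed(23)
  s2 <- runif(200); y2 <- as.numeric(s2 + rnorm(200, 0, 0.1) > 0.5)
  if (length(unique(y2)) < 2) y2[1] <- 1 - y2[1]
  cut <- select_cutoff(s2, y2, 93, 37)
  sens <- 100 * mean(s2[y2 == 1] >= cut)
  expect_lt(abs(sens - 93), 100 / sum(y2 == 1) + 1e-9)
  expect_error(select_cutoff(1:5, rep(1, 5)), "both classes")
})

test_that("exact Wilcoxon matches exhaustive sign-assignment enumeration", {
  a <- c(3.1, 4.7, 1.2, 6.6, 2.4, 5.9)
  b <- c(2.0, 5.1, 0.4, 4.1, 3.9, 4.2)
  d <- a - b
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  # enumerate all 2^6 sign assignments of the ranked differences
  n <- length(d)
  ws <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(r[signs == 1])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(wilcoxon_signed_rank(a, b), p_exact, tolerance = 1e-12)
})

test_that("Wilcoxon is symmetric and detects a constant shift", {
  set.seed(29)
  a <- rnorm(20); b <- a + 1
  p <- wilcoxon_signed_rank(a, b)
  expect_lt(p, 0.001)
  expect_equal(wilcoxon_signed_rank(b, a), p)
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4), c(2, 3, 4, 5)),
               "at least 5")
})

test_that("exact McNemar equals the binomial tail sum", {
  expect_equal(mcnemar_exact(5, 5), 1)
  expect_equal(mcnemar_exact(0, 0), 1)
  # 2 * P(X <= 2 | n = 12, p = 0.5)
  expected <- 2 * sum(choose(12, 0:2)) / 2^12
  expect_equal(mcnemar_exact(10, 2), expected, tolerance = 1e-12)
  expect_equal(mcnemar_exact(2, 10), expected, tolerance = 1e-12)
  # enumeration oracle for all discordant splits up to n = 12
  for (n in c(5, 9, 12)) {
    for (b01 in 0:n) {
      p_enum <- sum(vapply(0:n, function(k)
        if (abs(k - n / 2) >= abs(b01 - n / 2) - 1e-12)
          choose(n, k) / 2^n else 0, numeric(1)))
      expect_equal(mcnemar_exact(b01, n - b01), min(1, p_enum),
                   tolerance = 1e-10)
    }
  }
})

test_that("DeLong's test is rank-invariant and null for identical scores", {
  set.seed(31)
  y <- rbinom(60, 1, 0.5); if (sum(y) %in% c(0, 60)) y[1] <- 1 - y[1]
  s <- runif(60)
  same <- delong_test(s, s, y)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_1, same$auc_2)
  mono <- delong_test(s, exp(2 * s) - 0.5, y)
  expect_equal(mono$auc_1, mono$auc_2)
  expect_equal(mono$p_value, 1)
})

test_that("DeLong p agrees with a stratified bootstrap oracle", {
  set.seed(37)
  n <- 50
  y <- rep(c(1, 0), each = n / 2)
  base <- y + rnorm(n, 0, 1.2)
  s1 <- base + rnorm(n, 0, 0.6)
  s2 <- 0.85 * base + rnorm(n, 0, 0.8)
  dl <- delong_test(s1, s2, y)
  # stratified bootstrap of the AUC difference, 10,000 resamples
  B <- 10000
  ipos <- which(y == 1); ineg <- which(y == 0)
  diffs <- vapply(seq_len(B), function(b) {
    ii <- c(sample(ipos, length(ipos), TRUE),
            sample(ineg, length(ineg), TRUE))
    roc_auc(s1[ii], y[ii]) - roc_auc(s2[ii], y[ii])
  }, numeric(1))
  p_boot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p_boot <- min(1, p_boot)
  expect_lt(abs(dl$p_value - p_boot), 0.02)
})

test_that("the WGS precision test is null for identical raters", {
  truth <- c(1, 1, 0, 0, 1, 0, 1, 0)
  calls <- c(1, 1, 1, 0, 0, 0, 1, 1)
  res <- wgs_precision_test(truth, calls, calls)
  expect_equal(res$p_value, 1)
  expect_equal(res$ppv_1, res$ppv_2)
  expect_error(wgs_precision_test(truth, rep(0, 8), rep(0, 8)),
               "no positive calls")
})

test_that("the WGS test has power against a strictly better rater", {
  set.seed(41)
  rej <- 0; nrep <- 200
  for (i in seq_len(nrep)) {
    n <- 200
    truth <- rbinom(n, 1, 0.5)
    # rater 1 calls indiscriminately; rater 2 prefers true lesions
    c1 <- rbinom(n, 1, 0.5)
    c2 <- rbinom(n, 1, ifelse(truth == 1, 0.7, 0.2))
    p <- try(wgs_precision_test(truth, c1, c2)$p_value, silent = TRUE)
    if (!inherits(p, "try-error") && p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nrep, 0.8)
})

test_that("concordance reports rounded percent agreement with counts", {
  a <- c(rep(1, 114), rep(0, 33))
  b <- c(rep(1, 114), rep(1, 33))
  r <- concordance(a, b)
  expect_equal(r$pct, 78)
  expect_equal(r$numerator, 114)
  expect_equal(r$denominator, 147)
  r2 <- concordance(c(rep(1, 39), rep(0, 24)), rep(1, 63))
  expect_equal(r2$pct, 62)
  expect_equal(concordance(1:5, 1:5)$pct, 100)
  expect_error(concordance(1:3, 1:4), "equal length")
})
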