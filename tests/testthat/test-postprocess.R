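make_prob <- function(arr, spacing = c(1, 1, 1)) {
  voxel_grid(arr, spacing, kind = "probability")
}

test_that("argmax labels each voxel with the winning class", {
  mk <- function(v) make_prob(array(v, c(1, 1, 1)))
  lab <- zones_argmax(list(background = mk(0.1), pz = mk(0.7), cg = mk(0.2)))
  expect_identical(as.integer(lab$data), 1L)
  # exact tie background/PZ resolves to PZ (documented priority)
  lab2 <- zones_argmax(list(background = mk(0.5), pz = mk(0.5), cg = mk(0)))
  expect_identical(as.integer(lab2$data), 1L)
  # tie PZ/CG resolves to CG
  lab3 <- zones_argmax(list(background = mk(0), pz = mk(0.5), cg = mk(0.5)))
  expect_identical(as.integer(lab3$data), 2L)
})

test_that("argmax on one-hot channels recovers the label map", {
  ph <- tiny_phantom()
  ch <- zone_channels_from_labels(ph$zones_gt)
  expect_identical(zones_argmax(ch)$data, ph$zones_gt$data)
})

test_that("PAV isotonic fit matches the hand-worked and brute-force solutions", {
  cal <- fit_calibrator(c(0.1, 0.2, 0.3), c(1, 0, 1))
  expect_equal(cal$values, c(0.5, 0.5, 1.0))

  # brute-force oracle: minimize SSE over monotone step fits on a grid
  brute_isotonic <- function(x, y) {
    vals <- seq(0, 1, by = 0.05)
    n <- length(y)
    grids <- do.call(expand.grid, rep(list(vals), n))
    mono <- apply(grids, 1, function(v) all(diff(v) >= -1e-12))
    g <- as.matrix(grids[mono, , drop = FALSE])
    sse <- colSums((t(g) - y)^2)
    g[which.min(sse), ]
  }
  set.seed(21)
  for (i in 1:3) {
    x <- sort(runif(4)); y <- sample(0:1, 4, replace = TRUE)
    if (length(unique(y)) < 2) y <- c(1, 0, 1, 0)
    cal_i <- fit_calibrator(x, y)
    bf <- brute_isotonic(x, y)
    expect_equal(unname(cal_i$values), unname(as.numeric(bf)),
                 tolerance = 0.051)
  }
})

test_that("PAV agrees with stats::isoreg on untied scores", {
  set.seed(33)
  x <- sort(runif(40)); y <- rbinom(40, 1, x)
  if (length(unique(y)) < 2) y[1] <- 0
  cal <- fit_calibrator(x, y)
  ref <- stats::isoreg(x, y)
  expect_equal(cal$values, ref$yf, tolerance = 1e-12)
})

test_that("perfect separation calibrates to 0 then 1; degenerate labels fail", {
  cal <- fit_calibrator(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(cal$values, c(0, 0, 1, 1))
  expect_error(fit_calibrator(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("applying a calibrator is monotone and preserves AUC", {
  set.seed(9)
  x <- runif(200); y <- rbinom(200, 1, x^2)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  cal <- fit_calibrator(x, y)
  xc <- apply_calibrator(cal, x)
  expect_true(all(xc >= 0 & xc <= 1))
  # no rank inversions among distinct raw values
  ord <- order(x)
  expect_true(all(diff(xc[ord]) >= -1e-12))
  # when the fitted rates increase strictly (no pooled blocks among the
  # evaluated scores) the calibrated map is strictly monotone there and
  # the ROC AUC is exactly invariant
  xs <- rep(seq(0.1, 0.9, by = 0.1), each = 10)
  rates <- seq(0.05, 0.95, length.out = 9)
  ys <- unlist(lapply(rates, function(r) c(rep(1, round(10 * r)),
                                           rep(0, 10 - round(10 * r)))))
  cal_s <- fit_calibrator(xs, ys)
  expect_true(all(diff(cal_s$values) > 0))
  expect_equal(roc_auc(apply_calibrator(cal_s, xs), ys),
               roc_auc(xs, ys), tolerance = 1e-12)

  # identity calibrator leaves a map unchanged
  idc <- structure(list(breakpoints = c(0, 1), values = c(0, 1)),
                   class = "calibrator")
  g <- random_prob_grid(c(6, 6, 2), seed = 10)
  expect_equal(apply_calibrator(idc, g)$data, g$data, tolerance = 1e-12)
})

test_that("candidate extraction applies threshold, size and connectivity rules", {
  cfg <- postprocess_config(cutoff_C = 0.045, min_size_mm3 = 40)
  arr <- array(0, c(30, 30, 8))
  # blob A: 4x4x4 = 64 voxels = 64 mm^3 at prob 0.9 -> kept
  arr[3:6, 3:6, 2:5] <- 0.9
  # blob B: 13 voxels = 13 mm^3 at prob 0.8 -> removed (smaller than 40)
  arr[20:22, 20:22, 2][1:9] <- 0.8
  arr[20:22, 20:21, 3][1:4] <- 0.8
  # blob C: peak 0.03 below the cut-off -> never foreground
  arr[12:15, 12:15, 6:7] <- 0.03
  g <- make_prob(arr)
  cands <- extract_candidates(g, cfg)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$score, 0.9)
  expect_equal(cands[[1]]$volume_mm3, 64)

  # a component of exactly min_size is kept (strict "smaller than")
  arr2 <- array(0, c(20, 20, 5))
  arr2[3:6, 3:6, 2] <- 1  # 16 voxels
  g2 <- make_prob(arr2, spacing = c(1, 1, 2.5))  # 16 * 2.5 = 40 mm^3
  expect_length(extract_candidates(g2, cfg), 1)
  # one voxel less -> strictly smaller -> removed
  arr2[3, 3, 2] <- 0
  g3 <- make_prob(arr2, spacing = c(1, 1, 2.5))
  expect_length(extract_candidates(g3, cfg), 0)

  # a voxel exactly at the cut-off is positive
  arr4 <- array(0, c(10, 10, 3)); arr4[2:5, 2:5, 1:3] <- 0.045
  expect_length(extract_candidates(make_prob(arr4), cfg), 1)
})

test_that("diagonal blobs merge under 26- but not 6-connectivity", {
  arr <- array(0, c(12, 12, 4))
  arr[2:5, 2:5, 2] <- 1
  arr[6:9, 6:9, 3] <- 1  # touches only diagonally (corner + z step)
  g <- make_prob(arr)
  c26 <- extract_candidates(g, postprocess_config(min_size_mm3 = 0,
                                                  connectivity = 26))
  c6 <- extract_candidates(g, postprocess_config(min_size_mm3 = 0,
                                                 connectivity = 6))
  expect_length(c26, 1)
  expect_length(c6, 2)
})

test_that("candidate counts are monotone in cut-off and minimum size", {
  set.seed(14)
  arr <- array(0, c(24, 24, 8))
  for (i in 1:6) {
    x <- sample(2:20, 1); y <- sample(2:20, 1); z <- sample(2:6, 1)
    w <- sample(1:3, 1)
    arr[x:(x + w), y:(y + w), z:(z + 1)] <- runif(1, 0.05, 1)
  }
  g <- make_prob(arr)
  counts_c <- vapply(c(0.01, 0.1, 0.3, 0.6, 0.9), function(cc)
    length(extract_candidates(g, postprocess_config(cutoff_C = cc,
                                                    min_size_mm3 = 0))),
    numeric(1))
  expect_true(all(diff(counts_c) <= 0))
  counts_s <- vapply(c(0, 4, 8, 16, 40), function(ms)
    length(extract_candidates(g, postprocess_config(cutoff_C = 0.045,
                                                    min_size_mm3 = ms))),
    numeric(1))
  expect_true(all(diff(counts_s) <= 0))
})

test_that("an indicator map of ground-truth lesions reproduces its components", {
  ph <- generate_phantom(phantom_spec(
    grid_shape = c(48L, 48L, 20L), spacing = c(1, 1, 2.4),
    wp_semi_axes = c(18, 14, 18), cg_semi_axes = c(11, 8, 11),
    lesions = list(
      list(center = c(13, 0, 2), semi_axes = c(4, 4, 4), adc = 0.8e-3,
           is_cspca = TRUE),
      list(center = c(-13, 0, -2), semi_axes = c(3.5, 3.5, 4),
           adc = 0.9e-3, is_cspca = FALSE)),
    psa = 10, seed = 2))
  ind <- array(0, dim(ph$t2$data))
  for (les in ph$lesions_gt) ind[les$mask$data > 0] <- 1
  g <- voxel_grid(ind, ph$t2$spacing, kind = "probability")
  cands <- extract_candidates(g, postprocess_config(min_size_mm3 = 0))
  expect_length(cands, length(ph$lesions_gt))
  total_gt <- sum(ind)
  expect_equal(sum(vapply(cands, `[[`, numeric(1), "n_voxels")), total_gt)
  for (cd in cands) {
    matches <- vapply(ph$lesions_gt, function(l)
      identical(cd$mask$data > 0, l$mask$data > 0), logical(1))
    expect_true(any(matches))
  }
})

test_that("postprocess config validates its parameters", {
  expect_error(postprocess_config(cutoff_C = 0), "cutoff_C")
  expect_error(postprocess_config(min_size_mm3 = -1), "min_size")
  expect_error(postprocess_config(connectivity = 4), "connectivity")
})
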