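#' Fit the monoexponential DWI signal model to one voxel
#'
#' Fits \eqn{s(b) = s_0 \exp(-b \cdot ADC)} to observed signals by
#' non-linear least squares, minimizing \eqn{\sum_i (s_i - s_0 e^{-b_i
#' \cdot ADC})^2} subject to \eqn{s_0 \ge 0}, \eqn{ADC \ge 0}. The solver is
#' Gauss-Newton with step halving, initialized from the ordinary
#' least-squares fit of \eqn{\log s} against \eqn{b} (zero signals
#' excluded). If the iteration fails to converge the log-linear estimates
#' are returned with `converged = FALSE`.
#'
#' @param b_values Numeric vector of b-values (s/mm^2), at least two
#'   distinct.
#' @param signals Non-negative signal intensities, same length.
#' @param floor Signals all at or below this value short-circuit to
#'   `s0 = 0, adc = 0` (avoids NaNs in air).
#' @return A list of class `monoexp_fit` with `s0_est`, `adc_est` (mm^2/s),
#'   `residual_norm` (sum of squared residuals), `converged`.
#' @export
fit_monoexp <- function(b_values, signals, floor = 1e-6) {
  b <- as.numeric(b_values); s <- as.numeric(signals)
  if (length(b) != length(s))
    stop("b_values and signals must have equal length", call. = FALSE)
  if (length(unique(b)) < 2L)
    stop("need at least two distinct b-values", call. = FALSE)
  if (any(s < 0)) stop("signals must be non-negative", call. = FALSE)
  fit <- fit_monoexp_matrix(b, matrix(s, nrow = 1), floor = floor)
  structure(list(s0_est = fit$s0[1], adc_est = fit$adc[1],
                 residual_norm = fit$rss[1], converged = fit$converged[1]),
            class = "monoexp_fit")
}

# Vectorized NLS over many voxels at once: rows of S are voxels, columns
# b-values. Log-linear OLS init (zeros excluded per voxel via weighting),
# then Gauss-Newton with step halving on the 2-parameter model, all in
# closed-form 2x2 solves.
fit_monoexp_matrix <- function(b, S, floor = 1e-6, max_iter = 50L,
                               tol = 1e-14) {
  n <- nrow(S); m <- length(b)
  dead <- apply(S <= floor, 1L, all)
  # log-linear init: regress log s on b using only positive signals
  logS <- log(pmax(S, .Machine$double.xmin))
  W <- (S > floor) * 1
  nW <- pmax(rowSums(W), 1)
  bm <- as.numeric(W %*% b) / nW
  lm_ <- rowSums(W * logS) / nW
  sxx <- as.numeric(W %*% (b^2)) - nW * bm^2
  sxy <- rowSums(W * logS * rep(b, each = n)) - nW * bm * lm_
  slope <- ifelse(sxx > 0, sxy / sxx, 0)
  adc <- pmax(-slope, 0)
  s0 <- as.numeric(exp(lm_ - slope * bm))
  s0[dead] <- 0; adc[dead] <- 0

  rss_of <- function(Ssub, s0, adc) {
    P <- exp(-outer(adc, b))           # n x m
    rowSums((Ssub - s0 * P)^2)
  }
  rss <- rss_of(S, s0, adc)
  converged <- rep(FALSE, n); converged[dead] <- TRUE
  active <- !dead
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    ia <- which(active)
    P <- exp(-outer(adc[ia], b))                    # model / ds0
    Fv <- s0[ia] * P
    R <- S[ia, , drop = FALSE] - Fv                 # residuals
    J2 <- -Fv * rep(b, each = length(ia))           # d model / d adc
    # normal equations: [a11 a12; a12 a22] [d1; d2] = [g1; g2]
    a11 <- rowSums(P * P)
    a12 <- rowSums(P * J2)
    a22 <- rowSums(J2 * J2)
    g1 <- rowSums(P * R)
    g2 <- rowSums(J2 * R)
    det <- a11 * a22 - a12^2
    sing <- det <= .Machine$double.eps * (a11 * a22 + 1)
    d1 <- ifelse(sing, g1 / pmax(a11, .Machine$double.eps), # s0-only step
                 (a22 * g1 - a12 * g2) / det)
    d2 <- ifelse(sing, 0, (a11 * g2 - a12 * g1) / det)
    # step halving with projection onto s0 >= 0, adc >= 0
    step <- rep(1, length(ia))
    s0n <- s0[ia]; adcn <- adc[ia]; rssn <- rss[ia]
    improved <- rep(FALSE, length(ia))
    Sa <- S[ia, , drop = FALSE]
    for (h in 1:20) {
      cand_s0 <- pmax(s0[ia] + step * d1, 0)
      cand_adc <- pmax(adc[ia] + step * d2, 0)
      cand_rss <- rss_of(Sa, cand_s0, cand_adc)
      better <- !improved & (cand_rss <= rss[ia] + 1e-30)
      s0n[better] <- cand_s0[better]
      adcn[better] <- cand_adc[better]
      rssn[better] <- cand_rss[better]
      improved <- improved | better
      if (all(improved)) break
      step <- ifelse(improved, step, step / 2)
    }
    delta <- abs(rss[ia] - rssn)
    s0[ia] <- s0n; adc[ia] <- adcn; rss[ia] <- rssn
    settled <- delta <= tol * (rssn + tol)
    stuck <- !improved & !settled
    converged[ia[settled]] <- TRUE
    active[ia[settled | stuck]] <- FALSE
  }
  # flat-signal limit: constant positive signals => adc 0, s0 mean
  list(s0 = as.numeric(s0), adc = as.numeric(adc), rss = as.numeric(rss),
       converged = converged)
}

#' Extrapolate a computed high b-value signal from a fit
#'
#' Evaluates \eqn{s(b_c) = s_0^* \exp(-b_c \cdot ADC^*)} at the requested
#' high b-value.
#'
#' @param fit A `monoexp_fit` from [fit_monoexp()].
#' @param bc High b-value (s/mm^2), >= 0.
#' @return Extrapolated signal intensity.
#' @export
compute_high_b <- function(fit, bc) {
  stopifnot(inherits(fit, "monoexp_fit"))
  if (!is.numeric(bc) || bc < 0) stop("bc must be >= 0", call. = FALSE)
  fit$s0_est * exp(-bc * fit$adc_est)
}

#' Compute a high b-value DWI volume from a multi-b stack
#'
#' Fits the monoexponential model voxelwise across the acquired b-values
#' and extrapolates each voxel to `bc`. The default computed b-value is
#' 2000 s/mm^2.
#'
#' @param dwi Named list of [voxel_grid()]s, names are b-values; all grids
#'   must share geometry.
#' @param bc High b-value to extrapolate (default 2000).
#' @param return_fit If `TRUE`, also return voxelwise `s0` and `adc` grids.
#' @return A [voxel_grid()] of extrapolated signal (or a list with
#'   `highb`, `s0`, `adc` when `return_fit = TRUE`).
#' @export
compute_high_b_volume <- function(dwi, bc = 2000, return_fit = FALSE) {
  if (length(dwi) < 2L) stop("need >= 2 b-value volumes", call. = FALSE)
  b <- as.numeric(names(dwi))
  if (any(is.na(b))) stop("dwi list names must be numeric b-values",
                          call. = FALSE)
  ref <- dwi[[1]]
  for (g in dwi) stop_if_geometry_mismatch(ref, g, "DWI volumes")
  gs <- dim(ref$data)
  S <- vapply(dwi, function(g) as.numeric(g$data), numeric(prod(gs)))
  fit <- fit_monoexp_matrix(b, S)
  highb <- array(fit$s0 * exp(-bc * fit$adc), gs)
  out <- voxel_grid(highb, ref$spacing, ref$origin)
  if (!return_fit) return(out)
  list(highb = out,
       s0 = voxel_grid(array(fit$s0, gs), ref$spacing, ref$origin),
       adc = voxel_grid(array(fit$adc, gs), ref$spacing, ref$origin))
}

#' Compute a high b-value volume from a supplied ADC map
#'
#' Alternative pathway for datasets that ship a scanner-derived ADC map:
#' \eqn{s(b_c) = s(b_{low}) \exp(-(b_c - b_{low}) \cdot ADC)} using the
#' lowest-b acquired image.
#'
#' @param dwi_low [voxel_grid()] acquired at `b_low`.
#' @param b_low Its b-value (s/mm^2).
#' @param adc ADC map [voxel_grid()] (mm^2/s), same geometry.
#' @param bc High b-value to extrapolate.
#' @return A [voxel_grid()].
#' @export
compute_high_b_from_adc <- function(dwi_low, b_low, adc, bc = 2000) {
  stop_if_geometry_mismatch(dwi_low, adc, "DWI and ADC volumes")
  if (bc < b_low) stop("bc must be >= b_low", call. = FALSE)
  with_data(dwi_low, dwi_low$data * exp(-(bc - b_low) * adc$data))
}
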