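#' Preprocessing configuration
#'
#' Defaults follow the standard experimental settings of the pipeline: a
#' common in-plane resolution of 0.4018 mm, a 320 x 320 in-plane shape for
#' the zone-segmentation pathway and 256 x 256, centred on the prostate,
#' for the lesion pathway.
#'
#' @param target_spacing In-plane target spacing (mm).
#' @param zone_crop_shape,lesion_crop_shape Integer length-2 in-plane
#'   shapes.
#' @param crop_center_mode `"image-center"` or `"prostate-center"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = 0.4018,
                              zone_crop_shape = c(320L, 320L),
                              lesion_crop_shape = c(256L, 256L),
                              crop_center_mode = "prostate-center") {
  if (target_spacing <= 0) stop("target_spacing must be > 0", call. = FALSE)
  if (any(zone_crop_shape <= 0) || any(lesion_crop_shape <= 0))
    stop("crop shapes must be positive", call. = FALSE)
  crop_center_mode <- match.arg(crop_center_mode,
                                c("prostate-center", "image-center"))
  structure(list(target_spacing = target_spacing,
                 zone_crop_shape = as.integer(zone_crop_shape),
                 lesion_crop_shape = as.integer(lesion_crop_shape),
                 crop_center_mode = crop_center_mode),
            class = "preprocess_config")
}

#' Resample a volume to a target in-plane resolution
#'
#' Resamples each axial (x-y) slice to the target spacing; z spacing is
#' unchanged. Intensity and probability grids use bilinear interpolation,
#' label grids nearest-neighbour (so the label set is preserved). If the
#' grid is already at the target spacing it is returned bit-identically.
#'
#' @param grid A [voxel_grid()].
#' @param target Target in-plane spacing (mm).
#' @return `list(grid, record)` where `record` is the geometry record
#'   needed by [restore_geometry()].
#' @export
resample_inplane <- function(grid, target) {
  stopifnot(is_voxel_grid(grid))
  if (!is.numeric(target) || target <= 0)
    stop("target spacing must be > 0", call. = FALSE)
  gs <- dim(grid$data)
  rec <- geometry_record("resample", gs, grid$spacing,
                         resample_factor = c(grid$spacing[1] / target,
                                             grid$spacing[2] / target, 1))
  if (abs(grid$spacing[1] - target) < 1e-12 &&
      abs(grid$spacing[2] - target) < 1e-12)
    return(list(grid = grid, record = rec))
  new_xy <- pmax(round(gs[1:2] * grid$spacing[1:2] / target), 1L)
  filt <- if (grid$kind == "label") "none" else "bilinear"
  out <- array(0, c(new_xy, gs[3]))
  for (z in seq_len(gs[3]))
    out[, , z] <- EBImage::resize(grid$data[, , z], w = new_xy[1],
                                  h = new_xy[2], filter = filt)
  if (grid$kind == "label") storage.mode(out) <- "integer"
  g2 <- voxel_grid(out, c(target, target, grid$spacing[3]), grid$origin,
                   kind = grid$kind, label_set = grid$label_set)
  list(grid = g2, record = rec)
}

#' Crop or pad a volume in-plane around a centre
#'
#' Produces the requested in-plane shape; regions outside the source are
#' zero-padded. The geometry record stores the offsets needed to restore
#' the original shape exactly.
#'
#' @param grid A [voxel_grid()].
#' @param shape Integer length-2 target in-plane shape.
#' @param center In-plane voxel coordinates (1-based) of the crop centre;
#'   default is the image centre.
#' @return `list(grid, record)`.
#' @export
crop_or_pad_inplane <- function(grid, shape, center = NULL) {
  stopifnot(is_voxel_grid(grid))
  shape <- as.integer(shape)
  if (any(shape <= 0)) stop("crop shape must be positive", call. = FALSE)
  gs <- dim(grid$data)
  if (is.null(center)) center <- gs[1:2] %/% 2L + 1L
  center <- floor(center + 0.5)   # half-up, so a full-shape crop is identity
  # first source index included along each in-plane axis (may be < 1)
  start <- center - shape %/% 2L
  out <- array(0, c(shape, gs[3]))
  src_lo <- pmax(start, 1L)
  src_hi <- pmin(start + shape - 1L, gs[1:2])
  dst_lo <- src_lo - start + 1L
  dst_hi <- dst_lo + (src_hi - src_lo)
  if (all(src_hi >= src_lo))
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], ] <-
      grid$data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], ]
  if (grid$kind == "label") storage.mode(out) <- "integer"
  new_origin <- grid$origin +
    c((start - 1L) * grid$spacing[1:2], 0)
  g2 <- voxel_grid(out, grid$spacing, new_origin, kind = grid$kind,
                   label_set = grid$label_set)
  rec <- geometry_record("crop", gs, grid$spacing,
                         crop_offsets = c(start - 1L, 0L))
  list(grid = g2, record = rec)
}

#' Undo a preprocessing geometry operation
#'
#' Applies the inverse of the operation described by a geometry record,
#' recovering the original shape exactly. Inverting a resample uses the
#' same interpolation rules as the forward operation (interior intensities
#' are recovered within interpolation tolerance; shape and spacing
#' exactly).
#'
#' @param grid The transformed [voxel_grid()].
#' @param record The geometry record returned by the forward operation.
#' @return A [voxel_grid()] with the original shape.
#' @export
restore_geometry <- function(grid, record) {
  stopifnot(is_voxel_grid(grid), inherits(record, "geometry_record"))
  gs <- dim(grid$data)
  orig <- record$original_shape
  if (record$op == "crop") {
    off <- record$crop_offsets
    out <- array(0, orig)
    src_lo <- pmax(1L - off[1:2], 1L)
    src_hi <- pmin(orig[1:2] - off[1:2], gs[1:2])
    dst_lo <- src_lo + off[1:2]
    dst_hi <- src_hi + off[1:2]
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], ] <-
      grid$data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], ]
    if (grid$kind == "label") storage.mode(out) <- "integer"
    return(voxel_grid(out, grid$spacing,
                      grid$origin - c(off[1:2] * grid$spacing[1:2], 0),
                      kind = grid$kind, label_set = grid$label_set))
  }
  if (record$op == "resample") {
    if (all(abs(record$resample_factor - 1) < 1e-12) &&
        identical(gs, orig))
      return(grid)
    filt <- if (grid$kind == "label") "none" else "bilinear"
    out <- array(0, orig)
    for (z in seq_len(gs[3]))
      out[, , z] <- EBImage::resize(grid$data[, , z], w = orig[1],
                                    h = orig[2], filter = filt)
    if (grid$kind == "label") storage.mode(out) <- "integer"
    return(voxel_grid(out, record$original_spacing, grid$origin,
                      kind = grid$kind, label_set = grid$label_set))
  }
  stop(sprintf("unknown geometry record op '%s'", record$op), call. = FALSE)
}

#' Whiten voxel intensities
#'
#' Standardizes a volume to zero mean and unit standard deviation (sample
#' SD), computed over the whole volume.
#'
#' @param grid A [voxel_grid()].
#' @return A whitened [voxel_grid()].
#' @export
whiten <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  if (length(grid$data) < 2L)
    stop("whitening needs more than one voxel", call. = FALSE)
  s <- stats::sd(grid$data)
  if (!is.finite(s) || s == 0)
    stop("cannot whiten a zero-variance volume", call. = FALSE)
  with_data(grid, (grid$data - mean(grid$data)) / s, kind = "intensity")
}

#' Interquartile mean
#'
#' Mean of the values lying inclusively between the first and third
#' quartiles; quartiles are computed by linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param values Numeric vector, length >= 4.
#' @return The interquartile mean.
#' @export
interquartile_mean <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("interquartile mean needs >= 4 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  mean(values[values >= q[1] & values <= q[2]])
}

#' Normalize a volume by the central-gland interquartile mean
#'
#' Divides every voxel by the interquartile mean of the intensities under
#' the CG mask, making T2WI and computed high b-value intensities
#' comparable across patients. ADC maps must not pass through this
#' operation: they carry a quantitative measurement.
#'
#' @param grid A [voxel_grid()] (intensity).
#' @param cg_mask Binary [voxel_grid()] of the central gland, same
#'   geometry.
#' @return The normalized [voxel_grid()].
#' @export
normalize_by_cg <- function(grid, cg_mask) {
  stop_if_geometry_mismatch(grid, cg_mask, "grid and CG mask")
  vals <- grid$data[cg_mask$data > 0]
  if (length(vals) < 4L)
    stop("CG mask too small for interquartile mean", call. = FALSE)
  iqm <- interquartile_mean(vals)
  if (!is.finite(iqm) || iqm <= 0)
    stop("CG interquartile mean is not positive", call. = FALSE)
  with_data(grid, grid$data / iqm, kind = "intensity")
}

#' Identity registration provider
#'
#' Registration provider that assumes inputs are already co-registered; it
#' only resamples the moving image onto the fixed grid when geometries
#' differ (trilinear interpolation on physical coordinates).
#'
#' @return A provider function for [align_to_reference()].
#' @export
identity_provider <- function() {
  function(moving, fixed) list(kind = "identity")
}

#' Translation registration provider
#'
#' Provider returning a fixed physical translation (mm), mainly useful for
#' testing the resampling machinery.
#'
#' @param shift_mm Numeric length-3 translation applied to the moving
#'   image's physical coordinates.
#' @return A provider function.
#' @export
translation_provider <- function(shift_mm) {
  force(shift_mm)
  function(moving, fixed) list(kind = "translation",
                               shift = as.numeric(shift_mm))
}

#' Align a moving volume to a reference grid
#'
#' Resamples `moving` onto `fixed`'s voxel grid using the transform
#' returned by the provider. The default identity provider treats inputs
#' as co-registered. Full affine/non-rigid registration is delegated to
#' external tooling via custom providers.
#'
#' @param moving,fixed [voxel_grid()]s.
#' @param provider A provider function `(moving, fixed) -> transform`;
#'   default [identity_provider()].
#' @return `moving` resampled onto `fixed`'s grid.
#' @export
align_to_reference <- function(moving, fixed, provider = identity_provider()) {
  stopifnot(is_voxel_grid(moving), is_voxel_grid(fixed))
  tr <- tryCatch(provider(moving, fixed), error = function(e)
    stop(sprintf("registration provider failed: %s", conditionMessage(e)),
         call. = FALSE))
  shift <- if (identical(tr$kind, "translation")) tr$shift else c(0, 0, 0)
  if (identical(tr$kind, "identity") && same_geometry(moving, fixed))
    return(moving)
  resample_to_grid(moving, fixed, shift = shift)
}

# Trilinear (or nearest for labels) resampling of `moving` onto the voxel
# grid of `fixed`, with an optional physical shift applied to the moving
# image (a voxel of `fixed` at physical p samples `moving` at p - shift).
resample_to_grid <- function(moving, fixed, shift = c(0, 0, 0)) {
  gs_f <- dim(fixed$data)
  # continuous (1-based) moving-volume indices of each fixed voxel centre
  ix <- (fixed$origin[1] + (seq_len(gs_f[1]) - 1) * fixed$spacing[1] -
           shift[1] - moving$origin[1]) / moving$spacing[1] + 1
  iy <- (fixed$origin[2] + (seq_len(gs_f[2]) - 1) * fixed$spacing[2] -
           shift[2] - moving$origin[2]) / moving$spacing[2] + 1
  iz <- (fixed$origin[3] + (seq_len(gs_f[3]) - 1) * fixed$spacing[3] -
           shift[3] - moving$origin[3]) / moving$spacing[3] + 1
  gs_m <- dim(moving$data)
  nearest <- moving$kind == "label"
  IX <- array(rep(ix, times = gs_f[2] * gs_f[3]), gs_f)
  IY <- array(rep(rep(iy, each = gs_f[1]), times = gs_f[3]), gs_f)
  IZ <- array(rep(iz, each = gs_f[1] * gs_f[2]), gs_f)
  if (nearest) {
    X <- round(IX); Y <- round(IY); Z <- round(IZ)
    ok <- X >= 1 & X <= gs_m[1] & Y >= 1 & Y <= gs_m[2] &
      Z >= 1 & Z <= gs_m[3]
    out <- array(0L, gs_f)
    out[ok] <- moving$data[cbind(X[ok], Y[ok], Z[ok])]
  } else {
    X0 <- floor(IX); Y0 <- floor(IY); Z0 <- floor(IZ)
    fx <- IX - X0; fy <- IY - Y0; fz <- IZ - Z0
    out <- array(0, gs_f)
    ok <- X0 >= 1 & X0 + 1 <= gs_m[1] & Y0 >= 1 & Y0 + 1 <= gs_m[2] &
      Z0 >= 1 & Z0 + 1 <= gs_m[3]
    # clamp exact upper boundary
    hi <- IX == gs_m[1] | IY == gs_m[2] | IZ == gs_m[3]
    okb <- hi & IX >= 1 & IX <= gs_m[1] & IY >= 1 & IY <= gs_m[2] &
      IZ >= 1 & IZ <= gs_m[3]
    idx <- which(ok)
    if (length(idx)) {
      x0 <- X0[idx]; y0 <- Y0[idx]; z0 <- Z0[idx]
      gx <- fx[idx]; gy <- fy[idx]; gz <- fz[idx]
      md <- moving$data
      out[idx] <-
        md[cbind(x0, y0, z0)] * (1 - gx) * (1 - gy) * (1 - gz) +
        md[cbind(x0 + 1, y0, z0)] * gx * (1 - gy) * (1 - gz) +
        md[cbind(x0, y0 + 1, z0)] * (1 - gx) * gy * (1 - gz) +
        md[cbind(x0, y0, z0 + 1)] * (1 - gx) * (1 - gy) * gz +
        md[cbind(x0 + 1, y0 + 1, z0)] * gx * gy * (1 - gz) +
        md[cbind(x0 + 1, y0, z0 + 1)] * gx * (1 - gy) * gz +
        md[cbind(x0, y0 + 1, z0 + 1)] * (1 - gx) * gy * gz +
        md[cbind(x0 + 1, y0 + 1, z0 + 1)] * gx * gy * gz
    }
    idxb <- which(okb & !ok)
    if (length(idxb))
      out[idxb] <- moving$data[cbind(round(IX[idxb]), round(IY[idxb]),
                                     round(IZ[idxb]))]
  }
  voxel_grid(out, fixed$spacing, fixed$origin, kind = moving$kind,
             label_set = moving$label_set)
}
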