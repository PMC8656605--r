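#' Construct a voxel grid
#'
#' A `voxel_grid` is the shared 3D volume container of the package: a scalar
#' array together with voxel spacing and physical origin. The axis convention
#' is fixed throughout: x = transverse (left-right), y = anterior-posterior,
#' z = cranio-caudal with z increasing towards the head. Voxel centres sit at
#' `origin + (index - 1) * spacing` (indices are 1-based in R; slice numbers
#' shown in reports are also 1-based, counted from the most caudal slice).
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel spacing in mm; all components > 0.
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param kind One of `"intensity"`, `"probability"`, `"label"`. Probability
#'   grids are checked to lie in `[0, 1]`; label grids must take values in
#'   `label_set`.
#' @param label_set Integer vector of admissible labels for label grids.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       kind = "intensity", label_set = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  kind <- match.arg(kind, c("intensity", "probability", "label"))
  if (kind == "probability") {
    rng <- range(data, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("probability grid has values outside [0, 1]", call. = FALSE)
  }
  if (kind == "label") {
    if (is.null(label_set)) label_set <- sort(unique(as.vector(data)))
    if (!all(as.vector(data) %in% label_set))
      stop("label grid contains values outside the declared label set",
           call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = origin,
         kind = kind, label_set = label_set),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid [%s]> %d x %d x %d, spacing %.4g x %.4g x %.4g mm\n",
              x$kind, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Test that two grids share shape, spacing and origin
#' @param a,b `voxel_grid` objects.
#' @param tol Numeric tolerance on spacing/origin (mm).
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_mismatch <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(sprintf("%s do not share geometry (shape/spacing/origin)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Replace the data of a grid, keeping its geometry
#'
#' @param grid A `voxel_grid`.
#' @param data New array of identical shape.
#' @param kind Optional new kind (defaults to the grid's).
#' @param label_set Optional label set for label grids.
#' @return A `voxel_grid` with the same spacing/origin.
#' @export
with_data <- function(grid, data, kind = grid$kind, label_set = grid$label_set) {
  if (!identical(dim(data), dim(grid$data)))
    stop("replacement data has a different shape", call. = FALSE)
  voxel_grid(data, grid$spacing, grid$origin, kind = kind,
             label_set = label_set)
}

#' Physical coordinates of a voxel index
#' @param grid A `voxel_grid`.
#' @param idx Numeric length-3 (1-based voxel index, may be fractional).
#' @return Physical position in mm.
#' @export
voxel_to_physical <- function(grid, idx) {
  grid$origin + (as.numeric(idx) - 1) * grid$spacing
}

#' Clinical metadata attached to a case
#'
#' @param name Patient name.
#' @param hospital_number Identifier string.
#' @param date_of_birth,scan_date Dates (`Date` or parseable strings).
#' @param age Age in years (>= 0).
#' @param psa Serum PSA in ng/mL (>= 0), `NA` if unavailable.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(name = "Anonymous", hospital_number = "NA",
                           date_of_birth = as.Date("1960-01-01"),
                           scan_date = Sys.Date(), age = NA_real_,
                           psa = NA_real_) {
  if (!is.na(psa) && psa < 0) stop("psa must be >= 0", call. = FALSE)
  if (!is.na(age) && age < 0) stop("age must be >= 0", call. = FALSE)
  structure(
    list(name = as.character(name),
         hospital_number = as.character(hospital_number),
         date_of_birth = as.Date(date_of_birth),
         scan_date = as.Date(scan_date),
         age = as.numeric(age), psa = as.numeric(psa)),
    class = "patient_record")
}

# Geometry records make preprocessing invertible: each op returns the record
# needed to map its output back onto the input grid exactly.
geometry_record <- function(op, original_shape, original_spacing,
                            crop_offsets = c(0L, 0L, 0L),
                            resample_factor = c(1, 1, 1)) {
  structure(
    list(op = op,
         original_shape = as.integer(original_shape),
         original_spacing = as.numeric(original_spacing),
         crop_offsets = as.integer(crop_offsets),
         resample_factor = as.numeric(resample_factor)),
    class = "geometry_record")
}
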