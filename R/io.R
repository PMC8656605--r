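#' Read a 3D volume from NIfTI
#'
#' Reads a NIfTI-1 file into a [voxel_grid()]. The image is reoriented to the
#' package's canonical axes (x transverse, y anterior-posterior, z
#' cranio-caudal increasing cranially, i.e. RAS voxel order) using the header
#' direction information, so downstream measurements are unambiguous.
#' Spacing is taken from `pixdim`, the origin from the world position of the
#' first voxel.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param kind Grid kind passed to [voxel_grid()] (`"intensity"`,
#'   `"probability"` or `"label"`).
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, kind = "intensity") {
  if (!file.exists(path))
    stop(sprintf("file does not exist: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot parse '%s' as NIfTI: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  nd <- length(dim(img))
  if (nd == 4L && dim(img)[4] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), dim(img)[1:3]),
                           reference = img)
    nd <- 3L
  }
  if (nd != 3L)
    stop(sprintf("expected a 3D volume, got %d dimensions", nd),
         call. = FALSE)
  # canonicalize voxel order when the header carries orientation info
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(orient) && !identical(orient, "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header has missing or non-positive voxel spacing",
         call. = FALSE)
  xf <- RNifti::xform(img)
  org <- as.numeric(xf[1:3, 4])
  voxel_grid(array(as.numeric(img), dim(img)), spacing = sp, origin = org,
             kind = kind)
}

#' Write a voxel grid to NIfTI
#'
#' Label grids are stored as unsigned 8-bit integers, all other grids as
#' 32-bit float. Spacing and origin are written into the qform/sform so that
#' [read_volume()] recovers the grid (metadata exact, data within float
#' tolerance; labels exact).
#'
#' @param grid A [voxel_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  dirn <- dirname(path)
  if (!dir.exists(dirn))
    stop(sprintf("parent directory does not exist: %s", dirn), call. = FALSE)
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  dt <- if (grid$kind == "label") "uint8" else "float"
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = dt)
    TRUE
  }, error = function(e) {
    stop(sprintf("failed to write '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!file.exists(path))
    stop(sprintf("failed to write '%s'", path), call. = FALSE)
  invisible(path)
}
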