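#' CT volume container
#'
#' A 3D scalar grid of CT intensities in Hounsfield units (HU) together
#' with its voxel spacing and world origin in millimetres. All voxel
#' coordinates used in this package are 0-based (x, y, z) grid indices;
#' world coordinates enter only through metric distances.
#'
#' @param values numeric 3D array of HU.
#' @param spacing numeric length-3, voxel spacing (sx, sy, sz) in mm; all
#'   components must be positive.
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @return An object of class `ct_volume` with fields `values`, `spacing`,
#'   `origin`, `dims`.
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  structure(
    list(values = values, spacing = spacing,
         origin = as.numeric(origin), dims = dim(values)),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%g, %g, %g) mm\n",
              min(x$values), max(x$values),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Lobe label map container
#'
#' Integer label grid over the five lung lobes: 0 background, 1 LU
#' (left upper), 2 LL (left lower), 3 RU (right upper), 4 RM (right
#' middle), 5 RL (right lower).
#'
#' @param labels integer 3D array with values in 0..5.
#' @param spacing voxel spacing in mm.
#' @param origin world origin in mm.
#' @return An object of class `lobe_label_map`.
#' @export
lobe_label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3D volume")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 5L, na.rm = TRUE))
    stop("lobe labels must lie in 0..5")
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), dims = dim(labels),
         label_names = lobe_names()),
    class = "lobe_label_map")
}

#' Lobe label dictionary
#'
#' @return Named integer vector mapping lobe abbreviations to label values.
#' @export
lobe_names <- function() c(LU = 1L, LL = 2L, RU = 3L, RM = 4L, RL = 5L)

nifti_from_grid <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(spacing, rep(1, nd - 3L))
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  img
}

grid_meta <- function(img) {
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  list(spacing = as.numeric(sp), origin = as.numeric(xf[1:3, 4]))
}

#' Read a scalar volume from NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D scalar image.
#' @return A [ct_volume()] with HU values and header spacing/origin.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { dim(img) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D")
  m <- grid_meta(img)
  ct_volume(array(as.numeric(img), dim = d), m$spacing, m$origin)
}

#' Write a scalar volume to NIfTI
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, default single-precision float.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  img <- nifti_from_grid(vol$values, vol$spacing, vol$origin)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a lobe label map from NIfTI
#'
#' @param path path to a NIfTI integer label image (values 0..5).
#' @return A [lobe_label_map()].
#' @export
read_label_map <- function(path) {
  v <- read_volume(path)
  lobe_label_map(array(as.integer(round(v$values)), dim = v$dims),
                 v$spacing, v$origin)
}

#' Write a lobe label map to NIfTI
#'
#' @param lobes a [lobe_label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lobes, path) {
  img <- nifti_from_grid(lobes$labels, lobes$spacing, lobes$origin)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write an LVC vector field to 4D NIfTI
#'
#' The three vector components (vx, vy, vz) are stored on the fourth axis,
#' in that fixed order, as single-precision floats.
#'
#' @param lvc an `lvc_map` from [compute_lvc()], or any list with a 4D
#'   `vectors` array whose last dimension is 3 plus `spacing`/`origin`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(lvc, path) {
  v <- lvc$vectors
  if (length(dim(v)) != 4L || dim(v)[4] != 3L)
    stop("vector field must have 3 channels on the fourth axis")
  img <- nifti_from_grid(v, lvc$spacing, lvc$origin)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read an LVC vector field from 4D NIfTI
#'
#' @param path path to a 4D NIfTI with 3 components on the last axis.
#' @return A list of class `lvc_map` with `vectors`, `dims`, `spacing`,
#'   `origin`.
#' @export
read_vector_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected 4D vector field with 3 components")
  m <- grid_meta(img)
  structure(
    list(vectors = array(as.numeric(img), dim = d), dims = d[1:3],
         spacing = m$spacing, origin = m$origin),
    class = "lvc_map")
}
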