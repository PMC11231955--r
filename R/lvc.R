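#' x'th generation strongest neighbourhood (x-GSN)
#'
#' The x-GSN of a voxel is the voxel reached by following the stored
#' strongest-connectivity direction `generations` times. A step from a
#' code-13 voxel (seed, deactivated, or unreached) is a no-op, so walks
#' saturate at the seed.
#'
#' @param fc an `fc_map` from [compute_fc()].
#' @param v 0-based (x, y, z) voxel index, or an n x 3 matrix of indices.
#' @param generations number of steps, default 3.
#' @return Voxel index (or matrix) after `generations` steps.
#' @export
gsn <- function(fc, v, generations = 3L) {
  if (generations < 1L) stop("generations must be >= 1")
  for (i in seq_len(generations)) v <- strongest_neighbor_step(fc, v)
  v
}

#' LVC vector at a voxel
#'
#' The normalized displacement from a voxel to its x-GSN voxel, in voxel
#' index space; the zero vector when the walk does not move.
#'
#' @inheritParams gsn
#' @return Numeric length-3 unit vector, or `c(0, 0, 0)`.
#' @export
lvc_vector <- function(fc, v, generations = 3L) {
  vf <- gsn(fc, v, generations)
  d <- as.numeric(vf - v)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) c(0, 0, 0) else d / nrm
}

#' Compute the LVC vector field
#'
#' Builds the lung vessel connectivity map: for every voxel of the vessel
#' mask, the unit vector pointing from the voxel toward its
#' `generations`-GSN voxel (the voxel reached by following the
#' strongest-connectivity directions). With the seed placed in the heart,
#' these vectors point on average from distal vessels toward the heart.
#' All voxels outside the vessel mask hold the zero vector.
#'
#' Displacements are measured in voxel-index space before normalization
#' (the walk itself is a grid operation); set `world_space = TRUE` to
#' scale by voxel spacing first.
#'
#' @param fc an `fc_map` from [compute_fc()].
#' @param vessel_mask logical 3D array of segmented vessel voxels; same
#'   dims as `fc`.
#' @param generations walk length, default 3 (the 3-GSN of the method).
#' @param world_space scale displacements by spacing before normalizing.
#' @return An object of class `lvc_map` with `vectors` (4D array, last
#'   axis = (vx, vy, vz)), `dims`, `generations`, `spacing`, `origin`.
#' @export
compute_lvc <- function(fc, vessel_mask, generations = 3L,
                        world_space = FALSE) {
  if (!identical(dim(vessel_mask), as.integer(fc$dims)) &&
      !identical(as.integer(dim(vessel_mask)), as.integer(fc$dims)))
    stop("vessel mask dims do not match FC map dims")
  idx <- which(vessel_mask, arr.ind = TRUE) - 1L
  vectors <- array(0, dim = c(fc$dims, 3L))
  if (nrow(idx) > 0L) {
    unreached <- fc$strength[idx + 1L] == 0
    if (any(unreached))
      warning(sum(unreached),
              " vessel-mask voxel(s) have zero connectivity strength; ",
              "their LVC vectors are zero")
    vf <- gsn(fc, idx, generations)
    disp <- vf - idx
    storage.mode(disp) <- "double"
    if (world_space) disp <- sweep(disp, 2L, fc$spacing, `*`)
    nrm <- sqrt(rowSums(disp^2))
    nz <- nrm > 0
    disp[nz, ] <- disp[nz, , drop = FALSE] / nrm[nz]
    for (k in 1:3)
      vectors[cbind(idx + 1L, k)] <- disp[, k]
  }
  structure(
    list(vectors = vectors, dims = fc$dims, generations = generations,
         spacing = fc$spacing, origin = fc$origin),
    class = "lvc_map")
}

#' @export
print.lvc_map <- function(x, ...) {
  nrm <- sqrt(rowSums(matrix(x$vectors, ncol = 3L)^2))
  cat(sprintf("lvc_map: %d x %d x %d, %d nonzero vectors\n",
              x$dims[1], x$dims[2], x$dims[3], sum(nrm > 0)))
  invisible(x)
}

#' Count distinct realized LVC directions
#'
#' The 1-GSN offers at most 26 directions (the immediate neighbours);
#' walking x generations expands the reachable direction set to at most
#' 26^x, which is how the generational walk reduces angular
#' discretization error. This counts the distinct nonzero normalized
#' displacement directions realized over a mask.
#'
#' @param fc an `fc_map`.
#' @param mask logical 3D array of voxels to inspect.
#' @param generations walk length.
#' @return Integer count of distinct directions.
#' @export
direction_count <- function(fc, mask, generations = 3L) {
  if (generations < 1L) stop("generations must be >= 1")
  idx <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) return(0L)
  vf <- gsn(fc, idx, generations)
  disp <- vf - idx
  storage.mode(disp) <- "double"
  nrm <- sqrt(rowSums(disp^2))
  keep <- nrm > 0
  if (!any(keep)) return(0L)
  u <- round(disp[keep, , drop = FALSE] / nrm[keep], 9)
  nrow(unique(u))
}
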