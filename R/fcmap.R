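#' Neighbour code to 3D offset
#'
#' Each of the 27 voxels of a 3x3x3 neighbourhood is named by an integer
#' code in 0..26 via `code = 9*(dx+1) + 3*(dy+1) + (dz+1)`; code 13 is the
#' centre voxel (offset 0,0,0).
#'
#' @param code integer vector of codes in 0..26.
#' @return Integer matrix with columns dx, dy, dz, one row per code.
#' @export
code_to_offset <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 26L)) stop("neighbour code out of range 0..26")
  cbind(dx = code %/% 9L - 1L,
        dy = (code %/% 3L) %% 3L - 1L,
        dz = code %% 3L - 1L)
}

#' 3D offset to neighbour code
#'
#' Inverse of [code_to_offset()].
#'
#' @param offset integer length-3 vector or 3-column matrix with
#'   components in \{-1, 0, 1\}.
#' @return Integer code(s) in 0..26.
#' @export
offset_to_code <- function(offset) {
  if (is.null(dim(offset))) offset <- matrix(offset, ncol = 3L)
  storage.mode(offset) <- "integer"
  if (any(abs(offset) > 1L)) stop("offset components must be in {-1, 0, 1}")
  as.integer(9L * (offset[, 1] + 1L) + 3L * (offset[, 2] + 1L) +
               (offset[, 3] + 1L))
}

#' Vessel activation mask
#'
#' Voxels are active when their HU lies strictly inside the window
#' (default 0 < HU < 200, the soft-tissue/contrast range of pulmonary
#' vessels); all other voxels are deactivated and excluded from
#' propagation.
#'
#' @param ct a [ct_volume()].
#' @param window numeric length-2, (low, high) HU bounds.
#' @return Logical 3D array.
#' @export
activation_mask <- function(ct, window = c(0, 200)) {
  if (window[1] >= window[2]) stop("window low must be below high")
  ct$values > window[1] & ct$values < window[2]
}

#' Pairwise voxel affinity
#'
#' Affinity between two active voxels is the smaller of their objectness
#' scores g(x) = (HU - low)/(high - low); it is symmetric and monotone
#' non-decreasing in each intensity over the window.
#'
#' @param hu_u,hu_v HU values of the two voxels (vectorised).
#' @param window (low, high) HU bounds.
#' @return Affinity value(s) in `[0, 1]`.
#' @export
affinity <- function(hu_u, hu_v, window = c(0, 200)) {
  act <- function(h) h > window[1] & h < window[2]
  if (any(!act(hu_u)) || any(!act(hu_v)))
    stop("affinity is defined only between active voxels")
  g <- function(h) pmin(pmax((h - window[1]) / diff(window), 0), 1)
  pmin(g(hu_u), g(hu_v))
}

#' Fuzzy-connectedness map from a seed
#'
#' Propagates max-min fuzzy connectedness from a seed voxel over the
#' 26-neighbourhood, restricted to active voxels (HU strictly inside
#' `window`). The connectivity strength of a voxel is the maximum over
#' paths from the seed of the minimum pairwise affinity along the path.
#' Each reached voxel stores the neighbour code (0..26) of the direction
#' toward its predecessor on an optimal path; the seed and all
#' deactivated or unreached voxels store code 13 (self).
#'
#' Tie-breaking is deterministic: equal-strength voxels are finalized in
#' linear-index order and equal-strength predecessors resolve to the
#' lowest code, so repeated runs are bit-identical.
#'
#' @param ct a [ct_volume()].
#' @param seed integer length-3, 0-based (x, y, z) voxel index of the seed
#'   (placed inside the heart for lung-vessel use).
#' @param window (low, high) HU activation window, default `c(0, 200)`.
#' @param snap_radius if the given seed voxel is deactivated, snap to the
#'   nearest active voxel within this many voxels (0 disables snapping).
#' @return An object of class `fc_map` with fields `codes` (integer 3D
#'   array in 0..26), `strength` (3D array in `[0,1]`), `seed`, `window`,
#'   `spacing`, `origin`, `dims`.
#' @export
compute_fc <- function(ct, seed, window = c(0, 200), snap_radius = 5) {
  dims <- ct$dims
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || any(seed < 0L) || any(seed >= dims))
    stop("seed outside grid")
  if (any(dims < 3L)) stop("volume too small for a 27-neighbourhood")
  act <- activation_mask(ct, window)
  if (!act[seed[1] + 1L, seed[2] + 1L, seed[3] + 1L]) {
    seed <- snap_seed(act, seed, snap_radius)
  }
  seed0 <- seed[1] + dims[1] * (seed[2] + dims[2] * seed[3])
  res <- .fc_propagate(as.numeric(ct$values), dims, seed0,
                       window[1], window[2])
  structure(
    list(codes = array(res$codes, dim = dims),
         strength = array(res$strength, dim = dims),
         seed = seed, window = as.numeric(window),
         spacing = ct$spacing, origin = ct$origin, dims = dims),
    class = "fc_map")
}

snap_seed <- function(act, seed, snap_radius) {
  if (snap_radius <= 0) stop("seed voxel is deactivated")
  idx <- which(act, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) stop("seed voxel is deactivated and no voxel is active")
  d2 <- (idx[, 1] - seed[1])^2 + (idx[, 2] - seed[2])^2 + (idx[, 3] - seed[3])^2
  best <- which.min(d2)
  if (d2[best] > snap_radius^2)
    stop("seed voxel is deactivated and no active voxel within snap radius")
  as.integer(idx[best, ])
}

#' @export
print.fc_map <- function(x, ...) {
  nact <- sum(x$strength > 0)
  cat(sprintf("fc_map: %d x %d x %d, seed (%d, %d, %d), window (%g, %g) HU\n",
              x$dims[1], x$dims[2], x$dims[3], x$seed[1], x$seed[2], x$seed[3],
              x$window[1], x$window[2]))
  cat(sprintf("  %d reached voxels (%.2f%% of grid)\n", nact,
              100 * nact / prod(x$dims)))
  invisible(x)
}

#' One step toward the strongest-connectivity neighbour
#'
#' Moves a voxel along its stored neighbour code; a voxel with code 13
#' (seed, deactivated, or unreached) is a fixed point.
#'
#' @param fc an `fc_map` from [compute_fc()].
#' @param v 0-based (x, y, z) voxel index, or an n x 3 matrix of indices.
#' @return Voxel index (or matrix) after one step.
#' @export
strongest_neighbor_step <- function(fc, v) {
  single <- is.null(dim(v))
  if (single) v <- matrix(v, ncol = 3L)
  storage.mode(v) <- "integer"
  codes <- fc$codes[v + 1L]
  out <- v + code_to_offset(codes)
  dimnames(out) <- NULL
  if (single) out[1, ] else out
}
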