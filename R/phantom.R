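#' Default planted per-lobe directions
#'
#' Five unit vectors, one per lobe (LU, LL, RU, RM, RL), pointing from
#' the hilum toward the lobe periphery, arranged so that every pair is
#' at least 45 degrees apart — an idealisation of the distinct lobar
#' vessel-subsystem orientations.
#'
#' @return 5 x 3 numeric matrix of unit row vectors, rows named by lobe.
#' @export
default_lobe_directions <- function() {
  d <- rbind(
    LU = c(-0.70, 0.00,  0.714),
    LL = c(-0.70, 0.00, -0.714),
    RU = c( 0.70, 0.00,  0.714),
    RM = c( 0.966, 0.259, 0.00),
    RL = c( 0.70, 0.00, -0.714))
  d / sqrt(rowSums(d^2))
}

#' Phantom specification
#'
#' Parameters of the synthetic chest phantom: a body of `body_hu`, a
#' lung ellipsoid of `lung_hu` partitioned into five wedge-shaped lobes
#' around the hilum, a spherical heart of `vessel_hu` at the hilum
#' (containing the FC seed), and per-lobe vascular trees grown from the
#' hilum along the planted directions, rasterized as tubes at
#' `vessel_hu`. Vessel intensities sit strictly inside the (0, 200) HU
#' activation window; lung and body lie outside it.
#'
#' @param dims grid size, default 96^3 voxels.
#' @param spacing voxel spacing (mm), default isotropic 1 mm.
#' @param lobe_directions 5 x 3 matrix of planted unit directions
#'   (hilum to periphery), rows LU, LL, RU, RM, RL.
#' @param branches_per_lobe side branches per lobar tree, default 8.
#' @param branch_angle_jitter maximum angular deviation of a branch from
#'   its lobe direction, degrees, default 10.
#' @param vessel_radius tube radius in voxels, default 1.1.
#' @param vessel_hu vessel intensity at mid-tree, default 100 HU.
#' @param contrast_taper total HU drop from the hilum to the distal tree
#'   (default 80), emulating the caliber/partial-volume intensity
#'   falloff of contrast along the vascular tree; the heart is brightest
#'   and distal branches dimmest, all strictly inside (0, 200) HU.
#' @param lung_hu lung parenchyma intensity, default -850 HU.
#' @param body_hu body/background intensity, default -1000 HU.
#' @param heart_radius heart sphere radius in voxels, default 6.
#' @param trunk_length lobar trunk length in voxels; default 38% of the
#'   smallest grid dimension.
#' @param noise_sd additive Gaussian HU noise (0 disables); noise on
#'   vessel voxels is clipped so they never leave the activation window.
#' @param rng_seed integer seed making the phantom reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(96, 96, 96), spacing = c(1, 1, 1),
                         lobe_directions = default_lobe_directions(),
                         branches_per_lobe = 8, branch_angle_jitter = 10,
                         vessel_radius = 1.1, vessel_hu = 100,
                         contrast_taper = 80,
                         lung_hu = -850, body_hu = -1000,
                         heart_radius = 6, trunk_length = NULL,
                         noise_sd = 0, rng_seed = 42L) {
  if (vessel_hu <= 0 || vessel_hu >= 200)
    stop("vessel_hu must lie strictly inside (0, 200)")
  if (lung_hu > 0 && lung_hu < 200) stop("lung_hu must be outside (0, 200)")
  nrm <- sqrt(rowSums(lobe_directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("lobe directions must be unit vectors")
  if (is.null(trunk_length)) trunk_length <- round(0.38 * min(dims))
  structure(
    list(dims = as.integer(dims), spacing = as.numeric(spacing),
         lobe_directions = lobe_directions,
         branches_per_lobe = as.integer(branches_per_lobe),
         branch_angle_jitter = branch_angle_jitter,
         vessel_radius = vessel_radius, vessel_hu = vessel_hu,
         contrast_taper = contrast_taper,
         lung_hu = lung_hu, body_hu = body_hu,
         heart_radius = heart_radius, trunk_length = trunk_length,
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "phantom_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# unit vector rotated away from d by `angle` radians, at azimuth phi
# around d
rotate_about <- function(d, angle, phi) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  cos(angle) * d + sin(angle) * (cos(phi) * e1 + sin(phi) * e2)
}

# mark voxels within radius r (voxels) of segment p--q on a grid of dims
rasterize_segment <- function(mask, p, q, r) {
  d <- dim(mask)
  lo <- pmax(floor(pmin(p, q) - r), 0)
  hi <- pmin(ceiling(pmax(p, q) + r), d - 1)
  if (any(lo > hi)) return(mask)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  gx <- array(xs, dim = c(nx, ny, nz))
  gy <- array(rep(ys, each = nx), dim = c(nx, ny, nz))
  gz <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))
  ab <- q - p
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d2 <- (gx - p[1])^2 + (gy - p[2])^2 + (gz - p[3])^2
  } else {
    t <- ((gx - p[1]) * ab[1] + (gy - p[2]) * ab[2] + (gz - p[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (gx - p[1] - t * ab[1])^2 + (gy - p[2] - t * ab[2])^2 +
      (gz - p[3] - t * ab[3])^2
  }
  sub <- mask[xs + 1L, ys + 1L, zs + 1L, drop = FALSE]
  mask[xs + 1L, ys + 1L, zs + 1L] <- sub | (d2 <= r^2)
  mask
}

#' Generate a synthetic vascular chest phantom
#'
#' Builds a CT-like volume with five wedge-shaped lobes, a heart sphere
#' holding the FC seed, and per-lobe vascular trees planted along the
#' spec's lobe directions, plus the matching lobe label map, vessel mask
#' and planted directions. Identical spec (including `rng_seed`) yields
#' a bit-identical bundle.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_bundle`: `ct` ([ct_volume()]),
#'   `lobes` ([lobe_label_map()]), `vessel_mask` (logical array), `seed`
#'   (0-based voxel triple), `planted_directions` (5 x 3 matrix), `spec`.
#' @export
generate_phantom <- function(spec) {
  with_seed(spec$rng_seed, {
    d <- spec$dims
    hilum <- floor(d / 2)
    ct <- array(spec$body_hu, dim = d)

    x0 <- seq_len(d[1]) - 1; y0 <- seq_len(d[2]) - 1; z0 <- seq_len(d[3]) - 1
    gx <- array(x0, dim = d)
    gy <- array(rep(y0, each = d[1]), dim = d)
    gz <- array(rep(z0, each = d[1] * d[2]), dim = d)
    rx <- (gx - hilum[1]); ry <- (gy - hilum[2]); rz <- (gz - hilum[3])

    lung_r <- 0.46 * d
    lung <- (rx / lung_r[1])^2 + (ry / lung_r[2])^2 + (rz / lung_r[3])^2 <= 1
    ct[lung] <- spec$lung_hu

    r2 <- rx^2 + ry^2 + rz^2
    heart <- r2 <= spec$heart_radius^2
    vessel_hu_at <- function(r) {
      reach <- 1.35 * spec$trunk_length
      pmin(pmax(spec$vessel_hu + spec$contrast_taper * (0.5 - r / reach),
                5), 195)
    }
    ct[heart] <- vessel_hu_at(0)

    # wedge lobes: nearest planted direction wins
    labels <- array(0L, dim = d)
    region <- lung & !heart
    nr <- sqrt(r2[region])
    nr[nr == 0] <- 1
    dots <- sapply(1:5, function(j) {
      dj <- spec$lobe_directions[j, ]
      (rx[region] * dj[1] + ry[region] * dj[2] + rz[region] * dj[3]) / nr
    })
    labels[region] <- max.col(dots, ties.method = "first")

    # vascular trees
    vmask <- array(FALSE, dim = d)
    for (j in 1:5) {
      dj <- spec$lobe_directions[j, ]
      p0 <- hilum + dj * (0.5 * spec$heart_radius)
      p1 <- hilum + dj * spec$trunk_length
      vmask <- rasterize_segment(vmask, p0, p1, spec$vessel_radius)
      for (b in seq_len(spec$branches_per_lobe)) {
        frac <- stats::runif(1, 0.25, 0.85)
        start <- p0 + frac * (p1 - p0)
        ang <- stats::runif(1, 0.3, 1) * spec$branch_angle_jitter * pi / 180
        phi <- stats::runif(1, 0, 2 * pi)
        bd <- rotate_about(dj, ang, phi)
        blen <- stats::runif(1, 0.4, 0.7) * spec$trunk_length
        vmask <- rasterize_segment(vmask, start, start + bd * blen,
                                   spec$vessel_radius)
      }
    }
    vmask <- vmask & !heart
    ct[vmask] <- vessel_hu_at(sqrt(r2[vmask]))

    if (spec$noise_sd > 0) {
      ct <- ct + array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)
      inwin <- vmask | heart
      ct[inwin] <- pmin(pmax(ct[inwin], 1), 199)
      ct[!inwin] <- pmin(ct[!inwin], -1)
    }

    structure(
      list(ct = ct_volume(ct, spec$spacing),
           lobes = lobe_label_map(labels, spec$spacing),
           vessel_mask = vmask,
           seed = as.integer(hilum),
           planted_directions = spec$lobe_directions,
           spec = spec),
      class = "phantom_bundle")
  })
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf(
    "phantom_bundle: %d x %d x %d, %d vessel voxels, seed (%d, %d, %d)\n",
    x$spec$dims[1], x$spec$dims[2], x$spec$dims[3], sum(x$vessel_mask),
    x$seed[1], x$seed[2], x$seed[3]))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' A list of phantom subjects sharing the planted lobe directions but
#' with per-subject branch geometry (each subject gets its own derived
#' seed), emulating a cohort in which lobar orientation structure is
#' common while individual vascular trees vary.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param spec the shared [phantom_spec()].
#' @param cohort_seed integer seed for the per-subject seed draw.
#' @return List of `phantom_bundle`s, named subject01, subject02, ...
#' @export
generate_cohort <- function(n_subjects, spec = phantom_spec(),
                            cohort_seed = 1L) {
  if (n_subjects < 2L) stop("a cohort needs at least 2 subjects")
  seeds <- with_seed(cohort_seed, sample.int(.Machine$integer.max - 1L,
                                             n_subjects))
  out <- lapply(seq_len(n_subjects), function(i) {
    si <- spec
    si$rng_seed <- seeds[i]
    generate_phantom(si)
  })
  names(out) <- sprintf("subject%02d", seq_len(n_subjects))
  out
}

#' Cohort orientation table
#'
#' Runs the full FC + LVC + per-lobe orientation chain on every phantom
#' subject and stacks the results: one row per subject per lobe, the
#' observation unit of the lobe-separability MANOVA.
#'
#' @param bundles list of `phantom_bundle`s (see [generate_cohort()]).
#' @param generations GSN walk length, default 3.
#' @param window HU activation window, default `c(0, 200)`.
#' @return data.frame with columns `subject`, `lobe`, `vx`, `vy`, `vz`,
#'   `azimuth`, `elevation`, `n_voxels`, `degenerate`.
#' @export
cohort_orientation_table <- function(bundles, generations = 3L,
                                     window = c(0, 200)) {
  rows <- lapply(names(bundles), function(nm) {
    b <- bundles[[nm]]
    fc <- compute_fc(b$ct, b$seed, window)
    lvc <- compute_lvc(fc, b$vessel_mask, generations)
    ori <- lobe_average_orientation(lvc, b$lobes, b$vessel_mask)
    cbind(subject = nm,
          ori[, c("lobe", "vx", "vy", "vz", "azimuth", "elevation",
                  "n_voxels", "degenerate")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
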