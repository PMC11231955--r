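#' Per-lobe average LVC orientation
#'
#' For each lobe j, sums the nonzero LVC vectors over vessel voxels
#' labelled j and normalizes the sum to a unit vector. This is the
#' resultant-direction summary of the lobar vascular subsystem; lobes
#' whose vectors cancel (or that contain no vessel voxels) are flagged
#' degenerate and report a zero vector.
#'
#' @param lvc an `lvc_map` from [compute_lvc()].
#' @param lobes a [lobe_label_map()] with the same dims.
#' @param vessel_mask logical 3D array restricting which voxels
#'   contribute; defaults to all voxels with a nonzero vector.
#' @return A data.frame with one row per lobe: `lobe`, `vx`, `vy`, `vz`
#'   (average unit vector), `sum_x`, `sum_y`, `sum_z`, `n_voxels`,
#'   `azimuth`, `elevation` (radians; NA when degenerate), `degenerate`.
#' @export
lobe_average_orientation <- function(lvc, lobes, vessel_mask = NULL) {
  if (!identical(as.integer(lobes$dims), as.integer(lvc$dims)))
    stop("lobe map dims do not match LVC dims")
  if (is.null(vessel_mask)) vessel_mask <- array(TRUE, dim = lvc$dims)
  if (!identical(as.integer(dim(vessel_mask)), as.integer(lvc$dims)))
    stop("vessel mask dims do not match LVC dims")
  vx <- lvc$vectors[, , , 1]; vy <- lvc$vectors[, , , 2]
  vz <- lvc$vectors[, , , 3]
  nonzero <- (vx != 0 | vy != 0 | vz != 0) & vessel_mask
  nm <- lobe_names()
  out <- lapply(seq_along(nm), function(j) {
    sel <- nonzero & lobes$labels == nm[j]
    n <- sum(sel)
    s <- c(sum(vx[sel]), sum(vy[sel]), sum(vz[sel]))
    nrm <- sqrt(sum(s^2))
    degen <- nrm == 0
    avg <- if (degen) c(0, 0, 0) else s / nrm
    sph <- if (degen) c(NA_real_, NA_real_) else to_spherical(avg)
    data.frame(lobe = names(nm)[j], vx = avg[1], vy = avg[2], vz = avg[3],
               sum_x = s[1], sum_y = s[2], sum_z = s[3], n_voxels = n,
               azimuth = unname(sph[1]), elevation = unname(sph[2]),
               degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Unit vector to spherical coordinates
#'
#' Azimuth is `atan2(vy, vx)` in (-pi, pi]; elevation is `asin(vz)` in
#' `[-pi/2, pi/2]`. At the poles (vz = +/-1) the azimuth is 0 by
#' convention.
#'
#' @param v numeric length-3 unit vector.
#' @return Named numeric vector `c(azimuth, elevation)` in radians.
#' @export
to_spherical <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("spherical coordinates of the zero vector are undefined")
  if (abs(nrm - 1) > 1e-6) stop("expected a unit vector")
  az <- if (v[1] == 0 && v[2] == 0) 0 else atan2(v[2], v[1])
  c(azimuth = az, elevation = asin(max(-1, min(1, v[3]))))
}

#' One-way MANOVA with Wilks' lambda
#'
#' Tests whether multivariate group means differ, via
#' Lambda = det(W) / det(W + B) with W the pooled within-group scatter
#' and B the between-group scatter, and Rao's F approximation for the
#' p-value. Used here on the (azimuth, elevation) coordinates of
#' per-lobe average LVC vectors to test lobe separability.
#'
#' @param group factor or vector of group labels, one per observation.
#' @param response numeric matrix, one row per observation (here 2
#'   columns: azimuth, elevation).
#' @return A list of class `manova_wilks` with `wilks_lambda`, `f_stat`,
#'   `df1`, `df2`, `p_value`, `n_obs`, `n_groups`.
#' @export
manova_wilks <- function(group, response) {
  response <- as.matrix(response)
  group <- factor(group)
  if (any(!is.finite(response))) stop("responses must be finite")
  k <- nlevels(group)
  n <- nrow(response)
  p <- ncol(response)
  if (k < 2L) stop("need at least 2 groups")
  if (n <= k + 2L) stop("too few observations for the F approximation")
  if (length(group) != n) stop("group length does not match responses")

  grand <- colMeans(response)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (lev in levels(group)) {
    rows <- response[group == lev, , drop = FALSE]
    m <- colMeans(rows)
    cen <- sweep(rows, 2L, m)
    W <- W + crossprod(cen)
    B <- B + nrow(rows) * tcrossprod(m - grand)
  }
  Tm <- W + B
  dT <- det(Tm)
  if (dT <= 0 || !is.finite(dT))
    stop("singular total scatter: responses are collinear")
  lambda <- det(W) / dT
  lambda <- min(max(lambda, 0), 1)

  # Rao's F approximation
  q <- k - 1
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- s * ((n - k) - (p - q + 1) / 2) - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  f_stat <- if (lam_s == 0) Inf else (1 - lam_s) / lam_s * df2 / df1
  p_value <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  structure(
    list(wilks_lambda = lambda, f_stat = f_stat, df1 = df1, df2 = df2,
         p_value = p_value, n_obs = n, n_groups = k),
    class = "manova_wilks")
}

#' @export
print.manova_wilks <- function(x, ...) {
  cat(sprintf(
    "Wilks' lambda = %.4f, F(%g, %.1f) = %.3f, p = %.3g (n = %d, %d groups)\n",
    x$wilks_lambda, x$df1, x$df2, x$f_stat, x$p_value, x$n_obs, x$n_groups))
  invisible(x)
}

#' Recenter azimuths on their circular mean
#'
#' Azimuth is circular; a linear MANOVA on raw azimuths can manufacture a
#' group effect purely from the -pi/pi cut. Recentring all azimuths on
#' their circular mean moves the cut to the least populated direction.
#'
#' @param azimuth numeric vector of angles in radians.
#' @return Angles recentred to (-pi, pi].
#' @export
center_azimuth <- function(azimuth) {
  ctr <- atan2(mean(sin(azimuth)), mean(cos(azimuth)))
  wrapped <- (azimuth - ctr + pi) %% (2 * pi) - pi
  ifelse(wrapped == -pi, pi, wrapped)
}

#' Lobe-separability MANOVA on a cohort orientation table
#'
#' Runs [manova_wilks()] with lobe as the group factor and (azimuth,
#' elevation) as the bivariate response, one observation per subject per
#' lobe. Degenerate rows are dropped.
#'
#' @param table data.frame with columns `lobe`, `azimuth`, `elevation`
#'   (as produced by [cohort_orientation_table()]).
#' @param center recentre azimuths on their circular mean first
#'   (default TRUE); see [center_azimuth()].
#' @return A `manova_wilks` result.
#' @export
lobe_manova <- function(table, center = TRUE) {
  ok <- is.finite(table$azimuth) & is.finite(table$elevation)
  table <- table[ok, , drop = FALSE]
  az <- if (center) center_azimuth(table$azimuth) else table$azimuth
  manova_wilks(table$lobe, cbind(azimuth = az, elevation = table$elevation))
}
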