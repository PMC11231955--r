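# Independent oracles used across the suite. These deliberately avoid the
# package's own propagation/metric code paths.

# Max-min path-strength closure (Floyd-Warshall style) over the active
# voxels of a small HU grid. Returns a full 3D strength array comparable
# to compute_fc()$strength.
fw_maxmin_strength <- function(hu, seed, window = c(0, 200)) {
  d <- dim(hu)
  act <- hu > window[1] & hu < window[2]
  g <- pmin(pmax((hu - window[1]) / diff(window), 0), 1)
  ids <- which(act)
  n <- length(ids)
  out <- array(0, dim = d)
  if (n == 0L) return(out)
  pos <- arrayInd(ids, d)
  cheb <- pmax(abs(outer(pos[, 1], pos[, 1], `-`)),
               abs(outer(pos[, 2], pos[, 2], `-`)),
               abs(outer(pos[, 3], pos[, 3], `-`)))
  S <- ifelse(cheb == 1L, outer(g[ids], g[ids], pmin), 0)
  diag(S) <- 1
  for (k in seq_len(n))
    S <- pmax(S, outer(S[, k], S[k, ], pmin))
  seed_lin <- seed[1] + 1L + d[1] * (seed[2] + d[2] * seed[3])
  si <- match(seed_lin, ids)
  if (is.na(si)) return(out)
  out[ids] <- S[si, ]
  out[seed_lin] <- 1
  out
}

# All-pairs surface-distance ASD (symmetric mean), world units.
brute_asd <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- sweep(which(surface_voxels(a), arr.ind = TRUE) - 1L, 2L, spacing, `*`)
  pb <- sweep(which(surface_voxels(b), arr.ind = TRUE) - 1L, 2L, spacing, `*`)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2 <- pmax(d2, 0)
  (mean(sqrt(apply(d2, 1L, min))) + mean(sqrt(apply(d2, 2L, min)))) / 2
}

# Wilks' lambda by a different route: covariance-based scatter matrices.
brute_wilks <- function(group, response) {
  group <- factor(group)
  response <- as.matrix(response)
  n <- nrow(response)
  Tm <- (n - 1) * stats::cov(response)
  W <- Reduce(`+`, lapply(levels(group), function(lev) {
    rows <- response[group == lev, , drop = FALSE]
    (nrow(rows) - 1) * stats::cov(rows)
  }))
  det(W) / det(Tm)
}

# Uniform-density ball with a radial intensity ramp (bright centre),
# everything inside the activation window; used for direction counting.
ball_ct <- function(radius = 9) {
  n <- as.integer(2 * radius + 5)
  c0 <- (n - 1) / 2
  ax <- 0:(n - 1)
  gx <- array(ax, dim = c(n, n, n))
  gy <- array(rep(ax, each = n), dim = c(n, n, n))
  gz <- array(rep(ax, each = n * n), dim = c(n, n, n))
  r <- sqrt((gx - c0)^2 + (gy - c0)^2 + (gz - c0)^2)
  hu <- ifelse(r <= radius, 190 - 180 * r / (radius + 1), -1000)
  list(ct = ct_volume(array(hu, dim = c(n, n, n))),
       seed = rep(as.integer(c0), 3L))
}

# Small random active grid for oracle comparisons: HU drawn inside and
# slightly outside the window.
random_hu_grid <- function(d = c(5, 5, 5), p_inactive = 0.2) {
  hu <- array(stats::runif(prod(d), 10, 190), dim = d)
  drop_out <- stats::runif(prod(d)) < p_inactive
  hu[drop_out] <- sample(c(-500, 250), sum(drop_out), replace = TRUE)
  hu
}

# Follow stored codes until a fixed point; errors out if the walk exceeds
# the number of voxels (a cycle).
walk_to_fixed_point <- function(fc, v) {
  limit <- prod(fc$dims)
  for (i in seq_len(limit + 1L)) {
    nxt <- strongest_neighbor_step(fc, v)
    if (all(nxt == v)) return(v)
    v <- nxt
  }
  stop("walk did not terminate (cycle)")
}

small_phantom <- function(seed = 7, dims = c(48, 48, 48)) {
  generate_phantom(phantom_spec(dims = dims, rng_seed = seed))
}

angle_deg <- function(u, v) {
  acos(pmax(-1, pmin(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
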