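#' Componentwise median voxel spacing
#'
#' The dataset-fingerprint target resolution: the per-axis median of all
#' subjects' voxel spacings. For an even number of subjects the lower
#' median is taken per component (a spacing that actually occurs).
#'
#' @param spacings list of numeric length-3 spacing triples (mm).
#' @return Numeric length-3 median spacing.
#' @export
median_spacing <- function(spacings) {
  if (length(spacings) == 0L) stop("empty spacing list")
  m <- do.call(rbind, lapply(spacings, as.numeric))
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  apply(m, 2L, lower_median)
}

#' Resample a volume to a target spacing
#'
#' Trilinear interpolation for intensity volumes, nearest-neighbour for
#' label maps (never inventing labels). Output dims are
#' `round(dims * spacing / target)`; voxel i of the output sits at world
#' offset `i * target` along each axis, sampled from the input grid with
#' border clamping.
#'
#' @param vol a [ct_volume()] or [lobe_label_map()].
#' @param target_spacing numeric length-3 target spacing (mm).
#' @param interpolation "linear" (default for `ct_volume`) or "nearest"
#'   (forced for label maps).
#' @return Resampled object of the same class.
#' @export
resample <- function(vol, target_spacing,
                     interpolation = c("linear", "nearest")) {
  target_spacing <- as.numeric(target_spacing)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  is_labels <- inherits(vol, "lobe_label_map")
  interpolation <- if (is_labels) "nearest" else match.arg(interpolation)
  src <- if (is_labels) vol$labels else vol$values
  d <- dim(src)
  nd <- pmax(as.integer(round(d * vol$spacing / target_spacing)), 1L)
  if (all(nd == d) && all(vol$spacing == target_spacing)) return(vol)

  # continuous source index of each target sample, clamped to the grid
  ax <- lapply(1:3, function(k) {
    pmin(pmax((seq_len(nd[k]) - 1) * target_spacing[k] / vol$spacing[k], 0),
         d[k] - 1)
  })
  if (interpolation == "nearest") {
    ix <- lapply(ax, function(a) as.integer(round(a)) + 1L)
    out <- src[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(k) as.integer(pmin(floor(ax[[k]]), d[k] - 2L)))
    fr <- lapply(1:3, function(k) ax[[k]] - lo[[k]])
    g <- function(ox, oy, oz)
      src[lo[[1]] + 1L + ox, lo[[2]] + 1L + oy, lo[[3]] + 1L + oz,
          drop = FALSE]
    wx <- array(fr[[1]], dim = nd)
    wy <- array(rep(fr[[2]], each = nd[1]), dim = nd)
    wz <- array(rep(fr[[3]], each = nd[1] * nd[2]), dim = nd)
    out <- g(0, 0, 0) * (1 - wx) * (1 - wy) * (1 - wz) +
      g(1, 0, 0) * wx * (1 - wy) * (1 - wz) +
      g(0, 1, 0) * (1 - wx) * wy * (1 - wz) +
      g(0, 0, 1) * (1 - wx) * (1 - wy) * wz +
      g(1, 1, 0) * wx * wy * (1 - wz) +
      g(1, 0, 1) * wx * (1 - wy) * wz +
      g(0, 1, 1) * (1 - wx) * wy * wz +
      g(1, 1, 1) * wx * wy * wz
  }
  if (is_labels) lobe_label_map(out, target_spacing, vol$origin)
  else ct_volume(out, target_spacing, vol$origin)
}

#' Fit an intensity normalization spec
#'
#' Computes the percentile clipping bounds (default the `[0.5, 99.5]`
#' percentile range, linear interpolation between order statistics) and
#' the mean/sd of the clipped values, over a voxel population — either
#' one volume or a pooled dataset.
#'
#' @param values numeric vector (or array) of HU values.
#' @param p_low,p_high clipping percentiles (0..100).
#' @return A list of class `normalization_spec` with `p_low`, `p_high`,
#'   `i_low`, `i_high`, `mu`, `sigma`.
#' @export
fit_normalization <- function(values, p_low = 0.5, p_high = 99.5) {
  values <- as.numeric(values)
  if (length(unique(values)) < 2L)
    stop("constant input: normalization is undefined (sigma = 0)")
  qs <- stats::quantile(values, c(p_low, p_high) / 100, names = FALSE,
                        type = 7)
  clipped <- pmin(pmax(values, qs[1]), qs[2])
  sigma <- stats::sd(clipped)
  if (sigma == 0) stop("clipped values are constant (sigma = 0)")
  structure(
    list(p_low = p_low, p_high = p_high, i_low = qs[1], i_high = qs[2],
         mu = mean(clipped), sigma = sigma),
    class = "normalization_spec")
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat(sprintf(
    "normalization_spec: clip [%g, %g] HU (p%.3g..p%.3g), mu %.3f, sigma %.3f\n",
    x$i_low, x$i_high, x$p_low, x$p_high, x$mu, x$sigma))
  invisible(x)
}

#' Apply percentile clipping and z-score normalization
#'
#' Clips intensities to `[i_low, i_high]` then maps x to
#' `(x - mu)/sigma`. LVC vector fields are never normalized this way --
#' their components are already in `[-1, 1]` -- so `apply_normalization`
#' refuses `lvc_map` input.
#'
#' @param vol a [ct_volume()] (or bare numeric array/vector).
#' @param spec a `normalization_spec` from [fit_normalization()].
#' @return Object of the same shape with normalized intensities.
#' @export
apply_normalization <- function(vol, spec) {
  if (inherits(vol, "lvc_map"))
    stop("LVC maps are not intensity-normalized; components are already in [-1, 1]")
  if (spec$sigma <= 0) stop("sigma must be positive")
  tf <- function(x) (pmin(pmax(x, spec$i_low), spec$i_high) - spec$mu) / spec$sigma
  if (inherits(vol, "ct_volume"))
    ct_volume(tf(vol$values), vol$spacing, vol$origin)
  else tf(vol)
}

#' Weighted multitask loss combination
#'
#' The global training loss of the two-decoder (lobe + fissure)
#' configuration: `w_lobe * l_lobe + w_fissure * l_fissure`, default
#' weights (0.7, 0.3), with (0.5, 0.5) and (0.9, 0.1) as the standard
#' ablation settings.
#'
#' @param l_lobe,l_fissure nonnegative single-task loss values.
#' @param weights numeric length-2 `(w_lobe, w_fissure)` summing to 1.
#' @return Combined loss value.
#' @export
combined_loss <- function(l_lobe, l_fissure, weights = c(0.7, 0.3)) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(l_lobe < 0) || any(l_fissure < 0)) stop("losses must be nonnegative")
  weights[1] * l_lobe + weights[2] * l_fissure
}
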