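#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`. When both masks are empty the score is 1.0
#' by convention (perfect agreement on absence), so batch tables never
#' propagate NaN.
#'
#' @param a,b logical 3D arrays of equal dims.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dims do not match")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Surface voxels of a binary mask
#'
#' A mask voxel is on the surface when at least one of its six
#' face-adjacent neighbours is outside the mask; the grid border counts
#' as outside.
#'
#' @param mask logical 3D array.
#' @return Logical array marking surface voxels.
#' @export
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_and <- function(acc, ax, by) {
    padded <- array(FALSE, dim = d)
    src <- dst <- lapply(d, seq_len)
    if (by == 1L) { dst[[ax]] <- seq_len(d[ax] - 1L); src[[ax]] <- 2:d[ax] }
    else          { dst[[ax]] <- 2:d[ax]; src[[ax]] <- seq_len(d[ax] - 1L) }
    padded[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    acc & padded
  }
  for (ax in 1:3) for (by in c(1L, -1L))
    interior <- shift_and(interior, ax, by)
  mask & !interior
}

#' Average surface distance (symmetric)
#'
#' Mean distance in mm between the boundary surfaces of two masks:
#' the average of (mean distance from each surface voxel of A to the
#' nearest surface voxel of B) and the reverse direction. Distances are
#' Euclidean in world units via the voxel spacing.
#'
#' @param a,b nonempty logical 3D arrays of equal dims.
#' @param spacing voxel spacing (mm), default isotropic 1 mm.
#' @return ASD in mm.
#' @export
asd <- function(a, b, spacing = c(1, 1, 1)) {
  if (!identical(dim(a), dim(b))) stop("mask dims do not match")
  if (sum(a) == 0 || sum(b) == 0)
    stop("ASD is undefined for an empty mask")
  sa <- surface_voxels(a); sb <- surface_voxels(b)
  d <- dim(a)
  dist_to_b <- array(.edt(as.logical(sb), d, as.numeric(spacing)), dim = d)
  dist_to_a <- array(.edt(as.logical(sa), d, as.numeric(spacing)), dim = d)
  (mean(dist_to_b[sa]) + mean(dist_to_a[sb])) / 2
}

#' Per-lobe segmentation report
#'
#' Dice and ASD for each of the five lobes plus unweighted global means,
#' mirroring the usual by-lobe-and-global presentation of lobe
#' segmentation results. A lobe empty in both maps is skipped (noted in
#' the `note` column) and excluded from the global means; a lobe empty
#' in exactly one map gets Dice 0 and an NA ASD.
#'
#' @param pred,gt [lobe_label_map()]s of equal dims.
#' @param spacing voxel spacing (mm); defaults to the ground truth's.
#' @return A list of class `metrics_report` with `per_lobe` (data.frame:
#'   `lobe`, `dice`, `asd_mm`, `note`), `global_dice`, `global_asd`.
#' @export
per_lobe_report <- function(pred, gt, spacing = NULL) {
  if (!identical(as.integer(pred$dims), as.integer(gt$dims)))
    stop("label map dims do not match")
  if (is.null(spacing)) spacing <- gt$spacing
  nm <- lobe_names()
  rows <- lapply(seq_along(nm), function(j) {
    pm <- pred$labels == nm[j]
    gm <- gt$labels == nm[j]
    if (sum(pm) == 0 && sum(gm) == 0)
      return(data.frame(lobe = names(nm)[j], dice = NA_real_,
                        asd_mm = NA_real_, note = "empty in both",
                        stringsAsFactors = FALSE))
    d <- dice(pm, gm)
    a <- if (sum(pm) > 0 && sum(gm) > 0) asd(pm, gm, spacing) else NA_real_
    data.frame(lobe = names(nm)[j], dice = d, asd_mm = a, note = "",
               stringsAsFactors = FALSE)
  })
  per_lobe <- do.call(rbind, rows)
  structure(
    list(per_lobe = per_lobe,
         global_dice = mean(per_lobe$dice, na.rm = TRUE),
         global_asd = mean(per_lobe$asd_mm, na.rm = TRUE)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-lobe segmentation metrics:\n")
  print(x$per_lobe, row.names = FALSE)
  cat(sprintf("Global (unweighted): Dice %.4f, ASD %.3f mm\n",
              x$global_dice, x$global_asd))
  invisible(x)
}

#' Paired t-test on per-case metrics
#'
#' Two-sided paired t-test comparing two matched series of per-case
#' scores (e.g. per-subject Dice under two models). The reported
#' `mean_diff` is `mean(x - y)`: positive favours `x` for Dice,
#' negative favours `x` for ASD.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `t`, `p`, `mean_diff`, `n`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("paired series must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x - y) == 0) stop("zero-variance differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = mean(x - y), n = length(x))
}

#' Fissure mask from lobe labels
#'
#' Derives a fissure (inter-lobar boundary sheet) mask: voxels of either
#' lobe in an anatomically adjacent pair that touch the other lobe of
#' the pair across a face. Lung-background interfaces are excluded.
#' Default pairs cover the left oblique (LU|LL), right oblique (RU|RL
#' and RM|RL) and right horizontal (RU|RM) fissures.
#'
#' @param lobes a [lobe_label_map()].
#' @param pairs list of character pairs of lobe names.
#' @return Logical 3D array of fissure voxels.
#' @export
fissure_from_lobes <- function(lobes,
                               pairs = list(c("LU", "LL"), c("RU", "RL"),
                                            c("RM", "RL"), c("RU", "RM"))) {
  lab <- lobes$labels
  d <- dim(lab)
  nm <- lobe_names()
  touches <- function(mask_a, mask_b) {
    # voxels of mask_a with a face-adjacent voxel in mask_b
    out <- array(FALSE, dim = d)
    for (ax in 1:3) for (by in c(1L, -1L)) {
      shifted <- array(FALSE, dim = d)
      src <- dst <- lapply(d, seq_len)
      if (by == 1L) { dst[[ax]] <- seq_len(d[ax] - 1L); src[[ax]] <- 2:d[ax] }
      else          { dst[[ax]] <- 2:d[ax]; src[[ax]] <- seq_len(d[ax] - 1L) }
      shifted[dst[[1]], dst[[2]], dst[[3]]] <-
        mask_b[src[[1]], src[[2]], src[[3]]]
      out <- out | (mask_a & shifted)
    }
    out
  }
  fis <- array(FALSE, dim = d)
  for (p in pairs) {
    a <- lab == nm[[p[1]]]
    b <- lab == nm[[p[2]]]
    fis <- fis | touches(a, b) | touches(b, a)
  }
  fis
}
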