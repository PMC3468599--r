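# Lateralization-index curves: LI(t) = (T_a(t) - T_b(t)) / (T_a(t) + T_b(t))
# with T_x(t) the mean of the statistic map thresholded at t inside ROI x,
# evaluated over an ascending ladder of twenty thresholds and summarized by
# median, MAD, min and max.

#' Mean of a statistic map above a threshold within an ROI
#'
#' Mean of the statistic values strictly exceeding \code{t} among the
#' ROI's voxels; 0 when no voxel survives (the "no detection" convention
#' that gives the lateralization index its +/-1 endpoints).
#'
#' @param tmap statistic \code{gm_volume}.
#' @param roi logical \code{gm_volume}, nonempty.
#' @param t threshold (statistic units).
#' @return nonnegative scalar.
#' @export
roi_mean_above <- function(tmap, roi, t) {
  stop_if_grid_mismatch(tmap, roi, "tmap/roi")
  idx <- which(roi$data)
  if (!length(idx)) stop("ROI mask is empty")
  v <- tmap$data[idx]
  v <- v[!is.na(v) & v > t]
  if (!length(v)) 0 else mean(v)
}

#' Lateralization index from two ROI means
#'
#' \code{(T_a - T_b) / (T_a + T_b)}: ranges from -1 (detection only in
#' b) to +1 (detection only in a); undefined (NA) when both means are 0.
#'
#' @param t_a,t_b nonnegative mean suprathreshold statistics for the two
#'   ROIs (e.g. left/right or anterior/posterior).
#' @return scalar in \[-1, 1\], or NA when \code{t_a + t_b == 0}.
#' @export
li_value <- function(t_a, t_b) {
  if (t_a < 0 || t_b < 0)
    stop("ROI means must be nonnegative (suprathreshold positive statistics)")
  s <- t_a + t_b
  if (s == 0) return(NA_real_)
  (t_a - t_b) / s
}

#' Lateralization-index curve over a threshold ladder
#'
#' Evaluates the index at \code{n_thresholds} ascending thresholds
#' \code{t_i = (i / n) * M}, i = 0 ... n-1, with M the maximum statistic
#' over the union of the two ROIs (the top threshold is excluded so at
#' least the peak voxel survives the last rung). Undefined rungs (no
#' detection in either ROI) are recorded as NA. The curve carries a
#' median/MAD/min/max summary over its defined values.
#'
#' @param tmap statistic \code{gm_volume}.
#' @param roi_a,roi_b disjoint logical \code{gm_volume} ROIs on the same
#'   grid (a = left or anterior; b = right or posterior).
#' @param n_thresholds ladder length (default 20).
#' @param kind label for the contrast, e.g. \code{"L-R"} or \code{"A-P"}.
#' @return object of class \code{li_curve}: data.frame \code{curve}
#'   (\code{index}, \code{threshold}, \code{li}, \code{defined},
#'   \code{t_a}, \code{t_b}), \code{kind}, \code{summary} (from
#'   \code{\link{summarize_li_curve}}).
#' @export
li_curve <- function(tmap, roi_a, roi_b, n_thresholds = 20L,
                     kind = "L-R") {
  stop_if_grid_mismatch(roi_a, roi_b, "ROIs")
  stop_if_grid_mismatch(tmap, roi_a, "tmap/ROI")
  if (any(roi_a$data & roi_b$data)) stop("ROIs must be disjoint")
  if (n_thresholds < 1L) stop("need at least one threshold")
  vals <- tmap$data[roi_a$data | roi_b$data]
  vals <- vals[is.finite(vals)]
  m <- if (length(vals)) max(vals) else -Inf
  if (!is.finite(m) || m <= 0)
    stop("no detection: maximum statistic over the ROI union is not positive")
  th <- (seq_len(n_thresholds) - 1L) / n_thresholds * m
  rows <- lapply(seq_along(th), function(i) {
    ta <- roi_mean_above(tmap, roi_a, th[i])
    tb <- roi_mean_above(tmap, roi_b, th[i])
    li <- li_value(ta, tb)
    data.frame(index = i, threshold = th[i], li = li,
               defined = !is.na(li), t_a = ta, t_b = tb)
  })
  curve <- do.call(rbind, rows)
  out <- structure(list(curve = curve, kind = kind), class = "li_curve")
  out$summary <- summarize_li_curve(out)
  out
}

#' Summarize a lateralization-index curve
#'
#' Median, unscaled median absolute deviation
#' (median(|LI - median(LI)|), no normal-consistency factor), minimum and
#' maximum, over the curve's defined values only.
#'
#' @param curve an \code{li_curve} (or its \code{curve} data.frame).
#' @return named list: \code{median}, \code{mad}, \code{min}, \code{max},
#'   \code{n_defined}.
#' @export
summarize_li_curve <- function(curve) {
  df <- if (inherits(curve, "li_curve")) curve$curve else curve
  v <- df$li[df$defined]
  if (!length(v))
    stop("cannot summarize: the curve has no defined LI values")
  med <- stats::median(v)
  list(median = med, mad = stats::median(abs(v - med)),
       min = min(v), max = max(v), n_defined = length(v))
}

#' @export
print.li_curve <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<li_curve %s> %d thresholds (%d defined): median %.3f, MAD %.3f, range [%.3f, %.3f]\n",
    x$kind, nrow(x$curve), s$n_defined, s$median, s$mad, s$min, s$max))
  invisible(x)
}

#' @export
plot.li_curve <- function(x, ...) {
  df <- x$curve
  graphics::plot(df$threshold, df$li, type = "b", pch = 16,
                 ylim = c(-1, 1), xlab = "statistic threshold t",
                 ylab = sprintf("LI(%s)", x$kind), ...)
  graphics::abline(h = 0, lty = 2, col = "gray50")
  invisible(x)
}

#' Split an ROI into anterior and posterior parts at a coronal plane
#'
#' Anterior = voxels with world y strictly greater than the plane;
#' posterior = the rest; together they partition the ROI. An empty side
#' raises a warning (the index then degenerates to +/-1), not an error.
#'
#' @param roi logical \code{gm_volume}.
#' @param y_plane_mm coronal plane in world y mm (the classical
#'   equal-volume hippocampal split sits at Talairach y = -20).
#' @return list with \code{anterior} and \code{posterior} masks.
#' @export
split_roi_ap <- function(roi, y_plane_mm = -20) {
  if (!any(roi$data)) stop("ROI mask is empty")
  ys <- world_coord_array(roi, 2)
  ant <- roi$data & ys > y_plane_mm
  post <- roi$data & ys <= y_plane_mm
  if (!any(ant) || !any(post))
    warning("one side of the anterior/posterior split is empty")
  list(anterior = gm_volume(ant, roi$affine, roi$space),
       posterior = gm_volume(post, roi$affine, roi$space))
}

#' Coronal plane splitting an ROI into two equal halves
#'
#' Searches candidate planes (midpoints between consecutive distinct voxel
#' y coordinates) for the split minimizing the anterior/posterior voxel
#' count difference.
#'
#' @param roi logical \code{gm_volume}.
#' @return the world-y plane (mm).
#' @export
equal_volume_plane <- function(roi) {
  if (!any(roi$data)) stop("ROI mask is empty")
  ys <- sort(unique(world_coord_array(roi, 2)[roi$data]))
  if (length(ys) == 1L) return(ys)
  cand <- (ys[-1] + ys[-length(ys)]) / 2
  yy <- world_coord_array(roi, 2)[roi$data]
  imb <- vapply(cand, function(p) abs(sum(yy > p) - sum(yy <= p)),
                numeric(1))
  cand[which.min(imb)]
}
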