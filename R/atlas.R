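# Synthetic ROI atlas: mirror-symmetric ellipsoidal "hippocampi" on the
# simulation grid, each split into anterior/posterior at a coronal plane.
# Fixed mm geometry; errors out if the grid cannot contain it.

.hippo_geometry <- function() {
  list(center_left  = c(-14, -20, -6),
       center_right = c( 14, -20, -6),
       semi_axes    = c(6, 10, 6))
}

#' Build the synthetic ROI atlas
#'
#' Constructs left and right hippocampus masks as ellipsoids
#' mirror-symmetric about the x = 0 sagittal plane, plus
#' anterior/posterior subdivisions of each at the configured coronal
#' world-y plane, and an integer label volume (0 background, 1 left,
#' 2 right).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{labels} (integer \code{gm_volume}),
#'   \code{masks} (named list of logical \code{gm_volume}s:
#'   \code{hippocampus-left}, \code{hippocampus-right} and their
#'   \code{-anterior}/\code{-posterior} subdivisions), and
#'   \code{ap_plane_mm}.
#' @export
make_roi_atlas <- function(config) {
  aff <- sim_affine(config$grid_shape, config$voxel_size_mm)
  geom <- .hippo_geometry()
  half_extent <- config$voxel_size_mm * (config$grid_shape - 1) / 2
  need <- abs(geom$center_right) + geom$semi_axes
  if (any(need > half_extent))
    stop(sprintf(
      "grid too small to fit ROI ellipsoids: needs +/- (%s) mm, grid spans +/- (%s) mm",
      paste(need, collapse = ", "),
      paste(half_extent, collapse = ", ")))

  proto <- gm_volume(array(0, dim = config$grid_shape), aff)
  xs <- world_coord_array(proto, 1)
  ys <- world_coord_array(proto, 2)
  zs <- world_coord_array(proto, 3)

  in_ellipsoid <- function(center) {
    ((xs - center[1]) / geom$semi_axes[1])^2 +
      ((ys - center[2]) / geom$semi_axes[2])^2 +
      ((zs - center[3]) / geom$semi_axes[3])^2 <= 1
  }
  left  <- in_ellipsoid(geom$center_left)
  right <- in_ellipsoid(geom$center_right)
  if (!any(left) || !any(right))
    stop("grid too coarse: an ROI ellipsoid contains no voxel centers")

  plane <- config$ap_plane_mm
  ant <- ys > plane
  masks <- list(
    "hippocampus-left"            = left,
    "hippocampus-right"           = right,
    "hippocampus-left-anterior"   = left & ant,
    "hippocampus-left-posterior"  = left & !ant,
    "hippocampus-right-anterior"  = right & ant,
    "hippocampus-right-posterior" = right & !ant
  )
  masks <- lapply(masks, function(m) gm_volume(m, aff))
  labels <- array(0L, dim = config$grid_shape)
  labels[left] <- 1L
  labels[right] <- 2L
  list(labels = gm_volume(labels, aff), masks = masks,
       ap_plane_mm = plane)
}

#' Smooth anatomical baseline template
#'
#' A radially symmetric "head" profile built from a superposition of
#' Gaussians: one broad component plus two lateral temporal bumps, giving
#' nonnegative gray-matter-like values with a plausible dynamic range on
#' the simulation grid.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{gm_volume} of baseline GM values.
#' @export
baseline_template <- function(config) {
  aff <- sim_affine(config$grid_shape, config$voxel_size_mm)
  proto <- gm_volume(array(0, dim = config$grid_shape), aff)
  xs <- world_coord_array(proto, 1)
  ys <- world_coord_array(proto, 2)
  zs <- world_coord_array(proto, 3)
  g <- function(cx, cy, cz, sig, amp)
    amp * exp(-((xs - cx)^2 + (ys - cy)^2 + (zs - cz)^2) / (2 * sig^2))
  tmpl <- g(0, 0, 0, 22, 0.65) +
    g(-16, -16, -6, 10, 0.15) +
    g(16, -16, -6, 10, 0.15)
  gm_volume(tmpl, aff)
}
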