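# Cluster-level reporting: connected components with an extent filter,
# peak statistics and coordinates, MNI -> Talairach conversion, and
# per-region voxel counts against an atlas.

.neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(g != 0)
  keep <- switch(as.character(connectivity),
    "6" = nz == 1,
    "18" = nz >= 1 & nz <= 2,
    "26" = nz >= 1,
    stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Extract suprathreshold clusters with an extent filter
#'
#' Connected components of the suprathreshold map (18-connectivity by
#' default: faces + edges), dropping components smaller than \code{k}
#' voxels. Clusters are sorted by size descending (ties: higher peak t
#' first); each cluster's peak is its highest-t voxel, ties broken by the
#' smallest linear index.
#'
#' @param suprathreshold logical \code{gm_volume} (e.g. from
#'   \code{\link{threshold_map}}).
#' @param tmap statistic \code{gm_volume} on the same grid.
#' @param k nonnegative minimum cluster extent in voxels (the classical
#'   VBM default is 50).
#' @param connectivity 6, 18 or 26.
#' @return list of clusters; each is a list with \code{voxels} (n x 3
#'   matrix of 1-based array indices), \code{indices} (linear), \code{size},
#'   \code{peak_ijk} (1-based), \code{peak_t}, \code{peak_mm} (world
#'   coordinates of the peak).
#' @export
extract_clusters <- function(suprathreshold, tmap, k = 50L,
                             connectivity = 18L) {
  if (k < 0) stop("extent threshold k must be nonnegative")
  stop_if_grid_mismatch(suprathreshold, tmap, "suprathreshold/tmap")
  d <- dim(suprathreshold$data)
  supra <- suprathreshold$data
  lab <- array(0L, dim = d)
  offs <- .neighbor_offsets(connectivity)
  seeds <- which(supra)
  comp <- list()
  for (s in seeds) {
    if (lab[s] != 0L) next
    id <- length(comp) + 1L
    lab[s] <- id
    frontier <- s
    members <- s
    while (length(frontier)) {
      ai <- arrayInd(frontier, d)
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
        sweep(ai, 2, offs[o, ], `+`)))
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + d[1] * (cand[, 2] - 1) +
                      d[1] * d[2] * (cand[, 3] - 1))
      lin <- lin[supra[lin] & lab[lin] == 0L]
      lab[lin] <- id
      members <- c(members, lin)
      frontier <- lin
    }
    comp[[id]] <- sort(members)
  }
  comp <- comp[vapply(comp, length, integer(1)) >= k]
  clusters <- lapply(comp, function(idx) {
    tv <- tmap$data[idx]
    tv[is.na(tv)] <- -Inf
    best <- idx[tv == max(tv)][1]  # ties: smallest linear index
    pk <- arrayInd(best, d)[1, ]
    list(voxels = arrayInd(idx, d), indices = idx, size = length(idx),
         peak_ijk = pk, peak_t = tmap$data[best],
         peak_mm = voxel_to_world(tmap$affine, pk - 1))
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "size"),
               -vapply(clusters, `[[`, numeric(1), "peak_t"))
  clusters[ord]
}

#' Convert MNI coordinates to Talairach coordinates
#'
#' The standard piecewise-affine pose/scale correction: a common rotation
#' and x/y scaling with a different z scaling above and below the axial
#' z = 0 plane. The origin is a fixed point, and superior coordinates are
#' compressed. \code{passthrough = TRUE} returns the input unchanged, for
#' simulated native-space data that lives in no standard space.
#'
#' @param xyz length-3 vector or n x 3 matrix of MNI mm coordinates.
#' @param passthrough if TRUE, identity transform.
#' @return coordinates in Talairach mm, same shape as input.
#' @export
mni_to_talairach <- function(xyz, passthrough = FALSE) {
  if (passthrough) return(xyz)
  up <- matrix(c(0.9900, 0,       0,
                 0,      0.9688,  0.0460,
                 0,     -0.0485,  0.9189), 3, 3, byrow = TRUE)
  down <- matrix(c(0.9900, 0,       0,
                   0,      0.9688,  0.0420,
                   0,     -0.0485,  0.8390), 3, 3, byrow = TRUE)
  one <- is.null(dim(xyz))
  m <- if (one) matrix(xyz, 1, 3) else as.matrix(xyz)
  below <- m[, 3] < 0
  out <- m
  if (any(!below)) out[!below, ] <- m[!below, , drop = FALSE] %*% t(up)
  if (any(below)) out[below, ] <- m[below, , drop = FALSE] %*% t(down)
  if (one) drop(out) else out
}

#' Per-region breakdown of one cluster against an atlas
#'
#' Intersects the cluster's voxel set with each atlas mask and counts
#' voxels per region, plus an \code{"unlabeled"} remainder; counts always
#' sum to the cluster size. The atlas masks must partition (no overlap).
#'
#' @param cluster one cluster from \code{\link{extract_clusters}}.
#' @param atlas named list of logical \code{gm_volume} masks.
#' @return data.frame with columns \code{region}, \code{n_voxels}.
#' @export
label_cluster <- function(cluster, atlas) {
  if (!length(atlas)) stop("empty atlas")
  overlap <- Reduce(`+`, lapply(atlas, function(m) m$data * 1L))
  if (any(overlap > 1L))
    stop("atlas masks overlap; the atlas must partition the labeled voxels")
  idx <- cluster$indices
  counts <- vapply(atlas, function(m) sum(m$data[idx]), numeric(1))
  out <- data.frame(region = names(atlas), n_voxels = as.integer(counts))
  out <- rbind(out, data.frame(
    region = "unlabeled",
    n_voxels = cluster$size - as.integer(sum(counts))))
  out[out$n_voxels > 0 | out$region != "unlabeled", , drop = FALSE]
}

#' Suprathreshold extent inside a hippocampus mask
#'
#' Counts suprathreshold voxels inside the given side's mask and reports
#' the min/max of their (optionally Talairach-converted) world y
#' coordinates, the per-side involvement summary of a cluster table.
#'
#' @param suprathreshold logical \code{gm_volume}.
#' @param side_mask logical \code{gm_volume} ROI.
#' @param talairach convert world y through
#'   \code{\link{mni_to_talairach}}; use FALSE for native simulated space.
#' @return list with \code{n_voxels} and \code{y_range} (length-2 numeric,
#'   or NULL when no voxel survives).
#' @export
hippocampal_extent <- function(suprathreshold, side_mask,
                               talairach = FALSE) {
  stop_if_grid_mismatch(suprathreshold, side_mask, "map/mask")
  idx <- which(suprathreshold$data & side_mask$data)
  if (!length(idx)) return(list(n_voxels = 0L, y_range = NULL))
  ijk <- arrayInd(idx, dim(side_mask$data))
  mm <- voxel_to_world(side_mask$affine, ijk - 1)
  if (talairach) mm <- mni_to_talairach(mm)
  list(n_voxels = length(idx), y_range = range(mm[, 2]))
}

#' Tabulate clusters in the style of a VBM results table
#'
#' One row per cluster x region: region label, extent k, peak coordinates
#' (world mm, optionally Talairach) and peak T.
#'
#' @param clusters list from \code{\link{extract_clusters}}.
#' @param atlas named list of masks (see \code{\link{label_cluster}});
#'   NULL for no breakdown.
#' @param talairach convert peak coordinates to Talairach space.
#' @return data.frame with columns \code{cluster}, \code{region},
#'   \code{n_voxels}, \code{k}, \code{x}, \code{y}, \code{z}, \code{T}.
#' @export
cluster_table <- function(clusters, atlas = NULL, talairach = FALSE) {
  if (!length(clusters))
    return(data.frame(cluster = integer(), region = character(),
                      n_voxels = integer(), k = integer(), x = numeric(),
                      y = numeric(), z = numeric(), T = numeric()))
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    xyz <- if (talairach) mni_to_talairach(cl$peak_mm) else cl$peak_mm
    br <- if (is.null(atlas))
      data.frame(region = "all", n_voxels = cl$size)
    else label_cluster(cl, atlas)
    data.frame(cluster = i, region = br$region, n_voxels = br$n_voxels,
               k = cl$size, x = xyz[1], y = xyz[2], z = xyz[3],
               T = cl$peak_t)
  })
  do.call(rbind, rows)
}
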