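#' 3-D scalar volume with a voxel-to-world affine
#'
#' The basic spatial container of the package: a 3-D numeric array plus a
#' 4x4 voxel-to-world affine in mm (RAS orientation). Voxel indices in the
#' affine convention are 0-based, as in the NIfTI standard; R array indexing
#' remains 1-based.
#'
#' @param data 3-D numeric or logical array.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices
#'   \code{(i,j,k,1)} to world mm coordinates. Must be invertible.
#' @param space character space tag, e.g. \code{"native-sim"} or
#'   \code{"MNI-aligned"}.
#' @return An object of class \code{gm_volume}.
#' @export
gm_volume <- function(data, affine, space = "native-sim") {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  structure(list(data = data, affine = affine, space = space),
            class = "gm_volume")
}

#' @rdname gm_volume
#' @param x object to test.
#' @export
is_gm_volume <- function(x) inherits(x, "gm_volume")

#' @export
print.gm_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size_mm(x)
  cat(sprintf("<gm_volume> %d x %d x %d voxels, voxel size %s mm, space %s\n",
              d[1], d[2], d[3], paste(signif(vs, 4), collapse = " x "),
              x$space))
  invisible(x)
}

#' @export
dim.gm_volume <- function(x) dim(x$data)

#' Voxel size in mm along each axis
#'
#' @param vol a \code{gm_volume}.
#' @return numeric length-3 vector of voxel edge lengths in mm.
#' @export
voxel_size_mm <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Diagonal RAS affine for a simulated grid
#'
#' Places the world origin at the grid center with right-anterior-superior
#' axis order and isotropic voxels.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_size_mm positive scalar voxel edge length in mm.
#' @return 4x4 affine matrix.
#' @export
sim_affine <- function(grid_shape, voxel_size_mm) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            voxel_size_mm > 0)
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  # 0-based voxel (s-1)/2 maps to world 0
  aff[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  aff
}

#' Map voxel indices to world coordinates
#'
#' Applies the homogeneous product \code{affine \%*\% c(i, j, k, 1)} with
#' 0-based voxel indices (NIfTI convention).
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk numeric length-3 vector or n x 3 matrix of 0-based voxel
#'   indices.
#' @return world mm coordinates, same shape as \code{ijk}.
#' @export
voxel_to_world <- function(affine, ijk) {
  if (is.null(dim(ijk))) {
    drop(affine %*% c(ijk, 1))[1:3]
  } else {
    h <- cbind(ijk, 1)
    out <- h %*% t(affine)
    out[, 1:3, drop = FALSE]
  }
}

#' @rdname voxel_to_world
#' @param xyz world mm coordinates, length-3 vector or n x 3 matrix.
#' @export
world_to_voxel <- function(affine, xyz) {
  voxel_to_world(solve(affine), xyz)
}

#' World coordinate of every voxel along one axis
#'
#' Returns a 3-D array (matching the grid) holding the world mm coordinate
#' of each voxel center along the requested axis. Used for plane splits and
#' coordinate reporting.
#'
#' @param vol a \code{gm_volume}.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return 3-D numeric array of world coordinates.
#' @export
world_coord_array <- function(vol, axis) {
  stopifnot(axis %in% 1:3)
  d <- dim(vol$data)
  ii <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), dim = d)
  jj <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
              dim = d)
  kk <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), dim = d)
  a <- vol$affine
  a[axis, 1] * ii + a[axis, 2] * jj + a[axis, 3] * kk + a[axis, 4]
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @param space space tag to attach.
#' @return a \code{gm_volume}.
#' @export
read_volume <- function(path, space = "native-sim") {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  gm_volume(array(as.numeric(img), dim = dim(img)[1:3]),
            matrix(aff, 4, 4), space = space)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a \code{gm_volume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data * 1)  # logical -> numeric
  # pixdim must be set before the xforms or RNifti renormalizes the scales
  img <- RNifti::`pixdim<-`(img, voxel_size_mm(vol))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s have mismatched grids: %s vs %s", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  if (max(abs(a$affine - b$affine)) > 1e-6)
    stop(sprintf("%s have mismatched affines", what))
  invisible(TRUE)
}
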