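# Mass-univariate core: Gaussian smoothing, design construction, voxelwise
# OLS with t-contrasts, analysis masking and voxel-level thresholding.

.gauss_kernel_1d <- function(sigma_vox) {
  r <- ceiling(4 * sigma_vox)
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

.shift_zero <- function(a, k, axis) {
  # shift array by k voxels along axis, zero fill
  if (k == 0) return(a)
  d <- dim(a)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  idx_src <- idx_dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(do.call(`[`, c(list(a), idx_src)))))
  out
}

#' Smooth a volume with an isotropic Gaussian kernel
#'
#' Separable convolution with a Gaussian of the given full width at half
#' maximum in mm, converted per axis to voxel units
#' (sigma = fwhm / (2 sqrt(2 ln 2)) / voxel size). Borders are
#' zero-padded; grid and affine are unchanged. Axes where the FWHM is
#' below half a voxel are left untouched (identity limit).
#'
#' @param vol a \code{gm_volume}.
#' @param fwhm_mm positive full width at half maximum (mm).
#' @return the smoothed \code{gm_volume}.
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  vs <- voxel_size_mm(vol)
  a <- vol$data * 1
  for (axis in 1:3) {
    if (fwhm_mm < vs[axis] / 2) next
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs[axis]
    k <- .gauss_kernel_1d(sigma)
    r <- (length(k) - 1L) / 2L
    acc <- array(0, dim = dim(a))
    for (off in (-r):r)
      acc <- acc + k[off + r + 1L] * .shift_zero(a, off, axis)
    a <- acc
  }
  gm_volume(a, vol$affine, vol$space)
}

#' Build a GLM design matrix
#'
#' Intercept + covariate of interest + requested nuisance regressors.
#' Categorical nuisances (group, sex) are coded as 0/1 indicators. The
#' design is checked for full column rank; collinear pairs are named in
#' the error.
#'
#' @param cohort covariate data.frame with columns \code{subject_id},
#'   \code{group}, \code{age}, \code{sex}, \code{icv_mm3} as needed.
#' @param scores numeric covariate of interest, one value per cohort row
#'   (row order defines subject/volume order throughout).
#' @param nuisances character vector drawn from
#'   \code{c("group", "age", "icv", "sex")}; empty for none.
#' @return list of class \code{glm_design}: \code{X} (N x p matrix),
#'   \code{roles} (per-column role), \code{interest_col} (column index of
#'   the covariate of interest), \code{df} (residual df N - p).
#' @export
build_design <- function(cohort, scores,
                         nuisances = c("group", "age", "icv", "sex")) {
  n <- nrow(cohort)
  if (length(scores) != n)
    stop("scores must have one value per cohort row")
  cols <- list(intercept = rep(1, n), interest = as.numeric(scores))
  roles <- c("intercept", "interest")
  for (nu in nuisances) {
    v <- switch(nu,
      group = as.numeric(factor(cohort$group)) - 1,
      age = as.numeric(cohort$age),
      icv = as.numeric(cohort$icv_mm3),
      sex = as.numeric(factor(cohort$sex)) - 1,
      stop(sprintf("unknown nuisance role '%s'", nu)))
    cols[[nu]] <- v
    roles <- c(roles, paste0("nuisance:", nu))
  }
  X <- do.call(cbind, cols)
  rk <- qr(X)$rank
  if (rk < ncol(X)) {
    cc <- abs(stats::cor(X[, -1, drop = FALSE]))
    diag(cc) <- 0
    bad <- which(cc > 1 - 1e-10, arr.ind = TRUE)
    pair <- if (nrow(bad)) paste(colnames(X)[-1][bad[1, ]], collapse = " ~ ")
            else "unknown pair"
    stop(sprintf("design matrix is rank deficient (collinear columns: %s)",
                 pair))
  }
  structure(list(X = X, roles = roles, interest_col = 2L, df = n - ncol(X)),
            class = "glm_design")
}

#' Fit OLS with a t-contrast on a response matrix
#'
#' The matrix engine behind \code{\link{fit_voxelwise}}: ordinary least
#' squares of every column of \code{Y} on \code{X}, with
#' t = c'beta / sqrt(sigma2 c'(X'X)^-1 c) and residual df = N - rank(X).
#' Zero-residual-variance columns get t = +/-Inf (sign of the contrast
#' estimate; 0 when the estimate is 0) and are flagged.
#'
#' @param Y numeric N x V response matrix (V voxels).
#' @param X N x p design matrix of full column rank.
#' @param contrast numeric length-p contrast weights.
#' @return list: \code{beta} (p x V), \code{cb}, \code{t}, \code{p}
#'   (one-sided, positive direction), \code{sigma2}, \code{df},
#'   \code{zero_var} (logical V).
#' @export
glm_fit_matrix <- function(Y, X, contrast) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("Y and X row counts differ")
  if (length(contrast) != ncol(X))
    stop("contrast length must equal the number of design columns")
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - qr(X)$rank
  if (df < 1) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  cb <- drop(contrast %*% beta)
  zero_var <- sigma2 <= 1e-24 * pmax(colMeans(Y^2), 1e-300)
  tt <- cb / sqrt(sigma2 * cvar)
  tt[zero_var] <- sign(cb[zero_var]) * Inf
  tt[zero_var & cb == 0] <- 0
  p <- stats::pt(tt, df, lower.tail = FALSE)
  list(beta = beta, cb = cb, t = tt, p = p, sigma2 = sigma2, df = df,
       zero_var = zero_var)
}

#' Voxelwise GLM t-contrast over a set of volumes
#'
#' Fits the design at every in-mask voxel by OLS and forms the t map for
#' the given contrast. The default test is one-sided in the positive
#' direction (gray matter increasing with the score, the directional
#' hypothesis of a volume-behavior correlation analysis); set
#' \code{sided = 2} for two-sided p values.
#'
#' @param volumes list of \code{gm_volume}, one per design row, all on one
#'   grid.
#' @param design a \code{glm_design} from \code{\link{build_design}}.
#' @param contrast contrast weights; default picks out the covariate of
#'   interest.
#' @param mask logical \code{gm_volume} analysis mask (e.g. from
#'   \code{\link{make_analysis_mask}}).
#' @param sided 1 (one-sided, positive) or 2 (two-sided).
#' @return object of class \code{t_contrast}: \code{t}, \code{p} maps and
#'   \code{beta} (interest-coefficient map) as \code{gm_volume}s,
#'   \code{df}, \code{mask}, \code{zero_var} map, \code{n_mask},
#'   \code{sided}, \code{design}.
#' @export
fit_voxelwise <- function(volumes, design, contrast = NULL, mask,
                          sided = 1) {
  if (length(volumes) != nrow(design$X))
    stop("number of volumes must match design rows")
  for (v in volumes) stop_if_grid_mismatch(v, mask, "volumes/mask")
  if (is.null(contrast)) {
    contrast <- rep(0, ncol(design$X))
    contrast[design$interest_col] <- 1
  }
  m <- which(mask$data)
  if (!length(m)) stop("analysis mask is empty")
  Y <- vapply(volumes, function(v) v$data[m], numeric(length(m)))
  fit <- glm_fit_matrix(t(Y), design$X, contrast)
  if (any(fit$zero_var))
    warning(sprintf("%d in-mask voxels have zero residual variance; t set to +/-Inf",
                    sum(fit$zero_var)))
  p <- if (sided == 2) 2 * stats::pt(abs(fit$t), fit$df, lower.tail = FALSE)
       else fit$p
  blank <- function(fill = NA_real_) array(fill, dim = dim(mask$data))
  tmap <- blank(); tmap[m] <- fit$t
  pmap <- blank(); pmap[m] <- p
  bmap <- blank()
  bmap[m] <- fit$beta[design$interest_col, ]
  zv <- array(FALSE, dim = dim(mask$data)); zv[m] <- fit$zero_var
  structure(list(
    t = gm_volume(tmap, mask$affine, mask$space),
    p = gm_volume(pmap, mask$affine, mask$space),
    beta = gm_volume(bmap, mask$affine, mask$space),
    df = fit$df, mask = mask,
    zero_var = gm_volume(zv, mask$affine, mask$space),
    n_mask = length(m), sided = sided,
    design = design, contrast = contrast), class = "t_contrast")
}

#' @export
print.t_contrast <- function(x, ...) {
  cat(sprintf("<t_contrast> df = %d, %d in-mask voxels, %s-sided, peak t = %.3f\n",
              x$df, x$n_mask, ifelse(x$sided == 2, "two", "one"),
              suppressWarnings(max(x$t$data[is.finite(x$t$data)],
                                   na.rm = TRUE))))
  invisible(x)
}

#' Across-subject analysis mask
#'
#' Voxels whose mean gray-matter value across subjects exceeds an absolute
#' threshold (default 0.1 GM units), the usual absolute-masking rule for
#' modulated GM analyses.
#'
#' @param volumes list of \code{gm_volume}.
#' @param threshold absolute mean-GM cutoff (strict).
#' @return logical \code{gm_volume}.
#' @export
make_analysis_mask <- function(volumes, threshold = 0.1) {
  if (!length(volumes)) stop("need at least one volume")
  acc <- volumes[[1]]$data * 0
  for (v in volumes) {
    stop_if_grid_mismatch(v, volumes[[1]])
    acc <- acc + v$data
  }
  m <- (acc / length(volumes)) > threshold
  if (!any(m)) stop("analysis mask is empty at this threshold")
  gm_volume(m, volumes[[1]]$affine, volumes[[1]]$space)
}

#' Voxel-level thresholding of a t-contrast
#'
#' Marks in-mask voxels surviving the chosen voxelwise criterion:
#' \code{"uncorrected"} (p < alpha), \code{"bonferroni"}
#' (p < alpha / m, m = in-mask voxel count) or \code{"fdr"}
#' (Benjamini-Hochberg step-up over the in-mask one-sided p values).
#' Cluster extent is deliberately not applied here (see
#' \code{\link{extract_clusters}}). Zero-residual-variance voxels (p = 0)
#' survive every criterion but are excluded from the FDR ranking so they
#' cannot distort the step-up order.
#'
#' @param result a \code{t_contrast}.
#' @param method one of \code{"uncorrected"}, \code{"fdr"},
#'   \code{"bonferroni"}.
#' @param alpha significance level in (0, 1).
#' @return logical \code{gm_volume} of surviving voxels.
#' @export
threshold_map <- function(result, method = c("uncorrected", "fdr",
                                             "bonferroni"),
                          alpha = 0.005) {
  method <- match.arg(method)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  m <- which(result$mask$data)
  p <- result$p$data[m]
  zv <- result$zero_var$data[m]
  keep <- switch(method,
    uncorrected = p < alpha,
    bonferroni = p < alpha / length(m),
    fdr = {
      k <- rep(FALSE, length(m))
      ranked <- which(!zv)
      if (length(ranked))
        k[ranked] <- stats::p.adjust(p[ranked], method = "BH") < alpha
      k[zv] <- TRUE
      k
    })
  out <- array(FALSE, dim = dim(result$mask$data))
  out[m[keep]] <- TRUE
  gm_volume(out, result$mask$affine, result$mask$space)
}
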