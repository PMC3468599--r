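# End-to-end orchestration: simulate (or load) -> behavioral stats ->
# voxelwise GLM per score column -> threshold -> clusters -> LI curves,
# with per-stage logging and a JSON run manifest.

#' Pipeline run configuration
#'
#' @param sim a \code{\link{sim_config}} describing the synthetic cohort
#'   (alternatively supply \code{inputs}, a list with \code{covariates_csv},
#'   \code{scores_csv}, volume paths taken from the covariates table, and
#'   \code{mask_paths}, a named list of ROI mask NIfTIs).
#' @param score_columns score columns to analyze in independent GLMs.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 disables smoothing).
#' @param nuisances nuisance regressors for \code{\link{build_design}}.
#' @param sided 1 (one-sided positive) or 2.
#' @param mask_threshold absolute mean-GM cutoff for the analysis mask.
#' @param threshold_method,alpha,k voxelwise threshold and cluster extent,
#'   see \code{\link{threshold_map}} and \code{\link{extract_clusters}}.
#' @param n_li_thresholds LI ladder length.
#' @param talairach report cluster/extent coordinates in Talairach space
#'   (FALSE for simulated native-space data).
#' @param out_dir output directory (NULL: nothing written).
#' @param seed run seed; overrides the sim config's seed.
#' @param inputs see \code{sim}.
#' @return a \code{run_config} list.
#' @export
run_config <- function(sim = sim_config(),
                       score_columns = c("total", paste0("period", 1:5)),
                       fwhm_mm = 12, nuisances = c("group", "age", "icv",
                                                   "sex"),
                       sided = 1, mask_threshold = 0.1,
                       threshold_method = "uncorrected", alpha = 0.005,
                       k = 50L, n_li_thresholds = 20L, talairach = FALSE,
                       out_dir = NULL, seed = NULL, inputs = NULL) {
  ok_cols <- c("total", paste0("period", 1:5))
  if (!all(score_columns %in% ok_cols))
    stop("score_columns must be drawn from 'total', 'period1'..'period5'")
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, inputs = inputs,
                 score_columns = score_columns, fwhm_mm = fwhm_mm,
                 nuisances = nuisances, sided = sided,
                 mask_threshold = mask_threshold,
                 threshold_method = threshold_method, alpha = alpha,
                 k = as.integer(k),
                 n_li_thresholds = as.integer(n_li_thresholds),
                 talairach = talairach, out_dir = out_dir,
                 seed = if (is.null(seed)) sim$seed else as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline config from YAML
#'
#' Top-level keys mirror \code{\link{run_config}}; the \code{sim} key
#' holds \code{\link{sim_config}} fields.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    for (nm in c("effect_slopes", "group_atrophy"))
      if (!is.null(raw$sim[[nm]])) raw$sim[[nm]] <- unlist(raw$sim[[nm]])
    raw$sim <- do.call(sim_config,
                       raw$sim[intersect(names(raw$sim),
                                         names(formals(sim_config)))])
  }
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.log_line <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

.load_inputs <- function(inputs) {
  cohort <- utils::read.csv(inputs$covariates_csv,
                            stringsAsFactors = FALSE)
  scores <- utils::read.csv(inputs$scores_csv, stringsAsFactors = FALSE)
  volumes <- lapply(cohort$path, read_volume)
  names(volumes) <- cohort$subject_id
  masks <- lapply(inputs$mask_paths, function(p) {
    v <- read_volume(p)
    gm_volume(v$data > 0.5, v$affine, v$space)
  })
  list(cohort = cohort, scores = scores,
       score_table = mct_score_table(scores), volumes = volumes,
       atlas = list(masks = masks))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, runs the behavioral statistics, then for
#' each requested score column fits an independent voxelwise GLM with that
#' score as the covariate of interest, thresholds it, extracts clusters,
#' measures hippocampal extents and computes four LI curves (left-right
#' whole hippocampus, anterior-posterior within each hippocampus, and
#' left-right over the posterior parts). Returns (and optionally writes)
#' all results plus a JSON-serializable run manifest.
#'
#' @param config a \code{\link{run_config}}.
#' @param verbose log one line per stage.
#' @return list with \code{data}, \code{behavior}, \code{imaging} (one
#'   entry per score column: \code{fit}, \code{supra}, \code{clusters},
#'   \code{cluster_table}, \code{extents}, \code{li}), and
#'   \code{manifest}.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  data <- .stage("simulate", {
    if (!is.null(config$inputs)) .load_inputs(config$inputs)
    else generate_cohort(config$sim,
                         dir = if (!is.null(config$out_dir))
                           file.path(config$out_dir, "cohort"))
  })
  stab <- data$score_table
  n <- nrow(stab)
  .log_line(verbose, "simulate: %d subjects, grid %s", n,
            paste(dim(data$volumes[[1]]$data), collapse = "x"))

  behavior <- .stage("behave", {
    anc <- ancova_group(stab$total, stab$group, data$cohort$age)
    rma <- rm_anova_group_by_period(
      as.matrix(stab[, paste0("period", 1:5)]), stab$group,
      data$cohort$age)
    cell_means <- tapply(
      unlist(stab[, paste0("period", 1:5)]),
      list(group = rep(stab$group, times = 5),
           period = rep(1:5, each = n)), mean)
    within <- rma[rma$effect == "group:period", ]
    ng <- table(stab$group)
    lsd <- do.call(rbind, lapply(1:5, function(p) {
      m <- stats::setNames(cell_means[, p], rownames(cell_means))
      cbind(period = p, fisher_lsd(m, within$mse, within$df2, as.vector(ng)))
    }))
    list(ancova = anc, rm_anova = rma, lsd = lsd,
         group_means = tapply(stab$total, stab$group, mean))
  })
  .log_line(verbose,
            "behave: group F(%d,%d) = %.2f", behavior$ancova$df1,
            behavior$ancova$df2, behavior$ancova$F)

  smoothed <- .stage("smooth", {
    if (config$fwhm_mm > 0)
      lapply(data$volumes, smooth_volume, fwhm_mm = config$fwhm_mm)
    else data$volumes
  })
  mask <- .stage("mask", make_analysis_mask(smoothed,
                                            config$mask_threshold))
  .log_line(verbose, "mask: %d voxels", sum(mask$data))

  hip_l <- data$atlas$masks[["hippocampus-left"]]
  hip_r <- data$atlas$masks[["hippocampus-right"]]
  ap_plane <- if (!is.null(data$atlas$ap_plane_mm))
    data$atlas$ap_plane_mm else -20
  lsplit <- split_roi_ap(hip_l, ap_plane)
  rsplit <- split_roi_ap(hip_r, ap_plane)
  # labeling atlas must partition: use the four A/P quadrants
  label_atlas <- list(
    "hippocampus-left-anterior" = lsplit$anterior,
    "hippocampus-left-posterior" = lsplit$posterior,
    "hippocampus-right-anterior" = rsplit$anterior,
    "hippocampus-right-posterior" = rsplit$posterior)

  imaging <- list()
  stage_counts <- list()
  for (sc in config$score_columns) {
    res <- .stage(paste0("vbm:", sc), {
      design <- build_design(data$cohort, stab[[sc]], config$nuisances)
      fit <- fit_voxelwise(smoothed, design, mask = mask,
                           sided = config$sided)
      supra <- threshold_map(fit, config$threshold_method, config$alpha)
      clusters <- extract_clusters(supra, fit$t, k = config$k)
      ctab <- cluster_table(clusters, label_atlas,
                            talairach = config$talairach)
      ext <- list(
        left = hippocampal_extent(supra, hip_l, config$talairach),
        right = hippocampal_extent(supra, hip_r, config$talairach))
      li_pairs <- list(
        "L-R" = list(a = hip_l, b = hip_r),
        "A-P-left" = list(a = lsplit$anterior, b = lsplit$posterior),
        "A-P-right" = list(a = rsplit$anterior, b = rsplit$posterior),
        "L-R-posterior" = list(a = lsplit$posterior, b = rsplit$posterior))
      li <- Map(function(pair, kind) tryCatch(
        li_curve(fit$t, pair$a, pair$b, config$n_li_thresholds,
                 kind = kind),
        error = function(e) NULL),  # "no detection" is a data outcome
        li_pairs, names(li_pairs))
      list(fit = fit, supra = supra, clusters = clusters,
           cluster_table = ctab, extents = ext, li = li)
    })
    stage_counts[[sc]] <- list(
      n_supra = sum(res$supra$data), n_clusters = length(res$clusters),
      df = res$fit$df)
    .log_line(verbose, "vbm:%s: df %d, %d supra voxels, %d clusters",
              sc, res$fit$df, sum(res$supra$data), length(res$clusters))
    imaging[[sc]] <- res
  }

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_for_hash, tf, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- list(
    config_hash = cfg_hash, seed = config$seed,
    version = as.character(utils::packageVersion("vbmli")),
    n_subjects = n, mask_voxels = sum(mask$data),
    stages = stage_counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  out <- list(data = data, behavior = behavior, mask = mask,
              imaging = imaging, manifest = manifest)
  if (!is.null(config$out_dir)) .write_outputs(out, config)
  out
}

.write_outputs <- function(out, config) {
  d <- config$out_dir
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  bh <- out$behavior
  stats_tab <- rbind(
    cbind(analysis = "ancova_total", bh$ancova),
    cbind(analysis = "rm_anova", bh$rm_anova))
  utils::write.csv(stats_tab, file.path(d, "behavior_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(bh$lsd, file.path(d, "behavior_lsd.csv"),
                   row.names = FALSE)
  for (sc in names(out$imaging)) {
    res <- out$imaging[[sc]]
    sd <- file.path(d, sc)
    dir.create(sd, showWarnings = FALSE)
    write_volume(res$fit$t, file.path(sd, "tmap.nii.gz"))
    write_volume(res$fit$p, file.path(sd, "pmap.nii.gz"))
    write_volume(res$fit$beta, file.path(sd, "beta.nii.gz"))
    write_volume(res$supra, file.path(sd, "suprathreshold.nii.gz"))
    utils::write.csv(res$cluster_table, file.path(sd, "clusters.csv"),
                     row.names = FALSE)
    ext <- do.call(rbind, lapply(names(res$extents), function(side) {
      e <- res$extents[[side]]
      data.frame(side = side, n_voxels = e$n_voxels,
                 y_min = if (is.null(e$y_range)) NA else e$y_range[1],
                 y_max = if (is.null(e$y_range)) NA else e$y_range[2])
    }))
    utils::write.csv(ext, file.path(sd, "hippocampal_extent.csv"),
                     row.names = FALSE)
    curves <- do.call(rbind, lapply(names(res$li), function(kind) {
      cv <- res$li[[kind]]
      if (is.null(cv)) return(NULL)
      cbind(contrast = kind, cv$curve)
    }))
    if (!is.null(curves))
      utils::write.csv(curves, file.path(sd, "li_curves.csv"),
                       row.names = FALSE)
    summaries <- do.call(rbind, lapply(names(res$li), function(kind) {
      cv <- res$li[[kind]]
      s <- if (is.null(cv))
        list(median = NA, mad = NA, min = NA, max = NA, n_defined = 0L)
      else cv$summary
      data.frame(contrast = kind, score = sc, median = s$median,
                 mad = s$mad, min = s$min, max = s$max,
                 n_defined = s$n_defined)
    }))
    utils::write.csv(summaries, file.path(sd, "li_summary.csv"),
                     row.names = FALSE)
  }
  # manifest: design/threshold provenance sidecar
  jsonlite::write_json(out$manifest, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(d)
}
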