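#' Generate cue-word autobiographical memory scores
#'
#' Draws integer scores (0-5) for 6 cues x 5 life periods per subject from
#' a truncated, discretized normal: per cue-period score =
#' round(period mean + subject shift + cue noise), clamped to the 0-5
#' support. The subject shift (one draw per subject) induces
#' between-subject spread of the totals; the per-group period means come
#' from the configured score profile.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with columns \code{subject_id}, \code{group}
#'   (\code{"patient"}/\code{"control"}), \code{cue} (1-6), \code{period}
#'   (1-5), \code{score} (0-5); 30 rows per subject. Patients first.
#' @export
generate_mct_scores <- function(config) {
  set.seed(config$seed)
  n <- c(patient = config$n_patients, control = config$n_controls)
  prof <- list(patient = config$score_profile$patients,
               control = config$score_profile$controls)
  out <- list()
  for (grp in names(n)) {
    pr <- prof[[grp]]
    if (any(pr$mean < 0 | pr$mean > 5))
      stop("score profile target means must lie in [0, 5]")
    for (s in seq_len(n[[grp]])) {
      sid <- sprintf("%s%02d", ifelse(grp == "patient", "P", "C"), s)
      shift <- stats::rnorm(1, 0, pr$subject_sd)
      grid <- expand.grid(cue = 1:6, period = 1:5)
      raw <- pr$mean[grid$period] + shift +
        stats::rnorm(nrow(grid), 0, pr$cue_sd)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = grp, cue = grid$cue,
        period = grid$period,
        score = pmin(5L, pmax(0L, as.integer(round(raw)))))
    }
  }
  do.call(rbind, out)
}

#' Per-subject score table from long records
#'
#' Collapses 30-row score records to one row per subject with the total
#' (0-150) and the five period scores (0-30 each).
#'
#' @param records long score data.frame as from
#'   \code{\link{generate_mct_scores}}.
#' @return data.frame with columns \code{subject_id}, \code{total},
#'   \code{period1} ... \code{period5} (and \code{group} if present in
#'   the records).
#' @export
mct_score_table <- function(records) {
  ids <- unique(records$subject_id)
  rows <- lapply(ids, function(sid) {
    per <- vapply(1:5, function(p) mct_period_score(records, sid, p),
                  integer(1))
    data.frame(subject_id = sid, total = sum(per),
               period1 = per[1], period2 = per[2], period3 = per[3],
               period4 = per[4], period5 = per[5])
  })
  tab <- do.call(rbind, rows)
  if ("group" %in% names(records)) {
    grp <- records$group[match(tab$subject_id, records$subject_id)]
    tab <- cbind(tab[, "subject_id", drop = FALSE], group = grp,
                 tab[, -1, drop = FALSE])
  }
  tab
}

#' Generate a full synthetic cohort with planted structure
#'
#' Produces aligned modulated-gray-matter-like volumes: each subject's
#' volume is the smooth baseline template, plus, per configured region,
#' slope x (coupled score - cohort mean score), plus group-level atrophy
#' offsets for patients, plus i.i.d. Gaussian voxel noise, clipped at 0.
#' Covariates (age, sex, intracranial volume) are drawn per group.
#' Everything is reproducible from the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir optional output directory; when given, writes per-subject
#'   NIfTI volumes, \code{covariates.csv}, \code{scores.csv}, the
#'   ground-truth slope map and label volume as NIfTI, and
#'   \code{ground_truth.json}.
#' @return list with \code{cohort} (covariate data.frame), \code{scores}
#'   (long records), \code{score_table}, \code{volumes} (named list of
#'   \code{gm_volume}), \code{atlas}, \code{template} and \code{truth}
#'   (list: \code{slope_map}, \code{effect_score}, \code{group_atrophy},
#'   \code{score_center}).
#' @export
generate_cohort <- function(config, dir = NULL) {
  atlas <- make_roi_atlas(config)
  template <- baseline_template(config)

  scores <- generate_mct_scores(config)  # seeds the RNG stream
  stab <- mct_score_table(scores)
  n_tot <- nrow(stab)

  is_pat <- stab$group == "patient"
  age <- ifelse(is_pat, stats::rnorm(n_tot, 73, 6),
                stats::rnorm(n_tot, 69, 5))
  age <- round(pmin(90, pmax(55, age)), 1)
  sex <- sample(c("F", "M"), n_tot, replace = TRUE)
  icv <- round(stats::rnorm(n_tot, 1.40e6, 1.0e5) +
                 ifelse(sex == "M", 1.2e5, 0))
  cohort <- data.frame(subject_id = stab$subject_id, group = stab$group,
                       age = age, sex = sex, icv_mm3 = icv,
                       path = NA_character_)

  # planted effect layout
  for (r in unique(c(names(config$effect_slopes),
                     names(config$group_atrophy))))
    if (!r %in% names(atlas$masks))
      stop(sprintf("unknown region label '%s' in config", r))
  slope_map <- array(0, dim = config$grid_shape)
  for (r in names(config$effect_slopes))
    slope_map[atlas$masks[[r]]$data] <- config$effect_slopes[[r]]
  atrophy_map <- array(0, dim = config$grid_shape)
  for (r in names(config$group_atrophy))
    atrophy_map[atlas$masks[[r]]$data] <- config$group_atrophy[[r]]

  score_vec <- stab[[config$effect_score]]
  score_center <- mean(score_vec)

  volumes <- vector("list", n_tot)
  names(volumes) <- stab$subject_id
  for (i in seq_len(n_tot)) {
    v <- template$data +
      slope_map * (score_vec[i] - score_center) +
      if (is_pat[i]) atrophy_map else 0
    if (config$noise_sd > 0)
      v <- v + array(stats::rnorm(length(v), 0, config$noise_sd),
                     dim = dim(v))
    volumes[[i]] <- gm_volume(pmax(v, 0), template$affine)
  }

  truth <- list(slope_map = gm_volume(slope_map, template$affine),
                effect_score = config$effect_score,
                group_atrophy = as.list(config$group_atrophy),
                score_center = score_center)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_tot)) {
      p <- file.path(dir, paste0(stab$subject_id[i], "_gm.nii.gz"))
      write_volume(volumes[[i]], p)
      cohort$path[i] <- p
    }
    utils::write.csv(cohort, file.path(dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(scores, file.path(dir, "scores.csv"),
                     row.names = FALSE)
    write_volume(truth$slope_map, file.path(dir, "truth_slope_map.nii.gz"))
    write_volume(atlas$labels, file.path(dir, "atlas_labels.nii.gz"))
    jsonlite::write_json(
      list(effect_score = truth$effect_score,
           group_atrophy = truth$group_atrophy,
           score_center = truth$score_center,
           effect_slopes = as.list(config$effect_slopes)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }

  list(cohort = cohort, scores = scores, score_table = stab,
       volumes = volumes, atlas = atlas, template = template,
       truth = truth)
}
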