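#' Default behavioral score profile
#'
#' Per-group generative parameters for cue-word autobiographical memory
#' scores: a per-period mean score on the 0-5 scale (one value per life
#' period: 0-9 y, 10-29 y, 30-59 y, after 60 y, previous year), a per-cue
#' residual SD, and a subject-level random-shift SD that induces
#' between-subject spread of the totals.
#'
#' The default controls profile is flat-high with a childhood dip; the
#' default patients profile is graded 10-29 > 30-59 > after-60 > previous
#' year, with a childhood dip as well. With these settings simulated group
#' totals center near 121 (controls) and 71 (patients).
#'
#' @return named list with elements \code{controls} and \code{patients},
#'   each a list \code{mean} (length 5, values in \[0,5\]), \code{cue_sd},
#'   \code{subject_sd}.
#' @export
default_score_profile <- function() {
  list(
    controls = list(mean = c(3.6, 4.2, 4.1, 4.1, 4.2),
                    cue_sd = 0.7, subject_sd = 0.28),
    patients = list(mean = c(2.1, 3.1, 2.5, 2.2, 1.9),
                    cue_sd = 1.0, subject_sd = 0.95)
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator: grid geometry,
#' group sizes, voxel noise, planted score-volume couplings, group-level
#' atrophy, the behavioral score profile and the seed.
#'
#' @param grid_shape integer length-3, each dimension >= 16.
#' @param voxel_size_mm positive voxel edge length (mm).
#' @param n_patients,n_controls group sizes; total must be >= 4.
#' @param noise_sd nonnegative SD of additive i.i.d. Gaussian voxel noise
#'   (gray-matter units).
#' @param effect_slopes named numeric vector mapping region label (an
#'   atlas mask name, e.g. \code{"hippocampus-left"}) to the planted slope
#'   in GM units per point of the coupled score.
#' @param effect_score which score column the planted slopes couple to:
#'   \code{"total"} or \code{"period1"} ... \code{"period5"}.
#' @param group_atrophy named numeric vector mapping region label to the GM
#'   offset added for patients (negative = atrophy).
#' @param score_profile per-group score generator parameters, see
#'   \code{\link{default_score_profile}}.
#' @param ap_plane_mm world-y coordinate of the coronal plane splitting each
#'   hippocampus into anterior (y > plane) and posterior (y <= plane).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   output.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(grid_shape = c(32L, 32L, 32L),
                       voxel_size_mm = 2,
                       n_patients = 15L,
                       n_controls = 11L,
                       noise_sd = 0.05,
                       effect_slopes = c("hippocampus-left" = 0.002),
                       effect_score = "total",
                       group_atrophy = c("hippocampus-left" = -0.06,
                                         "hippocampus-right" = -0.06),
                       score_profile = default_score_profile(),
                       ap_plane_mm = -20,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be three integers, each >= 16")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  n_patients <- as.integer(n_patients)
  n_controls <- as.integer(n_controls)
  if (n_patients < 1L || n_controls < 1L)
    stop("both groups must be nonempty")
  if (n_patients + n_controls < 4L)
    stop("need at least 4 subjects in total")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!effect_score %in% c("total", paste0("period", 1:5)))
    stop("effect_score must be 'total' or 'period1'..'period5'")
  for (g in names(score_profile)) {
    pr <- score_profile[[g]]
    if (length(pr$mean) != 5L || any(pr$mean < 0) || any(pr$mean > 5))
      stop("score_profile means must be 5 values in [0, 5] per group")
    if (pr$cue_sd < 0 || pr$subject_sd < 0)
      stop("score_profile SDs must be nonnegative")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_patients = n_patients, n_controls = n_controls,
                 noise_sd = noise_sd, effect_slopes = effect_slopes,
                 effect_score = effect_score, group_atrophy = group_atrophy,
                 score_profile = score_profile, ap_plane_mm = ap_plane_mm,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation config from YAML or JSON
#'
#' The file mirrors the fields of \code{\link{sim_config}}; missing fields
#' take the defaults.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  raw <- raw[intersect(names(raw), known)]
  for (nm in c("effect_slopes", "group_atrophy"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}
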