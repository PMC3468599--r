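# Behavioral module: cue-word autobiographical memory (6 cues x 5 life
# periods, each memory scored 0-5 for episodic specificity; total 0-150),
# ANCOVA with age covariate, mixed group x period ANOVA, Fisher's LSD.

.subject_records <- function(records, subject) {
  r <- records[records$subject_id == subject, , drop = FALSE]
  if (nrow(r) == 0L) stop(sprintf("no records for subject '%s'", subject))
  r
}

.check_complete <- function(r, subject) {
  key <- paste(r$cue, r$period)
  if (anyDuplicated(key))
    stop(sprintf("duplicate cue x period rows for subject '%s'", subject))
  want <- paste(rep(1:6, times = 5), rep(1:5, each = 6))
  miss <- setdiff(want, key)
  if (length(miss))
    stop(sprintf("incomplete records for subject '%s': %d of 30 cells missing",
                 subject, length(miss)))
  if (!all(r$score %in% 0:5))
    stop("scores must be integers in 0..5")
  invisible(TRUE)
}

#' Total raw memory score for one subject
#'
#' Sum of all 30 cue x period scores; lies in \[0, 150\].
#'
#' @param records long score data.frame (\code{subject_id}, \code{cue},
#'   \code{period}, \code{score}).
#' @param subject subject identifier.
#' @return integer total.
#' @export
mct_total_score <- function(records, subject) {
  r <- .subject_records(records, subject)
  .check_complete(r, subject)
  as.integer(sum(r$score))
}

#' Per-period memory score for one subject
#'
#' Sum over the 6 cues of one life period; lies in \[0, 30\].
#'
#' @inheritParams mct_total_score
#' @param period life period index 1-5 (1 = 0-9 y, 2 = 10-29 y,
#'   3 = 30-59 y, 4 = after 60 y, 5 = previous year).
#' @return integer period score.
#' @export
mct_period_score <- function(records, subject, period) {
  if (!(length(period) == 1L && period %in% 1:5))
    stop(sprintf("unknown period index '%s' (must be 1..5)",
                 paste(period, collapse = ",")))
  r <- .subject_records(records, subject)
  .check_complete(r, subject)
  as.integer(sum(r$score[r$period == period]))
}

#' One-way ANCOVA for a group effect with an age covariate
#'
#' Fits \code{score ~ group + age} by least squares and tests the group
#' effect adjusting for age (Type III: full model vs the model with the
#' group factor removed). Denominator df = N - (number of groups) - 1.
#'
#' @param totals numeric response, one value per subject.
#' @param group factor (or coercible) of group membership.
#' @param age numeric covariate.
#' @return data.frame with columns \code{effect}, \code{F}, \code{df1},
#'   \code{df2}, \code{p}, \code{mse} (the error mean square).
#' @export
ancova_group <- function(totals, group, age) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (any(table(group) < 2L)) stop("need >= 2 subjects per group")
  if (stats::var(age) == 0) stop("age covariate is constant")
  full <- stats::lm(totals ~ group + age)
  if (any(is.na(stats::coef(full))))
    stop("singular design: group and age are confounded")
  red <- stats::lm(totals ~ age)
  cmp <- stats::anova(red, full)
  df2 <- cmp$Res.Df[2]
  mse <- cmp$RSS[2] / df2
  data.frame(effect = "group", F = cmp$F[2], df1 = cmp$Df[2], df2 = df2,
             p = cmp$`Pr(>F)`[2], mse = mse)
}

#' Mixed-design ANOVA: group x life period with an age covariate
#'
#' Univariate split-plot ANOVA with period as the within-subject factor,
#' group between subjects and age as a covariate. The covariate is crossed
#' with the within-subject factor, so the within-subject error has
#' df = (periods - 1) x (N - groups - 1) -- with 26 subjects in two groups
#' this yields the (4, 92) interaction test. No sphericity correction is
#' applied.
#'
#' @param period_scores numeric matrix, subjects x 5 periods.
#' @param group factor of group membership, length = subjects.
#' @param age numeric covariate, length = subjects.
#' @return data.frame with one row per within-stratum effect
#'   (\code{period}, \code{group:period}) plus the between-stratum
#'   \code{group} effect; columns \code{effect}, \code{F}, \code{df1},
#'   \code{df2}, \code{p}, \code{mse}.
#' @export
rm_anova_group_by_period <- function(period_scores, group, age) {
  period_scores <- as.matrix(period_scores)
  if (ncol(period_scores) != 5L)
    stop("period_scores must have 5 columns (one per life period)")
  if (anyNA(period_scores)) stop("missing period cells")
  n <- nrow(period_scores)
  group <- factor(group)
  long <- data.frame(
    subject = factor(rep(seq_len(n), times = 5)),
    group = rep(group, times = 5),
    age = rep(age, times = 5),
    period = factor(rep(1:5, each = n)),
    score = as.vector(period_scores))
  fit <- stats::aov(score ~ (group + age) * period + Error(subject),
                    data = long)
  sm <- summary(fit)
  btw <- sm[["Error: subject"]][[1]]
  wth <- sm[["Error: Within"]][[1]]
  pick <- function(tab, nm) {
    i <- match(nm, trimws(rownames(tab)))
    r <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = nm, F = tab[i, "F value"], df1 = tab[i, "Df"],
               df2 = tab[r, "Df"], p = tab[i, "Pr(>F)"],
               mse = tab[r, "Mean Sq"])
  }
  rbind(pick(btw, "group"), pick(wth, "period"), pick(wth, "group:period"))
}

#' Fisher's LSD pairwise comparisons
#'
#' Unadjusted pairwise t tests of cell means against a prior ANOVA's error
#' term: t = (m_i - m_j) / sqrt(MSE (1/n_i + 1/n_j)) on the error df,
#' two-sided p. No multiplicity correction (that is what LSD means).
#'
#' @param means named numeric vector of cell means.
#' @param mse error mean square from the omnibus ANOVA (> 0).
#' @param df error degrees of freedom.
#' @param n cell sizes: scalar or vector aligned with \code{means}.
#' @return data.frame with columns \code{a}, \code{b}, \code{diff},
#'   \code{t}, \code{p}; one row per unordered pair.
#' @export
fisher_lsd <- function(means, mse, df, n) {
  if (mse <= 0) stop("error mean square must be positive")
  if (df < 1) stop("error df must be >= 1")
  k <- length(means)
  if (k < 2L) stop("need at least two cell means")
  if (length(n) == 1L) n <- rep(n, k)
  if (length(n) != k) stop("cell sizes must align with means")
  nm <- names(means)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- means[i] - means[j]
    tt <- d / sqrt(mse * (1 / n[i] + 1 / n[j]))
    data.frame(a = nm[i], b = nm[j], diff = unname(d), t = unname(tt),
               p = 2 * stats::pt(-abs(tt), df))
  })
  do.call(rbind, out)
}
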