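test_that("total and period scores sum the 6 x 5 grid correctly", {
  r <- records_from_matrix(matrix(5L, 6, 5))
  expect_identical(mct_total_score(r, "S1"), 150L)
  expect_identical(mct_period_score(r, "S1", 3), 30L)

  r0 <- records_from_matrix(matrix(0L, 6, 5))
  expect_identical(mct_total_score(r0, "S1"), 0L)
  expect_identical(mct_period_score(r0, "S1", 1), 0L)

  # cues 1-3 score 1, cues 4-6 score 2, every period: 3*5*1 + 3*5*2 = 45
  m <- matrix(rep(c(1L, 1L, 1L, 2L, 2L, 2L), 5), 6, 5)
  expect_identical(mct_total_score(records_from_matrix(m), "S1"), 45L)

  # one period scored {5,4,3,2,1,0} across cues
  m2 <- matrix(0L, 6, 5); m2[, 2] <- 5:0
  expect_identical(mct_period_score(records_from_matrix(m2), "S1", 2), 15L)

  # total is always the sum of the period scores
  set.seed(9)
  for (i in 1:10) {
    rr <- records_from_matrix(matrix(sample(0:5, 30, TRUE), 6, 5))
    per <- vapply(1:5, function(p) mct_period_score(rr, "S1", p),
                  integer(1))
    expect_identical(mct_total_score(rr, "S1"), sum(per))
  }
})

test_that("incomplete, duplicated or malformed records raise errors", {
  r <- records_from_matrix(matrix(3L, 6, 5))
  expect_error(mct_total_score(r[-1, ], "S1"), "incomplete")
  expect_error(mct_total_score(rbind(r, r[1, ]), "S1"), "duplicate")
  expect_error(mct_period_score(r, "S1", 6), "unknown period")
  expect_error(mct_total_score(r, "nobody"), "no records")
  bad <- r; bad$score[3] <- 9L
  expect_error(mct_total_score(bad, "S1"), "0..5")
})

test_that("ANCOVA group effect has df N - groups - 1 and behaves at the null", {
  set.seed(21)
  g <- rep(c("patient", "control"), c(15, 11))
  age <- rnorm(26, 70, 6)
  y <- rnorm(26, 100, 10)
  res <- ancova_group(y, g, age)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 23)

  # identical adjusted means -> F ~ 0: project the group effect out of y
  gi <- as.numeric(factor(g)) - 1
  fit <- stats::lm(y ~ gi + age)
  y0 <- y - coef(fit)["gi"] * gi
  res0 <- ancova_group(y0, g, age)
  expect_lt(res0$F, 1e-6)

  expect_error(ancova_group(y, g, rep(70, 26)), "constant")
  expect_error(ancova_group(y, rep("a", 26), age), "two groups")
})

test_that("ANCOVA F matches a from-scratch projection-matrix computation", {
  set.seed(8)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  age <- rnorm(9, 60, 5)
  y <- rnorm(9, 50, 8) + 2 * (g == "b")
  res <- ancova_group(y, g, age)

  # brute-force Type III via explicit projections
  Xf <- cbind(1, g == "b", g == "c", age)
  Xr <- cbind(1, age)
  sse <- function(X) {
    P <- X %*% solve(crossprod(X)) %*% t(X)
    drop(crossprod(y - P %*% y))
  }
  df2 <- 9 - ncol(Xf)
  Fo <- ((sse(Xr) - sse(Xf)) / 2) / (sse(Xf) / df2)
  expect_equal(res$F, Fo, tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, df2)
  expect_equal(res$p, stats::pf(Fo, 2, df2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ANCOVA F is invariant to affine re-coding of age", {
  set.seed(13)
  g <- rep(c("patient", "control"), c(7, 6))
  age <- rnorm(13, 70, 5)
  y <- rnorm(13, 90, 15)
  a <- ancova_group(y, g, age)
  b <- ancova_group(y, g, 3.7 * age - 120)
  expect_equal(a$F, b$F, tolerance = 1e-10)
})

test_that("mixed group x period ANOVA has the split-plot df structure", {
  set.seed(77)
  n <- 26
  g <- rep(c("patient", "control"), c(15, 11))
  age <- rnorm(n, 70, 6)
  ps <- matrix(rnorm(n * 5, 20, 4), n, 5)
  res <- rm_anova_group_by_period(ps, g, age)
  inter <- res[res$effect == "group:period", ]
  expect_equal(inter$df1, 4)
  expect_equal(inter$df2, 92)
  per <- res[res$effect == "period", ]
  expect_equal(per$df1, 4)
  expect_equal(per$df2, 92)
  grp <- res[res$effect == "group", ]
  expect_equal(grp$df2, 23)

  # identical period profiles in both groups: interaction exactly 0
  # (the control block duplicates the patient block cell for cell)
  half <- matrix(rnorm(13 * 5, 20, 4), 13, 5)
  ps0 <- rbind(half, half)
  g0 <- rep(c("patient", "control"), each = 13)
  res0 <- rm_anova_group_by_period(ps0, g0, rnorm(26, 70, 5))
  expect_lt(res0[res0$effect == "group:period", "F"], 1e-6)

  expect_error(rm_anova_group_by_period(ps[, 1:4], g, age), "5 columns")
  psNA <- ps; psNA[2, 3] <- NA
  expect_error(rm_anova_group_by_period(psNA, g, age), "missing")
})

test_that("interaction F equals the within-contrast decomposition", {
  set.seed(101)
  n <- 6
  g <- factor(rep(c("a", "b"), each = 3))
  age <- rnorm(n, 65, 4)
  ps <- matrix(rnorm(n * 5, 15, 3), n, 5) + 2 * (g == "b") %o% c(1:5)
  res <- rm_anova_group_by_period(ps, g, age)

  # oracle: project onto orthonormal period contrasts, accumulate
  # sequential sums of squares across the 4 contrast variables
  C <- stats::contr.poly(5)
  Z <- ps %*% C
  ssh_period <- ssh_inter <- sse <- 0
  for (j in 1:4) {
    z <- Z[, j]
    ssh_period <- ssh_period + sum(z)^2 / n
    a1 <- stats::anova(stats::lm(z ~ g + age))
    ssh_inter <- ssh_inter + a1["g", "Sum Sq"]
    sse <- sse + a1["Residuals", "Sum Sq"]
  }
  df_err <- 4 * (n - 3)
  F_inter <- (ssh_inter / 4) / (sse / df_err)
  F_period <- (ssh_period / 4) / (sse / df_err)
  expect_equal(res[res$effect == "group:period", "F"], F_inter,
               tolerance = 1e-8)
  expect_equal(res[res$effect == "period", "F"], F_period,
               tolerance = 1e-8)
  expect_equal(res[res$effect == "group:period", "df2"], df_err)
})

test_that("Fisher's LSD matches the t-distribution tail computation", {
  # delta = 2, MSE = 1, n_i = n_j = 8, df = 23
  res <- fisher_lsd(c(a = 10, b = 8), mse = 1, df = 23, n = 8)
  t_expect <- 2 / sqrt(1 * (1 / 8 + 1 / 8))
  expect_equal(res$t, t_expect, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-abs(t_expect), 23),
               tolerance = 1e-12)

  eq <- fisher_lsd(c(a = 5, b = 5), mse = 2, df = 10, n = 6)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  three <- fisher_lsd(c(a = 1, b = 2, c = 4), mse = 1.5, df = 12,
                      n = c(4, 5, 6))
  expect_equal(nrow(three), 3)
  expect_setequal(paste(three$a, three$b),
                  c("a b", "a c", "b c"))

  expect_error(fisher_lsd(c(a = 1, b = 2), mse = 0, df = 5, n = 3),
               "positive")
})

test_that("ANCOVA type-I error is calibrated at the null", {
  # null simulation: no group effect; alpha = 0.05
  set.seed(1234)
  n_rep <- 1000
  g <- rep(c("patient", "control"), c(15, 11))
  rej <- 0L
  for (i in seq_len(n_rep)) {
    age <- rnorm(26, 70, 6)
    y <- rnorm(26, 100, 15) + 0.5 * age
    if (ancova_group(y, g, age)$p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.015)
})
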