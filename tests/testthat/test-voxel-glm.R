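test_that("smoothing is identity below half a voxel and preserves constants", {
  set.seed(4)
  v <- toy_volume(array(runif(14^3), c(14, 14, 14)))
  expect_equal(smooth_volume(v, 0.9)$data, v$data)  # fwhm < voxel/2

  const <- toy_volume(array(1, c(20, 20, 20)))
  sm <- smooth_volume(const, 8)
  # interior voxels (away from the zero-padded border) unchanged
  expect_equal(sm$data[8:13, 8:13, 8:13],
               const$data[8:13, 8:13, 8:13], tolerance = 1e-12)
  expect_error(smooth_volume(v, -2), "positive")
})

test_that("impulse response matches the separable normalized Gaussian", {
  d <- c(25, 25, 25)
  imp <- array(0, d); imp[13, 13, 13] <- 1
  v <- toy_volume(imp, voxel = 2)
  sm <- smooth_volume(v, 12)
  sigma <- 12 / (2 * sqrt(2 * log(2))) / 2   # voxels
  r <- ceiling(4 * sigma)
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, -1, 0), c(-3, 2, 1))) {
    expected <- prod(w[off + r + 1])
    got <- sm$data[13 + off[1], 13 + off[2], 13 + off[3]]
    expect_equal(got, expected, tolerance = 1e-12)
  }
  expect_equal(sum(sm$data), 1, tolerance = 1e-9)  # mass conserved
})

test_that("design matrix has the documented columns, df and rank checks", {
  co <- toy_cohort(26)
  sc <- rnorm(26, 100, 20)
  des <- build_design(co, sc)
  expect_equal(ncol(des$X), 6)
  expect_equal(des$df, 20)
  expect_equal(des$roles[des$interest_col], "interest")

  des2 <- build_design(co, sc, nuisances = character(0))
  expect_equal(ncol(des2$X), 2)

  co$icv_mm3 <- 2 * co$age + 5  # collinear with age
  expect_error(build_design(co, sc), "rank deficient")
  expect_error(build_design(co, sc[1:5]), "one value per cohort row")
  expect_error(build_design(toy_cohort(8), rnorm(8),
                            nuisances = "weight"), "unknown nuisance")
})

test_that("voxelwise t map equals independent per-voxel OLS via lm", {
  set.seed(19)
  for (gd in list(c(5, 5, 5), c(9, 8, 7))) {
    n <- 20
    co <- toy_cohort(n)
    sc <- rnorm(n, 100, 20)
    des <- build_design(co, sc)
    vols <- lapply(seq_len(n), function(i)
      toy_volume(array(rnorm(prod(gd), 0.5, 0.1), gd)))
    mask <- toy_volume(array(TRUE, gd))
    fit <- fit_voxelwise(vols, des, mask = mask)
    expect_equal(fit$df, n - ncol(des$X))
    cw <- rep(0, ncol(des$X)); cw[des$interest_col] <- 1
    idx <- sample(prod(gd), 25)
    for (v in idx) {
      y <- vapply(vols, function(x) x$data[v], numeric(1))
      lmf <- stats::lm(y ~ des$X - 1)
      tval <- drop(cw %*% coef(lmf)) /
        sqrt(drop(t(cw) %*% vcov(lmf) %*% cw))
      expect_equal(fit$t$data[v], tval, tolerance = 1e-10)
      expect_equal(fit$p$data[v],
                   stats::pt(tval, fit$df, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("t map is invariant to rescaling a nuisance column", {
  set.seed(29)
  n <- 16; gd <- c(6, 6, 6)
  co <- toy_cohort(n)
  sc <- rnorm(n, 100, 20)
  vols <- lapply(seq_len(n), function(i)
    toy_volume(array(rnorm(prod(gd), 0.5, 0.1), gd)))
  mask <- toy_volume(array(TRUE, gd))
  f1 <- fit_voxelwise(vols, build_design(co, sc), mask = mask)
  co2 <- co; co2$icv_mm3 <- co$icv_mm3 / 1000  # rescale nuisance
  f2 <- fit_voxelwise(vols, build_design(co2, sc), mask = mask)
  expect_equal(f1$t$data, f2$t$data, tolerance = 1e-8)
})

test_that("noiseless planted slope is recovered exactly with infinite t", {
  cfg <- tiny_config(noise_sd = 0, group_atrophy = numeric(0),
                     effect_slopes = c("hippocampus-left" = 0.003),
                     seed = 3)
  d <- generate_cohort(cfg)
  mask <- make_analysis_mask(d$volumes)
  des <- build_design(d$cohort, d$score_table$total,
                      nuisances = c("group", "age"))
  expect_warning(
    fit <- fit_voxelwise(d$volumes, des, mask = mask),
    "zero residual variance")
  L <- d$atlas$masks[["hippocampus-left"]]$data & mask$data
  expect_true(all(fit$t$data[L] == Inf))
  expect_equal(unname(fit$beta$data[L]),
               rep(0.003, sum(L)), tolerance = 1e-10)
  # degenerate path: intercept contrast on identical volumes
  same <- lapply(1:8, function(i) d$template)
  des0 <- build_design(d$cohort[1:8, ], rnorm(8),
                       nuisances = character(0))
  expect_warning(f0 <- fit_voxelwise(same, des0, mask = mask,
                                     contrast = c(1, 0)),
                 "zero residual variance")
  expect_true(all(f0$t$data[mask$data] %in% c(Inf, 0)))
})

test_that("analysis mask follows the mean-GM threshold rule", {
  cfg <- tiny_config()
  tmpl <- baseline_template(cfg)
  m <- make_analysis_mask(list(tmpl), 0.1)
  expect_identical(m$data, tmpl$data > 0.1)
  m0 <- make_analysis_mask(list(tmpl), 0)
  expect_identical(m0$data, tmpl$data > 0)
  zero <- gm_volume(array(0, dim(tmpl$data)), tmpl$affine)
  expect_error(make_analysis_mask(list(zero)), "empty")
})

test_that("thresholding implements BH step-up and the method hierarchy", {
  # hand-worked BH example over 10 p values
  p10 <- c(0.001, 0.002, 0.003, 0.004, 0.024, 0.2, 0.3, 0.4, 0.5, 0.6)
  # step-up at alpha = 0.05: largest i with p_(i) < (i/10)*0.05 is i = 5
  # (0.024 < 0.025), so the first five survive
  d <- c(10, 1, 1)
  mask <- toy_volume(array(TRUE, d))
  res <- structure(list(
    p = toy_volume(array(p10, d)),
    t = toy_volume(array(qt(p10, 10, lower.tail = FALSE), d)),
    mask = mask, zero_var = toy_volume(array(FALSE, d)),
    df = 10, n_mask = 10, sided = 1), class = "t_contrast")
  fdr <- threshold_map(res, "fdr", 0.05)
  expect_identical(as.vector(fdr$data), rep(c(TRUE, FALSE), c(5, 5)))
  unc <- threshold_map(res, "uncorrected", 0.05)
  expect_identical(as.vector(unc$data), p10 < 0.05)
  bon <- threshold_map(res, "bonferroni", 0.05)
  expect_identical(as.vector(bon$data), p10 < 0.005)  # first four
  # nesting: bonferroni subset of fdr subset of uncorrected
  expect_true(all(bon$data <= fdr$data))
  expect_true(all(fdr$data <= unc$data))
  expect_error(threshold_map(res, "uncorrected", 1.2), "alpha")
})

test_that("suprathreshold fraction grows with planted slope magnitude", {
  frac <- vapply(c(0.0004, 0.0008, 0.0012), function(sl) {
    cfg <- tiny_config(effect_slopes = c("hippocampus-left" = sl),
                       group_atrophy = numeric(0), seed = 99)
    d <- generate_cohort(cfg)
    mask <- make_analysis_mask(d$volumes)
    des <- build_design(d$cohort, d$score_table$total)
    fit <- fit_voxelwise(d$volumes, des, mask = mask)
    supra <- threshold_map(fit, "uncorrected", 0.005)
    L <- d$atlas$masks[["hippocampus-left"]]$data
    sum(supra$data[L]) / sum(L)
  }, numeric(1))
  expect_true(frac[1] < frac[2] && frac[2] < frac[3])
})
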