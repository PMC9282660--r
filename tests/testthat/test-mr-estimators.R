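test_that("Wald ratios use the first-order delta method", {
  h <- make_h(0.10, 0.02, se_outcome = 0.01)
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$se, 0.1)
  h0 <- make_h(c(0.1, 0), c(0.02, 0.01))
  expect_warning(wr0 <- wald_ratios(h0), "zero exposure effect")
  expect_equal(nrow(wr0), 1L)
})

test_that("first-order ratio SEs are close to second-order when F is large", {
  # exposure GWAS much larger than the outcome GWAS, as in two-sample
  # practice, so exposure noise is the smaller error component
  ss <- simulate_summary_stats(sumstats_config(
    n_variants = 50, true_causal_effect = 0.25,
    n_exposure_sample = 2e7, n_outcome_sample = 2e6, seed = 44L))
  h <- harmonize(ss$exposure, ss$outcome)
  h <- h[h$action != "excluded", ]
  strong <- (h$beta_exposure / h$se_exposure)^2 > 100
  h <- h[strong, ]
  expect_gt(nrow(h), 10)
  wr <- wald_ratios(h)
  # second-order delta oracle adds the exposure-noise term
  se2 <- sqrt(h$se_outcome^2 / h$beta_exposure^2 +
                h$beta_outcome^2 * h$se_exposure^2 / h$beta_exposure^4)
  expect_true(all(abs(wr$se - se2) / se2 < 0.05))
})

test_that("IVW reduces correctly under homogeneity and matches its oracle", {
  h <- make_h(c(0.1, 0.2, 0.4), 0.30 * c(0.1, 0.2, 0.4),
              se_outcome = c(0.01, 0.02, 0.015))
  res <- mr_ivw(h)
  expect_equal(res$estimate, 0.30, tolerance = 1e-12)
  expect_equal(res$Q, 0, tolerance = 1e-20)
  expect_equal(res$se, 1 / sqrt(sum(h$beta_exposure^2 / h$se_outcome^2)))

  h2 <- make_h(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.09),
               se_outcome = c(0.01, 0.01, 0.01))
  res2 <- mr_ivw(h2)
  w <- 1 / h2$se_outcome^2
  oracle <- oracle_wls(matrix(h2$beta_exposure), h2$beta_outcome, w)
  expect_equal(res2$estimate, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("single-variant IVW is the flagged Wald ratio", {
  res <- mr_ivw(make_h(0.1, 0.03, se_outcome = 0.01))
  expect_equal(res$estimate, 0.3)
  expect_match(res$note, "single variant")
  expect_error(mr_ivw(make_h(numeric(0), numeric(0))), "no variants")
})

test_that("Egger recovers exact linear and affine structure", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  res <- mr_egger(make_h(bx, 0.4 * bx))
  expect_equal(res$estimate, 0.4, tolerance = 1e-10)
  expect_equal(res$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(res$Q, 0, tolerance = 1e-16)

  res2 <- mr_egger(make_h(bx, 0.05 + 0.4 * bx))
  expect_equal(res2$estimate, 0.4, tolerance = 1e-10)
  expect_equal(res2$egger_intercept, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("IVW and Egger equal explicit normal-equations solutions", {
  set.seed(60)
  for (i in 1:100) {
    J <- sample(3:10, 1)
    bx <- rnorm(J, 0, 0.2)
    bx[bx == 0] <- 0.1
    by <- rnorm(J, 0.3 * bx, 0.05)
    sey <- runif(J, 0.01, 0.1)
    h <- make_h(bx, by, se_outcome = sey)
    w <- 1 / sey^2

    expect_equal(mr_ivw(h)$estimate,
                 oracle_wls(matrix(bx), by, w),
                 tolerance = 1e-8, ignore_attr = TRUE)

    s <- ifelse(bx < 0, -1, 1)
    oracle <- oracle_wls(cbind(1, s * bx), s * by, w)
    eg <- mr_egger(h)
    expect_equal(c(eg$egger_intercept, eg$estimate), oracle,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("weighted median interpolates the weighted percentile rule", {
  # equal weights, ratios 0.1/0.2/0.9: percentiles 1/6, 1/2, 5/6
  h <- make_h(c(1, 1, 1), c(0.1, 0.2, 0.9), se_outcome = c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 0)$estimate, 0.2)
  # weights 0.7/0.2/0.1 on sorted ratios 0.2/0.5/0.9:
  # percentiles 0.35, 0.80, 0.95; interpolate 0.5 -> 0.3
  expect_equal(weighted_median_est(c(0.2, 0.5, 0.9), c(0.7, 0.2, 0.1)), 0.3)
  expect_error(mr_weighted_median(make_h(c(1, 1), c(1, 1)), n_boot = 0),
               "at least 3")
})

test_that("equal-weight weighted median equals the interpolated plain median", {
  set.seed(70)
  for (i in 1:20) {
    r <- rnorm(sample(3:15, 1))
    expect_equal(weighted_median_est(r, rep(1 / length(r), length(r))),
                 plain_interp_median(r), tolerance = 1e-12)
  }
})

test_that("weighted median resists 40% invalid instruments where IVW fails", {
  res <- vapply(1:30, function(s) {
    ss <- mixed_invalid_sumstats(s)
    h <- harmonize(ss$exposure, ss$outcome)
    c(mr_ivw(h)$estimate, mr_weighted_median(h, n_boot = 0)$estimate)
  }, numeric(2))
  expect_lt(abs(mean(res[2, ]) - 0.2), 0.05)   # median near truth
  expect_gt(abs(mean(res[1, ]) - 0.2), 0.05)   # IVW pulled by pleiotropy
})

test_that("mode-based estimator finds the majority cluster", {
  h <- make_h(rep(1, 5), rep(0.25, 5), se_outcome = rep(0.05, 5))
  expect_equal(mr_mode(h, n_boot = 0)$estimate, 0.25)

  set.seed(80)
  r <- c(rnorm(30, 0.2, 0.01), rnorm(20, 0.8, 0.01))
  h2 <- make_h(rep(1, 50), r, se_outcome = rep(0.05, 50))
  expect_lt(abs(mr_mode(h2, n_boot = 0)$estimate - 0.2), 0.05)
  # halving the bandwidth moves the mode by less than the cluster separation
  e1 <- mr_mode(h2, bandwidth_factor = 1, n_boot = 0)$estimate
  e2 <- mr_mode(h2, bandwidth_factor = 0.5, n_boot = 0)$estimate
  expect_lt(abs(e1 - e2), 0.6)
  expect_error(mr_mode(make_h(c(1, 1), c(1, 1)), n_boot = 0), "at least 3")
})

test_that("bootstrap SEs are seed-deterministic and positive", {
  ss <- simulate_summary_stats(sumstats_config(
    n_variants = 30, true_causal_effect = 0.2, n_exposure_sample = 1e6,
    n_outcome_sample = 1e6, seed = 91L))
  h <- harmonize(ss$exposure, ss$outcome)
  m1 <- mr_weighted_median(h, n_boot = 200, seed = 4L)
  m2 <- mr_weighted_median(h, n_boot = 200, seed = 4L)
  expect_identical(m1$se, m2$se)
  expect_gt(m1$se, 0)
  expect_true(m1$ci_low < m1$estimate && m1$estimate < m1$ci_high)
  mo <- mr_mode(h, n_boot = 100, seed = 4L)
  expect_gt(mo$se, 0)
})

test_that("all four estimators agree with the truth under valid instruments", {
  for (s in c(3L, 14L)) {
    ss <- simulate_summary_stats(sumstats_config(
      n_variants = 50, true_causal_effect = 0.2,
      n_exposure_sample = 1e7, n_outcome_sample = 1e6, seed = s))
    h <- harmonize(ss$exposure, ss$outcome)
    for (fit in list(mr_ivw(h), mr_egger(h),
                     mr_weighted_median(h, n_boot = 300, seed = s),
                     mr_mode(h, n_boot = 300, seed = s))) {
      expect_lt(abs(fit$estimate - 0.2), 2 * fit$se + 0.02)
    }
  }
})
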