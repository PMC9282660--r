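test_that("zero-noise cohorts satisfy the structural equations exactly", {
  cc <- cohort_config(n_individuals = 100,
                      effect_exposure_on_mediator = 0.5,
                      effect_mediator_on_outcome = 0.4,
                      direct_effect = 0.3,
                      covariate_effects = c(age = 0.1),
                      noise_sd_mediator = 1e-12, noise_sd_outcome = 1e-12,
                      seed = 3L)
  tab <- simulate_cohort(cc)
  z_age <- (tab$age - 54.8) / 7.4
  res_m <- tab$liver_iron - (1.2 + 0.5 * tab$alcohol_std + 0.1 * z_age)
  res_y <- tab$putamen_chi -
    (0.3 * tab$alcohol_std + 0.4 * tab$liver_iron + 0.1 * z_age)
  expect_lt(max(abs(res_m)), 1e-10)
  expect_lt(max(abs(res_y)), 1e-10)
})

test_that("drinker-status fractions match the configured proportions", {
  tab <- simulate_cohort(cohort_config(n_individuals = 20000, seed = 11L))
  frac_never <- mean(tab$drinker_status == "never")
  # binomial sampling error around 2.7%: 4 * sqrt(p(1-p)/n) ~ 0.0046
  expect_lt(abs(frac_never - 0.027), 0.005)
  expect_true(all(tab$alcohol_units_weekly[tab$drinker_status != "current"] == 0))
  expect_true(all(tab$alcohol_std[tab$drinker_status != "current"] == 0))
})

test_that("cohort simulation is seed-deterministic and leaves caller RNG alone", {
  cc <- cohort_config(n_individuals = 500, seed = 42L)
  set.seed(777); before <- .Random.seed
  t1 <- simulate_cohort(cc)
  expect_identical(before, .Random.seed)
  t2 <- simulate_cohort(cc)
  expect_identical(t1, t2)
  t3 <- simulate_cohort(cohort_config(n_individuals = 500, seed = 43L))
  expect_false(identical(t1, t3))
})

test_that("dosages are binomial in [0,2] with roughly the configured frequency", {
  tab <- simulate_cohort(cohort_config(n_individuals = 20000, seed = 2L))
  for (snp in c("rs1800562", "rs1799945", "rs855791")) {
    expect_true(all(tab[[snp]] %in% 0:2))
  }
  expect_lt(abs(mean(tab$rs855791) / 2 - 0.45), 0.02)
})

test_that("invalid cohort configurations name the offending field", {
  expect_error(cohort_config(prop_never = 0.6, prop_previous = 0.5),
               "prop_never \\+ prop_previous")
  expect_error(cohort_config(noise_sd_mediator = 0), "noise_sd_mediator")
  expect_error(cohort_config(grs_snp_freqs = c(0, 0.5, 0.5)),
               "grs_snp_freqs")
  expect_error(cohort_config(covariate_effects = c(shoe_size = 1)),
               "covariate_effects")
})

test_that("summary-stat generator returns matched variant sets with truth", {
  ss <- simulate_summary_stats(sumstats_config(n_variants = 2, seed = 5L))
  expect_equal(nrow(ss$exposure), 2L)
  expect_equal(nrow(ss$outcome), 2L)
  expect_setequal(ss$exposure$snp, ss$outcome$snp)
  expect_named(ss$truth$pleiotropy, ss$exposure$snp)
  expect_true(all(ss$truth$valid))
})

test_that("directional pleiotropy has the configured mean", {
  alphas <- unlist(lapply(1:20, function(s) {
    ss <- simulate_summary_stats(sumstats_config(
      n_variants = 50, pleiotropy_mode = "directional",
      pleiotropy_mean = 0.05, pleiotropy_sd = 0.01, seed = s))
    ss$truth$pleiotropy
  }))
  # Monte-Carlo error on 1000 draws of sd 0.01: ~0.0003; allow 4x
  expect_lt(abs(mean(alphas) - 0.05), 0.0015)
})

test_that("generated standard errors shrink as 1/sqrt(n)", {
  se_at <- function(n) {
    ss <- simulate_summary_stats(sumstats_config(
      n_variants = 50, n_exposure_sample = n, n_outcome_sample = n,
      seed = 8L))
    c(mean(ss$exposure$se), mean(ss$outcome$se))
  }
  r <- se_at(50000) / se_at(200000)
  expect_true(all(abs(r - 2) < 0.1))  # quadrupling n halves SE within 5%
})

test_that("Egger intercept on pleiotropy-free data is consistent with zero", {
  ok <- vapply(1:20, function(s) {
    ss <- simulate_summary_stats(sumstats_config(
      n_variants = 50, true_causal_effect = 0.2,
      n_exposure_sample = 941280, n_outcome_sample = 100000, seed = s))
    h <- harmonize(ss$exposure, ss$outcome)
    e <- mr_egger(h)
    abs(e$egger_intercept) < 2 * e$intercept_se
  }, logical(1))
  expect_gte(sum(ok), 18L)  # per-seed 95% check; allow binomial slack
})

test_that("under no pleiotropy IVW recovers the causal effect", {
  est <- vapply(1:200, function(s) {
    ss <- simulate_summary_stats(sumstats_config(
      n_variants = 50, true_causal_effect = 0.2,
      n_exposure_sample = 941280, n_outcome_sample = 100000, seed = s))
    mr_ivw(harmonize(ss$exposure, ss$outcome))$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.2), 0.02)
})
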