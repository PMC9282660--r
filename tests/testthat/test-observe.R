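test_that("inverse normal transform evaluates Blom fractions", {
  # qnorm((r - 3/8)/(n + 1/4)) at n = 3: fractions 0.1923, 0.5, 0.8077
  out <- inverse_normal_transform(c(-1.3, 0.0, 2.1))
  expect_equal(out, c(-0.8694, 0, 0.8694), tolerance = 1e-3)
  expect_warning(tied <- inverse_normal_transform(c(5, 5, 5, 5)),
                 "identical")
  expect_equal(tied, rep(0, 4))
  expect_error(inverse_normal_transform(c(1)), "at least 2")
})

test_that("inverse normal transform preserves order and normalizes moments", {
  x <- sort(rexp(50))
  y <- inverse_normal_transform(x)
  expect_true(all(diff(y) > 0))
  set.seed(101)
  for (i in 1:5) {
    z <- inverse_normal_transform(rlnorm(500))
    expect_lt(abs(mean(z)), 1e-10)       # symmetric rank fractions
    expect_gt(sd(z), 0.95)
    expect_lt(sd(z), 1.05)
  }
  # NAs propagate without shifting ranks of the finite values
  xna <- c(3, NA, 1, 2)
  yna <- inverse_normal_transform(xna)
  expect_true(is.na(yna[2]))
  expect_equal(yna[c(3, 4, 1)], inverse_normal_transform(c(1, 2, 3)))
})

test_that("quantile categorization uses current drinkers only", {
  res <- categorize_quantiles(1:10, rep("current", 10), k = 5)
  expect_equal(as.vector(table(res$category)[paste0("Q", 1:5)]),
               rep(2L, 5))
  expect_equal(res$reference, "Q1")

  units <- c(1:10, 0, 0)
  status <- c(rep("current", 10), "never", "previous")
  res2 <- categorize_quantiles(units, status, k = 5)
  expect_equal(as.character(res2$category[11:12]), c("never", "previous"))
  expect_equal(res2$boundaries, res$boundaries)  # never/previous excluded

  res8 <- categorize_quantiles(1:80, rep("current", 80), k = 8)
  expect_equal(as.vector(table(res8$category)[paste0("Q", 1:8)]),
               rep(10L, 8))

  expect_error(categorize_quantiles(c(1, 1, 2), rep("current", 3), k = 5),
               "k = 5")
})

test_that("linear models recover exact and noisy structure", {
  d <- data.frame(x = seq(-2, 2, length.out = 20))
  d$y <- 2 * d$x
  # exact fits trigger base R's perfect-fit warning in summary.lm
  f1 <- suppressWarnings(fit_linear_model(d, "y", "x"))
  expect_equal(f1$terms$beta[f1$terms$term == "x"], 2, tolerance = 1e-10)
  expect_lt(f1$sigma, 1e-10)

  d$y2 <- d$x + 0.5 * d$x^2
  f2 <- suppressWarnings(fit_linear_model(d, "y2", "x", quadratic = "x"))
  expect_equal(f2$terms$beta[f2$terms$term == "I(x^2)"], 0.5,
               tolerance = 1e-10)

  d$g <- factor(rep(c("a", "b"), 10))
  d$y3 <- d$x + (d$g == "b") * 1.5
  f3 <- suppressWarnings(
    fit_linear_model(d, "y3", "x", covariates = "g",
                     interactions = list(c("x", "g"))))
  expect_true("x:gb" %in% f3$terms$term)
})

test_that("OLS coefficients match the brute-force normal-equations oracle", {
  set.seed(20)
  for (i in 1:20) {
    n <- 20
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- rnorm(n)
    fit <- fit_linear_model(d, "y", "x1", covariates = c("x2", "x3"))
    X <- cbind(1, d$x1, d$x2, d$x3)
    beta_oracle <- drop(solve(t(X) %*% X) %*% t(X) %*% d$y)
    expect_equal(fit$terms$beta, beta_oracle, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("rank-deficient designs raise an error naming collinear terms", {
  d <- data.frame(x = rnorm(20))
  d$z <- 2 * d$x
  d$y <- rnorm(20)
  expect_error(fit_linear_model(d, "y", "x", covariates = "z"),
               "collinear")
  expect_error(fit_linear_model(d, "y", "nope"), "not found")
})

test_that("fitted exposure coefficient matches the mediation identity", {
  cc <- cohort_config(n_individuals = 10000,
                      effect_exposure_on_mediator = 0.5,
                      effect_mediator_on_outcome = 0.4,
                      direct_effect = 0.3, seed = 21L)
  tab <- simulate_cohort(cc)
  # mediator omitted: coefficient estimates c' + a*b
  f_tot <- fit_linear_model(tab, "putamen_chi", "alcohol_std",
                            covariates = c("age", "bmi"))
  tr <- f_tot$terms[f_tot$terms$term == "alcohol_std", ]
  expect_lt(abs(tr$beta - (0.3 + 0.5 * 0.4)), 2 * tr$se)
  # mediator included: coefficient estimates c'
  f_dir <- fit_linear_model(tab, "putamen_chi", "alcohol_std",
                            covariates = c("liver_iron", "age", "bmi"))
  td <- f_dir$terms[f_dir$terms$term == "alcohol_std", ]
  expect_lt(abs(td$beta - 0.3), 2 * td$se)
})

test_that("iron risk score is the dosage-weighted sum", {
  expect_equal(build_iron_grs(matrix(c(0, 1, 2), 1), c(0.1, 0.2, 0.3)), 0.8)
  expect_equal(build_iron_grs(matrix(0, 1, 3), c(0.1, 0.2, 0.3)), 0)
  d <- matrix(runif(30, 0, 2), 10)
  w <- c(0.33, -0.19, 0.25)
  expect_equal(build_iron_grs(d, 2 * w), 2 * build_iron_grs(d, w))
  expect_error(build_iron_grs(matrix(c(0, 1, 2.5), 1), w), "\\[0, 2\\]")
})

test_that("multiple-testing corrections match hand-computed values", {
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "bonferroni"),
               c(0.03, 0.12, 0.09))
  # BH step-up by hand: sorted p*m/rank = 0.03, 0.03, 0.03; cummin ok
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "fdr_bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_pvalues(0.2, "fdr_bh"), 0.2)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(30)
  for (i in 1:10) {
    p <- runif(25)
    adj <- adjust_pvalues(p, "fdr_bh")
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})
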