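#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((beta_Y - estimate * beta_X)^2 / se_Y^2)` with `J - 1` degrees
#' of freedom and an upper chi-square tail p-value. Under homogeneity
#' (all variants estimating the same causal effect) Q is chi-square
#' distributed.
#'
#' @param h Harmonization table from [harmonize()], J >= 2 retained
#'   variants.
#' @param estimate Pooled causal estimate (typically the IVW estimate).
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(h, estimate) {
  h <- harmonized_kept(h)
  J <- nrow(h)
  if (J < 2L) stop("Cochran's Q needs at least 2 variants", call. = FALSE)
  check_scalar_number(estimate, "estimate")
  Q <- sum((h$beta_outcome - estimate * h$beta_exposure)^2 / h$se_outcome^2)
  df <- J - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Per-variant instrument strength (F statistics)
#'
#' `F_j = (beta_X / se_X)^2`; F below 10 conventionally flags a weak
#' instrument (weak-instrument bias in two-sample MR is toward the null).
#'
#' @param exposure Summary-statistic data frame for the exposure.
#' @return List with `per_variant` (data frame `snp`, `F`, `weak`),
#'   `mean_f`, and `prop_weak` (fraction with F < 10).
#' @export
instrument_strength <- function(exposure) {
  check_summary_set(exposure, "exposure")
  f <- (exposure$beta / exposure$se)^2
  per <- data.frame(snp = exposure$snp, F = f, weak = f < 10,
                    stringsAsFactors = FALSE)
  list(per_variant = per, mean_f = mean(f), prop_weak = mean(f < 10))
}

#' Analytic power of a two-sample MR analysis
#'
#' Normal-approximation power for detecting a standardized causal effect
#' on a continuous outcome:
#' \deqn{\mathrm{power} = \Phi\left(|\,\mathrm{effect}\,|\sqrt{n\,R^2}
#'   - z_{1-\alpha/2}\right)}
#' where `n` is the outcome sample size and `R^2` the exposure variance
#' explained by the instruments. For example, with n = 29,579,
#' R^2 = 0.003 and alpha = 0.05 the power to detect a 0.25 SD effect is
#' 65.4%.
#'
#' @param n Outcome sample size.
#' @param r2 Instrument-explained exposure variance, in (0, 1).
#' @param alpha Two-sided significance level, in (0, 1).
#' @param effect Standardized causal effect (SD per SD).
#' @return Power in \[0, 1\].
#' @export
mr_power <- function(n, r2, alpha = 0.05, effect) {
  check_count(n, "n", min = 1L)
  check_scalar_number(r2, "r2", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar_number(alpha, "alpha", 0, 1, open_lower = TRUE,
                      open_upper = TRUE)
  check_scalar_number(effect, "effect")
  stats::pnorm(abs(effect) * sqrt(n * r2) - stats::qnorm(1 - alpha / 2))
}
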