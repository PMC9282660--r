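# Shared fixtures: all built in code, no files.

# A harmonization-shaped table from raw effect vectors (all retained).
make_h <- function(beta_exposure, beta_outcome, se_exposure = NULL,
                   se_outcome = NULL) {
  J <- length(beta_exposure)
  if (is.null(se_exposure)) se_exposure <- rep(0.01, J)
  if (is.null(se_outcome)) se_outcome <- rep(0.01, J)
  data.frame(snp = sprintf("rs%d", seq_len(J)),
             beta_exposure = beta_exposure, se_exposure = se_exposure,
             beta_outcome = beta_outcome, se_outcome = se_outcome,
             palindromic = rep(FALSE, J), action = rep("kept", J),
             reason = rep(NA_character_, J), stringsAsFactors = FALSE)
}

# One-row summary-statistic table in the TSV dialect.
make_ss <- function(snp, ea, oa, eaf, beta, se = 0.01, pval = 1e-10) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, stringsAsFactors = FALSE)
}

# Explicit normal-equations weighted least squares: the independent oracle
# against which IVW (no intercept) and Egger (with intercept) are checked.
oracle_wls <- function(X, y, w) {
  XtWX <- t(X) %*% (w * X)
  drop(solve(XtWX) %*% t(X) %*% (w * y))
}

# Two-sample sets with 40% of instruments invalid (directional pleiotropy),
# valid instruments carrying 60% of the total instrument R-squared.
mixed_invalid_sumstats <- function(seed) {
  v <- simulate_summary_stats(sumstats_config(
    n_variants = 30, true_causal_effect = 0.2, n_exposure_sample = 1e7,
    n_outcome_sample = 1e7, instrument_r2_total = 0.003 * 0.6,
    seed = seed))
  iv <- simulate_summary_stats(sumstats_config(
    n_variants = 20, true_causal_effect = 0.2, n_exposure_sample = 1e7,
    n_outcome_sample = 1e7, instrument_r2_total = 0.003 * 0.4,
    pleiotropy_mode = "directional", pleiotropy_mean = 0.004,
    pleiotropy_sd = 0.001, seed = seed + 60000L))
  iv$exposure$snp <- iv$outcome$snp <- paste0(iv$exposure$snp, "b")
  list(exposure = rbind(v$exposure, iv$exposure),
       outcome = rbind(v$outcome, iv$outcome))
}

# Interpolated ordinary median matching the weighted-median percentile rule
# at equal weights (independent reference implementation).
plain_interp_median <- function(r) {
  r <- sort(r); n <- length(r)
  p <- (seq_len(n) - 0.5) / n
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}
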