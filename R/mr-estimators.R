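new_mr_result <- function(method, estimate, se, n_variants,
                          Q = NA_real_, Q_df = NA_integer_,
                          Q_pval = NA_real_,
                          egger_intercept = NA_real_,
                          intercept_se = NA_real_,
                          intercept_pval = NA_real_,
                          note = NA_character_) {
  z <- stats::qnorm(0.975)
  structure(list(
    method = method, estimate = estimate, se = se,
    ci_low = estimate - z * se, ci_high = estimate + z * se,
    pval = if (is.finite(se) && se > 0)
      2 * stats::pnorm(-abs(estimate / se)) else NA_real_,
    n_variants = as.integer(n_variants),
    Q = Q, Q_df = Q_df, Q_pval = Q_pval,
    egger_intercept = egger_intercept, intercept_se = intercept_se,
    intercept_pval = intercept_pval, note = note
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (J = %d variants)\n", x$method, x$n_variants))
  cat(sprintf("  estimate %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$pval))
  if (is.finite(x$Q)) {
    cat(sprintf("  Cochran's Q = %.2f, df = %d, p = %.3g\n",
                x$Q, x$Q_df, x$Q_pval))
  }
  if (is.finite(x$egger_intercept)) {
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
                x$egger_intercept, x$intercept_se, x$intercept_pval))
  }
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             n_variants = x$n_variants, Q = x$Q, Q_df = x$Q_df,
             Q_pval = x$Q_pval, egger_intercept = x$egger_intercept,
             intercept_se = x$intercept_se,
             intercept_pval = x$intercept_pval,
             stringsAsFactors = FALSE)
}

#' Per-variant Wald ratios
#'
#' The per-variant causal estimate `beta_Y / beta_X` with first-order
#' delta-method standard error `se_Y / |beta_X|`. Variants with a zero
#' exposure effect are dropped with a warning.
#'
#' @param h Harmonization table from [harmonize()] (excluded rows are
#'   ignored).
#' @return Data frame with `snp`, `ratio`, `se`.
#' @export
wald_ratios <- function(h) {
  h <- harmonized_kept(h)
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    warning(sum(zero), " variant(s) with zero exposure effect excluded ",
            "from Wald ratios")
    h <- h[!zero, , drop = FALSE]
  }
  data.frame(snp = if ("snp" %in% names(h)) h$snp else seq_len(nrow(h)),
             ratio = h$beta_outcome / h$beta_exposure,
             se = h$se_outcome / abs(h$beta_exposure),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate (multiplicative random effects)
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin, weights `1/se_Y^2`:
#' \deqn{\hat\beta = \frac{\sum \beta_X \beta_Y / se_Y^2}
#'                        {\sum \beta_X^2 / se_Y^2}}
#' The fixed-effect standard error `1/sqrt(sum(beta_X^2/se_Y^2))` is
#' inflated by `max(1, sqrt(Q/(J-1)))` under the multiplicative
#' random-effects model. With a single variant the estimate reduces to the
#' Wald ratio (fixed effect, flagged in `note`).
#'
#' @param h Harmonization table from [harmonize()].
#' @return An `mr_result`.
#' @export
mr_ivw <- function(h) {
  h <- harmonized_kept(h)
  J <- nrow(h)
  if (J == 0L) stop("no variants available for IVW", call. = FALSE)
  w <- 1 / h$se_outcome^2
  est <- sum(w * h$beta_exposure * h$beta_outcome) /
    sum(w * h$beta_exposure^2)
  se_fixed <- 1 / sqrt(sum(w * h$beta_exposure^2))
  if (J == 1L) {
    return(new_mr_result("IVW", est, se_fixed, 1L,
                         note = "single variant: Wald ratio, fixed effect"))
  }
  qq <- cochran_q(h, est)
  se <- se_fixed * max(1, sqrt(qq$Q / qq$df))
  new_mr_result("IVW (multiplicative random effects)", est, se, J,
                Q = qq$Q, Q_df = qq$df, Q_pval = qq$p)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept, weights `1/se_Y^2`, after orienting all
#' exposure effects non-negative (required for the intercept's
#' directional-pleiotropy interpretation). The slope is the causal
#' estimate, consistent under the InSIDE assumption; a nonzero intercept
#' indicates directional pleiotropy. Standard errors are inflated by
#' `max(1, sqrt(Q_egger/(J-2)))`.
#'
#' @param h Harmonization table from [harmonize()]; needs J >= 3.
#' @return An `mr_result` carrying slope, intercept, and Egger's residual
#'   heterogeneity `Q` with `J - 2` degrees of freedom.
#' @export
mr_egger <- function(h) {
  h <- harmonized_kept(h)
  J <- nrow(h)
  if (J < 3L) stop("MR-Egger needs at least 3 variants", call. = FALSE)
  s <- ifelse(h$beta_exposure < 0, -1, 1)
  bx <- s * h$beta_exposure
  by <- s * h$beta_outcome
  w <- 1 / h$se_outcome^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  fitted <- drop(X %*% coefs)
  Q <- sum(w * (by - fitted)^2)
  infl <- max(1, sqrt(Q / (J - 2)))
  covm <- solve(XtWX)
  se <- sqrt(diag(covm)) * infl
  res <- new_mr_result("MR-Egger", coefs[2], se[2], J,
                       Q = Q, Q_df = J - 2L,
                       Q_pval = stats::pchisq(Q, J - 2, lower.tail = FALSE),
                       egger_intercept = coefs[1], intercept_se = se[1],
                       intercept_pval = 2 * stats::pnorm(-abs(coefs[1] / se[1])))
  res
}

weighted_median_est <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]; w <- weight[o]
  S <- cumsum(w)
  p <- (S - w / 2) / S[length(S)]
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap over (beta_X, beta_Y) for ratio-based estimators
.ratio_boot <- function(h, n_boot, seed, est_fun) {
  if (n_boot <= 0L) return(NA_real_)
  with_seed(seed, {
    J <- nrow(h)
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, h$beta_exposure, h$se_exposure)
      by <- stats::rnorm(J, h$beta_outcome, h$se_outcome)
      ok <- bx != 0
      est_fun(by[ok] / bx[ok], h$se_outcome[ok] / abs(bx[ok]))
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median causal estimate
#'
#' The inverse-variance-weighted median of the per-variant Wald ratios:
#' ratios are sorted, each assigned the percentile
#' `(S_j - w_j/2) / S_J` of its cumulative standardized weight, and the
#' estimate is the linear interpolation at the 50th percentile. Consistent
#' when valid instruments contribute at least half the weight. The
#' standard error comes from a seeded parametric bootstrap resampling
#' `(beta_X, beta_Y)` from their sampling distributions.
#'
#' @param h Harmonization table from [harmonize()]; needs J >= 3.
#' @param n_boot Bootstrap resamples (0 skips the bootstrap; `se` is `NA`).
#' @param seed Bootstrap seed.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(h, n_boot = 5000L, seed = 1L) {
  h <- harmonized_kept(h)
  if (nrow(h) < 3L) {
    stop("weighted median needs at least 3 variants", call. = FALSE)
  }
  wr <- suppressWarnings(wald_ratios(h))
  w <- 1 / wr$se^2
  est <- weighted_median_est(wr$ratio, w / sum(w))
  se <- .ratio_boot(h, n_boot, seed,
                    function(r, s) weighted_median_est(r, 1 / s^2))
  new_mr_result("Weighted median", est, se, nrow(h))
}

mode_est <- function(ratio, se_ratio, bandwidth_factor = 1) {
  J <- length(ratio)
  w <- (1 / se_ratio^2)
  w <- w / sum(w)
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * J^(-1 / 5)
  bw <- bandwidth_factor * s
  if (!is.finite(bw) || bw <= 0) return(stats::median(ratio))
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512L)
  dens <- vapply(grid, function(x) {
    sum(w * stats::dnorm((x - ratio) / bw)) / bw
  }, numeric(1))
  grid[which.max(dens)]
}

#' Mode-based causal estimate
#'
#' The mode of the inverse-variance-weighted Gaussian kernel density of
#' the per-variant Wald ratios (simple weighted mode). The bandwidth is
#' `bandwidth_factor` times the modified Silverman rule
#' `0.9 min(sd, mad) J^(-1/5)` on the ratios. Consistent when the largest
#' group of instruments sharing a ratio is valid (plurality validity).
#' Standard error by seeded parametric bootstrap.
#'
#' @param h Harmonization table from [harmonize()]; needs J >= 3.
#' @param bandwidth_factor Multiplier on the modified-Silverman bandwidth.
#' @param n_boot Bootstrap resamples (0 skips the bootstrap).
#' @param seed Bootstrap seed.
#' @return An `mr_result`.
#' @export
mr_mode <- function(h, bandwidth_factor = 1, n_boot = 5000L, seed = 1L) {
  h <- harmonized_kept(h)
  if (nrow(h) < 3L) {
    stop("mode-based estimator needs at least 3 variants", call. = FALSE)
  }
  check_scalar_number(bandwidth_factor, "bandwidth_factor", lower = 0,
                      open_lower = TRUE)
  wr <- suppressWarnings(wald_ratios(h))
  est <- mode_est(wr$ratio, wr$se, bandwidth_factor)
  se <- .ratio_boot(h, n_boot, seed,
                    function(r, s) mode_est(r, s, bandwidth_factor))
  new_mr_result("Mode-based", est, se, nrow(h))
}
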