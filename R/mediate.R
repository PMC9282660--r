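#' Causal mediation analysis by product of coefficients with bootstrap CIs
#'
#' Fits two multiple linear regressions on complete cases: the mediator
#' model `mediator ~ exposure + covariates` (path `a`) and the outcome
#' model `outcome ~ exposure + mediator + covariates` (paths `c'` and
#' `b`). In the linear, no-interaction structural model the natural
#' indirect effect is `a * b`, the natural direct effect is `c'`, the
#' total effect is their sum, and the proportion mediated is
#' `indirect / total`. Percentile confidence intervals and p-values come
#' from a seeded nonparametric bootstrap resampling individuals with
#' replacement (1,000 resamples by default).
#'
#' @param table Data frame holding the named columns.
#' @param exposure,mediator,outcome Column names.
#' @param covariates Character vector of adjustment columns (may be
#'   factors).
#' @param n_boot Bootstrap resamples (>= 100).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level of the percentile intervals.
#' @return A list of class `mediation_result` with point estimates
#'   (`a_path`, `b_path`, `direct`, `indirect`, `total`, `prop_mediated`),
#'   a `ci` matrix of percentile bounds, bootstrap p-values, `n_used`,
#'   `n_boot` and `seed`. If the total effect is numerically zero the
#'   proportion mediated is `NA` with a warning.
#' @export
mediate <- function(table, exposure, mediator, outcome,
                    covariates = character(), n_boot = 1000L, seed = 1L,
                    conf_level = 0.95) {
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  vars <- c(exposure, mediator, outcome, covariates)
  miss <- setdiff(vars, names(table))
  if (length(miss)) {
    stop("columns not found in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- table[stats::complete.cases(table[, vars, drop = FALSE]), vars,
               drop = FALSE]
  if (nrow(dat) < length(covariates) + 3L) {
    stop("too few complete cases for mediation", call. = FALSE)
  }
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  X_med <- stats::model.matrix(
    stats::as.formula(paste("~", rhs)), data = dat)
  X_out <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c(exposure, mediator, covariates),
                                       collapse = " + "))), data = dat)
  m <- dat[[mediator]]
  y <- dat[[outcome]]
  i_exp_med <- match(exposure, colnames(X_med))
  i_exp_out <- match(exposure, colnames(X_out))
  i_med_out <- match(mediator, colnames(X_out))

  paths <- function(idx) {
    cm <- stats::.lm.fit(X_med[idx, , drop = FALSE], m[idx])$coefficients
    co <- stats::.lm.fit(X_out[idx, , drop = FALSE], y[idx])$coefficients
    a <- cm[i_exp_med]; b <- co[i_med_out]; cp <- co[i_exp_out]
    ind <- a * b
    tot <- cp + ind
    c(a = a, b = b, direct = cp, indirect = ind, total = tot,
      prop = if (abs(tot) > 1e-12) ind / tot else NA_real_)
  }

  pt <- paths(seq_len(nrow(dat)))
  if (is.na(pt["prop"])) {
    warning("total effect is numerically zero; proportion mediated undefined")
  }

  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(i) {
      paths(sample.int(nrow(dat), replace = TRUE))
    }, numeric(6)))
  })
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- t(apply(boot, 2, stats::quantile, probs = probs, na.rm = TRUE))
  colnames(ci) <- c("ci_low", "ci_high")
  pboot <- apply(boot, 2, function(d) {
    d <- d[is.finite(d)]
    if (!length(d)) return(NA_real_)
    min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  })

  structure(list(
    a_path = unname(pt["a"]), b_path = unname(pt["b"]),
    direct = unname(pt["direct"]), indirect = unname(pt["indirect"]),
    total = unname(pt["total"]), prop_mediated = unname(pt["prop"]),
    ci = ci, pval = pboot, n_used = nrow(dat),
    n_boot = n_boot, seed = seed,
    exposure = exposure, mediator = mediator, outcome = outcome
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(nm, v) sprintf(
    "  %-20s %8.4f  [%.4f, %.4f]  p = %.3g\n", nm, v,
    x$ci[rownames(x$ci) == nm2row(nm), 1],
    x$ci[rownames(x$ci) == nm2row(nm), 2],
    x$pval[nm2row(nm)])
  nm2row <- function(nm) switch(nm,
    "a (exp -> med)" = "a", "b (med -> out)" = "b",
    "direct (c')" = "direct", "indirect (a*b)" = "indirect",
    "total" = "total", "proportion mediated" = "prop")
  cat(sprintf("Mediation of %s -> %s through %s (n = %d, %d bootstraps)\n",
              x$exposure, x$outcome, x$mediator, x$n_used, x$n_boot))
  for (nm in c("a (exp -> med)", "b (med -> out)", "direct (c')",
               "indirect (a*b)", "total", "proportion mediated")) {
    v <- switch(nm2row(nm), a = x$a_path, b = x$b_path, direct = x$direct,
                indirect = x$indirect, total = x$total,
                prop = x$prop_mediated)
    cat(fmt(nm, v))
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(
    quantity = c("a_path", "b_path", "direct", "indirect", "total",
                 "prop_mediated"),
    estimate = c(x$a_path, x$b_path, x$direct, x$indirect, x$total,
                 x$prop_mediated),
    ci_low = x$ci[, 1], ci_high = x$ci[, 2], pval = unname(x$pval),
    row.names = NULL, stringsAsFactors = FALSE)
}
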