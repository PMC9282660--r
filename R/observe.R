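#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their Blom rank fractions,
#' `qnorm((r - 3/8) / (n + 1/4))`, with midranks for ties. This is the
#' standard way to enforce Gaussianity on phenotypes before linear
#' modelling. NAs are propagated; ranks are computed over finite values
#' only.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return Numeric vector of the same length, order-isomorphic to the
#'   input ranks. If all finite values are identical the result is all
#'   zeros, with a warning.
#' @export
inverse_normal_transform <- function(values) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  fin <- is.finite(values)
  n <- sum(fin)
  if (n < 2L) stop("need at least 2 finite values", call. = FALSE)
  out <- rep(NA_real_, length(values))
  v <- values[fin]
  if (length(unique(v)) == 1L) {
    warning("all values identical; transform is identically zero")
    out[fin] <- 0
    return(out)
  }
  r <- rank(v, ties.method = "average")
  out[fin] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Categorize weekly consumption into quantile bins among current drinkers
#'
#' Computes k-quantile boundaries (quintiles by default; octiles for the
#' sensitivity analysis) from current drinkers only; never and previous
#' drinkers keep their status label and receive no quantile. The lowest
#' bin is marked as the reference category.
#'
#' @param units Numeric vector of weekly units.
#' @param status Character or factor vector, values in
#'   `never`/`previous`/`current`.
#' @param k Number of bins (>= 2).
#' @return A list with `category` (factor with levels `never`, `previous`,
#'   `Q1`..`Qk`), `boundaries` (internal quantile cut points among current
#'   drinkers) and `reference` (`"Q1"`).
#' @export
categorize_quantiles <- function(units, status, k = 5L) {
  k <- check_count(k, "k", min = 2L)
  if (length(units) != length(status)) {
    stop("`units` and `status` must have equal length", call. = FALSE)
  }
  status <- as.character(status)
  if (!all(status %in% c("never", "previous", "current"))) {
    stop("`status` values must be never/previous/current", call. = FALSE)
  }
  if (any(units[status == "current"] < 0, na.rm = TRUE)) {
    stop("weekly units must be non-negative", call. = FALSE)
  }
  u_cur <- units[status == "current" & is.finite(units)]
  if (length(unique(u_cur)) < k) {
    stop(sprintf("need at least k = %d distinct unit values among current drinkers", k),
         call. = FALSE)
  }
  brks <- stats::quantile(u_cur, probs = seq_len(k - 1L) / k, names = FALSE)
  labs <- paste0("Q", seq_len(k))
  cat_cur <- cut(units, breaks = c(-Inf, brks, Inf), labels = labs)
  category <- factor(ifelse(status == "current", as.character(cat_cur), status),
                     levels = c("never", "previous", labs))
  list(category = category, boundaries = brks, reference = "Q1")
}

#' Fit a covariate-adjusted linear model
#'
#' Ordinary least squares on complete cases, with optional pairwise
#' interaction and quadratic terms, as used for the alcohol-iron and
#' iron-cognition association models. Categorical covariates are expanded
#' to indicator contrasts against their first factor level.
#'
#' @param table Data frame of phenotypes and covariates.
#' @param outcome Name of the dependent variable.
#' @param exposure Name of the main predictor (may be a factor, e.g. the
#'   quantile category).
#' @param covariates Character vector of adjustment columns.
#' @param interactions List of 2-element character vectors; each adds a
#'   pairwise product term.
#' @param quadratic Character vector of numeric columns to add as squared
#'   terms.
#' @return A list of class `regression_result`: `terms` (data frame with
#'   `term`, `beta`, `se`, `ci_low`, `ci_high`, `p`), `n_used`,
#'   `sigma` (residual SD) and `model` (a descriptor string).
#' @export
fit_linear_model <- function(table, outcome, exposure,
                             covariates = character(),
                             interactions = list(),
                             quadratic = character()) {
  vars <- unique(c(outcome, exposure, covariates, unlist(interactions),
                   quadratic))
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("columns not found in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rhs <- c(exposure, covariates,
           vapply(interactions, function(p) paste(p, collapse = ":"), ""),
           if (length(quadratic)) sprintf("I(%s^2)", quadratic))
  form <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  dat <- table[stats::complete.cases(table[, vars, drop = FALSE]), ,
               drop = FALSE]
  if (nrow(dat) < length(rhs) + 2L) {
    stop("too few complete cases for the requested model", call. = FALSE)
  }
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  dfres <- fit$df.residual
  tcrit <- stats::qt(0.975, dfres)
  terms <- data.frame(
    term = rownames(sm),
    beta = sm[, 1], se = sm[, 2],
    ci_low = sm[, 1] - tcrit * sm[, 2],
    ci_high = sm[, 1] + tcrit * sm[, 2],
    p = sm[, 4],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, n_used = nrow(dat),
                 sigma = summary(fit)$sigma,
                 model = deparse(form)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Linear model:", x$model, "\n")
  cat("Complete cases used:", x$n_used,
      " residual SD:", signif(x$sigma, 4), "\n")
  print(x$terms, digits = 4)
  invisible(x)
}

#' Genetic iron risk score
#'
#' Weighted sum of risk-allele dosages for the three common European
#' iron-metabolism variants (rs1800562 and rs1799945 in HFE, rs855791 in
#' TMPRSS6), with weights taken as their published per-allele associations
#' with serum iron.
#'
#' @param dosages Matrix or data frame with 3 columns of dosages in
#'   \[0, 2\].
#' @param weights Numeric vector of 3 per-allele effect sizes.
#' @return Numeric score vector, one value per row.
#' @export
build_iron_grs <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != 3L || length(weights) != 3L) {
    stop("expected 3 dosage columns and 3 weights", call. = FALSE)
  }
  if (!is.numeric(dosages) || any(!is.finite(dosages)) ||
      any(dosages < 0) || any(dosages > 2)) {
    stop("dosages must be numeric in [0, 2]", call. = FALSE)
  }
  drop(dosages %*% as.numeric(weights))
}

#' Multiple-testing correction for a family of p-values
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg FDR step-up adjusted
#' p-values; the family is the supplied vector. Correction families are
#' applied separately per analysis block (e.g. alcohol x susceptibility
#' models vs susceptibility x cognition models).
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"fdr_bh"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "fdr_bh")) {
  method <- match.arg(method)
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = switch(method, bonferroni = "bonferroni",
                                         fdr_bh = "BH"))
}
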