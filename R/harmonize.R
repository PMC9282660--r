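.required_ss_cols <- c("snp", "effect_allele", "other_allele", "eaf",
                       "beta", "se", "pval")

check_summary_set <- function(x, arg = "summary set") {
  if (!is.data.frame(x)) stop(arg, " must be a data frame", call. = FALSE)
  miss <- setdiff(.required_ss_cols, names(x))
  if (length(miss)) {
    stop("missing column: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$se)) || any(x$se <= 0)) {
    stop(arg, ": all standard errors must be > 0", call. = FALSE)
  }
  invisible(x)
}

#' Filter instruments by association p-value
#'
#' Keeps variants below the genome-wide significance threshold
#' (`p < 5e-8` by default), preserving input order.
#'
#' @param summary A summary-statistic data frame (dialect of
#'   [read_summary_stats()]).
#' @param p_threshold Significance threshold in (0, 1).
#' @return The filtered data frame, with attributes `n_input` and `n_kept`.
#' @export
select_instruments <- function(summary, p_threshold = 5e-8) {
  check_summary_set(summary, "summary")
  check_scalar_number(p_threshold, "p_threshold", 0, 1,
                      open_lower = TRUE, open_upper = TRUE)
  keep <- summary$pval < p_threshold
  if (!any(keep)) {
    stop(sprintf(
      "no variants pass p < %g; consider relaxing the threshold",
      p_threshold), call. = FALSE)
  }
  out <- summary[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(summary)
  attr(out, "n_kept") <- sum(keep)
  out
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "G" & oa == "C") | (ea == "C" & oa == "G")
}

#' Harmonize exposure and outcome summary statistics to a common allele
#'
#' Aligns per-variant outcome associations to the exposure's effect
#' allele. Nominal allele swaps flip the outcome beta's sign and
#' complement its frequency; strand flips are recognised by base
#' complement. Palindromic (A/T, G/C) variants cannot be resolved from
#' alleles alone: they are excluded when either effect-allele frequency is
#' missing or falls inside the ambiguity window, and otherwise aligned so
#' the two frequencies fall on the same side of 0.5. Variants whose
#' alleles cannot be reconciled are excluded with reason
#' `"allele-mismatch"`.
#'
#' @param exposure,outcome Summary-statistic data frames sharing variants
#'   by `snp`.
#' @param palindrome_eaf_window Frequency window (lo, hi) inside which a
#'   palindromic variant is treated as unresolvable.
#' @return A data frame with one row per intersecting variant: `snp`,
#'   `beta_exposure`, `se_exposure`, `pval_exposure`, `eaf_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_outcome`, `palindromic`, `action`
#'   (`kept`/`flipped`/`excluded`) and `reason`. Outcome columns of
#'   excluded rows are set `NA`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = c(0.30, 0.70)) {
  check_summary_set(exposure, "exposure")
  check_summary_set(outcome, "outcome")
  if (length(palindrome_eaf_window) != 2L ||
      palindrome_eaf_window[1] >= palindrome_eaf_window[2]) {
    stop("`palindrome_eaf_window` must be an increasing pair", call. = FALSE)
  }
  common <- intersect(exposure$snp, outcome$snp)
  if (!length(common)) {
    stop("no variants shared between exposure and outcome sets",
         call. = FALSE)
  }
  ex <- exposure[match(common, exposure$snp), ]
  ou <- outcome[match(common, outcome$snp), ]
  n <- length(common)
  lo <- palindrome_eaf_window[1]; hi <- palindrome_eaf_window[2]

  action <- character(n); reason <- rep(NA_character_, n)
  b_out <- ou$beta; eaf_out <- ou$eaf
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  for (j in seq_len(n)) {
    ea_x <- ex$effect_allele[j]; oa_x <- ex$other_allele[j]
    ea_y <- ou$effect_allele[j]; oa_y <- ou$other_allele[j]
    if (pal[j]) {
      # nominal alignment first (for a palindrome the strand-flipped pair
      # is the swapped pair, so names only decide nominal orientation)
      if (ea_y == oa_x && oa_y == ea_x) {
        b_out[j] <- -b_out[j]; eaf_out[j] <- 1 - eaf_out[j]
      } else if (!(ea_y == ea_x && oa_y == oa_x)) {
        action[j] <- "excluded"; reason[j] <- "allele-mismatch"
        next
      }
      fx <- ex$eaf[j]; fy <- eaf_out[j]
      if (is.na(fx) || is.na(fy) ||
          (fx > lo && fx < hi) || (fy > lo && fy < hi)) {
        action[j] <- "excluded"; reason[j] <- "palindromic-ambiguous"
        next
      }
      if (sign(fx - 0.5) == sign(fy - 0.5)) {
        action[j] <- "kept"
      } else {
        # frequencies disagree: infer a strand flip and re-orient
        b_out[j] <- -b_out[j]; eaf_out[j] <- 1 - eaf_out[j]
        action[j] <- "flipped"
      }
    } else {
      cy <- unname(.complement[c(ea_y, oa_y)])
      if (ea_y == ea_x && oa_y == oa_x) {
        action[j] <- "kept"
      } else if (ea_y == oa_x && oa_y == ea_x) {
        b_out[j] <- -b_out[j]; eaf_out[j] <- 1 - eaf_out[j]
        action[j] <- "flipped"
      } else if (cy[1] == ea_x && cy[2] == oa_x) {       # strand flip
        action[j] <- "kept"
      } else if (cy[1] == oa_x && cy[2] == ea_x) {       # flip + swap
        b_out[j] <- -b_out[j]; eaf_out[j] <- 1 - eaf_out[j]
        action[j] <- "flipped"
      } else {
        action[j] <- "excluded"; reason[j] <- "allele-mismatch"
      }
    }
  }
  excl <- action == "excluded"
  b_out[excl] <- NA_real_; eaf_out[excl] <- NA_real_
  h <- data.frame(
    snp = common,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se, pval_exposure = ex$pval,
    eaf_exposure = ex$eaf,
    beta_outcome = b_out, se_outcome = ou$se, eaf_outcome = eaf_out,
    palindromic = pal, action = action, reason = reason,
    stringsAsFactors = FALSE)
  rownames(h) <- NULL
  attr(h, "n_kept") <- sum(!excl)
  attr(h, "n_excluded") <- sum(excl)
  h
}

# retained (kept or flipped) rows of a harmonization table
harmonized_kept <- function(h) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!is.data.frame(h) || !all(need %in% names(h))) {
    stop("expected a harmonization table from harmonize()", call. = FALSE)
  }
  if ("action" %in% names(h)) h <- h[h$action != "excluded", , drop = FALSE]
  h
}
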