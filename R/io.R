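#' Read GWAS summary statistics (TSV dialect)
#'
#' Tab-separated, header required, columns `snp`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`; missing effect-allele
#' frequency encoded as `NA`. Rows with non-numeric `beta`/`se`/`pval`
#' or non-positive `se` are rejected with their file line numbers.
#'
#' @param path File path.
#' @return Summary-statistic data frame.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(.required_ss_cols, names(x))
  if (length(miss)) {
    stop("missing column: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  out <- data.frame(
    snp = x$snp, effect_allele = toupper(x$effect_allele),
    other_allele = toupper(x$other_allele),
    eaf = num(x$eaf), beta = num(x$beta), se = num(x$se),
    pval = num(x$pval), stringsAsFactors = FALSE)
  bad <- !is.finite(out$beta) | !is.finite(out$se) | out$se <= 0 |
    !is.finite(out$pval) |
    (!is.na(x$eaf) & x$eaf != "NA" & !is.finite(out$eaf))
  if (any(bad)) {
    # +1 for the header line
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  if (!nrow(out)) stop("no valid rows in ", path, call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Write GWAS summary statistics (TSV dialect)
#' @param x Summary-statistic data frame.
#' @param path Destination path.
#' @export
write_summary_stats <- function(x, path) {
  check_summary_set(x, "x")
  utils::write.table(x[, .required_ss_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an individual-level cohort table (CSV dialect)
#'
#' Comma-separated with a header row, `.` decimal. Dosage columns (names
#' starting `rs`) must be numeric in \[0, 2\]; offending rows are
#' reported by index.
#'
#' @param path File path.
#' @return Cohort data frame; character status columns become factors
#'   with the levels used by [simulate_cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(x)) stop("empty cohort table: ", path, call. = FALSE)
  dos_cols <- grep("^rs", names(x), value = TRUE)
  for (dc in dos_cols) {
    v <- suppressWarnings(as.numeric(x[[dc]]))
    bad <- !is.finite(v) | v < 0 | v > 2
    if (any(bad)) {
      stop(sprintf("invalid dosage in column %s at row(s): %s", dc,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    x[[dc]] <- v
  }
  for (fc in c("drinker_status", "smoking_status")) {
    if (fc %in% names(x)) {
      x[[fc]] <- factor(x[[fc]], levels = c("never", "previous", "current"))
    }
  }
  if ("sex" %in% names(x) && is.character(x$sex)) {
    x$sex <- factor(x$sex, levels = c("female", "male"))
  }
  for (fc in intersect(c("education", "income", "job"), names(x))) {
    if (is.character(x[[fc]])) x[[fc]] <- factor(x[[fc]])
  }
  x
}

#' Write a cohort table (CSV dialect)
#' @param x Cohort data frame.
#' @param path Destination path.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a ground-truth record as a key:value sidecar file
#' @param truth Truth list from [simulate_summary_stats()] or a flat list.
#' @param path Destination path.
#' @export
write_truth <- function(truth, path) {
  lines <- unlist(lapply(names(truth), function(nm) {
    v <- truth[[nm]]
    if (length(v) == 1L && is.null(names(v))) {
      sprintf("%s: %s", nm, format(v, digits = 15))
    } else {
      sprintf("%s.%s: %s", nm, names(v), format(unname(v), digits = 15))
    }
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a table of MR results (one row per method)
#' @param results List of `mr_result` objects.
#' @param path Destination path.
#' @export
write_mr_results <- function(results, path) {
  tab <- do.call(rbind, lapply(results, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
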