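#' Default pipeline configuration
#'
#' Nested list consumed by [run_pipeline()]. All per-stage seeds are
#' expanded deterministically from the single top-level `seed`.
#'
#' @param seed Master seed.
#' @param stages Stages to run, in order, among `simulate`, `observe`,
#'   `mr`, `mediate`, `power`.
#' @param cohort A [cohort_config()] (its seed is overridden by the
#'   expanded stage seed).
#' @param sumstats A [sumstats_config()] (likewise).
#' @param exposure_path,outcome_path Paths to existing summary-statistic
#'   TSVs, used by the `mr` stage when `simulate` is not requested.
#' @param cohort_path Path to an existing cohort CSV, used by `observe`
#'   and `mediate` when `simulate` is not requested.
#' @param p_threshold Instrument significance threshold.
#' @param palindrome_eaf_window Palindrome ambiguity window.
#' @param n_boot_mr Bootstrap resamples for median/mode standard errors.
#' @param n_boot_mediation Bootstrap resamples for mediation CIs.
#' @param correction Multiple-testing method for the observational block.
#' @param power Named list `n`, `r2`, `alpha`, `effect` for the power
#'   stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "observe", "mr", "mediate",
                                  "power"),
                       cohort = cohort_config(),
                       sumstats = sumstats_config(),
                       exposure_path = NULL, outcome_path = NULL,
                       cohort_path = NULL,
                       p_threshold = 5e-8,
                       palindrome_eaf_window = c(0.30, 0.70),
                       n_boot_mr = 5000L,
                       n_boot_mediation = 1000L,
                       correction = c("fdr_bh", "bonferroni"),
                       power = list(n = 29579, r2 = 0.003, alpha = 0.05,
                                    effect = 0.25)) {
  stages <- match.arg(stages, several.ok = TRUE)
  correction <- match.arg(correction)
  structure(list(seed = as.integer(seed), stages = stages, cohort = cohort,
                 sumstats = sumstats, exposure_path = exposure_path,
                 outcome_path = outcome_path, cohort_path = cohort_path,
                 p_threshold = p_threshold,
                 palindrome_eaf_window = palindrome_eaf_window,
                 n_boot_mr = n_boot_mr,
                 n_boot_mediation = n_boot_mediation,
                 correction = correction, power = power),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [run_config()]; nested
#' `cohort:` and `sumstats:` blocks override the corresponding generator
#' defaults field by field.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("cohort", "sumstats"))]
  if (!is.null(args$power)) {
    # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
    names(args$power)[names(args$power) == "FALSE"] <- "n"
  }
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$sumstats)) {
    args$sumstats <- do.call(sumstats_config, y$sumstats)
  }
  do.call(run_config, args)
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the triangulation pipeline end to end
#'
#' Executes the requested stages in order — `simulate` (cohort + two-sample
#' summary statistics), `observe` (quantile normalization, quantile
#' categories, adjusted linear models, multiple-testing correction), `mr`
#' (instrument selection, harmonization, IVW / Egger / weighted-median /
#' mode estimators with heterogeneity and instrument strength), `mediate`
#' (bootstrap mediation through liver iron) and `power` — writing one or
#' more TSV/report files per stage plus a plain-text run log recording
#' seeds and exclusion counts. A stage failure halts the run with an error
#' naming the stage; outputs already written are retained.
#'
#' @param config A [run_config()] or [read_run_config()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) {
    stop_config("config", "must be created by run_config()")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, 5L))
  names(stage_seeds) <- c("simulate", "observe", "mr", "mediate", "power")
  log_path <- file.path(out_dir, "run_log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  .log_line(con, "irontri pipeline; master seed ", config$seed)
  results <- list()

  run_stage <- function(name, fun) {
    .log_line(con, "stage ", name, " (seed ", stage_seeds[[name]], ")")
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- NULL; ss <- NULL

  if ("simulate" %in% config$stages) {
    results$simulate <- run_stage("simulate", function() {
      cfg_c <- config$cohort; cfg_c$seed <- stage_seeds[["simulate"]]
      cohort <<- simulate_cohort(cfg_c)
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
      cfg_s <- config$sumstats; cfg_s$seed <- stage_seeds[["simulate"]]
      ss <<- simulate_summary_stats(cfg_s)
      write_summary_stats(ss$exposure,
                          file.path(out_dir, "exposure_sumstats.tsv"))
      write_summary_stats(ss$outcome,
                          file.path(out_dir, "outcome_sumstats.tsv"))
      write_truth(ss$truth[c("true_causal_effect", "pleiotropy", "valid")],
                  file.path(out_dir, "truth.txt"))
      .log_line(con, "  cohort n = ", nrow(cohort),
                "; variants J = ", nrow(ss$exposure))
      list(cohort = cohort, sumstats = ss)
    })
  }

  if (any(c("observe", "mediate") %in% config$stages) && is.null(cohort)) {
    if (is.null(config$cohort_path)) {
      first <- intersect(config$stages, c("observe", "mediate"))[1]
      stop(sprintf("stage '%s': no cohort available; request the simulate stage or supply cohort_path",
                   first), call. = FALSE)
    }
    cohort <- read_cohort(config$cohort_path)
  }

  if ("observe" %in% config$stages) {
    results$observe <- run_stage("observe", function() {
      tab <- cohort
      qc <- categorize_quantiles(tab$alcohol_units_weekly,
                                 tab$drinker_status, k = 5L)
      tab$quintile <- qc$category
      outcomes <- intersect(config$cohort$outcomes, names(tab))
      covs <- intersect(c("age", "sex", "smoking_status", "bmi", "sbp",
                          "dbp", "cholesterol", "townsend", "education",
                          "income", "job", "diabetes"), names(tab))
      rows <- lapply(outcomes, function(oc) {
        tab2 <- tab
        tab2[[oc]] <- inverse_normal_transform(tab2[[oc]])
        fit <- fit_linear_model(tab2, oc, "alcohol_std", covariates = covs)
        tr <- fit$terms[fit$terms$term == "alcohol_std", ]
        tr$outcome <- oc; tr$n_used <- fit$n_used
        tr
      })
      res <- do.call(rbind, rows)
      res$p_bonf <- adjust_pvalues(res$p, "bonferroni")
      res$p_fdr <- adjust_pvalues(res$p, "fdr_bh")
      utils::write.table(
        res[, c("outcome", "term", "beta", "se", "ci_low", "ci_high", "p",
                "p_bonf", "p_fdr", "n_used")],
        file.path(out_dir, "observational_results.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      .log_line(con, "  models fitted: ", nrow(res))
      res
    })
  }

  if ("mr" %in% config$stages) {
    results$mr <- run_stage("mr", function() {
      if (is.null(ss)) {
        if (is.null(config$exposure_path) || is.null(config$outcome_path)) {
          stop("no summary statistics available; request the simulate ",
               "stage or supply exposure_path/outcome_path")
        }
        ss <<- list(exposure = read_summary_stats(config$exposure_path),
                    outcome = read_summary_stats(config$outcome_path))
      }
      inst <- select_instruments(ss$exposure, config$p_threshold)
      h <- harmonize(inst, ss$outcome, config$palindrome_eaf_window)
      utils::write.table(h, file.path(out_dir, "harmonization_log.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      .log_line(con, "  instruments: ", nrow(inst), " selected; ",
                attr(h, "n_kept"), " harmonized, ",
                attr(h, "n_excluded"), " excluded")
      for (j in which(h$action == "excluded")) {
        .log_line(con, "  excluded ", h$snp[j], ": ", h$reason[j])
      }
      mr_seed <- stage_seeds[["mr"]]
      fits <- list(
        ivw = mr_ivw(h),
        egger = mr_egger(h),
        weighted_median = mr_weighted_median(h, config$n_boot_mr, mr_seed),
        mode = mr_mode(h, n_boot = config$n_boot_mr, seed = mr_seed))
      write_mr_results(fits, file.path(out_dir, "mr_results.tsv"))
      fstat <- instrument_strength(inst)
      utils::write.table(fstat$per_variant,
                         file.path(out_dir, "instrument_strength.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      .log_line(con, sprintf("  mean F = %.1f; %.0f%% of instruments weak (F < 10)",
                             fstat$mean_f, 100 * fstat$prop_weak))
      c(fits, list(harmonization = h, strength = fstat))
    })
  }

  if ("mediate" %in% config$stages) {
    results$mediate <- run_stage("mediate", function() {
      oc <- intersect(config$cohort$outcomes, names(cohort))[1]
      med <- mediate(cohort, exposure = "alcohol_std",
                     mediator = "liver_iron", outcome = oc,
                     covariates = intersect(c("age", "sex", "bmi"),
                                            names(cohort)),
                     n_boot = config$n_boot_mediation,
                     seed = stage_seeds[["mediate"]])
      utils::write.table(as.data.frame(med),
                         file.path(out_dir, "mediation_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep_path <- file.path(out_dir, "mediation_report.txt")
      sink(rep_path); print(med); sink()
      .log_line(con, sprintf("  proportion mediated = %.3f",
                             med$prop_mediated))
      med
    })
  }

  if ("power" %in% config$stages) {
    results$power <- run_stage("power", function() {
      p <- config$power
      pw <- mr_power(p$n, p$r2, p$alpha, p$effect)
      utils::write.table(
        data.frame(n = p$n, r2 = p$r2, alpha = p$alpha, effect = p$effect,
                   power = pw),
        file.path(out_dir, "power.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      .log_line(con, sprintf("  power = %.3f", pw))
      pw
    })
  }

  .log_line(con, "pipeline complete")
  invisible(results)
}
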