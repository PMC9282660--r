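#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with known ground truth.
#
# Emulates the two data resources of the triangulation design: an
# individual-level imaging cohort (alcohol exposure, liver iron mediator,
# regional brain susceptibility outcomes, covariates, three iron-risk SNP
# dosages) and a pair of two-sample GWAS summary-statistic tables for the
# alcohol instruments. Defaults mirror the study conditions: cohort
# n = 20,729 with 2.7% never drinkers, 91 instruments from a 941,280-sample
# exposure GWAS against a 29,579-sample outcome GWAS, instruments jointly
# explaining 0.3% of exposure variance.

library(irontri)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(cohort_config(seed = 101L))
write_cohort(cohort, file.path(out, "cohort.csv"))
cat(sprintf("cohort: %d individuals, %.1f%% never drinkers, mean %.1f units/week among current drinkers\n",
            nrow(cohort), 100 * mean(cohort$drinker_status == "never"),
            mean(cohort$alcohol_units_weekly[cohort$drinker_status == "current"])))

ss <- simulate_summary_stats(sumstats_config(seed = 101L))
write_summary_stats(ss$exposure, file.path(out, "exposure_sumstats.tsv"))
write_summary_stats(ss$outcome, file.path(out, "outcome_sumstats.tsv"))
write_truth(ss$truth[c("true_causal_effect", "pleiotropy", "valid")],
            file.path(out, "truth.txt"))
cat(sprintf("summary statistics: %d variants (%d palindromic), true causal effect %.2f\n",
            nrow(ss$exposure), sum(ss$truth$palindromic),
            ss$truth$true_causal_effect))
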