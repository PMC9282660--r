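#' Configuration for a synthetic individual-level cohort
#'
#' Describes the ground-truth structural model of the cohort generator:
#' a continuous exposure (standardized weekly alcohol among current
#' drinkers), a continuous mediator (liver iron, mg/g) on a partially
#' mediated path to one or more continuous outcomes (standardized regional
#' brain susceptibility), plus drinker-status categories, covariates and
#' three iron-risk SNP dosages.
#'
#' Default path coefficients mirror the mediation figures of the motivating
#' study: `a` = 0.05 mg/g liver iron per SD alcohol, `b` = 0.44 SD
#' susceptibility per mg/g liver iron, direct effect `c'` = 0.047 SD per SD
#' (so roughly a third of the total effect travels through the mediator).
#' Never drinkers default to 2.7% of the sample.
#'
#' @param n_individuals Number of records to simulate.
#' @param effect_exposure_on_mediator Path `a`: mediator units per SD of
#'   exposure.
#' @param effect_mediator_on_outcome Path `b`: outcome SD per mediator unit.
#' @param direct_effect Path `c'`: outcome SD per SD of exposure, not through
#'   the mediator.
#' @param covariate_effects Named numeric vector of slopes applied (on the
#'   standardized covariate scale) in both the mediator and outcome
#'   equations. Names must be among `age`, `sex`, `bmi`, `sbp`, `dbp`,
#'   `cholesterol`, `townsend`, `diabetes`.
#' @param noise_sd_mediator,noise_sd_outcome Residual standard deviations.
#' @param prop_never,prop_previous Fractions of never and previous drinkers;
#'   their sum must be below 1.
#' @param grs_snp_freqs Effect-allele frequencies of the three iron-risk
#'   variants (rs1800562, rs1799945, rs855791), each in (0, 1).
#' @param outcomes Character vector of outcome column names.
#' @param seed Integer seed; identical configurations produce identical
#'   tables.
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_individuals = 20729,
                          effect_exposure_on_mediator = 0.05,
                          effect_mediator_on_outcome = 0.44,
                          direct_effect = 0.047,
                          covariate_effects = c(age = 0.10, bmi = 0.05),
                          noise_sd_mediator = 0.30,
                          noise_sd_outcome = 1.00,
                          prop_never = 0.027,
                          prop_previous = 0.035,
                          grs_snp_freqs = c(rs1800562 = 0.07,
                                            rs1799945 = 0.14,
                                            rs855791  = 0.45),
                          outcomes = c("putamen_chi", "caudate_chi",
                                       "thalamus_chi"),
                          seed = 1L) {
  check_count(n_individuals, "n_individuals", min = 2L)
  for (f in c("effect_exposure_on_mediator", "effect_mediator_on_outcome",
              "direct_effect")) {
    check_scalar_number(get(f), f)
  }
  check_scalar_number(noise_sd_mediator, "noise_sd_mediator", lower = 0,
                      open_lower = TRUE)
  check_scalar_number(noise_sd_outcome, "noise_sd_outcome", lower = 0,
                      open_lower = TRUE)
  check_scalar_number(prop_never, "prop_never", 0, 1)
  check_scalar_number(prop_previous, "prop_previous", 0, 1)
  if (prop_never + prop_previous >= 1) {
    stop_config("prop_never + prop_previous", "must be < 1")
  }
  if (length(grs_snp_freqs) != 3L || any(!is.finite(grs_snp_freqs)) ||
      any(grs_snp_freqs <= 0) || any(grs_snp_freqs >= 1)) {
    stop_config("grs_snp_freqs", "must be 3 frequencies in the open (0,1)")
  }
  allowed <- c("age", "sex", "bmi", "sbp", "dbp", "cholesterol", "townsend",
               "diabetes")
  if (length(covariate_effects) &&
      (is.null(names(covariate_effects)) ||
       !all(names(covariate_effects) %in% allowed))) {
    stop_config("covariate_effects",
                paste("names must be among:", paste(allowed, collapse = ", ")))
  }
  if (!is.character(outcomes) || length(outcomes) < 1L) {
    stop_config("outcomes", "must name at least one outcome column")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    effect_exposure_on_mediator = effect_exposure_on_mediator,
    effect_mediator_on_outcome = effect_mediator_on_outcome,
    direct_effect = direct_effect,
    covariate_effects = covariate_effects,
    noise_sd_mediator = noise_sd_mediator,
    noise_sd_outcome = noise_sd_outcome,
    prop_never = prop_never,
    prop_previous = prop_previous,
    grs_snp_freqs = grs_snp_freqs,
    outcomes = outcomes,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Weekly-units distribution among current drinkers: lognormal matched to the
# cohort's mean 17.7 and SD 15.9 units (1 UK unit = 8 g ethanol).
.units_lognormal <- local({
  m <- 17.7; s <- 15.9
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
})

#' Simulate an individual-level cohort with known ground truth
#'
#' Draws a cohort under a linear structural model:
#' \deqn{M = \mu_M + a X + \gamma^T Z + \epsilon_M,\qquad
#'       Y_k = c' X + b M + \gamma^T Z + \epsilon_{Y_k}}
#' where `X` is the standardized exposure (standard normal among current
#' drinkers, 0 for never/previous drinkers), `M` the mediator (liver iron,
#' mg/g, baseline 1.2), `Z` standardized covariates and each outcome an
#' independent draw around the same structural mean. Raw weekly alcohol
#' units are the lognormal back-transform of `X` (matched to mean 17.7, SD
#' 15.9 units); never/previous drinkers carry 0 units and their category
#' label. SNP dosages are Binomial(2, freq).
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with one row per individual: identifiers, drinker
#'   status, raw and standardized alcohol, covariates (natural units),
#'   dosage columns named after the three variants, the mediator
#'   `liver_iron`, and one column per configured outcome.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_config("config", "must be created by cohort_config()")
  }
  n <- config$n_individuals
  with_seed(config$seed, {
    status <- sample(c("never", "previous", "current"), n, replace = TRUE,
                     prob = c(config$prop_never, config$prop_previous,
                              1 - config$prop_never - config$prop_previous))
    status <- factor(status, levels = c("never", "previous", "current"))
    cur <- status == "current"

    x <- numeric(n)
    x[cur] <- stats::rnorm(sum(cur))
    units <- numeric(n)
    units[cur] <- stats::qlnorm(stats::pnorm(x[cur]),
                                meanlog = .units_lognormal$meanlog,
                                sdlog = .units_lognormal$sdlog)

    # covariates: natural units in the table, z-scores in the equations
    z <- cbind(age = stats::rnorm(n), sex = stats::rnorm(n),
               bmi = stats::rnorm(n), sbp = stats::rnorm(n),
               dbp = stats::rnorm(n), cholesterol = stats::rnorm(n),
               townsend = stats::rnorm(n), diabetes = stats::rnorm(n))
    sex <- factor(ifelse(z[, "sex"] < stats::qnorm(0.486), "female", "male"),
                  levels = c("female", "male"))
    diabetes <- as.integer(z[, "diabetes"] > stats::qnorm(0.95))
    smoking <- factor(sample(c("never", "previous", "current"), n,
                             replace = TRUE, prob = c(0.55, 0.39, 0.06)),
                      levels = c("never", "previous", "current"))
    education <- factor(sample(c("degree", "a_levels", "none", "other"), n,
                               replace = TRUE,
                               prob = c(0.486, 0.132, 0.053, 0.329)),
                        levels = c("none", "other", "a_levels", "degree"))
    income <- factor(sample(paste0("band", 1:5), n, replace = TRUE),
                     levels = paste0("band", 1:5))
    job <- factor(sample(paste0("soc", 1:9), n, replace = TRUE),
                  levels = paste0("soc", 1:9))

    cov_term <- numeric(n)
    if (length(config$covariate_effects)) {
      zi <- z[, names(config$covariate_effects), drop = FALSE]
      cov_term <- drop(zi %*% config$covariate_effects)
    }

    dos <- sapply(config$grs_snp_freqs,
                  function(f) stats::rbinom(n, 2L, f))
    colnames(dos) <- names(config$grs_snp_freqs)

    mediator <- 1.2 + config$effect_exposure_on_mediator * x + cov_term +
      stats::rnorm(n, sd = config$noise_sd_mediator)

    out <- sapply(config$outcomes, function(nm) {
      config$direct_effect * x +
        config$effect_mediator_on_outcome * mediator + cov_term +
        stats::rnorm(n, sd = config$noise_sd_outcome)
    })

    tab <- data.frame(
      id = sprintf("id%06d", seq_len(n)),
      drinker_status = status,
      alcohol_units_weekly = units,
      alcohol_std = x,
      age = 54.8 + 7.4 * z[, "age"],
      sex = sex,
      smoking_status = smoking,
      bmi = 26.5 + 4.0 * z[, "bmi"],
      sbp = 136.9 + 18.6 * z[, "sbp"],
      dbp = 81.6 + 10.5 * z[, "dbp"],
      cholesterol = 5.7 + 1.1 * z[, "cholesterol"],
      townsend = -2.0 + 2.6 * z[, "townsend"],
      education = education,
      income = income,
      job = job,
      diabetes = diabetes,
      stringsAsFactors = FALSE
    )
    tab <- cbind(tab, as.data.frame(dos),
                 liver_iron = mediator, as.data.frame(out))
    rownames(tab) <- NULL
    tab
  })
}

#' Configuration for two-sample GWAS summary statistics
#'
#' Describes the generating model for per-variant exposure and outcome
#' associations: `J` independent variants whose true exposure effects
#' jointly explain `instrument_r2_total` of exposure variance, an outcome
#' effect `beta * beta_exposure + pleiotropy`, and sampling noise with
#' standard errors scaling as 1/sqrt(2 f (1-f) n). Defaults match the
#' motivating study's alcohol-consumption instrument set: 91 variants from
#' a 941,280-individual exposure GWAS, a 29,579-individual outcome sample,
#' instruments explaining 0.3% of exposure variance and a causal effect of
#' 0.25 SD.
#'
#' @param n_variants Number of independent instruments (J >= 2).
#' @param n_exposure_sample,n_outcome_sample GWAS sample sizes.
#' @param true_causal_effect The causal slope `beta` of exposure on outcome.
#' @param instrument_r2_total Fraction of exposure variance jointly
#'   explained, in (0, 1).
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`. Under `inside_violating` the per-variant
#'   pleiotropic effect correlates 0.5 with instrument strength, breaking
#'   the InSIDE assumption.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-variant
#'   pleiotropic effects (ignored for `"none"`).
#' @param palindromic_rate Fraction of variants given A/T or G/C alleles to
#'   exercise strand-ambiguity handling downstream.
#' @param seed Integer seed.
#' @return A list of class `sumstats_config`.
#' @seealso [simulate_summary_stats()]
#' @export
sumstats_config <- function(n_variants = 91,
                            n_exposure_sample = 941280,
                            n_outcome_sample = 29579,
                            true_causal_effect = 0.25,
                            instrument_r2_total = 0.003,
                            pleiotropy_mode = c("none", "balanced",
                                                "directional",
                                                "inside_violating"),
                            pleiotropy_mean = 0,
                            pleiotropy_sd = 0,
                            palindromic_rate = 0.10,
                            seed = 1L) {
  check_count(n_variants, "n_variants", min = 2L)
  check_count(n_exposure_sample, "n_exposure_sample", min = 1L)
  check_count(n_outcome_sample, "n_outcome_sample", min = 1L)
  check_scalar_number(true_causal_effect, "true_causal_effect")
  check_scalar_number(instrument_r2_total, "instrument_r2_total", 0, 1,
                      open_lower = TRUE, open_upper = TRUE)
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  check_scalar_number(pleiotropy_mean, "pleiotropy_mean")
  check_scalar_number(pleiotropy_sd, "pleiotropy_sd", lower = 0)
  check_scalar_number(palindromic_rate, "palindromic_rate", 0, 1)
  structure(list(
    n_variants = as.integer(n_variants),
    n_exposure_sample = as.integer(n_exposure_sample),
    n_outcome_sample = as.integer(n_outcome_sample),
    true_causal_effect = true_causal_effect,
    instrument_r2_total = instrument_r2_total,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    palindromic_rate = palindromic_rate,
    seed = as.integer(seed)
  ), class = "sumstats_config")
}

.complement <- c(A = "T", T = "A", G = "C", C = "G")

#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Generates exposure and outcome summary-association tables for `J`
#' independent variants. True per-allele exposure effects are drawn with
#' half-normal magnitudes (effect-allele oriented trait-increasing) and
#' rescaled so that the per-variant variance contributions
#' `2 f (1-f) beta^2` sum to the configured instrument R-squared. Outcome
#' effects are `beta * beta_X + alpha_j` with the pleiotropy vector
#' `alpha` drawn per `pleiotropy_mode`. Estimated effects add Gaussian
#' noise with SE `1/sqrt(2 f (1-f) n)` for standardized traits. The
#' outcome table's allele presentation is deliberately scrambled per
#' variant (allele swaps and strand flips) so harmonization is exercised;
#' the truth record stores the aligned generating values.
#'
#' @param config A [sumstats_config()].
#' @return A list with elements `exposure` and `outcome` (data frames in
#'   the summary-statistic dialect: `snp`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`) and `truth`, a list carrying the causal
#'   effect, per-variant true exposure effects, pleiotropic effects,
#'   validity flags and palindromic flags.
#' @export
simulate_summary_stats <- function(config) {
  if (!inherits(config, "sumstats_config")) {
    stop_config("config", "must be created by sumstats_config()")
  }
  J <- config$n_variants
  with_seed(config$seed, {
    snp <- sprintf("rs%07d", sample.int(9999999L, J))
    eaf <- stats::runif(J, 0.05, 0.95)

    pal <- stats::runif(J) < config$palindromic_rate
    pal_pairs <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
    npal_pairs <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                       c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
    alle <- t(vapply(seq_len(J), function(j) {
      if (pal[j]) pal_pairs[[sample.int(4L, 1L)]]
      else npal_pairs[[sample.int(8L, 1L)]]
    }, character(2)))
    ea <- alle[, 1]; oa <- alle[, 2]

    # true exposure effects: half-normal magnitudes, scaled to total R2
    raw <- abs(stats::rnorm(J))
    v <- 2 * eaf * (1 - eaf)
    scale_f <- sqrt(config$instrument_r2_total / sum(v * raw^2))
    bx_true <- raw * scale_f

    alpha <- switch(config$pleiotropy_mode,
      none = rep(0, J),
      balanced = stats::rnorm(J, 0, config$pleiotropy_sd),
      directional = stats::rnorm(J, config$pleiotropy_mean,
                                 config$pleiotropy_sd),
      inside_violating = {
        zb <- as.numeric(scale(bx_true))
        config$pleiotropy_mean + config$pleiotropy_sd *
          (0.5 * zb + sqrt(0.75) * stats::rnorm(J))
      })
    by_true <- config$true_causal_effect * bx_true + alpha

    se_x <- 1 / sqrt(v * config$n_exposure_sample)
    se_y <- 1 / sqrt(v * config$n_outcome_sample)
    bx_hat <- bx_true + stats::rnorm(J, sd = se_x)
    by_hat <- by_true + stats::rnorm(J, sd = se_y)

    exposure <- data.frame(
      snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = bx_hat, se = se_x,
      pval = 2 * stats::pnorm(-abs(bx_hat / se_x)),
      stringsAsFactors = FALSE)

    # outcome presentation: scramble alleles to exercise harmonization
    eaf_out <- pmin(pmax(eaf + stats::rnorm(J, sd = 0.005), 0.01), 0.99)
    o_ea <- ea; o_oa <- oa; o_beta <- by_hat; o_eaf <- eaf_out
    mode_draw <- stats::runif(J)
    for (j in seq_len(J)) {
      if (pal[j]) {
        if (mode_draw[j] < 0.3) { # strand flip: relabel by complement
          o_ea[j] <- .complement[[ea[j]]]; o_oa[j] <- .complement[[oa[j]]]
        }
      } else if (mode_draw[j] < 0.3) {        # allele swap
        o_ea[j] <- oa[j]; o_oa[j] <- ea[j]
        o_beta[j] <- -o_beta[j]; o_eaf[j] <- 1 - o_eaf[j]
      } else if (mode_draw[j] < 0.5) {        # strand flip
        o_ea[j] <- .complement[[ea[j]]]; o_oa[j] <- .complement[[oa[j]]]
      }
    }
    outcome <- data.frame(
      snp = snp, effect_allele = o_ea, other_allele = o_oa, eaf = o_eaf,
      beta = o_beta, se = se_y,
      pval = 2 * stats::pnorm(-abs(by_hat / se_y)),
      stringsAsFactors = FALSE)

    truth <- list(
      true_causal_effect = config$true_causal_effect,
      beta_exposure_true = stats::setNames(bx_true, snp),
      beta_outcome_true = stats::setNames(by_true, snp),
      pleiotropy = stats::setNames(alpha, snp),
      valid = stats::setNames(alpha == 0, snp),
      palindromic = stats::setNames(pal, snp)
    )
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}
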