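#' Simulate a two-sample GWAS summary table
#'
#' Generates per-SNP exposure effects and outcome effects under a linear
#' causal model \eqn{\beta_{Yj} = \theta \beta_{Xj} + \alpha_j + \epsilon_j},
#' where \eqn{\alpha_j} is a direct (pleiotropic) outcome effect carried by a
#' configurable fraction of SNPs and \eqn{\epsilon_j \sim N(0, se_{Yj})} is
#' estimation noise. Defaults emulate a well-powered GWAS of a BMI-like
#' trait: 50 independent instruments with strength far above the weak-IV
#' threshold (F around 100) and genome-wide-significant exposure p-values,
#' and a causal effect of 0.2 on the transformed outcome scale.
#'
#' Balanced pleiotropy uses `pleiotropy_mean = 0`; directional pleiotropy
#' (what outlier tests are exercised against) uses a nonzero mean.
#'
#' @param n_snps number of independent instruments.
#' @param true_theta causal effect of exposure on outcome per unit of the
#'   transformed exposure.
#' @param exposure_beta_mean,exposure_beta_sd distribution of the per-allele
#'   exposure effects.
#' @param se_exposure,se_outcome per-SNP standard errors (scalars or vectors
#'   of length `n_snps`).
#' @param pleiotropy_frac fraction of SNPs with a direct outcome effect.
#' @param pleiotropy_mean,pleiotropy_sd distribution of the direct effects.
#' @param seed integer seed; fixed seeds give bit-identical tables.
#' @return a harmonized summary table (as produced by [harmonize()]) with
#'   allele columns and per-trait p-values, plus attributes `true_theta` and
#'   `pleiotropic_ids` (the SNPs carrying a direct effect).
#' @export
simulate_gwas <- function(n_snps = 50, true_theta = 0.2,
                          exposure_beta_mean = 0.03, exposure_beta_sd = 0.01,
                          se_exposure = 0.003, se_outcome = 0.003,
                          pleiotropy_frac = 0, pleiotropy_mean = 0,
                          pleiotropy_sd = 0.05, seed = NULL) {
  stopifnot(n_snps >= 1, pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            all(se_exposure > 0), all(se_outcome > 0))
  if (!is.null(seed)) set.seed(seed)
  se_x <- rep_len(se_exposure, n_snps)
  se_y <- rep_len(se_outcome, n_snps)

  # instruments come out of a GWAS, so they are genome-wide significant by
  # construction: redraw any exposure effect below the significance bound
  z_min <- stats::qnorm(2.5e-8, lower.tail = FALSE)
  beta_x <- stats::rnorm(n_snps, exposure_beta_mean, exposure_beta_sd)
  repeat {
    weak <- abs(beta_x) / se_x < z_min
    if (!any(weak)) break
    beta_x[weak] <- stats::rnorm(sum(weak), exposure_beta_mean,
                                 exposure_beta_sd)
  }
  n_pleio <- round(pleiotropy_frac * n_snps)
  pleio_idx <- if (n_pleio > 0) sample.int(n_snps, n_pleio) else integer(0)
  alpha <- numeric(n_snps)
  alpha[pleio_idx] <- stats::rnorm(n_pleio, pleiotropy_mean, pleiotropy_sd)
  beta_y <- true_theta * beta_x + alpha + stats::rnorm(n_snps, 0, se_y)

  # non-palindromic allele pairs so strand checks never fire on fixtures
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(nrow(pairs), n_snps, replace = TRUE)

  tab <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    effect_allele = pairs[pick, 1],
    other_allele = pairs[pick, 2],
    beta_exposure = beta_x,
    se_exposure = se_x,
    pval_exposure = 2 * stats::pnorm(-abs(beta_x / se_x)),
    beta_outcome = beta_y,
    se_outcome = se_y,
    pval_outcome = 2 * stats::pnorm(-abs(beta_y / se_y)),
    stringsAsFactors = FALSE
  )
  structure(tab,
            true_theta = true_theta,
            pleiotropic_ids = tab$snp_id[sort(pleio_idx)],
            exposure_name = "simulated_exposure",
            outcome_name = "simulated_outcome")
}

#' Split a simulated summary table into single-trait files
#'
#' Writes the exposure and outcome associations of a simulated (harmonized)
#' table as two single-trait tab-separated files with the default headers
#' (`SNP, EA, OA, BETA, SE, P`), the format [read_summary_table()] consumes.
#'
#' @param table a table from [simulate_gwas()].
#' @param exposure_path,outcome_path output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_gwas_pair <- function(table, exposure_path, outcome_path) {
  exp_tab <- data.frame(SNP = table$snp_id, EA = table$effect_allele,
                        OA = table$other_allele, BETA = table$beta_exposure,
                        SE = table$se_exposure, P = table$pval_exposure)
  out_tab <- data.frame(SNP = table$snp_id, EA = table$effect_allele,
                        OA = table$other_allele, BETA = table$beta_outcome,
                        SE = table$se_outcome, P = table$pval_outcome)
  write_summary_table(exp_tab, exposure_path)
  write_summary_table(out_tab, outcome_path)
  invisible(c(exposure_path, outcome_path))
}

#' Simulate a prospective cohort with a rare survival outcome
#'
#' Emulates a cohort of postmenopausal women followed for incident breast
#' cancer: a BMI-like continuous exposure (mean 24.3, SD 3.5 kg/m2), a
#' uric-acid-like mediator linear in the exposure (slope 5 umol/l per kg/m2,
#' residual SD 72 so the marginal SD is about 75 umol/l), a correlated waist
#' measurement, an independent covariate block matching the cohort's
#' baseline prevalences, and an event time from a Weibull baseline hazard
#' multiplied by \eqn{\exp(\theta_1 X + \theta_2 M)}, administratively
#' censored. The baseline rate is calibrated in closed form (first-order in
#' the cumulative hazard, accurate for rare outcomes) so the expected
#' cumulative incidence over the follow-up horizon matches
#' `target_incidence` — by default about 1% over 8.2 years, roughly 211
#' events among 19,518 women.
#'
#' Default log-hazard coefficients correspond to a hazard ratio of 1.25 per
#' exposure SD directly and 1.05 per exposure SD through the mediator, so
#' the generator's true proportion mediated is
#' \eqn{\theta_2\beta_1 / (\theta_1 + \theta_2\beta_1)} = log(1.05)/log(1.3125),
#' about 0.178 (see attribute `truth`).
#'
#' @param n_subjects cohort size.
#' @param exposure_mean,exposure_sd exposure distribution (kg/m2).
#' @param beta1 mediator slope on the exposure (umol/l per kg/m2).
#' @param mediator_intercept intercept of the mediator model (umol/l).
#' @param mediator_resid_sd residual SD of the mediator (umol/l).
#' @param theta1 log-hazard per exposure unit; default log(1.25)/exposure_sd.
#' @param theta2 log-hazard per mediator unit; default log(1.05)/17.5, which
#'   under the default slope (5 umol/l per kg/m2) and exposure SD (3.5)
#'   makes the indirect path contribute log(1.05) per exposure SD.
#' @param baseline_shape Weibull shape of the baseline hazard (1 =
#'   exponential).
#' @param target_incidence expected cumulative incidence over the follow-up
#'   horizon (must be below 0.1: the rare-outcome regime).
#' @param censor_admin_years administrative censoring horizon (years).
#' @param confounded tie age to both exposure and hazard (for testing
#'   adjustment behaviour); default independent covariates.
#' @param seed integer seed.
#' @return data.frame with one row per subject: `id`, `enroll_date`,
#'   `diagnosis_date`, `censor_date`, `time_years`, `event`, `bmi`, `waist`,
#'   `ua`, and the covariate block (`age`, `smoking`, `drinking`,
#'   `education`, `marital`, `batch`, `parity`, `menopause_age`, `mastitis`,
#'   `diuretics`, `antibiotics`, `hrt`). Attribute `truth` records the
#'   generating parameters including the true proportion mediated.
#' @export
simulate_cohort <- function(n_subjects = 19518,
                            exposure_mean = 24.3, exposure_sd = 3.5,
                            beta1 = 5, mediator_intercept = 151.6,
                            mediator_resid_sd = 72,
                            theta1 = log(1.25) / exposure_sd,
                            theta2 = log(1.05) / 17.5,
                            baseline_shape = 1,
                            target_incidence = 211 / 19518,
                            censor_admin_years = 8.2,
                            confounded = FALSE, seed = NULL) {
  stopifnot(n_subjects >= 10, is.finite(theta1), is.finite(theta2),
            exposure_sd > 0, mediator_resid_sd > 0,
            baseline_shape > 0, target_incidence > 0, target_incidence < 0.1,
            censor_admin_years > 0)
  if (!is.null(seed)) set.seed(seed)

  age <- stats::rnorm(n_subjects, 61.3, 8.0)
  bmi <- stats::rnorm(n_subjects, exposure_mean, exposure_sd)
  gamma_age <- 0
  if (confounded) {
    bmi <- bmi + 0.1 * (age - 61.3)
    gamma_age <- 0.03
  }
  ua <- mediator_intercept + beta1 * bmi +
    stats::rnorm(n_subjects, 0, mediator_resid_sd)
  waist <- 81.4 + (0.7 * 9.2 / exposure_sd) * (bmi - exposure_mean) +
    stats::rnorm(n_subjects, 0, 9.2 * sqrt(1 - 0.7^2))

  covs <- data.frame(
    age = age,
    smoking = stats::rbinom(n_subjects, 1, 0.031),
    drinking = stats::rbinom(n_subjects, 1, 0.086),
    education = stats::rbinom(n_subjects, 1, 0.377),
    marital = stats::rbinom(n_subjects, 1, 0.854),
    batch = stats::rbinom(n_subjects, 1, 0.343),
    parity = stats::rpois(n_subjects, 2),
    menopause_age = stats::rnorm(n_subjects, 49.1, 3.7),
    mastitis = stats::rbinom(n_subjects, 1, 0.048),
    diuretics = stats::rbinom(n_subjects, 1, 0.019),
    antibiotics = stats::rbinom(n_subjects, 1, 0.086),
    hrt = stats::rbinom(n_subjects, 1, 0.031)
  )

  eta <- theta1 * bmi + theta2 * ua + gamma_age * (age - 61.3)
  # closed-form calibration of the Weibull rate to the target incidence:
  # P(T < h) ~= lambda h^k E[exp(eta)], with E[exp(eta)] from normal moments
  mu_eta <- theta1 * exposure_mean +
    theta2 * (mediator_intercept + beta1 * exposure_mean)
  var_eta <- (theta1 + theta2 * beta1)^2 * exposure_sd^2 +
    theta2^2 * mediator_resid_sd^2 + (gamma_age * 8.0)^2
  mean_rr <- exp(mu_eta + var_eta / 2)
  lambda <- target_incidence / (censor_admin_years^baseline_shape * mean_rr)

  u <- stats::runif(n_subjects)
  t_event <- (-log(u) / (lambda * exp(eta)))^(1 / baseline_shape)
  event <- as.integer(t_event <= censor_admin_years)
  time_raw <- pmin(t_event, censor_admin_years)

  # emit day-resolution dates consistent with the follow-up times
  enroll_start <- as.Date(ifelse(covs$batch == 1, "2013-04-01", "2008-09-01"))
  enroll_span <- ifelse(covs$batch == 1, 213, 667)
  enroll_date <- enroll_start +
    floor(stats::runif(n_subjects) * (enroll_span + 1))
  time_days <- pmax(1, round(time_raw * DAYS_PER_YEAR))
  end_date <- enroll_date + time_days
  time_years <- time_days / DAYS_PER_YEAR

  out <- data.frame(
    id = sprintf("S%05d", seq_len(n_subjects)),
    enroll_date = enroll_date,
    diagnosis_date = as.Date(ifelse(event == 1, as.character(end_date), NA)),
    censor_date = as.Date(ifelse(event == 0, as.character(end_date), NA)),
    time_years = time_years,
    event = event,
    bmi = bmi, waist = waist, ua = ua,
    covs,
    stringsAsFactors = FALSE
  )
  structure(out,
            truth = list(theta1 = theta1, theta2 = theta2, beta1 = beta1,
                         exposure_sd = exposure_sd,
                         lambda = lambda, shape = baseline_shape,
                         target_incidence = target_incidence,
                         true_pm = (theta2 * beta1) /
                           (theta1 + theta2 * beta1)))
}

#' Deterministic micro-fixtures
#'
#' A 3-SNP exposure/outcome table pair (including one allele-swapped SNP)
#' and a 5-subject survival fixture with one binary covariate and no tied
#' event times, used by oracle tests. These do not depend on any seed.
#' @return list with `snp3_exposure`, `snp3_outcome` (SNP record tables) and
#'   `cox5` (5-row survival data.frame with columns `time_years`, `event`,
#'   `x`).
#' @export
micro_fixtures <- function() {
  snp3_exposure <- data.frame(
    snp_id = c("rs000001", "rs000002", "rs000003"),
    effect_allele = c("A", "C", "T"),
    other_allele = c("G", "T", "C"),
    beta = c(0.02, 0.03, 0.04),
    se = c(0.003, 0.003, 0.004),
    pval = c(3e-11, 1e-23, 1e-23),
    stringsAsFactors = FALSE
  )
  snp3_outcome <- data.frame(
    snp_id = c("rs000001", "rs000002", "rs000003"),
    effect_allele = c("G", "C", "T"),   # rs000001 reported on the other allele
    other_allele = c("A", "T", "C"),
    beta = c(-0.004, 0.006, 0.008),
    se = c(0.003, 0.003, 0.004),
    pval = c(0.18, 0.046, 0.045),
    stringsAsFactors = FALSE
  )
  cox5 <- data.frame(
    time_years = c(1.0, 2.0, 3.0, 4.0, 5.0),
    event = c(1L, 0L, 1L, 1L, 0L),
    x = c(1, 1, 0, 1, 0)
  )
  list(snp3_exposure = snp3_exposure, snp3_outcome = snp3_outcome,
       cox5 = cox5)
}

#' Write the full fixture suite
#'
#' Writes every small test fixture to a directory: the deterministic
#' micro-fixtures (3-SNP pair, 5-subject survival table), a null GWAS pair
#' (no causal effect), an effect GWAS pair with one constructed outlier
#' (one SNP's outcome beta displaced by 10 standard errors), a default
#' synthetic cohort, and a JSON manifest recording every generator parameter
#' and ground-truth value. Stochastic fixtures are derived from `seed`;
#' the micro-fixtures are seed-independent.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the stochastic fixtures.
#' @param n_subjects cohort size for the default cohort fixture.
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_fixture_suite <- function(out_dir, seed = 1, n_subjects = 19518) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  mf <- micro_fixtures()
  write_summary_table(data.frame(SNP = mf$snp3_exposure$snp_id,
                                 EA = mf$snp3_exposure$effect_allele,
                                 OA = mf$snp3_exposure$other_allele,
                                 BETA = mf$snp3_exposure$beta,
                                 SE = mf$snp3_exposure$se,
                                 P = mf$snp3_exposure$pval),
                      p("snp3_exposure.tsv"))
  write_summary_table(data.frame(SNP = mf$snp3_outcome$snp_id,
                                 EA = mf$snp3_outcome$effect_allele,
                                 OA = mf$snp3_outcome$other_allele,
                                 BETA = mf$snp3_outcome$beta,
                                 SE = mf$snp3_outcome$se,
                                 P = mf$snp3_outcome$pval),
                      p("snp3_outcome.tsv"))
  utils::write.csv(mf$cox5, p("cox5.csv"), row.names = FALSE)

  effect <- simulate_gwas(n_snps = 50, true_theta = 0.2, seed = seed)
  null_tab <- simulate_gwas(n_snps = 50, true_theta = 0, seed = seed + 1)
  outlier_tab <- effect
  outlier_tab$beta_outcome[1] <- outlier_tab$beta_outcome[1] +
    10 * outlier_tab$se_outcome[1]
  write_gwas_pair(effect, p("gwas_effect_exposure.tsv"),
                  p("gwas_effect_outcome.tsv"))
  write_gwas_pair(null_tab, p("gwas_null_exposure.tsv"),
                  p("gwas_null_outcome.tsv"))
  write_gwas_pair(outlier_tab, p("gwas_outlier_exposure.tsv"),
                  p("gwas_outlier_outcome.tsv"))

  cohort <- simulate_cohort(n_subjects = n_subjects, seed = seed + 2)
  utils::write.csv(cohort, p("cohort_default.csv"), row.names = FALSE,
                   na = "")

  manifest <- list(
    seed = seed,
    fixtures = list(
      snp3 = list(files = c("snp3_exposure.tsv", "snp3_outcome.tsv"),
                  deterministic = TRUE,
                  note = "rs000001 is reported on swapped alleles in the outcome table"),
      cox5 = list(files = "cox5.csv", deterministic = TRUE),
      gwas_effect = list(files = c("gwas_effect_exposure.tsv",
                                   "gwas_effect_outcome.tsv"),
                         deterministic = FALSE, n_snps = 50, true_theta = 0.2),
      gwas_null = list(files = c("gwas_null_exposure.tsv",
                                 "gwas_null_outcome.tsv"),
                       deterministic = FALSE, n_snps = 50, true_theta = 0),
      gwas_outlier = list(files = c("gwas_outlier_exposure.tsv",
                                    "gwas_outlier_outcome.tsv"),
                          deterministic = FALSE, n_snps = 50,
                          true_theta = 0.2,
                          outlier_snp = outlier_tab$snp_id[1],
                          displacement = "10 se_outcome"),
      cohort_default = list(files = "cohort_default.csv",
                            deterministic = FALSE,
                            n_subjects = n_subjects,
                            truth = attr(cohort, "truth"),
                            n_events = sum(cohort$event))
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
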