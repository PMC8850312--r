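#' Fit the linear mediator model
#'
#' Ordinary least squares of the continuous mediator on the exposure and
#' covariates over complete cases. The exposure coefficient (mediator units
#' per exposure unit) is the quantity the indirect effect is built from.
#'
#' @param data cohort data.frame.
#' @param exposure exposure column name.
#' @param mediator mediator column name.
#' @param covariates character vector of covariate column names.
#' @return list of class `mediator_fit`: `beta1` (exposure coefficient),
#'   `se_beta1`, `coefficients`, `sigma` (residual SD), `vcov`, `n_used`,
#'   and the underlying `lm` object as `fit`.
#' @export
fit_mediator_model <- function(data, exposure, mediator,
                               covariates = character()) {
  stopifnot(exposure %in% names(data), mediator %in% names(data),
            all(covariates %in% names(data)))
  vars <- c(mediator, exposure, covariates)
  use <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[use, vars, drop = FALSE]
  p <- length(c(exposure, covariates)) + 1L
  if (nrow(d) < p + 2L) stop("too few complete cases for the mediator model")
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(mediator, "~", rhs)), data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient mediator model; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  structure(list(beta1 = unname(stats::coef(fit)[exposure]),
                 se_beta1 = unname(sm$coefficients[exposure, "Std. Error"]),
                 coefficients = stats::coef(fit),
                 sigma = sm$sigma,
                 vcov = stats::vcov(fit),
                 n_used = nrow(d),
                 fit = fit),
            class = "mediator_fit")
}

#' Counterfactual mediation effects for a survival outcome
#'
#' Decomposes the exposure's effect on the log hazard-ratio scale under the
#' rare-outcome approximation, with a linear mediator model (no
#' exposure-mediator interaction):
#' \deqn{NDE = \theta_1 \Delta a, \quad NIE = \theta_2 \beta_1 \Delta a,
#'       \quad TE = NDE + NIE, \quad PM = NIE / TE,}
#' where \eqn{\theta_1, \theta_2} are the exposure and mediator coefficients
#' of the outcome Cox model, \eqn{\beta_1} the exposure coefficient of the
#' mediator model, and \eqn{\Delta a} the exposure contrast. Delta-method
#' variances treat the two models as independent:
#' \eqn{Var(NDE) = \Delta a^2 Var(\theta_1)},
#' \eqn{Var(NIE) = \Delta a^2 (\beta_1^2 Var(\theta_2) +
#'                             \theta_2^2 Var(\beta_1))}.
#'
#' @param mediator_fit a `mediator_fit`.
#' @param outcome_fit a `cox_fit` containing both exposure and mediator terms.
#' @param exposure,mediator term names in the outcome fit.
#' @param delta_a exposure contrast \eqn{a - a^*} in exposure units
#'   (conventionally one exposure SD).
#' @return list of class `mediation_result`: `nde_log`, `nie_log`, `te_log`,
#'   `proportion_mediated`, `delta_a`, a data.frame `effects` with HR-scale
#'   NDE/NIE/TE and 95% CIs, `se` (log-scale SEs), and `method = "delta"`.
#'   An opposite-signed NDE/NIE pair triggers a warning that the proportion
#'   lies outside [0, 1]; a zero total effect yields `NA` with a warning.
#' @export
mediation_effects <- function(mediator_fit, outcome_fit, exposure, mediator,
                              delta_a = 1) {
  stopifnot(inherits(mediator_fit, "mediator_fit"),
            inherits(outcome_fit, "cox_fit"))
  co <- outcome_fit$coefficients
  if (!all(c(exposure, mediator) %in% names(co))) {
    stop("outcome model must contain both the exposure and the mediator term")
  }
  theta1 <- unname(co[exposure])
  theta2 <- unname(co[mediator])
  var_theta1 <- outcome_fit$vcov[match(exposure, names(co)),
                                 match(exposure, names(co))]
  var_theta2 <- outcome_fit$vcov[match(mediator, names(co)),
                                 match(mediator, names(co))]
  beta1 <- mediator_fit$beta1
  var_beta1 <- mediator_fit$se_beta1^2

  nde <- theta1 * delta_a
  nie <- theta2 * beta1 * delta_a
  te <- nde + nie
  pm <- if (te == 0) {
    warning("total effect is zero; proportion mediated undefined")
    NA_real_
  } else {
    nie / te
  }
  if (!is.na(pm) && (pm < 0 || pm > 1)) {
    warning("NDE and NIE have opposite signs; proportion mediated lies ",
            "outside [0, 1]")
  }
  se_nde <- sqrt(delta_a^2 * var_theta1)
  se_nie <- sqrt(delta_a^2 * (beta1^2 * var_theta2 + theta2^2 * var_beta1))
  se_te <- sqrt(se_nde^2 + se_nie^2)  # independence across the two models

  eff <- data.frame(
    effect = c("NDE", "NIE", "TE"),
    log_hr = c(nde, nie, te),
    se = c(se_nde, se_nie, se_te),
    hr = exp(c(nde, nie, te)),
    ci_low = exp(c(nde - Z975 * se_nde, nie - Z975 * se_nie,
                   te - Z975 * se_te)),
    ci_high = exp(c(nde + Z975 * se_nde, nie + Z975 * se_nie,
                    te + Z975 * se_te)),
    pval = 2 * stats::pnorm(-abs(c(nde / se_nde, nie / se_nie, te / se_te))),
    stringsAsFactors = FALSE
  )
  structure(list(nde_log = nde, nie_log = nie, te_log = te,
                 proportion_mediated = pm, delta_a = delta_a,
                 effects = eff,
                 se = c(nde = se_nde, nie = se_nie, te = se_te),
                 method = "delta"),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (%s CIs, exposure contrast %.4g):\n",
              x$method, x$delta_a))
  print(x$effects, row.names = FALSE, digits = 4)
  cat(sprintf("Proportion mediated (log-HR scale): %.1f%%\n",
              100 * x$proportion_mediated))
  invisible(x)
}

#' Mediation analysis of a cohort in one call
#'
#' Fits the mediator model (OLS) and the outcome Cox model (exposure +
#' mediator + covariates, no interaction) on a cohort data.frame and returns
#' the counterfactual decomposition with the chosen exposure contrast.
#'
#' @param data cohort data.frame with `time_years`, `event`, exposure,
#'   mediator, covariates.
#' @param exposure,mediator column names.
#' @param covariates covariate column names used in both models.
#' @param delta_a exposure contrast; `"sd"` (default) uses one sample SD of
#'   the exposure, otherwise a numeric value in exposure units.
#' @return a `mediation_result` (delta-method CIs), with the two component
#'   fits attached as attributes `mediator_fit` and `outcome_fit`.
#' @export
mediate_survival <- function(data, exposure, mediator,
                             covariates = model_covariates(2),
                             delta_a = "sd") {
  if (identical(delta_a, "sd")) {
    delta_a <- per_sd(data[[exposure]])$sd
  }
  mfit <- fit_mediator_model(data, exposure, mediator, covariates)
  ofit <- fit_cox(data, c(exposure, mediator, covariates))
  res <- mediation_effects(mfit, ofit, exposure, mediator, delta_a = delta_a)
  attr(res, "mediator_fit") <- mfit
  attr(res, "outcome_fit") <- ofit
  res
}

#' Bootstrap confidence intervals for the mediation decomposition
#'
#' Resamples subjects with replacement, refits both models, and recomputes
#' NDE, NIE, TE and the proportion mediated in each replicate. Point
#' estimates remain the full-data values; intervals are percentile 95% CIs.
#'
#' @inheritParams mediate_survival
#' @param n_boot bootstrap replicates (>= 200).
#' @param seed integer seed (fixed seeds give bit-identical CIs).
#' @param max_fail_frac maximum tolerated fraction of non-converging
#'   replicates before erroring (default 0.1).
#' @return a `mediation_result` with `method = "bootstrap"`, percentile CIs
#'   in `effects`, element `pm_ci` (95% CI for the proportion mediated), and
#'   `n_boot_ok` successful replicates.
#' @export
mediation_bootstrap <- function(data, exposure, mediator,
                                covariates = model_covariates(2),
                                delta_a = "sd", n_boot = 200, seed = NULL,
                                max_fail_frac = 0.1) {
  if (n_boot < 200) stop("n_boot must be at least 200")
  if (identical(delta_a, "sd")) delta_a <- per_sd(data[[exposure]])$sd
  full <- mediate_survival(data, exposure, mediator, covariates,
                           delta_a = delta_a)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                 dimnames = list(NULL, c("nde", "nie", "te", "pm")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- tryCatch(
      suppressWarnings(mediate_survival(data[idx, , drop = FALSE], exposure,
                                        mediator, covariates,
                                        delta_a = delta_a)),
      error = function(e) NULL)
    if (!is.null(r)) {
      reps[b, ] <- c(r$nde_log, r$nie_log, r$te_log, r$proportion_mediated)
    }
  }
  ok <- stats::complete.cases(reps)
  if (mean(!ok) > max_fail_frac) {
    stop(sprintf("%d of %d bootstrap replicates failed to converge",
                 sum(!ok), n_boot))
  }
  ci <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  out <- full
  out$method <- "bootstrap"
  out$effects$se <- apply(reps[ok, c("nde", "nie", "te")], 2, stats::sd)
  out$effects$ci_low <- exp(ci[1, c("nde", "nie", "te")])
  out$effects$ci_high <- exp(ci[2, c("nde", "nie", "te")])
  out$effects$pval <- NA_real_
  out$pm_ci <- unname(ci[, "pm"])
  out$n_boot_ok <- sum(ok)
  out
}
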