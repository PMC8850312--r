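#' @importFrom survival coxph Surv cox.zph coxph.control
NULL

DAYS_PER_YEAR <- 365.25

#' Covariate sets for the nested Cox models
#'
#' Model 1 adjusts for demographics and lifestyle (age, smoking, drinking,
#' education, marital status, enrollment batch); model 2 adds reproductive
#' history and medication use (parity, age at menopause, mastitis history,
#' diuretics, antibiotics, hormone replacement therapy); model 3 additionally
#' adjusts each exposure for the other member of the exposure/mediator pair.
#'
#' @param model 1, 2 or 3.
#' @param mutual_adjustment column name added in model 3 (the other exposure),
#'   ignored for models 1-2.
#' @return character vector of covariate column names.
#' @export
model_covariates <- function(model, mutual_adjustment = NULL) {
  m1 <- c("age", "smoking", "drinking", "education", "marital", "batch")
  m2 <- c(m1, "parity", "menopause_age", "mastitis", "diuretics",
          "antibiotics", "hrt")
  cov <- switch(as.character(model), "1" = m1, "2" = m2, "3" = m2,
                stop("model must be 1, 2 or 3"))
  if (model == 3) {
    if (is.null(mutual_adjustment)) {
      stop("model 3 requires the mutual-adjustment column name")
    }
    cov <- c(cov, mutual_adjustment)
  }
  cov
}

#' Follow-up time and event status from dates
#'
#' Follow-up runs from enrollment to the earliest of cancer diagnosis, death,
#' loss to follow-up, or the administrative end of follow-up; the event flag
#' is set only when that earliest date is a diagnosis (a diagnosis recorded
#' on the same day as death counts as a diagnosis). Time is in years
#' (days / 365.25).
#'
#' @param enroll_date,diagnosis_date,death_date,loss_date Date vectors (or
#'   ISO-8601 strings); all but `enroll_date` may be `NA`.
#' @param admin_end_date administrative end of follow-up (scalar).
#' @return data.frame with columns `time_years` and `event` (0/1).
#' @export
compute_follow_up <- function(enroll_date, diagnosis_date = NA,
                              death_date = NA, loss_date = NA,
                              admin_end_date) {
  enroll <- as.Date(enroll_date)
  if (anyNA(enroll)) stop("enroll_date must be present for every subject")
  n <- length(enroll)
  cand <- cbind(
    diagnosis = as.numeric(rep_len(as.Date(diagnosis_date), n)),
    death     = as.numeric(rep_len(as.Date(death_date), n)),
    loss      = as.numeric(rep_len(as.Date(loss_date), n)),
    admin     = as.numeric(rep_len(as.Date(admin_end_date), n))
  )
  end <- apply(cand, 1, min, na.rm = TRUE)
  time_years <- (end - as.numeric(enroll)) / DAYS_PER_YEAR
  if (any(time_years < 0)) stop("negative follow-up time: end date before enrollment")
  event <- as.integer(!is.na(cand[, "diagnosis"]) & cand[, "diagnosis"] == end)
  data.frame(time_years = time_years, event = event)
}

#' Scale values to standard-deviation units
#'
#' Divides by the sample standard deviation (denominator n - 1) of complete
#' cases, so a fitted coefficient is an effect per SD.
#'
#' @param values numeric vector (NAs allowed).
#' @return list with `scaled` (same length, NAs preserved) and `sd`.
#' @export
per_sd <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero variance; cannot scale to SD units")
  list(scaled = values / s, sd = s)
}

#' Quartile group assignment
#'
#' Cut points are the empirical 25th/50th/75th percentiles
#' (linear-interpolation quantile definition); groups are labelled Q1-Q4 in
#' increasing order and a value tied with a boundary goes to the lower group.
#'
#' @param values numeric vector (NAs allowed, propagated).
#' @return list with `cut_points` (length 3) and `group` (factor Q1-Q4).
#' @export
assign_quartiles <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4) stop("need at least 4 non-missing values")
  cuts <- stats::quantile(values[ok], probs = c(0.25, 0.5, 0.75),
                          names = FALSE, type = 7)
  if (any(duplicated(cuts)) || length(unique(values[ok])) == 1L) {
    stop("degenerate distribution: quartile cut points are not distinct")
  }
  group <- cut(values, breaks = c(-Inf, cuts, Inf),
               labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  list(cut_points = cuts, group = group)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default;
#' Breslow available for cross-checks) on the complete cases for the given
#' terms. Subjects with missing exposure, outcome or covariate information
#' are excluded, and the fit reports how many subjects and events were used.
#'
#' @param data cohort data.frame containing `time_years`, `event`, and every
#'   model term.
#' @param terms character vector of right-hand-side column names; the first
#'   is conventionally the exposure of interest.
#' @param ties `"efron"` or `"breslow"`.
#' @return a list of class `cox_fit`: `coefficients`, `vcov`, `loglik`
#'   (at the optimum), `hr` (data.frame term/hr/ci_low/ci_high/pval),
#'   `n_used`, `n_events`, and the underlying `survival::coxph` object as
#'   `fit`.
#' @export
fit_cox <- function(data, terms, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time_years", "event") %in% names(data)),
            all(terms %in% names(data)))
  use <- stats::complete.cases(data[, c("time_years", "event", terms),
                                    drop = FALSE])
  d <- data[use, , drop = FALSE]
  if (sum(d$event) < 1) stop("no events among complete cases")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- stats::as.formula(paste("survival::Surv(time_years, event) ~", rhs))
  fit <- survival::coxph(f, data = d, ties = ties,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
  if (length(terms) && any(!is.finite(sqrt(diag(fit$var))))) {
    stop("unstable Cox fit (possible separation / monotone likelihood)")
  }
  co <- stats::coef(fit)
  if (is.null(co)) co <- numeric(0)
  se <- if (length(co)) sqrt(diag(fit$var)) else numeric(0)
  hr <- data.frame(term = as.character(names(co)),
                   coef = unname(co),
                   se = unname(se),
                   hr = exp(unname(co)),
                   ci_low = exp(unname(co) - Z975 * se),
                   ci_high = exp(unname(co) + Z975 * se),
                   pval = 2 * stats::pnorm(-abs(unname(co) / se)),
                   stringsAsFactors = FALSE)
  structure(list(coefficients = co,
                 vcov = fit$var,
                 loglik = fit$loglik[length(fit$loglik)],
                 hr = hr,
                 n_used = fit$n,
                 n_events = fit$nevent,
                 ties = ties,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, loglik = %.3f\n",
              x$ties, x$n_used, x$n_events, x$loglik))
  if (nrow(x$hr)) print(x$hr, row.names = FALSE, digits = 4)
  invisible(x)
}

#' First-year sensitivity exclusion
#'
#' Removes subjects diagnosed (event) within the first year of follow-up to
#' attenuate reverse causation; censored subjects with short follow-up are
#' kept.
#'
#' @param data cohort data.frame with `time_years` and `event`.
#' @return the filtered data.frame.
#' @export
sensitivity_exclude_first_year <- function(data) {
  drop <- data$event == 1 & data$time_years < 1
  out <- data[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportional-hazards check
#'
#' Tests, per model term, the association of the scaled Schoenfeld residuals
#' with follow-up time (identity time transform); p < 0.05 flags a violation
#' of the proportional-hazards assumption.
#'
#' @param fit a `cox_fit`.
#' @return data.frame with columns `term`, `pval`, `violation`; zero rows for
#'   a model with no covariates.
#' @export
ph_check <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!length(fit$coefficients)) {
    return(data.frame(term = character(), pval = numeric(),
                      violation = logical()))
  }
  z <- survival::cox.zph(fit$fit, transform = "identity", global = FALSE)
  data.frame(term = rownames(z$table),
             pval = unname(z$table[, "p"]),
             violation = unname(z$table[, "p"]) < 0.05,
             stringsAsFactors = FALSE)
}

#' Fit the full nested-model suite for one exposure
#'
#' Runs Cox models 1-3 for the exposure coded three ways: continuous per SD,
#' binary at a threshold (overweight cut-off 24 kg/m2 for BMI; 80 cm for
#' waist), and quartiles with Q1 as the reference. Optionally repeats model 3
#' after excluding first-year cases (sensitivity analysis). Person-years are
#' reported per stratum.
#'
#' @param data cohort data.frame (`time_years`, `event`, exposure, mediator,
#'   covariates).
#' @param exposure exposure column name (e.g. `"bmi"` or `"ua"`).
#' @param mutual_adjustment column added in model 3 (the paired
#'   exposure/mediator, e.g. `"ua"` when the exposure is `"bmi"`).
#' @param binary_threshold cut-off for the binary coding; `NA` skips it.
#' @param quartiles fit the quartile coding (Q1 reference).
#' @param sensitivity also fit model 3 after [sensitivity_exclude_first_year()].
#' @return data.frame with columns `exposure`, `coding`, `model`, `term`,
#'   `person_years`, `n_events`, `hr`, `ci_low`, `ci_high`, `pval`
#'   (reference rows carry `hr = 1` and `NA` intervals).
#' @export
run_model_suite <- function(data, exposure, mutual_adjustment,
                            binary_threshold = 24, quartiles = TRUE,
                            sensitivity = TRUE) {
  stopifnot(exposure %in% names(data))
  d <- data
  sc <- per_sd(d[[exposure]])
  d$.exp_sd <- sc$scaled
  if (!is.na(binary_threshold)) {
    d$.exp_bin <- as.integer(d[[exposure]] >= binary_threshold)
  }
  if (quartiles) {
    q <- assign_quartiles(d[[exposure]])
    d$.exp_q <- q$group
  }

  py <- function(rows) sum(d$time_years[rows], na.rm = TRUE)
  ev <- function(rows) sum(d$event[rows], na.rm = TRUE)

  rows_for <- function(fit, coding, model, dat, strata_col = NULL) {
    keep <- grepl("^\\.exp", fit$hr$term)
    hr <- fit$hr[keep, , drop = FALSE]
    out <- data.frame(exposure = exposure, coding = coding, model = model,
                      term = sub("^\\.exp_(sd|bin|q)", coding, hr$term),
                      person_years = NA_real_, n_events = NA_real_,
                      hr = hr$hr, ci_low = hr$ci_low, ci_high = hr$ci_high,
                      pval = hr$pval, stringsAsFactors = FALSE)
    out
  }

  fit_block <- function(dat, term, coding, model) {
    cov <- model_covariates(model, mutual_adjustment)
    fit <- fit_cox(dat, c(term, cov))
    rows_for(fit, coding, as.character(model), dat)
  }

  res <- list()
  for (m in 1:3) {
    res[[length(res) + 1L]] <- fit_block(d, ".exp_sd", "per_sd", m)
    if (!is.na(binary_threshold)) {
      res[[length(res) + 1L]] <- fit_block(d, ".exp_bin", "binary", m)
    }
    if (quartiles) {
      block <- fit_block(d, ".exp_q", "quartile", m)
      ref <- data.frame(exposure = exposure, coding = "quartile",
                        model = as.character(m),
                        term = "quartileQ1", person_years = NA_real_,
                        n_events = NA_real_, hr = 1, ci_low = NA_real_,
                        ci_high = NA_real_, pval = NA_real_,
                        stringsAsFactors = FALSE)
      res[[length(res) + 1L]] <- rbind(ref, block)
    }
  }
  if (sensitivity) {
    ds <- sensitivity_exclude_first_year(d)
    res[[length(res) + 1L]] <- transform(
      fit_block(ds, ".exp_sd", "per_sd", 3), model = "3_sensitivity")
  }
  out <- do.call(rbind, res)

  # person-years / events per stratum
  fill <- function(coding, term, rows) {
    i <- out$coding == coding & out$term == term
    out$person_years[i] <<- py(rows)
    out$n_events[i] <<- ev(rows)
  }
  fill("per_sd", "per_sd", !is.na(d$.exp_sd))
  if (!is.na(binary_threshold)) {
    fill("binary", "binary", !is.na(d$.exp_bin) & d$.exp_bin == 1)
  }
  if (quartiles) {
    for (qq in paste0("Q", 1:4)) {
      fill("quartile", paste0("quartile", qq), !is.na(d$.exp_q) & d$.exp_q == qq)
    }
  }
  rownames(out) <- NULL
  attr(out, "exposure_sd") <- sc$sd
  out
}
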