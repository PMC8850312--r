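test_that("follow-up runs to the earliest terminating date, event only on diagnosis", {
  fu <- compute_follow_up("2010-01-01", diagnosis_date = "2015-01-01",
                          admin_end_date = "2018-12-31")
  expect_equal(fu$time_years, as.numeric(as.Date("2015-01-01") -
                                           as.Date("2010-01-01")) / 365.25)
  expect_equal(fu$event, 1L)
  expect_equal(round(fu$time_years, 1), 5.0)

  fu2 <- compute_follow_up("2013-06-01", admin_end_date = "2018-12-31")
  expect_equal(fu2$event, 0L)
  expect_equal(fu2$time_years, 5.58, tolerance = 0.01)

  # death precedes a (recorded) later diagnosis: censored at death
  fu3 <- compute_follow_up("2010-01-01", diagnosis_date = "2015-06-01",
                           death_date = "2014-06-01",
                           admin_end_date = "2018-12-31")
  expect_equal(fu3$event, 0L)
  expect_equal(fu3$time_years,
               as.numeric(as.Date("2014-06-01") - as.Date("2010-01-01")) /
                 365.25)
  expect_error(compute_follow_up("2019-01-01", admin_end_date = "2018-12-31"),
               "negative")
})

test_that("per-SD scaling divides by the n-1 sample SD and is scale-equivariant", {
  sc <- per_sd(c(1, 2, 3))
  expect_equal(sc$sd, 1)
  expect_equal(sc$scaled, c(1, 2, 3))
  v <- c(2, 4, 9, 11, NA)
  a <- per_sd(v)
  b <- per_sd(v * 10)
  expect_equal(b$sd, 10 * a$sd)
  expect_equal(b$scaled, a$scaled)
  expect_true(is.na(a$scaled[5]))
  expect_error(per_sd(c(3, 3, 3)), "zero variance")
  expect_error(per_sd(c(1, NA, NA)), "non-missing")
})

test_that("quartile cut points are interpolated percentiles with ties going lower", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q$group),
               rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
  expect_equal(q$cut_points, quantile(1:8, c(0.25, 0.5, 0.75), names = FALSE))
  # a value exactly on the median cut point belongs to the lower group
  q2 <- assign_quartiles(c(1, 2, 2, 3))
  expect_equal(as.character(q2$group)[2:3], c("Q2", "Q2"))
  expect_error(assign_quartiles(rep(5, 10)), "degenerate")
  # normal data: cut points near mean and mean +/- 0.674 sd
  set.seed(8)
  x <- rnorm(20000, 273, 75)
  q3 <- assign_quartiles(x)
  expect_equal(q3$cut_points, 273 + qnorm(c(0.25, 0.5, 0.75)) * 75,
               tolerance = 0.01)
})

test_that("the null Cox model log partial likelihood counts risk sets", {
  d <- data.frame(time_years = c(1, 2, 3), event = c(1L, 1L, 1L))
  fit <- fit_cox(d, character(0))
  expect_equal(fit$loglik, -log(6))
  expect_equal(fit$n_events, 3)
  expect_equal(nrow(ph_check(fit)), 0L)  # nothing to test without covariates
})

test_that("the Cox coefficient matches a grid search of the hand-written partial likelihood", {
  d <- micro_fixtures()$cox5
  fit <- fit_cox(d, "x")
  oracle <- cox_grid_oracle(d$time_years, d$event, d$x)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
  # and the reported optimum is at least as good as the grid's best
  expect_gte(cox_partial_loglik(unname(fit$coefficients), d$time_years,
                                d$event, d$x),
             cox_partial_loglik(oracle, d$time_years, d$event, d$x) - 1e-10)
})

test_that("rescaling a covariate rescales its coefficient, leaving the HR per original unit fixed", {
  d <- micro_fixtures()$cox5
  d$x10 <- d$x * 10
  f1 <- fit_cox(d, "x")
  f2 <- fit_cox(d, "x10")
  expect_equal(unname(f2$coefficients), unname(f1$coefficients) / 10,
               tolerance = 1e-8)
})

test_that("Efron and Breslow tie corrections coincide on untied data", {
  set.seed(12)
  d <- data.frame(time_years = rexp(60), event = rbinom(60, 1, 0.6),
                  x = rnorm(60))
  fe <- fit_cox(d, "x", ties = "efron")
  fb <- fit_cox(d, "x", ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)
})

test_that("complete-case filtering and HR formatting are reported in the fit", {
  set.seed(13)
  d <- data.frame(time_years = rexp(100) + 0.01, event = rbinom(100, 1, 0.5),
                  x = rnorm(100))
  d$x[1:10] <- NA
  fit <- fit_cox(d, "x")
  expect_equal(fit$n_used, 90)
  expect_equal(fit$hr$hr, exp(unname(fit$coefficients)))
  expect_equal(fit$hr$ci_low, exp(unname(fit$coefficients) -
                                    qnorm(0.975) * fit$hr$se))
})

test_that("first-year sensitivity removes early cases but keeps early censoring", {
  d <- data.frame(time_years = c(0.5, 0.5, 2, 0.99, 1.01),
                  event = c(1L, 0L, 1L, 1L, 1L))
  out <- sensitivity_exclude_first_year(d)
  expect_equal(nrow(out), 3L)
  expect_true(all(!(out$event == 1 & out$time_years < 1)))
  clean <- data.frame(time_years = c(2, 3), event = c(1L, 0L))
  expect_identical(sensitivity_exclude_first_year(clean), clean)
  # counting oracle: injected early cases drop n by exactly their number
  co <- simulate_cohort(n_subjects = 2000, seed = 3)
  co <- co[!(co$event == 1 & co$time_years < 1), ]
  inject <- co[1:10, ]
  inject$event <- 1L
  inject$time_years <- 0.4
  expect_equal(nrow(sensitivity_exclude_first_year(rbind(co, inject))),
               nrow(co))
})

test_that("the PH check flags a strongly time-varying effect and passes a PH model", {
  set.seed(14)
  n <- 1500
  x <- rbinom(n, 1, 0.5)
  # increasing-hazard group vs decreasing-hazard group: grossly non-PH
  t_nonph <- ifelse(x == 1, rweibull(n, 4, 2), rweibull(n, 0.5, 2))
  d <- data.frame(time_years = pmin(t_nonph, 5),
                  event = as.integer(t_nonph <= 5), x = x)
  flags <- ph_check(fit_cox(d, "x"))
  expect_true(flags$violation[flags$term == "x"])
  # proportional hazards: exponential times, multiplicative effect
  t_ph <- rexp(n, rate = 0.2 * exp(0.5 * x))
  d2 <- data.frame(time_years = pmin(t_ph, 5),
                   event = as.integer(t_ph <= 5), x = x)
  flags2 <- ph_check(fit_cox(d2, "x"))
  expect_false(flags2$violation[flags2$term == "x"])
})

test_that("the model suite reproduces the expected table structure", {
  co <- simulate_cohort(n_subjects = 6000, target_incidence = 0.04, seed = 15)
  res <- run_model_suite(co, "bmi", "ua", binary_threshold = 24)
  expect_setequal(unique(res$coding), c("per_sd", "binary", "quartile"))
  expect_setequal(unique(res$model), c("1", "2", "3", "3_sensitivity"))
  # Q1 is the reference in every quartile block
  q1 <- res[res$coding == "quartile" & res$term == "quartileQ1", ]
  expect_true(all(q1$hr == 1))
  # person-years over quartile strata sum to the per-SD (all-subject) total
  q_py <- res[res$coding == "quartile" & res$model == "1" &
                res$term != "quartileQ1", "person_years"]
  q1_py <- res[res$coding == "quartile" & res$model == "1" &
                 res$term == "quartileQ1", "person_years"]
  tot <- res[res$coding == "per_sd" & res$model == "1", "person_years"]
  expect_equal(sum(q_py) + q1_py, tot, tolerance = 1e-8)
  # per-SD estimate is in the right neighbourhood of the generating truth
  truth <- attr(co, "truth")
  per_sd_hr <- res[res$coding == "per_sd" & res$model == "3", ]
  expect_gt(per_sd_hr$ci_high, exp(truth$theta1 * truth$exposure_sd) * 0.9)
  expect_gt(exp(truth$theta1 * truth$exposure_sd), per_sd_hr$ci_low * 0.9)
})
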