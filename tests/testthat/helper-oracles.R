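# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Weighted through-origin regression slope/SE via stats::lm — the closed-form
# twin of the fixed-effect inverse-variance weighted estimator.
ivw_lm_oracle <- function(table) {
  w <- 1 / table$se_outcome^2
  fit <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = table, weights = w)
  beta <- unname(coef(fit))
  # model-based (fixed-effect) SE, not the lm residual-scaled one
  se <- sqrt(1 / sum(w * table$beta_exposure^2))
  list(beta = beta, se = se)
}

# Hand-written Cox partial likelihood for untied, single-covariate data.
cox_partial_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Grid-search maximizer of the hand-written partial likelihood.
cox_grid_oracle <- function(time, event, x, lower = -5, upper = 5,
                            step = 1e-4) {
  grid <- seq(lower, upper, by = step)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Harmonized-table constructor for estimator tests: unit exposure betas give
# Wald ratios equal to the outcome betas.
toy_table <- function(ratios, se_outcome = rep(0.1, length(ratios)),
                      beta_exposure = rep(1, length(ratios)),
                      se_exposure = rep(0.01, length(ratios))) {
  data.frame(
    snp_id = sprintf("rs%06d", seq_along(ratios)),
    beta_exposure = beta_exposure,
    se_exposure = se_exposure,
    pval_exposure = 2 * pnorm(-abs(beta_exposure / se_exposure)),
    beta_outcome = ratios * beta_exposure,
    se_outcome = se_outcome,
    pval_outcome = 2 * pnorm(-abs(ratios * beta_exposure / se_outcome)),
    stringsAsFactors = FALSE
  )
}
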