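#' @importFrom stats pnorm qnorm rnorm sd median quantile setNames
NULL

Z975 <- stats::qnorm(0.975)

mr_estimate <- function(method, beta, se, n_snps) {
  z <- beta / se
  structure(list(method = method,
                 beta = beta,
                 se = se,
                 ci_low = beta - Z975 * se,
                 ci_high = beta + Z975 * se,
                 pval = 2 * stats::pnorm(-abs(z)),
                 n_snps = n_snps),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (95%% CI %.4f, %.4f), p = %.3g, n_snps = %d\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$pval, x$n_snps))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' Ratio of outcome to exposure effect per instrument, with the first-order
#' delta-method standard error \eqn{se_Y / |\beta_X|}.
#'
#' @param table harmonized summary table.
#' @return data.frame with columns `snp_id`, `ratio`, `se_ratio`.
#' @export
wald_ratio <- function(table) {
  check_summary_table(table)
  if (any(table$beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure = 0 for ",
         paste(table$snp_id[table$beta_exposure == 0], collapse = ", "))
  }
  data.frame(snp_id = table$snp_id,
             ratio = table$beta_outcome / table$beta_exposure,
             se_ratio = table$se_outcome / abs(table$beta_exposure),
             stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance weighted estimator
#'
#' Combines all instruments assuming one common causal effect:
#' \deqn{\hat\beta = \frac{\sum_j \beta_{Xj}\beta_{Yj}/se_{Yj}^2}
#'                        {\sum_j \beta_{Xj}^2/se_{Yj}^2},\qquad
#'       SE = \sqrt{1 / \sum_j \beta_{Xj}^2/se_{Yj}^2},}
#' equivalent to a weighted regression of outcome on exposure betas through
#' the origin, or to meta-analysing the Wald ratios with inverse-variance
#' weights \eqn{1/se_{ratio}^2}. Two-sided normal p-value.
#'
#' @param table harmonized summary table (>= 1 SNP, all exposure betas nonzero).
#' @return an `mr_estimate` (method `"IVW"`).
#' @export
mr_ivw <- function(table) {
  check_summary_table(table)
  if (any(table$beta_exposure == 0)) stop("beta_exposure must be nonzero for IVW")
  w <- 1 / table$se_outcome^2
  denom <- sum(w * table$beta_exposure^2)
  beta <- sum(w * table$beta_exposure * table$beta_outcome) / denom
  mr_estimate("IVW", beta, sqrt(1 / denom), nrow(table))
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)           # stable: ties keep input order
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = list("ordered", mean))$y
}

#' Weighted-median causal estimator
#'
#' The 50%-cumulative-weight point of the ordered Wald ratios, with weights
#' proportional to the inverse variance of each ratio. Consistent when
#' instruments carrying at least half of the weight are valid. The point
#' estimate is deterministic; the standard error comes from a parametric
#' bootstrap resampling \eqn{\beta_{Xj}^* \sim N(\beta_{Xj}, se_{Xj})} and
#' \eqn{\beta_{Yj}^* \sim N(\beta_{Yj}, se_{Yj})}.
#'
#' @param table harmonized summary table.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed integer seed for the bootstrap (required for reproducibility).
#' @return an `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(table, n_boot = 1000, seed = NULL) {
  check_summary_table(table)
  if (nrow(table) < 3) warning("weighted median with fewer than 3 instruments")
  wr <- wald_ratio(table)
  weights <- 1 / wr$se_ratio^2
  if (!any(is.finite(weights) & weights > 0)) {
    stop("all weights are zero or non-finite")
  }
  est <- weighted_median_point(wr$ratio, weights)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table)
  boot <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(n, table$beta_exposure, table$se_exposure)
    by <- stats::rnorm(n, table$beta_outcome, table$se_outcome)
    ok <- bx != 0
    weighted_median_point(by[ok] / bx[ok],
                          (abs(bx[ok]) / table$se_outcome[ok])^2)
  }, numeric(1))
  mr_estimate("weighted_median", est, stats::sd(boot), n)
}

loo_ivw_slopes <- function(bx, by, w) {
  # leave-one-out slope of the weighted through-origin regression, closed form
  s_xy <- sum(w * bx * by)
  s_xx <- sum(w * bx^2)
  (s_xy - w * bx * by) / (s_xx - w * bx^2)
}

#' MR-PRESSO global and outlier tests
#'
#' Residual-sum-of-squares resampling test for horizontal pleiotropy in the
#' instrument-outcome versus instrument-exposure regression. For each SNP the
#' leave-one-out IVW slope \eqn{\hat\beta_{(-j)}} gives an expected outcome
#' effect; the observed weighted residual sum
#' \eqn{RSS_{obs} = \sum_j w_j (\beta_{Yj} - \hat\beta_{(-j)}\beta_{Xj})^2}
#' (weights \eqn{w_j = 1/se_{Yj}^2}) is compared with its distribution under
#' the no-pleiotropy model, simulated by redrawing
#' \eqn{\beta_{Yj}^{sim} \sim N(\hat\beta_{(-j)}\beta_{Xj}, se_{Yj})}.
#' Per-SNP outlier p-values compare each observed squared residual with its
#' simulated distribution, Bonferroni-adjusted by the number of instruments;
#' the corrected estimate is the fixed-effect IVW on non-outliers. The
#' distortion test of the original method is not included.
#'
#' @param table harmonized summary table with at least 4 instruments.
#' @param n_sim simulated replicate tables (>= 100; default 1000).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed integer seed; fixed seeds give bit-identical results.
#' @return a list of class `presso_result`: `global_pval`, `outlier_pvals`
#'   (named, Bonferroni-adjusted), `outlier_ids`, `corrected`
#'   (an `mr_estimate` on non-outliers, method `"MR_PRESSO"`), `rss_obs`,
#'   `n_simulations`, `seed`.
#' @export
mr_presso <- function(table, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  check_summary_table(table)
  n <- nrow(table)
  if (n < 4) stop("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)

  bx <- table$beta_exposure
  by <- table$beta_outcome
  sy <- table$se_outcome
  w <- 1 / sy^2
  slopes <- loo_ivw_slopes(bx, by, w)
  res2_obs <- w * (by - slopes * bx)^2
  rss_obs <- sum(res2_obs)

  # one simulated table per column; recompute LOO slopes within each replicate
  mu <- slopes * bx
  ysim <- matrix(stats::rnorm(n * n_sim, mean = mu, sd = sy), nrow = n)
  s_xy <- colSums(w * bx * ysim)
  s_xx <- sum(w * bx^2)
  slopes_sim <- (matrix(s_xy, n, n_sim, byrow = TRUE) - (w * bx) * ysim) /
    (s_xx - w * bx^2)
  res2_sim <- w * (ysim - slopes_sim * bx)^2
  rss_sim <- colSums(res2_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_raw <- (1 + rowSums(res2_sim >= res2_obs)) / (n_sim + 1)
  outlier_pvals <- pmin(1, outlier_raw * n)
  names(outlier_pvals) <- table$snp_id
  outlier_ids <- table$snp_id[outlier_pvals < outlier_alpha]

  keep <- !(table$snp_id %in% outlier_ids)
  if (!any(keep)) stop("all instruments flagged as outliers; no corrected estimate")
  corrected <- mr_ivw(table[keep, , drop = FALSE])
  corrected$method <- "MR_PRESSO"

  structure(list(global_pval = global_pval,
                 outlier_pvals = outlier_pvals,
                 outlier_ids = outlier_ids,
                 corrected = corrected,
                 rss_obs = rss_obs,
                 n_simulations = n_sim,
                 seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global p = %.4g (RSS_obs = %.4g, %d simulations)\n",
              x$global_pval, x$rss_obs, x$n_simulations))
  if (length(x$outlier_ids)) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat("  no outliers detected\n")
  }
  print(x$corrected)
  invisible(x)
}

#' Run every MR estimator on one summary table
#'
#' @param table harmonized summary table.
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulation replicates.
#' @param seed integer seed for the stochastic estimators.
#' @return data.frame with one row per method (IVW, weighted median,
#'   MR-PRESSO corrected) and columns `method`, `n_snps`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`.
#' @export
mr_all_methods <- function(table, n_boot = 1000, n_sim = 1000, seed = NULL) {
  res <- list(
    as.data.frame(mr_ivw(table)),
    as.data.frame(mr_weighted_median(table, n_boot = n_boot, seed = seed)),
    as.data.frame(mr_presso(table, n_sim = n_sim, seed = seed)$corrected)
  )
  do.call(rbind, res)
}

#' Bidirectional two-sample MR driver
#'
#' For each direction (forward: exposure -> outcome; reverse: outcome ->
#' exposure on its own instrument set) runs instrument selection and all
#' three estimators twice — on all instruments passing the strength filters,
#' and after additionally applying the direction's pleiotropy exclusion list —
#' reproducing the four-block layout of a bidirectional MR results table.
#'
#' @param forward,reverse harmonized summary tables for the two directions.
#' @param forward_exclusions,reverse_exclusions snp_ids excluded as
#'   pleiotropic in each direction.
#' @param config base [selection_config()] (strength filters; its
#'   exclusion_list is ignored in favour of the per-direction lists).
#' @param n_boot,n_sim,seed passed to the stochastic estimators.
#' @return tidy data.frame with columns `direction` (forward/reverse),
#'   `iv_set` (`all` / `pruned`), `method`, `n_snps`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`.
#' @export
bidirectional_mr <- function(forward, reverse,
                             forward_exclusions = character(),
                             reverse_exclusions = character(),
                             config = selection_config(),
                             n_boot = 1000, n_sim = 1000, seed = NULL) {
  one_block <- function(table, exclusions, direction, iv_set) {
    cfg <- selection_config(f_threshold = config$f_threshold,
                            gwas_p_threshold = config$gwas_p_threshold,
                            exclusion_list = exclusions)
    sel <- select_instruments(table, cfg)
    if (nrow(sel$retained) == 0L) {
      stop("no instruments retained for ", direction, " (", iv_set, ") block")
    }
    cbind(direction = direction, iv_set = iv_set,
          mr_all_methods(sel$retained, n_boot = n_boot, n_sim = n_sim,
                         seed = seed),
          stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_block(forward, character(), "forward", "all"),
    one_block(forward, forward_exclusions, "forward", "pruned"),
    one_block(reverse, character(), "reverse", "all"),
    one_block(reverse, reverse_exclusions, "reverse", "pruned")
  )
  rownames(out) <- NULL
  out
}
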