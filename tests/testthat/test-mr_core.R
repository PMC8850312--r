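test_that("Wald ratios follow the delta-method formula", {
  tab <- data.frame(snp_id = c("a", "b", "c"),
                    beta_exposure = c(1, 2, -1),
                    se_exposure = c(0.1, 0.1, 0.1),
                    pval_exposure = rep(1e-10, 3),
                    beta_outcome = c(0.5, 0.5, 0.3),
                    se_outcome = c(0.1, 0.2, 0.1),
                    pval_outcome = rep(0.01, 3))
  wr <- wald_ratio(tab)
  expect_equal(wr$ratio, c(0.5, 0.25, -0.3))
  expect_equal(wr$se_ratio, c(0.1, 0.1, 0.1))
  tab$beta_exposure[1] <- 0
  expect_error(wald_ratio(tab), "degenerate")
})

test_that("IVW collapses to the Wald ratio for a single instrument", {
  tab <- toy_table(0.37, se_outcome = 0.12)
  est <- mr_ivw(tab)
  wr <- wald_ratio(tab)
  expect_equal(est$beta, wr$ratio)
  expect_equal(est$se, wr$se_ratio)
  expect_equal(est$n_snps, 1L)
})

test_that("IVW matches the weighted through-origin regression oracle", {
  # frozen two-instrument case: beta = 0.3, se = sqrt(1/200)
  tab2 <- toy_table(c(0.2, 0.4), se_outcome = c(0.1, 0.1))
  est2 <- mr_ivw(tab2)
  expect_equal(est2$beta, 0.3, tolerance = 1e-12)
  expect_equal(est2$se, sqrt(1 / 200), tolerance = 1e-12)
  # random tables against the lm oracle
  for (s in 1:5) {
    tab <- simulate_gwas(n_snps = 30, se_outcome = runif(30, 0.002, 0.01),
                         seed = s)
    est <- mr_ivw(tab)
    oracle <- ivw_lm_oracle(tab)
    expect_equal(est$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(est$se, oracle$se, tolerance = 1e-10)
    # permutation invariance
    perm <- tab[sample(nrow(tab)), ]
    expect_equal(mr_ivw(perm)$beta, est$beta, tolerance = 1e-12)
  }
})

test_that("doubling every outcome SE doubles the IVW SE and fixes the estimate", {
  tab <- simulate_gwas(n_snps = 40, seed = 11)
  est <- mr_ivw(tab)
  tab2 <- tab
  tab2$se_outcome <- 2 * tab2$se_outcome
  est2 <- mr_ivw(tab2)
  expect_equal(est2$beta, est$beta, tolerance = 1e-12)
  expect_equal(est2$se, 2 * est$se, tolerance = 1e-12)
})

test_that("confidence intervals and p-values are normal-theory on the estimate scale", {
  est <- mr_ivw(simulate_gwas(n_snps = 20, seed = 5))
  expect_equal(est$ci_low, est$beta - 1.96 * est$se, tolerance = 1e-4)
  expect_equal(est$ci_high, est$beta + 1.96 * est$se, tolerance = 1e-4)
  expect_equal(est$pval, 2 * pnorm(-abs(est$beta / est$se)))
})

test_that("the weighted median interpolates the 50% cumulative-weight point", {
  tab <- toy_table(c(0.1, 0.2, 0.3))
  est <- mr_weighted_median(tab, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.2)
  # equal weights, odd n: ordinary median, any ordering
  for (s in 1:5) {
    set.seed(s)
    ratios <- round(rnorm(7, 0.2, 0.3), 3)
    est <- mr_weighted_median(toy_table(sample(ratios)), n_boot = 200,
                              seed = s)
    expect_equal(est$beta, median(ratios))
  }
})

test_that("the weighted median stays within the ratio range and resists one outlier", {
  # single wild ratio among five concordant equal-weight instruments
  tab <- toy_table(c(0.18, 0.19, 0.21, 0.22, 10))
  est <- mr_weighted_median(tab, n_boot = 200, seed = 2)
  expect_gte(est$beta, 0.18)
  expect_lte(est$beta, 0.22)
  # range property on random unequal-weight tables
  for (s in 1:10) {
    set.seed(s)
    n <- sample(3:15, 1)
    tab <- toy_table(rnorm(n, 0.2, 0.5), se_outcome = runif(n, 0.05, 0.5))
    est <- mr_weighted_median(tab, n_boot = 200, seed = s)
    wr <- wald_ratio(tab)
    expect_gte(est$beta, min(wr$ratio))
    expect_lte(est$beta, max(wr$ratio))
  }
})

test_that("the weighted-median point estimate is deterministic, its bootstrap SE seed-stable", {
  tab <- simulate_gwas(n_snps = 30, seed = 9)
  a <- mr_weighted_median(tab, n_boot = 300, seed = 4)
  b <- mr_weighted_median(tab, n_boot = 300, seed = 4)
  c <- mr_weighted_median(tab, n_boot = 300, seed = 5)
  expect_identical(a$se, b$se)
  expect_equal(a$beta, c$beta)  # point estimate independent of the seed
  expect_false(identical(a$se, c$se))
})

test_that("MR-PRESSO is seed-reproducible with a valid global p-value", {
  tab <- simulate_gwas(n_snps = 50, seed = 21)
  a <- mr_presso(tab, n_sim = 500, seed = 3)
  b <- mr_presso(tab, n_sim = 500, seed = 3)
  expect_identical(a$global_pval, b$global_pval)
  expect_identical(a$outlier_pvals, b$outlier_pvals)
  expect_gt(a$global_pval, 0)
  expect_lte(a$global_pval, 1)
  expect_length(a$outlier_ids, 0)  # clean table: nothing flagged
  expect_equal(a$corrected$beta, mr_ivw(tab)$beta)
  expect_error(mr_presso(tab[1:3, ], seed = 1), "at least 4")
  expect_error(mr_presso(tab, n_sim = 50, seed = 1), "n_sim")
})

test_that("MR-PRESSO flags a constructed 10-SE outlier and corrects toward the truth", {
  tab <- simulate_gwas(n_snps = 50, true_theta = 0.2, seed = 21)
  tab$beta_outcome[7] <- tab$beta_outcome[7] + 10 * tab$se_outcome[7]
  res <- mr_presso(tab, n_sim = 1000, seed = 3)
  expect_identical(res$outlier_ids, tab$snp_id[7])
  expect_lt(res$global_pval, 0.05)
  # the corrected estimate is exactly the IVW without the planted SNP, and
  # removing an upward-displaced instrument must pull the estimate down
  expect_equal(res$corrected$beta, mr_ivw(tab[-7, ])$beta, tolerance = 1e-12)
  uncorrected <- mr_ivw(tab)
  expect_gt(uncorrected$beta, res$corrected$beta)
  expect_lt(abs(res$corrected$beta - 0.2), 2 * res$corrected$se)
  expect_equal(res$corrected$n_snps, 49L)
})

test_that("the bidirectional driver reproduces the four-block results layout", {
  forward <- simulate_gwas(n_snps = 40, true_theta = 0.2, seed = 31)
  reverse <- simulate_gwas(n_snps = 30, true_theta = 0, seed = 32)
  res <- bidirectional_mr(forward, reverse,
                          forward_exclusions = forward$snp_id[1:8],
                          reverse_exclusions = reverse$snp_id[1:5],
                          n_boot = 200, n_sim = 200, seed = 1)
  expect_equal(nrow(res), 12L)
  expect_setequal(unique(res$direction), c("forward", "reverse"))
  expect_setequal(unique(res$iv_set), c("all", "pruned"))
  fwd <- res[res$direction == "forward", ]
  expect_true(all(fwd$ci_low > 0))                   # strong positive effect
  rev <- res[res$direction == "reverse", ]
  expect_true(all(abs(rev$beta) < 3 * rev$se))       # null: no effect detected
  expect_equal(res$n_snps[res$direction == "forward" & res$iv_set == "pruned" &
                            res$method == "IVW"], 32L)
})

test_that("empty exclusion lists make the pruned block equal the all-SNP block", {
  forward <- simulate_gwas(n_snps = 25, seed = 41)
  reverse <- simulate_gwas(n_snps = 25, true_theta = 0, seed = 42)
  res <- bidirectional_mr(forward, reverse, n_boot = 200, n_sim = 200,
                          seed = 7)
  for (dir in c("forward", "reverse")) {
    all_block <- res[res$direction == dir & res$iv_set == "all", -2]
    pruned <- res[res$direction == dir & res$iv_set == "pruned", -2]
    rownames(all_block) <- rownames(pruned) <- NULL
    expect_equal(all_block, pruned)
  }
})
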