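#' Per-SNP F-statistic from summary statistics
#'
#' Instrument strength computed as the squared Wald z, \eqn{F = (\beta/SE)^2},
#' the only form available from summary data alone. F < 10 conventionally
#' marks a weak instrument.
#'
#' @param beta_exposure per-allele effect(s) on the exposure.
#' @param se_exposure standard error(s), positive.
#' @return numeric vector of F values.
#' @examples
#' f_statistic(0.0317, 0.01)  # ~10.05, retained at the usual threshold
#' @export
f_statistic <- function(beta_exposure, se_exposure) {
  if (any(se_exposure <= 0)) stop("se_exposure must be positive")
  (beta_exposure / se_exposure)^2
}

#' Instrument selection configuration
#'
#' @param f_threshold minimum per-SNP F (default 10).
#' @param gwas_p_threshold maximum exposure p-value (default 5e-8,
#'   genome-wide significance).
#' @param exclusion_list character vector of snp_ids to remove as pleiotropic
#'   (typically variants associated with traits other than the exposure).
#' @return a list of class `selection_config`.
#' @export
selection_config <- function(f_threshold = 10, gwas_p_threshold = 5e-8,
                             exclusion_list = character()) {
  stopifnot(f_threshold >= 0,
            gwas_p_threshold > 0, gwas_p_threshold <= 1)
  structure(list(f_threshold = f_threshold,
                 gwas_p_threshold = gwas_p_threshold,
                 exclusion_list = as.character(exclusion_list)),
            class = "selection_config")
}

#' Read a pleiotropy exclusion list
#'
#' Plain text, one snp_id per line; blank lines and lines starting with `#`
#' are ignored.
#' @param path file path.
#' @return character vector of snp_ids.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("exclusion list not found: ", path)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids) & !startsWith(ids, "#")]
}

#' Select instruments for MR
#'
#' Applies the instrument QC filters in a fixed order: exposure p-value
#' (genome-wide significance), per-SNP F-statistic (weak-instrument removal),
#' then the pleiotropy exclusion list. A SNP failing several criteria is
#' counted once, under the first failed criterion in that order. The retained
#' table preserves input order.
#'
#' @param table harmonized summary table (see [harmonize()]).
#' @param config a [selection_config()].
#' @return a list of class `selection_report` with elements `retained`
#'   (filtered summary table), `f_values` (named per-SNP F for the full
#'   input), `n_removed_pvalue`, `n_removed_weak`, `n_removed_pleiotropy`.
#' @export
select_instruments <- function(table, config = selection_config()) {
  check_summary_table(table)
  stopifnot(inherits(config, "selection_config"))
  f_values <- f_statistic(table$beta_exposure, table$se_exposure)
  names(f_values) <- table$snp_id

  fail_p    <- !is.na(table$pval_exposure) &
               table$pval_exposure >= config$gwas_p_threshold
  fail_f    <- f_values < config$f_threshold
  fail_plei <- table$snp_id %in% config$exclusion_list

  n_removed_pvalue     <- sum(fail_p)
  n_removed_weak       <- sum(fail_f & !fail_p)
  n_removed_pleiotropy <- sum(fail_plei & !fail_p & !fail_f)

  retained <- table[!(fail_p | fail_f | fail_plei), , drop = FALSE]
  rownames(retained) <- NULL
  for (a in c("exposure_name", "outcome_name")) {
    attr(retained, a) <- attr(table, a)
  }
  structure(list(retained = retained,
                 f_values = f_values,
                 n_removed_pvalue = n_removed_pvalue,
                 n_removed_weak = n_removed_weak,
                 n_removed_pleiotropy = n_removed_pleiotropy),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Instrument selection report\n")
  cat("  input SNPs:            ",
      nrow(x$retained) + x$n_removed_pvalue + x$n_removed_weak +
        x$n_removed_pleiotropy, "\n")
  cat("  removed (p-value):     ", x$n_removed_pvalue, "\n")
  cat("  removed (weak, F):     ", x$n_removed_weak, "\n")
  cat("  removed (pleiotropy):  ", x$n_removed_pleiotropy, "\n")
  cat("  retained:              ", nrow(x$retained), "\n")
  invisible(x)
}
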