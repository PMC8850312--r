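#' Two-sample MR from files
#'
#' Convenience wrapper: reads single-trait exposure and outcome tables,
#' harmonizes them, applies instrument selection, and runs the requested
#' estimators. This is what the command-line `mr` and `presso` subcommands
#' call.
#'
#' @param exposure_path,outcome_path single-trait summary-statistic files.
#' @param exclusion_list snp_ids to exclude as pleiotropic (or a file path
#'   via [read_exclusion_list()]).
#' @param f_threshold,gwas_p_threshold instrument-strength filters.
#' @param method `"ivw"`, `"wmedian"`, `"presso"` or `"all"`.
#' @param n_boot,n_sim,seed stochastic-estimator controls.
#' @return for `method = "presso"` a `presso_result`; otherwise a tidy
#'   data.frame of estimates. The selection report is attached as attribute
#'   `selection`.
#' @export
mr_from_files <- function(exposure_path, outcome_path,
                          exclusion_list = character(),
                          f_threshold = 10, gwas_p_threshold = 5e-8,
                          method = c("all", "ivw", "wmedian", "presso"),
                          n_boot = 1000, n_sim = 1000, seed = NULL) {
  method <- match.arg(method)
  exposure <- read_summary_table(exposure_path)
  outcome <- read_summary_table(outcome_path)
  tab <- harmonize(exposure, outcome)
  cfg <- selection_config(f_threshold = f_threshold,
                          gwas_p_threshold = gwas_p_threshold,
                          exclusion_list = exclusion_list)
  sel <- select_instruments(tab, cfg)
  res <- switch(method,
    ivw = as.data.frame(mr_ivw(sel$retained)),
    wmedian = as.data.frame(mr_weighted_median(sel$retained, n_boot = n_boot,
                                               seed = seed)),
    presso = mr_presso(sel$retained, n_sim = n_sim, seed = seed),
    all = mr_all_methods(sel$retained, n_boot = n_boot, n_sim = n_sim,
                         seed = seed))
  attr(res, "selection") <- sel
  res
}

#' Write a tab-separated results file with a JSON run-metadata sidecar
#'
#' Every command-line subcommand records its inputs, parameters, seed and
#' package version next to its results so runs are auditable.
#'
#' @param results data.frame to write.
#' @param path output TSV path; the sidecar is written to `<path>.meta.json`.
#' @param params named list of run parameters to record.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, params = list()) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  meta <- list(
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = params
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
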