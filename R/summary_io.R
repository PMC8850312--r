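#' Default column mapping for summary-statistic files
#'
#' Maps the internal field names of a SNP association record to the column
#' headers used in the input file. Repository-export and generic tables can
#' both be parsed by overriding individual entries.
#'
#' @param ... named overrides, e.g. `beta = "Effect"` or `snp_id = "rsid"`.
#' @return named character vector mapping internal names to file headers.
#' @examples
#' default_column_map()
#' default_column_map(beta = "Effect", se = "StdErr")
#' @export
default_column_map <- function(...) {
  map <- c(
    snp_id = "SNP", effect_allele = "EA", other_allele = "OA",
    beta = "BETA", se = "SE", pval = "P", n = "N"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(map))
    if (length(bad)) {
      stop("unknown column-map field(s): ", paste(bad, collapse = ", "))
    }
    map[names(overrides)] <- overrides
  }
  map
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated table of per-SNP association estimates (one trait),
#' validates each row, and drops rows whose beta or standard error cannot be
#' parsed (the dropped count is attached as an attribute and reported via
#' `message()`).
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map mapping from internal field names to file headers, as
#'   produced by [default_column_map()]. The `n` column is optional.
#' @return a data.frame of SNP records with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and (when present) `n`, one row per
#'   retained input row, in file order. Attribute `n_dropped` carries the
#'   number of unparseable rows removed.
#' @seealso [write_summary_table()], [harmonize()]
#' @export
read_summary_table <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("summary-statistic file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  if (nrow(raw) == 0L) stop("empty summary-statistic file: ", path)
  required <- setdiff(names(column_map), "n")
  missing_cols <- setdiff(unname(column_map[required]), names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  has_n <- !is.na(column_map["n"]) && column_map[["n"]] %in% names(raw)
  out <- data.frame(
    snp_id        = raw[[column_map[["snp_id"]]]],
    effect_allele = toupper(raw[[column_map[["effect_allele"]]]]),
    other_allele  = toupper(raw[[column_map[["other_allele"]]]]),
    beta          = suppressWarnings(as.numeric(raw[[column_map[["beta"]]]])),
    se            = suppressWarnings(as.numeric(raw[[column_map[["se"]]]])),
    pval          = suppressWarnings(as.numeric(raw[[column_map[["pval"]]]])),
    stringsAsFactors = FALSE
  )
  if (has_n) out$n <- suppressWarnings(as.integer(raw[[column_map[["n"]]]]))
  bad <- !is.finite(out$beta) | !is.finite(out$se) | out$se <= 0
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) with unparseable or invalid beta/se dropped from ",
            basename(path))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  stopifnot(all(out$pval >= 0 & out$pval <= 1, na.rm = TRUE))
  if (anyDuplicated(out$snp_id)) {
    stop("duplicated snp_id in ", path, "; one record per variant is required")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a summary-statistic or harmonized table
#'
#' Tab-separated UTF-8, "." decimal point, full double precision so that
#' read/write round-trips are exact.
#'
#' @param x a data.frame (SNP records or a harmonized summary table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins two single-trait SNP tables on `snp_id` and aligns the outcome
#' effect to the exposure's effect allele. When the outcome's effect/other
#' alleles are swapped relative to the exposure, the outcome beta is
#' sign-flipped; when the allele pairs are inconsistent (neither matched nor
#' swapped) the SNP is dropped. SNPs absent from the outcome table are dropped
#' and counted, mirroring the exclusion of instruments with missing outcome
#' estimates.
#'
#' Palindromic variants (A/T or C/G) cannot be strand-checked without allele
#' frequencies; by default they are kept with a warning, and
#' `drop_palindromic = TRUE` removes them (counted as inconsistent).
#'
#' @param exposure,outcome SNP record data.frames from [read_summary_table()].
#' @param exposure_name,outcome_name provenance labels stored as attributes.
#' @param drop_palindromic drop A/T and C/G variants instead of warning.
#' @return a harmonized summary table: one row per retained SNP with columns
#'   `snp_id`, `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `pval_exposure`, `beta_outcome`, `se_outcome`, `pval_outcome`. Attributes
#'   `n_dropped_missing` and `n_dropped_inconsistent` carry the bookkeeping
#'   counts; `exposure_name`/`outcome_name` carry provenance.
#' @export
harmonize <- function(exposure, outcome,
                      exposure_name = "exposure", outcome_name = "outcome",
                      drop_palindromic = FALSE) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (anyDuplicated(exposure$snp_id) || anyDuplicated(outcome$snp_id)) {
    stop("snp_id must be unique within each table before harmonization")
  }
  idx <- match(exposure$snp_id, outcome$snp_id)
  present <- !is.na(idx)
  n_missing <- sum(!present)
  if (!any(present)) stop("no overlapping SNPs between exposure and outcome tables")

  exp_m <- exposure[present, , drop = FALSE]
  out_m <- outcome[idx[present], , drop = FALSE]

  same    <- exp_m$effect_allele == out_m$effect_allele &
             exp_m$other_allele  == out_m$other_allele
  swapped <- exp_m$effect_allele == out_m$other_allele &
             exp_m$other_allele  == out_m$effect_allele
  # A variant may be recorded identically in both tables; "same" wins the tie.
  swapped <- swapped & !same
  consistent <- same | swapped

  pal <- is_palindromic(exp_m$effect_allele, exp_m$other_allele)
  if (drop_palindromic) {
    consistent <- consistent & !pal
  } else if (any(pal & consistent)) {
    warning(sum(pal & consistent),
            " palindromic (A/T or C/G) variant(s) kept; strand cannot be ",
            "verified without allele frequencies")
  }
  n_inconsistent <- sum(!consistent)

  keep <- which(consistent)
  tab <- data.frame(
    snp_id         = exp_m$snp_id[keep],
    effect_allele  = exp_m$effect_allele[keep],
    other_allele   = exp_m$other_allele[keep],
    beta_exposure  = exp_m$beta[keep],
    se_exposure    = exp_m$se[keep],
    pval_exposure  = exp_m$pval[keep],
    beta_outcome   = ifelse(swapped[keep], -out_m$beta[keep], out_m$beta[keep]),
    se_outcome     = out_m$se[keep],
    pval_outcome   = out_m$pval[keep],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(tab,
            n_dropped_missing = n_missing,
            n_dropped_inconsistent = n_inconsistent,
            exposure_name = exposure_name,
            outcome_name = outcome_name)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Validate a harmonized summary table
#'
#' Internal guard used by every estimator: non-empty, unique SNP ids,
#' positive standard errors on both sides.
#' @param table harmonized summary table.
#' @return `table`, invisibly.
#' @keywords internal
check_summary_table <- function(table) {
  needed <- c("snp_id", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("not a harmonized summary table; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("summary table is empty")
  if (anyDuplicated(table$snp_id)) stop("duplicated snp_id in summary table")
  if (any(table$se_exposure <= 0) || any(table$se_outcome <= 0)) {
    stop("standard errors must be positive")
  }
  invisible(table)
}
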