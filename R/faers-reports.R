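#' Assembled spontaneous-report set
#'
#' A `faers_reports` object holds the six linked FAERS-style tables as
#' tibbles keyed by `primaryid` (the report-version identifier):
#'
#' * `demo` — one row per report: `primaryid`, `caseid`, `fda_dt` (integer
#'   `YYYYMMDD`), `event_dt` (character, possibly partial), `sex`, `age` +
#'   `age_cod`, `wt` + `wt_cod`, `occp_cod`, `reporter_country`
#' * `drug` — `drug_seq`, `role_cod` (PS/SS/C/I), `drugname`, `prod_ai`
#' * `reac` — reaction preferred terms (`pt`)
#' * `ther` — therapy dates per drug (`dsg_drug_seq`, `start_dt`, `end_dt`)
#' * `indi` — indication preferred terms (`indi_drug_seq`, `indi_pt`)
#' * `outc` — outcome codes (`outc_cod`)
#'
#' @param demo,drug,reac,ther,indi,outc tibbles with the columns above.
#' @return A `faers_reports` object.
#' @export
faers_reports <- function(demo, drug, reac, ther, indi, outc) {
  stopifnot(
    all(c("primaryid", "caseid", "fda_dt") %in% names(demo)),
    all(c("primaryid", "drug_seq", "role_cod", "drugname") %in% names(drug)),
    all(c("primaryid", "pt") %in% names(reac))
  )
  structure(
    list(demo = tibble::as_tibble(demo),
         drug = tibble::as_tibble(drug),
         reac = tibble::as_tibble(reac),
         ther = tibble::as_tibble(ther),
         indi = tibble::as_tibble(indi),
         outc = tibble::as_tibble(outc)),
    class = "faers_reports"
  )
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports>\n")
  cat("  reports:", nrow(x$demo),
      "| cases:", length(unique(x$demo$caseid)), "\n")
  cat("  drug rows:", nrow(x$drug),
      "| reaction rows:", nrow(x$reac),
      "| therapy rows:", nrow(x$ther), "\n")
  invisible(x)
}

#' Number of reports in a report set
#' @param x a `faers_reports` object.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "faers_reports"))
  nrow(x$demo)
}

# restrict every table to a set of primaryids, preserving attributes we own
subset_reports <- function(x, ids) {
  out <- faers_reports(
    demo = dplyr::filter(x$demo, .data$primaryid %in% ids),
    drug = dplyr::filter(x$drug, .data$primaryid %in% ids),
    reac = dplyr::filter(x$reac, .data$primaryid %in% ids),
    ther = dplyr::filter(x$ther, .data$primaryid %in% ids),
    indi = dplyr::filter(x$indi, .data$primaryid %in% ids),
    outc = dplyr::filter(x$outc, .data$primaryid %in% ids)
  )
  attr(out, "truth") <- attr(x, "truth")
  out
}

#' Ground truth attached to a synthetic report set
#'
#' @param x a `faers_reports` object produced by [generate_reports()].
#' @return The ground-truth list (`survivors`, `drug_rows`, `exposure`,
#'   `planted`) or `NULL` for non-synthetic data.
#' @export
synthetic_truth <- function(x) attr(x, "truth")
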