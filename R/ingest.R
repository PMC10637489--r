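#' Read a quarter of FAERS-style dollar-delimited tables
#'
#' Parses the six expected files (`DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#' `THER.txt`, `INDI.txt`, `OUTC.txt`) from a directory. Fields are split on
#' the literal `$` delimiter (FAERS files carry no quoting or escaping);
#' Windows line endings are handled transparently. Rows whose field count
#' does not match the header are counted as malformed and excluded — never
#' silently dropped: the per-table malformed counts are kept as an attribute
#' and reading aborts if any table exceeds the tolerance.
#'
#' @param directory path containing the six files.
#' @param tolerance maximum tolerated fraction of malformed rows per table.
#' @return A named list of tibbles (`demo`, `drug`, `reac`, `ther`, `indi`,
#'   `outc`) with lowercase column names, dates kept as text (`event_dt`,
#'   `start_dt`, `end_dt`) except `fda_dt` (integer), and numeric `age`,
#'   `wt`, and sequence columns. Attribute `malformed` holds the per-table
#'   excluded-row counts.
#' @export
read_quarter <- function(directory, tolerance = 0.05) {
  files <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
             ther = "THER.txt", indi = "INDI.txt", outc = "OUTC.txt")
  paths <- file.path(directory, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    stop("missing mandatory file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  int_cols <- c("fda_dt", "drug_seq", "dsg_drug_seq", "indi_drug_seq")
  num_cols <- c("age", "wt")

  malformed <- integer(0)
  out <- lapply(seq_along(files), function(i) {
    lines <- readLines(paths[i], encoding = "UTF-8", warn = FALSE)
    lines <- sub("\r$", "", lines)
    if (!length(lines)) stop("empty file: ", files[i], call. = FALSE)
    header <- tolower(strsplit(lines[1], "$", fixed = TRUE)[[1]])
    body <- lines[-1]
    body <- body[nzchar(body)]
    fields <- strsplit(body, "$", fixed = TRUE)
    # strsplit drops a trailing empty field; pad to header length
    nf <- lengths(fields)
    short1 <- nf == length(header) - 1L & endsWith(body, "$")
    fields[short1] <- lapply(fields[short1], function(f) c(f, ""))
    nf <- lengths(fields)
    bad <- nf != length(header)
    n_bad <- sum(bad)
    if (length(body) && n_bad / length(body) > tolerance) {
      stop(sprintf("%s: %d of %d rows malformed (tolerance %.0f%%)",
                   files[i], n_bad, length(body), 100 * tolerance),
           call. = FALSE)
    }
    malformed[[names(files)[i]]] <<- n_bad
    good <- fields[!bad]
    mat <- matrix(as.character(unlist(good)), ncol = length(header),
                  byrow = TRUE)
    df <- stats::setNames(as.data.frame(mat, stringsAsFactors = FALSE), header)
    df[df == ""] <- NA
    tb <- tibble::as_tibble(df)
    for (cl in intersect(int_cols, names(tb))) {
      tb[[cl]] <- suppressWarnings(as.integer(tb[[cl]]))
    }
    for (cl in intersect(num_cols, names(tb))) {
      tb[[cl]] <- suppressWarnings(as.numeric(tb[[cl]]))
    }
    tb
  })
  names(out) <- names(files)
  if (sum(malformed) > 0) {
    message("read_quarter: excluded ", sum(malformed), " malformed row(s)")
  }
  attr(out, "malformed") <- malformed
  out
}

#' Deduplicate case versions
#'
#' FAERS quarterly extracts re-publish earlier versions of the same case.
#' The rule applied here keeps exactly one row per `caseid`: the row with
#' the latest `fda_dt`, and — when several versions share that date — the
#' highest `primaryid`. Both steps are implemented as one lexicographic
#' maximization of `(fda_dt, primaryid)`; `primaryid` is compared numerically
#' when all values are digit strings, otherwise as text. The operation is
#' idempotent.
#'
#' @param demo tibble with at least `caseid`, `fda_dt`, `primaryid`.
#' @return The deduplicated demo tibble (one row per case).
#' @export
deduplicate <- function(demo) {
  stopifnot(all(c("caseid", "fda_dt", "primaryid") %in% names(demo)))
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  pid_key <- if (!anyNA(pid_num)) pid_num else demo$primaryid
  ord <- order(demo$caseid, demo$fda_dt, pid_key, na.last = FALSE)
  sorted <- demo[ord, ]
  sorted[!duplicated(sorted$caseid, fromLast = TRUE), ]
}

#' Assemble joined report records from raw quarter tables
#'
#' Deduplicates the DEMO table, then restricts every child table
#' (DRUG/REAC/THER/INDI/OUTC) to the surviving report versions. Child rows
#' referencing dropped or unknown `primaryid`s are excluded and counted.
#'
#' @param tables the list returned by [read_quarter()].
#' @return A `faers_reports` object; attribute `dropped_child_rows` holds the
#'   per-table counts of discarded child rows.
#' @export
assemble_reports <- function(tables) {
  stopifnot(is.list(tables), all(c("demo", "drug", "reac") %in% names(tables)))
  demo <- deduplicate(tables$demo)
  keep <- demo$primaryid
  dropped <- integer(0)
  pick <- function(nm) {
    tb <- tables[[nm]]
    if (is.null(tb)) tb <- tibble::tibble(primaryid = character(0))
    ok <- tb$primaryid %in% keep
    dropped[[nm]] <<- sum(!ok)
    tb[ok, ]
  }
  out <- faers_reports(
    demo = demo,
    drug = pick("drug"), reac = pick("reac"), ther = pick("ther"),
    indi = pick("indi"), outc = pick("outc")
  )
  if (sum(dropped) > 0) {
    message("assemble_reports: discarded ", sum(dropped),
            " child row(s) from dropped report versions")
  }
  attr(out, "dropped_child_rows") <- dropped
  out
}
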