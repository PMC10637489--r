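#' Build the case/non-case 2x2 table for one event
#'
#' Under the case/non-case design the counting unit is the distinct
#' (report, PT) record: `a` = target-drug records with the target event,
#' `b` = target-drug records with other events, `c` = the event's records
#' under other drugs, `d` = everything else. `a + b + c + d` equals the
#' total record count of the database.
#'
#' @param all_pairs tibble of `(primaryid, pt)` records for the whole
#'   database.
#' @param target_pairs tibble of `(primaryid, pt)` records for the target
#'   drug (a subset of `all_pairs`).
#' @param event the PT (matched case-insensitively).
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(all_pairs, target_pairs, event) {
  ev <- tolower(trimws(event))
  in_t <- tolower(trimws(target_pairs$pt)) == ev
  in_all <- tolower(trimws(all_pairs$pt)) == ev
  a <- sum(in_t)
  b <- nrow(target_pairs) - a
  c_ <- sum(in_all) - a
  d <- nrow(all_pairs) - a - b - c_
  tibble::tibble(a = a, b = b, c = c_, d = d)
}

#' Contingency counts for every term at once
#'
#' Vectorized version of [build_contingency()]: one row per distinct value
#' of `term_col` occurring in the target pairs (optionally all pairs).
#'
#' @param all_pairs database-wide `(primaryid, <term>)` records.
#' @param target_pairs target-drug records.
#' @param term_col column holding the event term (`"pt"` or `"soc"`).
#' @return Tibble with columns `term`, `a`, `b`, `c`, `d`.
#' @export
contingency_counts <- function(all_pairs, target_pairs, term_col = "pt") {
  total_pairs <- nrow(all_pairs)
  n_t <- nrow(target_pairs)
  tab_t <- dplyr::count(target_pairs, term = .data[[term_col]], name = "a")
  tab_all <- dplyr::count(all_pairs, term = .data[[term_col]],
                          name = "n_term")
  out <- dplyr::left_join(tab_t, tab_all, by = "term")
  out$n_term[is.na(out$n_term)] <- out$a[is.na(out$n_term)]
  dplyr::transmute(
    out,
    term = .data$term,
    a = as.integer(.data$a),
    b = as.integer(n_t - .data$a),
    c = as.integer(.data$n_term - .data$a),
    d = as.integer(total_pairs - .data$n_term - (n_t - .data$a))
  )
}

#' Disproportionality estimators for 2x2 report counts
#'
#' Computes, for each table, the four classical signal-detection statistics
#' with `N = a + b + c + d`:
#'
#' * reporting odds ratio `ROR = ad/(bc)` with the log-normal 95% CI
#'   `exp(ln ROR +/- 1.96 * s)`, `s = sqrt(1/a + 1/b + 1/c + 1/d)`;
#' * proportional reporting ratio `PRR = a(c+d) / (c(a+b))` with the
#'   uncorrected chi-squared
#'   `(ad - bc)^2 N / ((a+b)(c+d)(a+c)(b+d))`;
#' * information component `IC = log2(aN / ((a+c)(a+b)))` with
#'   `IC025 = IC - 2 * s / ln 2` (delta-method spread on the log2 scale);
#' * observed-to-expected ratio `EBGM = aN / ((a+c)(a+b))` with
#'   `EBGM05 = exp(ln EBGM - 1.96 * s)`.
#'
#' By these definitions `2^IC = EBGM` exactly, and all four estimators equal
#' 1 (IC = 0) whenever `ad = bc`. Any zero cell leaves the affected
#' estimators `NA` (undefined); no continuity correction is applied unless
#' `haldane = TRUE` adds 0.5 to every cell.
#'
#' @param counts tibble with numeric columns `a`, `b`, `c`, `d` (extra
#'   columns such as `term` are carried through). Counts need not be
#'   integers, so hypothetical tables (e.g. with `d` chosen to fix the ROR)
#'   are supported.
#' @param haldane apply a +0.5 correction to all cells (default off).
#' @return The input with columns `ror`, `ror_lo`, `ror_hi`, `prr`, `chi2`,
#'   `ic`, `ic025`, `ebgm`, `ebgm05` appended.
#' @export
signal_stats <- function(counts, haldane = FALSE) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(counts)))
  a <- as.numeric(counts$a); b <- as.numeric(counts$b)
  c_ <- as.numeric(counts$c); d <- as.numeric(counts$d)
  if (any(c(a, b, c_, d) < 0, na.rm = TRUE)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  n <- a + b + c_ + d
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0

  s <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  ror <- (a * d) / (b * c_)
  ror_lo <- exp(log(ror) - 1.96 * s)
  ror_hi <- exp(log(ror) + 1.96 * s)
  prr <- a * (c_ + d) / (c_ * (a + b))
  chi2 <- (a * d - b * c_)^2 * n / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  ebgm <- a * n / ((a + c_) * (a + b))
  ic <- log2(ebgm)
  ic025 <- ic - 2 * s / log(2)
  ebgm05 <- exp(log(ebgm) - 1.96 * s)

  for (v in c("ror", "ror_lo", "ror_hi", "prr", "chi2",
              "ic", "ic025", "ebgm", "ebgm05")) {
    val <- get(v)
    val[zero] <- NA_real_
    assign(v, val)
  }

  dplyr::bind_cols(
    counts,
    tibble::tibble(ror, ror_lo, ror_hi, prr, chi2, ic, ic025, ebgm, ebgm05)
  )
}

#' Single-table convenience wrapper around [signal_stats()]
#'
#' @param a,b,c,d the four cells of the case/non-case table.
#' @inheritParams signal_stats
#' @return A one-row tibble of cells plus estimators.
#' @examples
#' compute_signal_stats(10, 90, 100, 9800)
#' @export
compute_signal_stats <- function(a, b, c, d, haldane = FALSE) {
  signal_stats(tibble::tibble(a = a, b = b, c = c, d = d), haldane = haldane)
}

#' Apply the four positivity criteria
#'
#' * ROR: lower 95% bound > 1 (and at least `min_cases` cases);
#' * PRR: PRR >= 2 and chi-squared >= 4 (and at least `min_cases` cases);
#' * BCPNN: IC025 > 0;
#' * MGPS-style: EBGM05 > 2.
#'
#' `all_four` is the conjunction — the screening rule for retained signals.
#' Undefined (NA) estimators yield `FALSE` flags.
#'
#' @param stats output of [signal_stats()].
#' @param min_cases minimum target-drug case count (`a`), default 3.
#' @return `stats` with logical columns `ror_pos`, `prr_pos`, `bcpnn_pos`,
#'   `mgps_pos`, `all_four` appended.
#' @export
apply_criteria <- function(stats, min_cases = 3) {
  isT <- function(x) !is.na(x) & x
  out <- dplyr::mutate(
    stats,
    ror_pos = isT(.data$ror_lo > 1) & .data$a >= min_cases,
    prr_pos = isT(.data$prr >= 2) & isT(.data$chi2 >= 4) &
      .data$a >= min_cases,
    bcpnn_pos = isT(.data$ic025 > 0),
    mgps_pos = isT(.data$ebgm05 > 2)
  )
  dplyr::mutate(out, all_four = .data$ror_pos & .data$prr_pos &
                  .data$bcpnn_pos & .data$mgps_pos)
}

#' Retain signals positive under all four algorithms
#'
#' @param stats output of [apply_criteria()].
#' @return The subset with `all_four = TRUE`; the count is reported.
#' @export
screen_signals <- function(stats) {
  if (!"all_four" %in% names(stats)) {
    stop("run apply_criteria() first", call. = FALSE)
  }
  out <- dplyr::filter(stats, .data$all_four)
  message("screen_signals: ", nrow(out), " of ", nrow(stats),
          " terms positive under all four algorithms")
  out
}

#' Rank significant signals by EBGM05
#'
#' Keeps rows with case count strictly greater than `min_a` and orders them
#' by `ebgm05` descending (the most stringent bound), ties broken by `a`
#' descending, then term name.
#'
#' @param signals significant-signal tibble with `term`, `a`, `ebgm05`.
#' @param min_a strict lower bound on the case count (default 30).
#' @return The ordered, filtered tibble.
#' @export
rank_and_filter <- function(signals, min_a = 30) {
  dplyr::arrange(
    dplyr::filter(signals, .data$a > min_a),
    dplyr::desc(.data$ebgm05), dplyr::desc(.data$a), .data$term
  )
}

#' SOC-level disproportionality
#'
#' Aggregates the (report, PT) records by System Organ Class — `a` is the
#' number of target-drug records falling in the SOC — and computes the same
#' statistics and criteria as at the PT level.
#'
#' @param all_pairs_soc database-wide pairs annotated with `soc` (see
#'   [map_pt_to_soc()]).
#' @param target_pairs_soc target-drug pairs annotated with `soc`.
#' @param min_cases minimum case count for the frequency-based criteria.
#' @return Tibble of SOC-level counts, estimators, and flags.
#' @export
soc_level_signals <- function(all_pairs_soc, target_pairs_soc, min_cases = 3) {
  stopifnot("soc" %in% names(all_pairs_soc), "soc" %in% names(target_pairs_soc))
  counts <- contingency_counts(all_pairs_soc, target_pairs_soc,
                               term_col = "soc")
  apply_criteria(signal_stats(counts), min_cases = min_cases)
}

#' Flag signals absent from the drug label
#'
#' A retained signal is "unexpected" (novel) when its PT does not appear in
#' the label PT list; matching is case-insensitive and exact.
#'
#' @param signals significant-signal tibble with a `term` column.
#' @param label_pts character vector of labelled PTs (e.g. from
#'   [read_label_pts()]); an empty list marks everything unexpected.
#' @return `signals` with a logical `unexpected` column appended.
#' @export
flag_unexpected <- function(signals, label_pts) {
  dplyr::mutate(
    signals,
    unexpected = !(tolower(trimws(.data$term)) %in%
                     tolower(trimws(label_pts)))
  )
}

#' Read a label PT list (one PT per line)
#' @param path plain-text file; blank lines and `#` comments are skipped.
#' @export
read_label_pts <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
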