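#' Stratum assignment for subgroup analyses
#'
#' Maps each report to a level of the stratification variable: age
#' (`<18` / `18-64` / `>64` years), weight (`<80` / `80-100` / `>100` kg),
#' sex (`F` / `M`), or reporter (`Consumer` / `Health professional`).
#' Reports whose level is unknown get `NA` and are excluded from that
#' stratification.
#'
#' @param demo the DEMO tibble of a `faers_reports` object.
#' @param variable one of `"age"`, `"weight"`, `"sex"`, `"reporter"`.
#' @return Character vector of levels (`NA` = unknown).
#' @export
assign_stratum <- function(demo, variable = c("age", "weight", "sex",
                                              "reporter")) {
  variable <- match.arg(variable)
  switch(variable,
    age = {
      lab <- age_band(age_in_years(demo$age, demo$age_cod))
      ifelse(lab == "Unknown", NA_character_, lab)
    },
    weight = {
      lab <- weight_band(weight_in_kg(demo$wt, demo$wt_cod))
      ifelse(lab == "Unknown", NA_character_, lab)
    },
    sex = ifelse(!is.na(demo$sex) & toupper(demo$sex) %in% c("F", "M"),
                 toupper(demo$sex), NA_character_),
    reporter = {
      lab <- reporter_category(demo$occp_cod)
      ifelse(lab == "Unknown", NA_character_, lab)
    }
  )
}

stratum_levels <- function(variable) {
  switch(variable,
    age = c("<18", "18-64", ">64"),
    weight = c("<80", "80-100", ">100"),
    sex = c("F", "M"),
    reporter = c("Consumer", "Health professional")
  )
}

#' Subgroup disproportionality screening
#'
#' Re-runs the full four-algorithm screen inside each level of the
#' stratification variable: both the target drug's records and the
#' comparator database are restricted to that level's reports, so each
#' stratum is screened against its own background. Within each level the
#' retained signals (all four criteria, minimum case count) are ranked by
#' case count and the top `top_n` reported.
#'
#' @param reports the full deduplicated `faers_reports` database.
#' @param query the target [drug_query()].
#' @param variable stratification variable (see [assign_stratum()]).
#' @param min_cases minimum case count (default 3).
#' @param top_n rows to keep per level (default 10).
#' @return Named list of per-level signal tibbles (possibly empty).
#' @export
subgroup_signals <- function(reports, query,
                             variable = c("age", "weight", "sex", "reporter"),
                             min_cases = 3, top_n = 10) {
  stopifnot(inherits(reports, "faers_reports"))
  variable <- match.arg(variable)
  level <- assign_stratum(reports$demo, variable)
  out <- list()
  for (lv in stratum_levels(variable)) {
    ids <- reports$demo$primaryid[!is.na(level) & level == lv]
    slice <- subset_reports(reports, ids)
    target <- suppressWarnings(identify_drug_reports(slice, query))
    if (!length(attr(target, "target_ids"))) {
      warning("stratum ", lv, " has no target-drug reports", call. = FALSE)
      out[[lv]] <- tibble::tibble()
      next
    }
    all_pairs <- extract_case_pairs(slice)
    target_pairs <- extract_case_pairs(target)
    stats <- apply_criteria(
      signal_stats(contingency_counts(all_pairs, target_pairs)),
      min_cases = min_cases
    )
    sig <- suppressMessages(screen_signals(stats))
    out[[lv]] <- utils::head(dplyr::arrange(sig, dplyr::desc(.data$a)), top_n)
  }
  out
}

#' Within-drug sex-difference disproportionality
#'
#' For each PT with at least `min_cases` target-drug cases, builds the 2x2
#' table of (event vs all other events) by (female vs male) restricted to
#' the target drug's records, and computes the female-over-male reporting
#' odds ratio `ROR = (a_f * b_m) / (b_f * a_m)` with its log-normal 95% CI,
#' a two-sided Fisher exact p-value, and Benjamini-Hochberg adjusted
#' p-values across all tested PTs. Reports of unknown sex are excluded.
#'
#' @param target_reports target-drug subset from [identify_drug_reports()].
#' @param min_cases minimum total case count per PT (default 3).
#' @return Tibble with columns `term`, `a_f`, `b_f`, `a_m`, `b_m`,
#'   `ror_fm`, `ror_lo`, `ror_hi`, `p_value`, `p_adj`.
#' @export
gender_disproportionality <- function(target_reports, min_cases = 3) {
  stopifnot(inherits(target_reports, "faers_reports"))
  demo <- target_reports$demo
  sex <- ifelse(!is.na(demo$sex) & toupper(demo$sex) %in% c("F", "M"),
                toupper(demo$sex), NA_character_)
  sex_of <- stats::setNames(sex, demo$primaryid)

  pairs <- extract_case_pairs(target_reports)
  pairs$sex <- sex_of[pairs$primaryid]
  pairs <- pairs[!is.na(pairs$sex), ]

  n_f <- sum(pairs$sex == "F")
  n_m <- sum(pairs$sex == "M")
  counts <- pairs |>
    dplyr::count(term = .data$pt, .data$sex) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n",
                       values_fill = 0L)
  if (!"F" %in% names(counts)) counts$F <- 0L
  if (!"M" %in% names(counts)) counts$M <- 0L
  counts <- dplyr::transmute(
    counts,
    term = .data$term,
    a_f = as.integer(.data$F), b_f = as.integer(n_f - .data$F),
    a_m = as.integer(.data$M), b_m = as.integer(n_m - .data$M)
  )
  counts <- dplyr::filter(counts, .data$a_f + .data$a_m >= min_cases)
  if (!nrow(counts)) {
    return(tibble::tibble(term = character(0), a_f = integer(0),
                          b_f = integer(0), a_m = integer(0),
                          b_m = integer(0), ror_fm = numeric(0),
                          ror_lo = numeric(0), ror_hi = numeric(0),
                          p_value = numeric(0), p_adj = numeric(0)))
  }

  zero <- counts$a_f == 0 | counts$b_f == 0 | counts$a_m == 0 |
    counts$b_m == 0
  s <- sqrt(1 / counts$a_f + 1 / counts$b_f + 1 / counts$a_m +
              1 / counts$b_m)
  ror <- (counts$a_f * counts$b_m) / (counts$b_f * counts$a_m)
  lo <- exp(log(ror) - 1.96 * s)
  hi <- exp(log(ror) + 1.96 * s)
  ror[zero] <- NA_real_; lo[zero] <- NA_real_; hi[zero] <- NA_real_
  counts$ror_fm <- ror
  counts$ror_lo <- lo
  counts$ror_hi <- hi
  counts$p_value <- vapply(seq_len(nrow(counts)), function(i) {
    stats::fisher.test(matrix(c(counts$a_f[i], counts$b_f[i],
                                counts$a_m[i], counts$b_m[i]),
                              nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  counts$p_adj <- bh_adjust(counts$p_value)
  counts
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotone enforcement, capped at 1 (delegates to
#' `stats::p.adjust(method = "BH")` after validating the input).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Volcano-plot coordinates for sex-difference signals
#'
#' `x = log2(ROR_{F/M})` and `y = -log10(p_adj)`; points with an undefined
#' ROR (a zero cell) are omitted and counted. A point is labelled
#' significant when `p_adj < alpha`, with `x > 0` marking female-risk and
#' `x < 0` male-risk terms.
#'
#' @param signals output of [gender_disproportionality()].
#' @param alpha significance threshold on the adjusted p-value.
#' @return Tibble with `term`, `log2_ror`, `neg_log10_p_adj`, `significant`,
#'   `direction`; attribute `n_omitted` counts dropped points.
#' @export
volcano_coordinates <- function(signals, alpha = 0.05) {
  ok <- !is.na(signals$ror_fm)
  n_om <- sum(!ok)
  if (n_om > 0) {
    message("volcano_coordinates: omitted ", n_om,
            " term(s) with undefined ROR")
  }
  sg <- signals[ok, ]
  out <- tibble::tibble(
    term = sg$term,
    log2_ror = log2(sg$ror_fm),
    neg_log10_p_adj = -log10(sg$p_adj),
    significant = sg$p_adj < alpha
  )
  out$direction <- dplyr::case_when(
    !out$significant ~ "ns",
    out$log2_ror > 0 ~ "female-risk",
    out$log2_ror < 0 ~ "male-risk",
    TRUE ~ "ns"
  )
  attr(out, "n_omitted") <- n_om
  out
}
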