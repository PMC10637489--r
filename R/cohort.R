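#' Define a target-drug query
#'
#' Spontaneous reports carry free-text drug names, so a drug is identified by
#' a list of search names (generic plus brand/shorthand names) matched, after
#' normalization, against the `DRUGNAME` and/or `PROD_AI` fields. By default
#' only primary-suspect (PS) drug rows qualify a report.
#'
#' Normalization uppercases, trims, collapses internal whitespace, and strips
#' a trailing formulation qualifier after a period (so `"Etoposide. 100MG"`
#' matches `"ETOPOSIDE"`); matching is exact on the normalized token, never a
#' substring match.
#'
#' @param name_list character vector of search names (non-empty).
#' @param fields which fields to search: subset of
#'   `c("drugname", "prod_ai")`.
#' @param roles role codes a matching drug row must carry (subset of
#'   PS/SS/C/I; default `"PS"`).
#' @return A `drug_query` object.
#' @examples
#' drug_query(c("ETOPOSIDE", "VP-16", "VEPESID", "TOPOSAR"))
#' @export
drug_query <- function(name_list,
                       fields = c("drugname", "prod_ai"),
                       roles = "PS") {
  name_list <- name_list[!is.na(name_list) & nzchar(trimws(name_list))]
  if (!length(name_list)) stop("name_list must be non-empty", call. = FALSE)
  fields <- match.arg(fields, c("drugname", "prod_ai"), several.ok = TRUE)
  if (!all(roles %in% c("PS", "SS", "C", "I"))) {
    stop("roles must be a subset of PS, SS, C, I", call. = FALSE)
  }
  structure(list(name_list = unique(normalize_drug_name(name_list)),
                 fields = fields, roles = roles),
            class = "drug_query")
}

#' Normalize a free-text drug name for matching
#'
#' @param x character vector.
#' @return Uppercased, whitespace-collapsed names with any trailing
#'   period-delimited qualifier removed.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("\\..*$", "", x)     # drop trailing formulation qualifier
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Identify reports for the target drug
#'
#' A report is included iff at least one of its drug rows matches a query
#' name in a searched field *and* carries one of the kept role codes.
#'
#' @param reports a `faers_reports` object (deduplicated).
#' @param query a [drug_query()].
#' @return The target subset as a `faers_reports` object; attribute
#'   `target_ids` holds the matching `primaryid`s.
#' @export
identify_drug_reports <- function(reports, query) {
  stopifnot(inherits(reports, "faers_reports"), inherits(query, "drug_query"))
  dr <- reports$drug
  hit <- rep(FALSE, nrow(dr))
  if ("drugname" %in% query$fields) {
    hit <- hit | normalize_drug_name(dr$drugname) %in% query$name_list
  }
  if ("prod_ai" %in% query$fields && "prod_ai" %in% names(dr)) {
    hit <- hit | normalize_drug_name(dr$prod_ai) %in% query$name_list
  }
  hit <- hit & dr$role_cod %in% query$roles
  ids <- unique(dr$primaryid[hit])
  if (!length(ids)) {
    warning("no reports matched the drug query", call. = FALSE)
  }
  out <- subset_reports(reports, ids)
  attr(out, "target_ids") <- ids
  out
}

#' Extract distinct (report, PT) case pairs
#'
#' The counting unit of the whole analysis: one pair per distinct preferred
#' term per report. Duplicate PT mentions within a report collapse to one.
#'
#' @param reports a `faers_reports` object.
#' @return Tibble with columns `primaryid`, `pt`.
#' @export
extract_case_pairs <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  dplyr::distinct(
    tibble::tibble(primaryid = reports$reac$primaryid,
                   pt = trimws(reports$reac$pt))
  )
}

#' Remove indication PTs from the case-pair set
#'
#' Events that merely restate what the drug was prescribed for (e.g. the
#' tumour type) are excluded from screening. The exclusion set is matched
#' case-insensitively; the removal count is kept as an attribute and
#' reported.
#'
#' @param pairs tibble of `(primaryid, pt)` pairs.
#' @param indication_pts character vector of indication PTs (possibly empty).
#' @return Filtered pairs; attribute `n_excluded` gives the removed count.
#' @export
exclude_indications <- function(pairs, indication_pts) {
  drop <- tolower(trimws(pairs$pt)) %in% tolower(trimws(indication_pts))
  out <- pairs[!drop, ]
  if (sum(drop) > 0) {
    message("exclude_indications: removed ", sum(drop), " pair(s)")
  }
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Indication PTs observed in a report set
#'
#' The default exclusion list: every PT that appears in the INDI rows of the
#' target-drug reports.
#'
#' @param reports a `faers_reports` object (normally the target subset).
#' @return Character vector of indication PTs.
#' @export
observed_indication_pts <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  unique(trimws(reports$indi$indi_pt[!is.na(reports$indi$indi_pt)]))
}

#' Annotate case pairs with their System Organ Class
#'
#' @param pairs tibble of `(primaryid, pt)` pairs.
#' @param map two-column tibble (`pt`, `soc`) giving each PT's primary SOC.
#' @return Pairs with an added `soc` column; PTs absent from the map are
#'   annotated `"Unmapped"` and counted in attribute `n_unmapped`.
#' @export
map_pt_to_soc <- function(pairs, map) {
  stopifnot(all(c("pt", "soc") %in% names(map)))
  idx <- match(tolower(trimws(pairs$pt)), tolower(trimws(map$pt)))
  out <- pairs
  out$soc <- as.character(ifelse(is.na(idx), "Unmapped", map$soc[idx]))
  n_un <- sum(is.na(idx))
  if (n_un > 0) message("map_pt_to_soc: ", n_un, " unmapped PT record(s)")
  attr(out, "n_unmapped") <- n_un
  out
}

#' Read a PT-to-SOC map from a two-column CSV
#' @param path CSV file with columns `pt` and `soc` (case-insensitive names).
#' @export
read_pt_soc_map <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  names(tb) <- tolower(names(tb))
  if (!all(c("pt", "soc") %in% names(tb))) {
    stop("PT-to-SOC map must have columns pt, soc", call. = FALSE)
  }
  tb[, c("pt", "soc")]
}

# ---- demographic normalization ---------------------------------------------

#' Convert reported age to years
#'
#' Applies the FAERS age-unit codes: DEC (decades), YR, MON, WK, DY, HR.
#' Unknown or missing codes yield `NA`.
#'
#' @param age numeric age values.
#' @param age_cod character unit codes.
#' @return Numeric age in years.
#' @export
age_in_years <- function(age, age_cod) {
  factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
              DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor[toupper(age_cod)]
  out <- age * unname(f)
  out[is.na(age) | is.na(f)] <- NA_real_
  out
}

#' Convert reported weight to kilograms
#'
#' @param wt numeric weight values.
#' @param wt_cod unit codes: KG, LBS, GMS.
#' @return Numeric weight in kg.
#' @export
weight_in_kg <- function(wt, wt_cod) {
  factor <- c(KG = 1, LBS = 0.4536, GMS = 1 / 1000)
  f <- factor[toupper(wt_cod)]
  out <- wt * unname(f)
  out[is.na(wt) | is.na(f)] <- NA_real_
  out
}

age_band <- function(years) {
  dplyr::case_when(
    is.na(years) ~ "Unknown",
    years < 18 ~ "<18",
    years <= 64 ~ "18-64",
    TRUE ~ ">64"
  )
}

weight_band <- function(kg) {
  dplyr::case_when(
    is.na(kg) ~ "Unknown",
    kg < 80 ~ "<80",
    kg <= 100 ~ "80-100",
    TRUE ~ ">100"
  )
}

reporter_category <- function(occp_cod) {
  dplyr::case_when(
    is.na(occp_cod) ~ "Unknown",
    toupper(occp_cod) == "CN" ~ "Consumer",
    toupper(occp_cod) %in% c("MD", "PH", "OT", "HP", "RN") ~
      "Health professional",
    TRUE ~ "Unknown"
  )
}

#' Descriptive characteristics of a report set
#'
#' Counts and percentages (of total reports, one decimal) for sex, weight
#' bands (<80 / 80-100 / >100 kg), age bands (<18 / 18-64 / >64 years),
#' top-`k` reporting countries, reporter category, outcome codes, and
#' top-`k` indications. Missing values fall into explicit "Unknown" rows, so
#' within each single-valued characteristic the counts sum to the total.
#'
#' @param reports a `faers_reports` object (normally the target subset).
#' @param top_k how many countries/indications to list.
#' @return Tibble with columns `characteristic`, `level`, `n`, `pct`.
#' @export
demographics_summary <- function(reports, top_k = 5) {
  stopifnot(inherits(reports, "faers_reports"))
  demo <- reports$demo
  total <- nrow(demo)
  pct <- function(n) round(100 * n / total, 1)

  count_levels <- function(chr, values, level_order = NULL) {
    tb <- table(values)
    lv <- if (is.null(level_order)) names(tb) else level_order
    tibble::tibble(
      characteristic = chr, level = lv,
      n = as.integer(tb[lv]), pct = pct(as.integer(tb[lv]))
    ) |>
      dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
                    pct = ifelse(is.na(.data$pct), 0, .data$pct))
  }

  sex_lab <- dplyr::case_when(
    is.na(demo$sex) ~ "Unknown",
    toupper(demo$sex) == "F" ~ "Female",
    toupper(demo$sex) == "M" ~ "Male",
    TRUE ~ "Unknown"
  )
  wt_lab <- weight_band(weight_in_kg(demo$wt, demo$wt_cod))
  age_lab <- age_band(age_in_years(demo$age, demo$age_cod))
  rep_lab <- reporter_category(demo$occp_cod)

  country <- demo$reporter_country
  country[is.na(country)] <- "Unknown"
  top_countries <- names(sort(table(country), decreasing = TRUE))
  top_countries <- utils::head(top_countries, top_k)

  # outcome percentages are shares of all outcome entries (a report may
  # carry several codes), the convention of published FAERS summaries
  outc <- reports$outc
  outc_tb <- if (nrow(outc)) {
    oc <- dplyr::distinct(outc)
    dplyr::count(oc, .data$outc_cod, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n)) |>
      dplyr::transmute(characteristic = "outcome", level = .data$outc_cod,
                       n = as.integer(.data$n),
                       pct = round(100 * .data$n / nrow(oc), 1))
  } else {
    tibble::tibble(characteristic = character(0), level = character(0),
                   n = integer(0), pct = numeric(0))
  }

  indi <- reports$indi
  indi_tb <- if (nrow(indi)) {
    dplyr::count(dplyr::distinct(indi[, c("primaryid", "indi_pt")]),
                 .data$indi_pt, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n)) |>
      utils::head(top_k) |>
      dplyr::transmute(characteristic = "indication", level = .data$indi_pt,
                       n = as.integer(.data$n), pct = pct(.data$n))
  } else {
    tibble::tibble(characteristic = character(0), level = character(0),
                   n = integer(0), pct = numeric(0))
  }

  dplyr::bind_rows(
    tibble::tibble(characteristic = "total", level = "reports",
                   n = total, pct = 100),
    count_levels("sex", sex_lab, c("Female", "Male", "Unknown")),
    count_levels("weight_kg", wt_lab, c("<80", "80-100", ">100", "Unknown")),
    count_levels("age_years", age_lab, c("<18", "18-64", ">64", "Unknown")),
    count_levels("country", country, top_countries),
    count_levels("reporter", rep_lab,
                 c("Health professional", "Consumer", "Unknown")),
    outc_tb,
    indi_tb
  )
}

#' Annual report counts
#'
#' Counts reports by the calendar year of `fda_dt`. Years with zero reports
#' inside the requested range are included.
#'
#' @param reports a `faers_reports` object.
#' @param years integer vector of years to cover; defaults to the observed
#'   range.
#' @return Tibble with columns `year`, `n`.
#' @export
annual_counts <- function(reports, years = NULL) {
  stopifnot(inherits(reports, "faers_reports"))
  yr <- reports$demo$fda_dt %/% 10000L
  if (is.null(years)) {
    years <- if (length(yr)) seq(min(yr, na.rm = TRUE), max(yr, na.rm = TRUE))
             else integer(0)
  }
  tb <- table(factor(yr, levels = years))
  tibble::tibble(year = as.integer(years), n = as.integer(tb))
}
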