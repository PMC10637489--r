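#' Generate a synthetic FAERS-like report set with known ground truth
#'
#' Draws `n_reports` unique cases under the configured catalogs. Each report
#' receives a set of drugs (independent inclusion by catalog prevalence, with
#' one drug forced into otherwise-empty reports, sampled by prevalence and
#' independently of everything else), exactly one primary-suspect (PS) role,
#' free-text name variants, reaction PTs drawn per-PT with probability
#' `baseline` — multiplied by `lambda` (capped at 1) in reports exposed to a
#' planted drug — therapy start dates, an event date equal to the PS drug's
#' therapy start plus a Weibull-distributed onset lag (floored to whole
#' days), indications, and outcome codes. Missing and partial dates are
#' injected at the configured rates, and duplicate case versions are appended
#' via [inject_duplicates()].
#'
#' The returned object carries a ground-truth attribute (see
#' [synthetic_truth()]) recording the intended deduplication survivors, the
#' canonical drug content of every report, and planted-signal exposure, so
#' every downstream stage can be checked exactly.
#'
#' @param config a [synthetic_config()].
#' @return A `faers_reports` object (including injected duplicate versions).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- withr::with_seed(config$seed, generate_reports_impl(config))
  if (config$p_duplicate_case > 0) {
    out <- inject_duplicates(out, config$p_duplicate_case,
                             seed = config$seed + 1L)
  }
  out
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  dcat <- config$drug_catalog
  pcat <- config$pt_catalog
  dg <- config$demographics

  caseid <- as.character(10000000 + seq_len(n))
  primaryid <- paste0(caseid, "1") # version-1 suffix

  fda_date <- sample(seq(as.Date("2004-01-01"), as.Date("2022-12-31"),
                         by = "day"), n, replace = TRUE)
  fda_dt <- date_to_ymd_int(fda_date)

  ## --- demographics -------------------------------------------------------
  sex <- sample(c("F", "M", NA_character_), n, TRUE, prob = dg$sex)
  age_group <- sample(names(dg$age), n, TRUE, prob = dg$age)
  age <- rep(NA_real_, n)
  age[age_group == "<18"] <- runif(sum(age_group == "<18"), 0, 17.99)
  age[age_group == "18-64"] <- runif(sum(age_group == "18-64"), 18, 64.99)
  age[age_group == ">64"] <- runif(sum(age_group == ">64"), 65, 90)
  age_cod <- ifelse(is.na(age), NA_character_, "YR")
  # infants coded in months, a slice of adults in decades
  inf <- !is.na(age) & age < 2
  age[inf] <- round(age[inf] * 12)
  age_cod[inf] <- "MON"
  dec <- !is.na(age) & age_cod == "YR" & runif(n) < 0.05
  age[dec] <- round(age[dec] / 10, 1)
  age_cod[dec] <- "DEC"
  age[age_cod == "YR" & !is.na(age)] <- round(age[age_cod == "YR" & !is.na(age)])

  wt_known <- runif(n) < dg$p_weight_known
  wt <- rep(NA_real_, n)
  wt[wt_known] <- round(stats::rlnorm(sum(wt_known), dg$weight_meanlog,
                                      dg$weight_sdlog), 1)
  wt_cod <- ifelse(wt_known, "KG", NA_character_)
  lbs <- wt_known & runif(n) < 0.10
  wt[lbs] <- round(wt[lbs] / 0.4536, 1)
  wt_cod[lbs] <- "LBS"

  country <- sample(names(dg$country), n, TRUE, prob = dg$country)
  occp <- sample(names(dg$occp), n, TRUE, prob = dg$occp)
  occp[occp == "unknown"] <- NA_character_

  ## --- drugs --------------------------------------------------------------
  K <- nrow(dcat)
  prev <- dcat$prevalence
  inc <- matrix(runif(n * K), n, K) < matrix(rep(prev, each = n), n, K)
  empty <- which(rowSums(inc) == 0)
  if (length(empty)) {
    forced <- sample.int(K, length(empty), replace = TRUE, prob = prev)
    inc[cbind(empty, forced)] <- TRUE
  }

  idx <- which(inc, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  row_of <- idx[ord, 1]
  col_of <- idx[ord, 2]
  nr <- length(row_of)
  m <- tabulate(row_of, nbins = n) # drugs per report (all >= 1)
  drug_seq <- sequence(m)
  starts <- cumsum(c(0L, m[-n]))
  ps_row <- starts + 1L + floor(runif(n) * m) # one PS per report
  role <- sample(c("SS", "C", "I"), nr, TRUE, prob = c(0.3, 0.5, 0.2))
  role[ps_row] <- "PS"

  canonical <- dcat$name[col_of]
  drugname <- canonical
  for (k in seq_len(K)) {
    syn <- dcat$synonyms[[k]]
    if (length(syn)) {
      pickr <- which(col_of == k & runif(nr) < 0.20)
      if (length(pickr)) {
        drugname[pickr] <- sample(syn, length(pickr), replace = TRUE)
      }
    }
  }
  u <- runif(nr)
  title <- u < 0.25
  lower <- u >= 0.25 & u < 0.45
  drugname[title] <- paste0(substr(drugname[title], 1, 1),
                            tolower(substring(drugname[title], 2)))
  drugname[lower] <- tolower(drugname[lower])
  qual <- runif(nr) < 0.05
  drugname[qual] <- paste0(drugname[qual], ". INJECTION")
  pad <- runif(nr) < 0.05
  drugname[pad] <- paste0(" ", drugname[pad], " ")

  drug <- tibble::tibble(
    primaryid = primaryid[row_of],
    drug_seq = as.integer(drug_seq),
    role_cod = role,
    drugname = drugname,
    prod_ai = dcat$prod_ai[col_of]
  )

  ## --- reactions ----------------------------------------------------------
  M <- nrow(pcat)
  pmat <- matrix(rep(pcat$baseline, each = n), n, M)
  planted <- config$planted_signals
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      dk <- match(planted$drug[i], dcat$name)
      pj <- match(planted$pt[i], pcat$pt)
      exposed <- inc[, dk]
      ag <- planted$age_group[i]
      if (!is.na(ag)) exposed <- exposed & !is.na(age_group) & age_group == ag
      newp <- planted$lambda[i] * pcat$baseline[pj]
      if (newp > 1) {
        warning("planted probability for (", planted$drug[i], ", ",
                planted$pt[i], ") exceeds 1; capped", call. = FALSE)
        newp <- 1
      }
      pmat[exposed, pj] <- newp
    }
  }
  if (!is.null(config$sex_effects) && nrow(config$sex_effects) > 0) {
    fem <- !is.na(sex) & sex == "F"
    for (i in seq_len(nrow(config$sex_effects))) {
      pj <- match(config$sex_effects$pt[i], pcat$pt)
      if (is.na(pj)) stop("sex effect names an unknown PT", call. = FALSE)
      pmat[fem, pj] <- pmin(1, pmat[fem, pj] * config$sex_effects$f_multiplier[i])
    }
  }
  rsel <- matrix(runif(n * M), n, M) < pmat
  ridx <- which(rsel, arr.ind = TRUE)
  rord <- order(ridx[, 1], ridx[, 2])
  reac <- tibble::tibble(
    primaryid = primaryid[ridx[rord, 1]],
    pt = pcat$pt[ridx[rord, 2]]
  )

  ## --- therapy and event dates -------------------------------------------
  report_delay <- sample(0:60, n, replace = TRUE)
  event_date <- fda_date - report_delay
  lag_days <- floor(stats::rweibull(nr, shape = config$onset_shape,
                                    scale = config$onset_scale_days))
  ps_lag <- lag_days[ps_row]
  start_ps <- event_date - ps_lag
  jitter <- sample(-15:15, nr, replace = TRUE)
  is_ps <- role == "PS"
  start_date <- start_ps[row_of] + ifelse(is_ps, 0L, jitter)
  end_date <- start_date + sample(1:120, nr, replace = TRUE)

  truncate_dates <- function(txt, p) {
    hit <- !is.na(txt) & runif(length(txt)) < p
    short <- runif(length(txt)) < 0.5
    txt[hit & short] <- substr(txt[hit & short], 1, 6)
    txt[hit & !short] <- substr(txt[hit & !short], 1, 4)
    txt
  }
  event_txt <- format(event_date, "%Y%m%d")
  event_txt[runif(n) < config$p_missing_event_date] <- NA_character_
  event_txt <- truncate_dates(event_txt, config$p_invalid_date)
  start_txt <- truncate_dates(format(start_date, "%Y%m%d"),
                              config$p_invalid_date)
  end_txt <- format(end_date, "%Y%m%d")
  end_txt[runif(nr) < 0.3] <- NA_character_

  ther <- tibble::tibble(
    primaryid = primaryid[row_of],
    dsg_drug_seq = as.integer(drug_seq),
    start_dt = start_txt,
    end_dt = end_txt
  )

  ## --- indications --------------------------------------------------------
  icat <- default_indication_catalog()
  has_indi <- runif(n) < 0.85
  indi <- tibble::tibble(
    primaryid = primaryid[has_indi],
    indi_drug_seq = as.integer(drug_seq[ps_row][has_indi]),
    indi_pt = sample(icat$indi_pt, sum(has_indi), TRUE, prob = icat$weight)
  )

  ## --- outcomes -----------------------------------------------------------
  has_outc <- runif(n) < dg$p_any_outcome
  oc1 <- sample(names(dg$outcome), n, TRUE, prob = dg$outcome)
  two <- has_outc & runif(n) < 0.3
  oc2 <- sample(names(dg$outcome), n, TRUE, prob = dg$outcome)
  outc <- dplyr::bind_rows(
    tibble::tibble(primaryid = primaryid[has_outc], outc_cod = oc1[has_outc]),
    tibble::tibble(primaryid = primaryid[two & oc2 != oc1],
                   outc_cod = oc2[two & oc2 != oc1])
  )
  outc <- dplyr::arrange(outc, .data$primaryid)

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_txt, sex = sex, age = age, age_cod = age_cod,
    wt = wt, wt_cod = wt_cod, occp_cod = occp, reporter_country = country
  )

  out <- faers_reports(demo, drug, reac, ther, indi, outc)
  attr(out, "truth") <- list(
    survivors = tibble::tibble(caseid = caseid, primaryid = primaryid),
    drug_rows = tibble::tibble(primaryid = primaryid[row_of],
                               caseid = caseid[row_of],
                               drug = canonical, role_cod = role),
    exposure = tibble::tibble(primaryid = primaryid[row_of],
                              drug = canonical),
    planted = planted
  )
  out
}

#' Inject duplicate case versions
#'
#' Re-submits each case with probability `rate` as a second report version:
#' the duplicate copies the case's rows in every table under a new, higher
#' `primaryid` and an `fda_dt` greater than or equal to the original's
#' (sometimes equal, so both arms of the deduplication rule are exercised).
#' The intended survivor under the rule — latest `fda_dt`, ties broken by the
#' higher `primaryid`, i.e. always the duplicate — is recorded in the
#' ground-truth attribute.
#'
#' @param reports a `faers_reports` object.
#' @param rate probability in `[0, 1]` that a case is duplicated.
#' @param seed integer seed.
#' @return The report set with duplicate versions appended.
#' @export
inject_duplicates <- function(reports, rate, seed = 1L) {
  stopifnot(inherits(reports, "faers_reports"), rate >= 0, rate <= 1)
  if (rate == 0) return(reports)
  demo <- reports$demo
  sel <- withr::with_seed(seed, which(runif(nrow(demo)) < rate))
  if (!length(sel)) return(reports)
  withr::with_seed(seed + 104729L, {
    old_id <- demo$primaryid[sel]
    # bump the trailing version digit: higher primaryid for the same case
    new_id <- paste0(demo$caseid[sel], "2")
    delta <- sample(0:90, length(sel), replace = TRUE)
    new_fda <- date_to_ymd_int(ymd_int_to_date(demo$fda_dt[sel]) + delta)

    dup_demo <- demo[sel, ]
    dup_demo$primaryid <- new_id
    dup_demo$fda_dt <- new_fda

    copy_children <- function(tb) {
      hit <- tb[tb$primaryid %in% old_id, ]
      hit$primaryid <- new_id[match(hit$primaryid, old_id)]
      dplyr::bind_rows(tb, hit)
    }

    out <- faers_reports(
      demo = dplyr::bind_rows(demo, dup_demo),
      drug = copy_children(reports$drug),
      reac = copy_children(reports$reac),
      ther = copy_children(reports$ther),
      indi = copy_children(reports$indi),
      outc = copy_children(reports$outc)
    )
    truth <- attr(reports, "truth")
    if (!is.null(truth)) {
      hit <- match(demo$caseid[sel], truth$survivors$caseid)
      truth$survivors$primaryid[hit] <- new_id
      extra <- truth$drug_rows[truth$drug_rows$primaryid %in% old_id, ]
      extra$primaryid <- new_id[match(extra$primaryid, old_id)]
      truth$drug_rows <- dplyr::bind_rows(truth$drug_rows, extra)
      extra_e <- truth$exposure[truth$exposure$primaryid %in% old_id, ]
      extra_e$primaryid <- new_id[match(extra_e$primaryid, old_id)]
      truth$exposure <- dplyr::bind_rows(truth$exposure, extra_e)
      attr(out, "truth") <- truth
    }
    out
  })
}

#' Write a report set as FAERS-style quarterly ASCII files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `INDI.txt`, and
#' `OUTC.txt` as dollar-delimited UTF-8 text with FAERS header names. A
#' round trip through [read_quarter()] and [assemble_reports()] reproduces
#' the records exactly.
#'
#' @param reports a `faers_reports` object.
#' @param directory output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
emit_quarterly_files <- function(reports, directory) {
  stopifnot(inherits(reports, "faers_reports"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)

  up <- function(tb) stats::setNames(tb, toupper(names(tb)))
  tables <- list(
    DEMO = up(reports$demo), DRUG = up(reports$drug),
    REAC = up(reports$reac), THER = up(reports$ther),
    INDI = up(reports$indi), OUTC = up(reports$outc)
  )
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(directory, paste0(nm, ".txt"))
    readr::write_delim(tables[[nm]], p, delim = "$", na = "")
    p
  }, character(1))
  invisible(paths)
}
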