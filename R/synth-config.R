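#' Default drug catalog for the synthetic generator
#'
#' A small formulary of oncology-adjacent drugs with per-report inclusion
#' probabilities. The first entry, etoposide, carries its common brand and
#' shorthand names so that free-text name matching can be exercised.
#'
#' @return A tibble with columns `name`, `prod_ai`, `prevalence`, and a
#'   `synonyms` list-column of alternative trade names.
#' @export
default_drug_catalog <- function() {
  tibble::tibble(
    name = c(
      "ETOPOSIDE", "CISPLATIN", "CARBOPLATIN", "CYCLOPHOSPHAMIDE",
      "DOXORUBICIN", "PACLITAXEL", "RITUXIMAB", "METHOTREXATE",
      "FILGRASTIM", "ONDANSETRON", "DEXAMETHASONE", "ALLOPURINOL"
    ),
    prod_ai = c(
      "ETOPOSIDE", "CISPLATIN", "CARBOPLATIN", "CYCLOPHOSPHAMIDE",
      "DOXORUBICIN HYDROCHLORIDE", "PACLITAXEL", "RITUXIMAB", "METHOTREXATE",
      "FILGRASTIM", "ONDANSETRON", "DEXAMETHASONE", "ALLOPURINOL"
    ),
    prevalence = c(0.10, 0.20, 0.15, 0.18, 0.15, 0.18,
                   0.12, 0.15, 0.20, 0.25, 0.30, 0.10),
    synonyms = list(
      c("VP-16", "VEPESID", "TOPOSAR", "LASTET"),
      character(0), character(0), character(0),
      c("ADRIAMYCIN"), c("TAXOL"), c("RITUXAN"), character(0),
      c("NEUPOGEN"), c("ZOFRAN"), character(0), c("ZYLOPRIM")
    )
  )
}

#' Default preferred-term catalog for the synthetic generator
#'
#' Adverse-event preferred terms (PTs) with their primary System Organ Class
#' (SOC) and a per-report baseline occurrence probability. Baselines span the
#' range from common constitutional events (~15% of reports) down to rare
#' events near two per thousand, so that both abundant and sparse 2x2 cells
#' arise downstream; they sum to about 1.9, giving a realistic average
#' reaction count per report.
#'
#' @return A tibble with columns `pt`, `soc`, `baseline`.
#' @export
default_pt_catalog <- function() {
  rows <- list(
    # soc, pt, baseline
    c("Blood and lymphatic system disorders", "Febrile neutropenia", 0.025),
    c("Blood and lymphatic system disorders", "Neutropenia", 0.030),
    c("Blood and lymphatic system disorders", "Thrombocytopenia", 0.030),
    c("Blood and lymphatic system disorders", "Anaemia", 0.038),
    c("Blood and lymphatic system disorders", "Pancytopenia", 0.015),
    c("Blood and lymphatic system disorders", "Leukopenia", 0.020),
    c("Blood and lymphatic system disorders", "Bone marrow failure", 0.008),
    c("Gastrointestinal disorders", "Nausea", 0.150),
    c("Gastrointestinal disorders", "Vomiting", 0.100),
    c("Gastrointestinal disorders", "Diarrhoea", 0.125),
    c("Gastrointestinal disorders", "Constipation", 0.050),
    c("Gastrointestinal disorders", "Stomatitis", 0.020),
    c("Gastrointestinal disorders", "Abdominal pain", 0.075),
    c("General disorders and administration site conditions", "Fatigue", 0.125),
    c("General disorders and administration site conditions", "Pyrexia", 0.075),
    c("General disorders and administration site conditions", "Asthenia", 0.062),
    c("General disorders and administration site conditions", "Death", 0.050),
    c("General disorders and administration site conditions", "Mucosal inflammation", 0.010),
    c("General disorders and administration site conditions", "Malaise", 0.050),
    c("General disorders and administration site conditions", "Chills", 0.038),
    c("Infections and infestations", "Pneumonia", 0.050),
    c("Infections and infestations", "Sepsis", 0.020),
    c("Infections and infestations", "Septic shock", 0.010),
    c("Infections and infestations", "Urinary tract infection", 0.030),
    c("Infections and infestations", "Neutropenic sepsis", 0.005),
    c("Nervous system disorders", "Headache", 0.100),
    c("Nervous system disorders", "Dizziness", 0.075),
    c("Nervous system disorders", "Neuropathy peripheral", 0.025),
    c("Nervous system disorders", "Encephalopathy", 0.008),
    c("Nervous system disorders", "Syncope", 0.020),
    c("Skin and subcutaneous tissue disorders", "Alopecia", 0.030),
    c("Skin and subcutaneous tissue disorders", "Rash", 0.088),
    c("Skin and subcutaneous tissue disorders", "Pruritus", 0.050),
    c("Respiratory, thoracic and mediastinal disorders", "Dyspnoea", 0.075),
    c("Respiratory, thoracic and mediastinal disorders", "Cough", 0.050),
    c("Respiratory, thoracic and mediastinal disorders", "Pneumonitis", 0.010),
    c("Respiratory, thoracic and mediastinal disorders", "Respiratory failure", 0.012),
    c("Respiratory, thoracic and mediastinal disorders", "Pulmonary embolism", 0.015),
    c("Cardiac disorders", "Myocardial infarction", 0.015),
    c("Cardiac disorders", "Cardiac failure congestive", 0.012),
    c("Cardiac disorders", "Atrial fibrillation", 0.018),
    c("Cardiac disorders", "Tachycardia", 0.025),
    c("Renal and urinary disorders", "Acute kidney injury", 0.025),
    c("Renal and urinary disorders", "Renal failure", 0.015),
    c("Renal and urinary disorders", "Nephropathy toxic", 0.003),
    c("Metabolism and nutrition disorders", "Decreased appetite", 0.062),
    c("Metabolism and nutrition disorders", "Hyponatraemia", 0.015),
    c("Metabolism and nutrition disorders", "Tumour lysis syndrome", 0.003),
    c("Metabolism and nutrition disorders", "Dehydration", 0.030),
    c("Reproductive system and breast disorders", "Ovarian failure", 0.0025),
    c("Reproductive system and breast disorders", "Gynaecomastia", 0.003),
    c("Ear and labyrinth disorders", "Ototoxicity", 0.0025),
    c("Ear and labyrinth disorders", "Tinnitus", 0.010),
    c("Ear and labyrinth disorders", "Deafness", 0.005),
    c("Hepatobiliary disorders", "Hepatotoxicity", 0.008),
    c("Hepatobiliary disorders", "Hepatic failure", 0.005),
    c("Vascular disorders", "Hypertension", 0.050),
    c("Vascular disorders", "Hypotension", 0.038),
    c("Vascular disorders", "Flushing", 0.020),
    c("Injury, poisoning and procedural complications", "Off label use", 0.075),
    c("Injury, poisoning and procedural complications", "Infusion related reaction", 0.015),
    c("Investigations", "Ejection fraction decreased", 0.005),
    c("Investigations", "Blood creatinine increased", 0.020)
  )
  tibble::tibble(
    pt = vapply(rows, `[`, character(1), 2),
    soc = vapply(rows, `[`, character(1), 1),
    baseline = as.numeric(vapply(rows, `[`, character(1), 3))
  )
}

#' Default planted drug-event associations
#'
#' Ground-truth signals injected by the generator: reports containing the
#' named drug draw the named PT with probability `lambda` times its baseline.
#' `age_group` restricts the effect to one age stratum (`NA` = all ages).
#'
#' @return A tibble with columns `drug`, `pt`, `lambda`, `age_group`.
#' @export
default_planted_signals <- function() {
  tibble::tibble(
    drug = "ETOPOSIDE",
    pt = c("Febrile neutropenia", "Pancytopenia", "Thrombocytopenia",
           "Ovarian failure", "Ototoxicity", "Tumour lysis syndrome"),
    lambda = c(8, 6, 5, 15, 12, 10),
    age_group = NA_character_
  )
}

default_indication_catalog <- function() {
  tibble::tibble(
    indi_pt = c(
      "Product used for unknown indication", "Acute myeloid leukaemia",
      "Small cell lung cancer", "Hodgkin's disease",
      "Acute lymphocytic leukaemia", "Testicular cancer",
      "Non-Hodgkin's lymphoma", "Breast cancer", "Ovarian cancer"
    ),
    weight = c(0.20, 0.15, 0.13, 0.12, 0.12, 0.10, 0.08, 0.05, 0.05)
  )
}

default_demographics <- function() {
  list(
    sex = c(F = 0.40, M = 0.48, unknown = 0.12),
    # proportions of the three age strata plus unknown
    age = c("<18" = 0.20, "18-64" = 0.45, ">64" = 0.20, unknown = 0.15),
    p_weight_known = 0.35,
    weight_meanlog = log(70), weight_sdlog = 0.25,
    country = c(US = 0.30, FR = 0.12, JP = 0.10, CA = 0.08, IT = 0.05,
                GB = 0.08, DE = 0.07, CN = 0.06, AU = 0.05, ES = 0.09),
    occp = c(MD = 0.45, PH = 0.20, OT = 0.20, CN = 0.08, unknown = 0.07),
    p_any_outcome = 0.75,
    outcome = c(DE = 0.12, LT = 0.06, HO = 0.35, DS = 0.02,
                CA = 0.01, RI = 0.02, OT = 0.42)
  )
}

#' Configuration for the synthetic FAERS-like generator
#'
#' Bundles everything the generator needs: catalog sizes and occurrence
#' probabilities, planted drug-event associations with their relative
#' reporting ratios, the Weibull onset-lag distribution, missing/invalid-date
#' and duplicate-case rates, demographic category distributions, and the
#' seed. Defaults emulate an oncology drug cohort in a spontaneous reporting
#' system: a target drug present in ~10% of reports, a handful of strong
#' planted signals, heavily right-skewed onset lags, and substantial date
#' missingness.
#'
#' @param n_reports number of unique cases to generate (before duplicate
#'   injection).
#' @param drug_catalog tibble as [default_drug_catalog()].
#' @param pt_catalog tibble as [default_pt_catalog()].
#' @param planted_signals tibble as [default_planted_signals()]; `lambda >= 0`
#'   multiplies the PT baseline in reports containing the drug. Use an empty
#'   tibble or `lambda = 1` rows for a null configuration.
#' @param sex_effects optional tibble (`pt`, `f_multiplier`) multiplying a
#'   PT's occurrence probability in female reports (for sex-difference
#'   validation); `NULL` for none.
#' @param onset_scale_days,onset_shape Weibull scale (days) and shape of the
#'   event lag after therapy start.
#' @param p_missing_event_date probability the event date is absent.
#' @param p_invalid_date probability a date field is truncated to a partial
#'   (`YYYYMM` or `YYYY`) form.
#' @param p_duplicate_case probability a case is re-submitted as a second
#'   report version.
#' @param demographics list of categorical distributions (see
#'   `default_demographics`).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_reports = 5000,
                             drug_catalog = default_drug_catalog(),
                             pt_catalog = default_pt_catalog(),
                             planted_signals = default_planted_signals(),
                             sex_effects = NULL,
                             onset_scale_days = 38.56,
                             onset_shape = 0.55,
                             p_missing_event_date = 0.5,
                             p_invalid_date = 0.05,
                             p_duplicate_case = 0.10,
                             demographics = default_demographics(),
                             seed = 1L) {
  stopifnot(
    is.numeric(n_reports), length(n_reports) == 1, n_reports >= 1,
    onset_scale_days > 0, onset_shape > 0
  )
  probs <- c(p_missing_event_date, p_invalid_date, p_duplicate_case)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(drug_catalog) == 0 || nrow(pt_catalog) == 0) {
    stop("drug and PT catalogs must be non-empty", call. = FALSE)
  }
  if (any(drug_catalog$prevalence < 0 | drug_catalog$prevalence > 1) ||
      any(pt_catalog$baseline < 0 | pt_catalog$baseline > 1)) {
    stop("catalog probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(planted_signals) > 0) {
    if (any(planted_signals$lambda < 0)) {
      stop("planted lambda must be >= 0", call. = FALSE)
    }
    if (!all(planted_signals$drug %in% drug_catalog$name)) {
      stop("planted signal names a drug absent from the drug catalog",
           call. = FALSE)
    }
    if (!all(planted_signals$pt %in% pt_catalog$pt)) {
      stop("planted signal names a PT absent from the PT catalog",
           call. = FALSE)
    }
    if (is.null(planted_signals$age_group)) {
      planted_signals$age_group <- NA_character_
    }
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      drug_catalog = drug_catalog,
      pt_catalog = pt_catalog,
      planted_signals = planted_signals,
      sex_effects = sex_effects,
      onset_scale_days = onset_scale_days,
      onset_shape = onset_shape,
      p_missing_event_date = p_missing_event_date,
      p_invalid_date = p_invalid_date,
      p_duplicate_case = p_duplicate_case,
      demographics = demographics,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  reports:", x$n_reports,
      "| drugs:", nrow(x$drug_catalog),
      "| PTs:", nrow(x$pt_catalog),
      "| planted signals:", nrow(x$planted_signals), "\n")
  cat("  onset ~ Weibull(scale =", x$onset_scale_days,
      "d, shape =", x$onset_shape, ")\n")
  cat("  p(missing event date) =", x$p_missing_event_date,
      "| p(partial date) =", x$p_invalid_date,
      "| p(duplicate case) =", x$p_duplicate_case, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' PT-to-SOC map implied by a synthetic configuration
#'
#' @param config a `synthetic_config`.
#' @return Two-column tibble (`pt`, `soc`) usable wherever a MedDRA-style
#'   primary-SOC map is expected.
#' @export
pt_soc_map <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  config$pt_catalog[, c("pt", "soc")]
}
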