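#' Configure an end-to-end signal-detection run
#'
#' @param data_dir directory of quarterly dollar-delimited tables (see
#'   [read_quarter()]).
#' @param drug_names search names for the target drug.
#' @param roles role codes kept for identification (default `"PS"`).
#' @param pt_soc_map_path two-column CSV mapping PT to SOC.
#' @param label_pts_path optional plain-text label PT list (one per line)
#'   for novelty flagging; `NULL` skips the flag.
#' @param indication_exclusion `"auto"` (derive the exclusion set from the
#'   INDI rows of the target reports), a path to a one-PT-per-line file, or
#'   `NULL` to skip exclusion.
#' @param min_cases minimum case count for the screening criteria.
#' @param rank_min_a strict case-count threshold for the ranked table.
#' @param stratifications subgroup variables to run.
#' @param years year range for annual counts (`NULL` = observed range).
#' @param out_dir output directory for tables and the manifest.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(data_dir, drug_names, roles = "PS",
                            pt_soc_map_path, label_pts_path = NULL,
                            indication_exclusion = "auto",
                            min_cases = 3, rank_min_a = 30,
                            stratifications = c("age", "weight", "sex",
                                                "reporter"),
                            years = NULL, out_dir, seed = 1L) {
  structure(
    list(data_dir = data_dir, drug_names = drug_names, roles = roles,
         pt_soc_map_path = pt_soc_map_path, label_pts_path = label_pts_path,
         indication_exclusion = indication_exclusion, min_cases = min_cases,
         rank_min_a = rank_min_a, stratifications = stratifications,
         years = years, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full signal-detection pipeline
#'
#' Executes ingest, deduplication, target-drug identification, indication
#' exclusion, PT- and SOC-level disproportionality screening with ranking
#' and novelty flags, time-to-onset analysis, subgroup screens, and the
#' sex-difference analysis; writes every deliverable as CSV (plus a JSON
#' TTO summary) and a manifest recording input hashes, configuration,
#' package versions, and all exclusion tallies. Outputs are staged in a
#' temporary directory and moved into `out_dir` only on success, so a
#' failing stage leaves no partial outputs behind.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the principal in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$pt_soc_map_path)) {
    stop("PT-to-SOC map not found: ", config$pt_soc_map_path, call. = FALSE)
  }
  if (!is.null(config$label_pts_path) &&
      !file.exists(config$label_pts_path)) {
    stop("label PT list not found: ", config$label_pts_path, call. = FALSE)
  }
  stage_dir <- tempfile("faersignal_run_")
  dir.create(stage_dir)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  wcsv <- function(x, nm) readr::write_csv(x, file.path(stage_dir, nm))

  raw <- run_stage("ingest", read_quarter(config$data_dir))
  reports <- run_stage("assemble", suppressMessages(assemble_reports(raw)))
  query <- drug_query(config$drug_names, roles = config$roles)
  target <- run_stage("identify", identify_drug_reports(reports, query))

  soc_map <- run_stage("soc-map", read_pt_soc_map(config$pt_soc_map_path))

  all_pairs <- extract_case_pairs(reports)
  target_pairs <- extract_case_pairs(target)

  ind_pts <- if (identical(config$indication_exclusion, "auto")) {
    observed_indication_pts(target)
  } else if (is.character(config$indication_exclusion) &&
             !is.null(config$indication_exclusion)) {
    read_label_pts(config$indication_exclusion)
  } else {
    character(0)
  }
  all_pairs <- suppressMessages(exclude_indications(all_pairs, ind_pts))
  n_ind_all <- attr(all_pairs, "n_excluded")
  target_pairs <- suppressMessages(exclude_indications(target_pairs, ind_pts))
  n_ind_target <- attr(target_pairs, "n_excluded")

  ## descriptive tables
  run_stage("describe", {
    wcsv(demographics_summary(target), "demographics.csv")
    wcsv(annual_counts(target, years = config$years), "annual_counts.csv")
  })

  ## disproportionality: PT level
  pt_results <- run_stage("disprop-pt", {
    apply_criteria(
      signal_stats(contingency_counts(all_pairs, target_pairs)),
      min_cases = config$min_cases
    )
  })
  significant <- suppressMessages(screen_signals(pt_results))
  if (!is.null(config$label_pts_path)) {
    significant <- flag_unexpected(significant,
                                   read_label_pts(config$label_pts_path))
  }
  ranked <- rank_and_filter(significant, min_a = config$rank_min_a)
  run_stage("disprop-pt-write", {
    wcsv(pt_results, "signals_pt.csv")
    wcsv(significant, "signals_pt_significant.csv")
    wcsv(round_estimates(ranked), "signals_pt_ranked.csv")
  })

  ## disproportionality: SOC level
  soc_results <- run_stage("disprop-soc", {
    soc_level_signals(
      suppressMessages(map_pt_to_soc(all_pairs, soc_map)),
      suppressMessages(map_pt_to_soc(target_pairs, soc_map)),
      min_cases = config$min_cases
    )
  })
  wcsv(soc_results, "signals_soc.csv")

  ## time-to-onset
  tto <- run_stage("tto", compute_tto(target, query))
  tto_fit <- if (length(tto$values) >= 30 &&
                 length(unique(tto$values)) > 1) {
    fit_weibull(tto)
  } else {
    NULL
  }
  run_stage("tto-write", {
    wcsv(tto$records, "tto_records.csv")
    summary_json <- list(
      n = length(tto$values),
      excluded = list(missing = tto$n_excluded_missing,
                      invalid = tto$n_excluded_invalid,
                      negative = tto$n_excluded_negative),
      summary = summarize_tto(tto),
      bins = bin_tto(tto),
      weibull = if (!is.null(tto_fit)) {
        list(alpha = tto_fit$alpha, alpha_ci = tto_fit$alpha_ci,
             beta = tto_fit$beta, beta_ci = tto_fit$beta_ci,
             failure_type = classify_failure(tto_fit))
      }
    )
    jsonlite::write_json(summary_json, file.path(stage_dir,
                                                 "tto_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  ## subgroups and sex differences
  run_stage("strata", {
    for (v in config$stratifications) {
      tabs <- suppressWarnings(subgroup_signals(reports, query, v,
                                                min_cases = config$min_cases))
      for (lv in names(tabs)) {
        if (nrow(tabs[[lv]])) {
          safe <- gsub("[^A-Za-z0-9]+", "_", lv)
          wcsv(tabs[[lv]], sprintf("subgroup_%s_%s.csv", v, safe))
        }
      }
    }
  })
  gender <- run_stage("gender", {
    gs <- gender_disproportionality(target, min_cases = config$min_cases)
    if (nrow(gs)) {
      vc <- suppressMessages(volcano_coordinates(gs))
      gs <- dplyr::left_join(gs, vc, by = "term")
    }
    wcsv(gs, "gender_signals.csv")
    gs
  })

  ## manifest
  run_stage("manifest", {
    inputs <- list.files(config$data_dir, full.names = TRUE)
    manifest <- list(
      package = list(name = "faersignal",
                     version = as.character(utils::packageVersion("faersignal")),
                     r_version = as.character(getRversion())),
      seed = config$seed,
      config = config[setdiff(names(config), "out_dir")],
      input_md5 = as.list(tools::md5sum(inputs)),
      counts = list(
        raw_demo_rows = nrow(raw$demo),
        malformed_rows = as.list(attr(raw, "malformed")),
        deduplicated_reports = nrow(reports$demo),
        dedup_losers = nrow(raw$demo) - nrow(reports$demo),
        dropped_child_rows = as.list(attr(reports, "dropped_child_rows")),
        target_reports = nrow(target$demo),
        database_pairs = nrow(all_pairs),
        target_pairs = nrow(target_pairs),
        indication_excluded = list(database = n_ind_all,
                                   target = n_ind_target),
        significant_pt = nrow(significant),
        ranked_pt = nrow(ranked),
        tto = list(n = length(tto$values),
                   missing = tto$n_excluded_missing,
                   invalid = tto$n_excluded_invalid,
                   negative = tto$n_excluded_negative)
      )
    )
    jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage_dir, full.names = TRUE)) {
    file.copy(f, file.path(config$out_dir, basename(f)), overwrite = TRUE)
  }
  invisible(list(reports = reports, target = target,
                 pt_results = pt_results, significant = significant,
                 ranked = ranked, soc_results = soc_results,
                 tto = tto, tto_fit = tto_fit, gender = gender))
}

# rendered precision for deliverable tables: 2 decimals on estimators
round_estimates <- function(tb) {
  est <- intersect(c("ror", "ror_lo", "ror_hi", "prr", "chi2",
                     "ic", "ic025", "ebgm", "ebgm05"), names(tb))
  for (v in est) tb[[v]] <- round(tb[[v]], 2)
  tb
}
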