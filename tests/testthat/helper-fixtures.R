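# Build a faers_reports object from partial tables, filling the rest with
# empty-but-typed tibbles. Keeps hand-built fixtures short.
tiny_reports <- function(demo = NULL, drug = NULL, reac = NULL,
                         ther = NULL, indi = NULL, outc = NULL) {
  n <- if (!is.null(demo)) nrow(demo) else 0L
  if (is.null(demo)) {
    demo <- tibble::tibble(primaryid = character(0), caseid = character(0),
                           fda_dt = integer(0))
  }
  for (col in c("event_dt", "sex", "age_cod", "wt_cod", "occp_cod",
                "reporter_country")) {
    if (is.null(demo[[col]])) demo[[col]] <- rep(NA_character_, nrow(demo))
  }
  for (col in c("age", "wt")) {
    if (is.null(demo[[col]])) demo[[col]] <- rep(NA_real_, nrow(demo))
  }
  if (is.null(drug)) {
    drug <- tibble::tibble(primaryid = character(0), drug_seq = integer(0),
                           role_cod = character(0), drugname = character(0),
                           prod_ai = character(0))
  }
  if (is.null(drug$prod_ai)) drug$prod_ai <- rep(NA_character_, nrow(drug))
  if (is.null(reac)) {
    reac <- tibble::tibble(primaryid = character(0), pt = character(0))
  }
  if (is.null(ther)) {
    ther <- tibble::tibble(primaryid = character(0),
                           dsg_drug_seq = integer(0),
                           start_dt = character(0), end_dt = character(0))
  }
  if (is.null(indi)) {
    indi <- tibble::tibble(primaryid = character(0),
                           indi_drug_seq = integer(0),
                           indi_pt = character(0))
  }
  if (is.null(outc)) {
    outc <- tibble::tibble(primaryid = character(0), outc_cod = character(0))
  }
  faers_reports(demo, drug, reac, ther, indi, outc)
}

# A single-drug-row demo+drug fixture: one report per row of `pts` list.
reports_with_pts <- function(pts, sex = NULL, drugname = "ETOPOSIDE",
                             role = "PS") {
  n <- length(pts)
  ids <- as.character(seq_len(n) + 1000)
  demo <- tibble::tibble(primaryid = ids, caseid = ids,
                         fda_dt = rep(20200101L, n))
  if (!is.null(sex)) demo$sex <- sex
  drug <- tibble::tibble(primaryid = ids, drug_seq = 1L, role_cod = role,
                         drugname = drugname, prod_ai = drugname)
  reac <- tibble::tibble(
    primaryid = rep(ids, lengths(pts)),
    pt = unlist(pts, use.names = FALSE)
  )
  tiny_reports(demo = demo, drug = drug, reac = reac)
}

# standard target-drug query used across tests
etoposide_query <- function(roles = "PS") {
  drug_query(c("ETOPOSIDE", "VP-16", "VEPESID", "TOPOSAR", "LASTET"),
             roles = roles)
}

# generate + assemble in one go (dedup applied), returning both
synth_assembled <- function(config) {
  rep <- generate_reports(config)
  raw <- list(demo = rep$demo, drug = rep$drug, reac = rep$reac,
              ther = rep$ther, indi = rep$indi, outc = rep$outc)
  asm <- suppressMessages(assemble_reports(raw))
  attr(asm, "truth") <- synthetic_truth(rep)
  list(generated = rep, assembled = asm)
}
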