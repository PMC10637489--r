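#' Compute time-to-onset for the target drug
#'
#' Time-to-onset (TTO) is the delay in whole days between the start of the
#' target drug's therapy (`START_DT`, THER table) and the adverse-event
#' onset date (`EVENT_DT`, DEMO table). When a report carries several
#' therapy rows for the target drug the earliest full-precision `START_DT`
#' is used. Records are excluded — and tallied, never silently dropped —
#' when either date is missing (`n_excluded_missing`), partial or invalid
#' (`n_excluded_invalid`), or when the event precedes the therapy start
#' (`n_excluded_negative`). Same-day onsets (delay 0) are retained.
#'
#' @param target_reports the target-drug subset from
#'   [identify_drug_reports()].
#' @param query the [drug_query()] used to identify the target drug (needed
#'   to pick out the target drug's own therapy rows).
#' @return A `tto_sample`: list with `values` (non-negative integer days),
#'   the three exclusion tallies, and a per-report `records` tibble
#'   (`primaryid`, `delay`, `status`).
#' @export
compute_tto <- function(target_reports, query) {
  stopifnot(inherits(target_reports, "faers_reports"),
            inherits(query, "drug_query"))
  dr <- target_reports$drug
  hit <- rep(FALSE, nrow(dr))
  if ("drugname" %in% query$fields) {
    hit <- hit | normalize_drug_name(dr$drugname) %in% query$name_list
  }
  if ("prod_ai" %in% query$fields && "prod_ai" %in% names(dr)) {
    hit <- hit | normalize_drug_name(dr$prod_ai) %in% query$name_list
  }
  hit <- hit & dr$role_cod %in% query$roles
  target_seq <- dr[hit, c("primaryid", "drug_seq")]

  ther <- dplyr::inner_join(
    target_reports$ther, target_seq,
    by = c("primaryid", "dsg_drug_seq" = "drug_seq")
  )
  ther_parsed <- parse_faers_date(ther$start_dt)
  ther$start_status <- ther_parsed$status
  ther$start_date <- ther_parsed$date

  # per report: earliest full-precision start; note whether any start row
  # existed and whether all of them were unusable because partial/invalid
  start_by_report <- ther |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      start_date = if (any(.data$start_status == "full"))
        min(.data$start_date[.data$start_status == "full"]) else as.Date(NA),
      any_partial = any(.data$start_status %in% c("partial", "invalid")),
      .groups = "drop"
    )

  demo <- target_reports$demo
  ev <- parse_faers_date(demo$event_dt)
  rec <- tibble::tibble(
    primaryid = demo$primaryid,
    event_status = ev$status,
    event_date = ev$date
  )
  rec <- dplyr::left_join(rec, start_by_report, by = "primaryid")
  rec$any_partial[is.na(rec$any_partial)] <- FALSE

  delay <- as.integer(rec$event_date - rec$start_date)
  status <- dplyr::case_when(
    rec$event_status == "missing" ~ "missing",
    rec$event_status %in% c("partial", "invalid") ~ "invalid",
    is.na(rec$start_date) & rec$any_partial ~ "invalid",
    is.na(rec$start_date) ~ "missing",
    delay < 0 ~ "negative",
    TRUE ~ "ok"
  )
  records <- tibble::tibble(
    primaryid = rec$primaryid,
    delay = ifelse(status == "ok", delay, NA_integer_),
    status = status
  )
  structure(
    list(
      values = delay[status == "ok"],
      n_excluded_missing = sum(status == "missing"),
      n_excluded_invalid = sum(status == "invalid"),
      n_excluded_negative = sum(status == "negative"),
      records = records
    ),
    class = "tto_sample"
  )
}

#' @export
print.tto_sample <- function(x, ...) {
  cat("<tto_sample> n =", length(x$values),
      "| excluded: missing", x$n_excluded_missing,
      ", invalid", x$n_excluded_invalid,
      ", negative", x$n_excluded_negative, "\n")
  invisible(x)
}

#' Summary statistics of a time-to-onset sample
#'
#' Median and quartiles use the standard linear-interpolation convention
#' (`stats::quantile`, type 7).
#'
#' @param sample a `tto_sample` or numeric vector of delays.
#' @return List with `n`, `median`, `q1`, `q3`, `min`, `max`; all `NA` with
#'   `n = 0` for an empty sample.
#' @export
summarize_tto <- function(sample) {
  x <- if (inherits(sample, "tto_sample")) sample$values else sample
  if (!length(x)) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                min = NA_real_, max = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       min = min(x), max = max(x))
}

#' Bin time-to-onset into 30-day months
#'
#' Bin `k` covers days `[30(k-1), 30k)`, so day 0 falls in the first month;
#' delays of `tail_after` days or more fall into a single tail bin.
#' Percentages are of the sample size, one decimal.
#'
#' @param sample a `tto_sample` or numeric vector of delays.
#' @param bin_days bin width in days (default 30).
#' @param tail_after start of the open tail bin (default 360 days).
#' @return Tibble with `bin` (label), `lower`, `upper`, `n`, `pct`.
#' @export
bin_tto <- function(sample, bin_days = 30, tail_after = 360) {
  x <- if (inherits(sample, "tto_sample")) sample$values else sample
  n_bins <- tail_after %/% bin_days
  lower <- (seq_len(n_bins) - 1L) * bin_days
  upper <- lower + bin_days
  counts <- vapply(seq_len(n_bins), function(k) {
    sum(x >= lower[k] & x < upper[k])
  }, integer(1))
  tail_n <- sum(x >= tail_after)
  tb <- tibble::tibble(
    bin = c(sprintf("%d-%d", lower, upper - 1L), sprintf(">%d", tail_after)),
    lower = c(lower, tail_after),
    upper = c(upper - 1L, Inf),
    n = c(counts, tail_n)
  )
  tb$pct <- round(100 * tb$n / max(length(x), 1L), 1)
  tb
}

#' Fit a two-parameter Weibull distribution to onset delays
#'
#' Maximum-likelihood fit of the Weibull scale (alpha, days) and shape
#' (beta). Because the Weibull has positive support, same-day onsets (delay
#' 0) are mapped to `zero_adjust` days before fitting; the number of
#' adjusted values is recorded. 95% confidence intervals are built by the
#' normal approximation on the log of each parameter (guaranteeing positive
#' bounds) from the observed information matrix. The fit is deterministic
#' given the sample.
#'
#' @param sample a `tto_sample` or numeric vector of delays (days, >= 0).
#' @param zero_adjust replacement value for zero delays (default 0.5 day).
#' @param min_n sample size below which a warning is attached (default 30).
#' @return A `weibull_fit`: list with `alpha`, `alpha_ci`, `beta`,
#'   `beta_ci`, `n`, `n_zero_adjusted`.
#' @export
fit_weibull <- function(sample, zero_adjust = 0.5, min_n = 30) {
  x <- if (inherits(sample, "tto_sample")) sample$values else sample
  x <- as.numeric(x[!is.na(x)])
  if (!length(x) || length(unique(x)) == 1L) {
    stop("degenerate sample: need at least two distinct delay values",
         call. = FALSE)
  }
  if (length(x) < min_n) {
    warning("fewer than ", min_n, " delays; Weibull fit is unstable",
            call. = FALSE)
  }
  n_zero <- sum(x == 0)
  x[x == 0] <- zero_adjust

  fit <- fitdistrplus::fitdist(
    x, "weibull",
    start = list(shape = 1, scale = mean(x))
  )
  est <- fit$estimate
  se <- fit$sd
  # CI on the log scale, then exponentiate
  ci <- function(par) {
    lse <- se[par] / est[par]
    unname(exp(log(est[par]) + c(-1.96, 1.96) * lse))
  }
  structure(
    list(
      alpha = unname(est["scale"]), alpha_ci = ci("scale"),
      beta = unname(est["shape"]), beta_ci = ci("shape"),
      n = length(x), n_zero_adjusted = n_zero
    ),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n = %d | scale alpha = %.2f (%.2f-%.2f) d | shape beta = %.2f (%.2f-%.2f) | %s\n",
    x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], classify_failure(x)
  ))
  invisible(x)
}

#' Classify the hazard profile from the Weibull shape
#'
#' The shape parameter's confidence interval determines the failure type:
#' a decreasing hazard (upper bound of beta below 1) is an *early* failure
#' pattern, an increasing hazard (lower bound above 1) is *wear-out*, and a
#' CI spanning 1 is *random* (approximately constant hazard).
#'
#' @param fit a `weibull_fit`.
#' @return `"early"`, `"random"`, or `"wear-out"`.
#' @export
classify_failure <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (fit$beta_ci[2] < 1) "early"
  else if (fit$beta_ci[1] > 1) "wear-out"
  else "random"
}
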