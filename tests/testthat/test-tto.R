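make_tto_reports <- function(event_dt, start_dt) {
  n <- length(event_dt)
  ids <- as.character(seq_len(n) + 500)
  demo <- tibble::tibble(primaryid = ids, caseid = ids,
                         fda_dt = rep(20210101L, n), event_dt = event_dt)
  drug <- tibble::tibble(primaryid = ids, drug_seq = 1L, role_cod = "PS",
                         drugname = "ETOPOSIDE", prod_ai = "ETOPOSIDE")
  ther <- tibble::tibble(primaryid = ids, dsg_drug_seq = 1L,
                         start_dt = start_dt, end_dt = NA_character_)
  tiny_reports(demo = demo, drug = drug, ther = ther)
}

test_that("onset delays are event minus start in days, with exclusions tallied", {
  reports <- make_tto_reports(
    event_dt = c("20200115", "20200101", "20200110", NA, "202003",
                 "20200110"),
    start_dt = c("20200101", "20200115", "202001", "20200101", "20200101",
                 "20200110")
  )
  tto <- compute_tto(reports, etoposide_query())
  expect_equal(sort(tto$values), c(0L, 14L)) # day-0 onset retained
  expect_equal(tto$n_excluded_negative, 1)
  expect_equal(tto$n_excluded_invalid, 2) # partial start, partial event
  expect_equal(tto$n_excluded_missing, 1)
  # tallies + retained = input
  expect_equal(length(tto$values) + tto$n_excluded_missing +
                 tto$n_excluded_invalid + tto$n_excluded_negative,
               nrow(reports$demo))
})

test_that("the earliest full-precision therapy start is used when several exist", {
  ids <- "901"
  demo <- tibble::tibble(primaryid = ids, caseid = ids, fda_dt = 20210101L,
                         event_dt = "20200301")
  drug <- tibble::tibble(primaryid = ids, drug_seq = 1L, role_cod = "PS",
                         drugname = "ETOPOSIDE", prod_ai = "ETOPOSIDE")
  ther <- tibble::tibble(
    primaryid = ids, dsg_drug_seq = 1L,
    start_dt = c("20200210", "202001", "20200120"), # partial one ignored
    end_dt = NA_character_
  )
  tto <- compute_tto(tiny_reports(demo = demo, drug = drug, ther = ther),
                     etoposide_query())
  expect_equal(tto$values, as.integer(as.Date("2020-03-01") -
                                        as.Date("2020-01-20")))
})

test_that("therapy rows of non-target drugs never contribute delays", {
  ids <- "902"
  demo <- tibble::tibble(primaryid = ids, caseid = ids, fda_dt = 20210101L,
                         event_dt = "20200301")
  drug <- tibble::tibble(
    primaryid = ids, drug_seq = c(1L, 2L), role_cod = c("PS", "C"),
    drugname = c("ETOPOSIDE", "CISPLATIN"),
    prod_ai = c("ETOPOSIDE", "CISPLATIN")
  )
  ther <- tibble::tibble(
    primaryid = ids, dsg_drug_seq = c(1L, 2L),
    start_dt = c("20200220", "20200101"), end_dt = NA_character_
  )
  tto <- compute_tto(tiny_reports(demo = demo, drug = drug, ther = ther),
                     etoposide_query())
  expect_equal(tto$values, 10L) # cisplatin's earlier start is ignored
})

test_that("summary quantiles match an independent interpolation oracle", {
  expect_equal(summarize_tto(c(1, 2, 3))$median, 2)
  z <- summarize_tto(c(0, 0, 0, 0))
  expect_equal(c(z$median, z$q1, z$q3), c(0, 0, 0))
  expect_equal(summarize_tto(numeric(0))$n, 0)

  set.seed(14)
  x <- rweibull(501, 0.7, 30)
  s <- summarize_tto(x)
  # sort-based linear interpolation at p(n-1)+1
  oracle <- function(p) {
    xs <- sort(x)
    h <- p * (length(xs) - 1) + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }
  expect_equal(s$median, oracle(0.5))
  expect_equal(s$q1, oracle(0.25))
  expect_equal(s$q3, oracle(0.75))
  expect_equal(s$min, min(x))
  expect_equal(s$max, max(x))
})

test_that("monthly bins use [30(k-1), 30k) with day 0 in month 1 and a >360 tail", {
  x <- c(0, 29, 30, 59, 359, 360, 400, 4900)
  tb <- bin_tto(x)
  expect_equal(tb$n[1], 2) # 0 and 29
  expect_equal(tb$n[2], 2) # 30 and 59
  expect_equal(tb$n[12], 1) # 359
  expect_equal(tb$n[13], 3) # >= 360
  expect_equal(sum(tb$n), length(x))
  expect_equal(sum(tb$pct), 100, tolerance = 0.3)

  all_tail <- bin_tto(rep(400, 7))
  expect_equal(all_tail$pct[13], 100)

  # the printed-proportion convention: count/total at one decimal
  expect_equal(bin_tto(c(rep(10, 738), rep(40, 262)))$pct[1:2],
               c(73.8, 26.2))
})

test_that("Weibull fitting recovers a unit shape for exponential data", {
  set.seed(21)
  x <- rexp(5000, rate = 1 / 20) # exponential = Weibull with shape 1
  fit <- fit_weibull(x)
  expect_gt(fit$beta, 0.95)
  expect_lt(fit$beta, 1.05)
  expect_gt(fit$alpha, 18)
  expect_lt(fit$alpha, 22)
  expect_lt(fit$beta_ci[1], fit$beta)
  expect_gt(fit$beta_ci[2], fit$beta)
})

test_that("the likelihood fit agrees with an independent survival-regression fit", {
  skip_if_not_installed("survival")
  set.seed(33)
  x <- rweibull(1500, 0.6, 40)
  fit <- fit_weibull(x)
  sr <- survival::survreg(survival::Surv(x) ~ 1, dist = "weibull")
  expect_equal(fit$beta, 1 / sr$scale, tolerance = 1e-3)
  expect_equal(fit$alpha, unname(exp(coef(sr))), tolerance = 1e-3)
})

test_that("degenerate and tiny samples are rejected or flagged", {
  expect_error(fit_weibull(rep(5, 50)), "degenerate")
  expect_error(fit_weibull(numeric(0)), "degenerate")
  expect_warning(fit_weibull(c(1, 2, 3, 4, 10)), "unstable")
})

test_that("scale and shape are recovered across seeded replicates", {
  set.seed(88)
  rel_err <- t(sapply(1:20, function(i) {
    x <- rweibull(2000, 0.55, 38.56)
    f <- fit_weibull(x)
    c(alpha = abs(f$alpha - 38.56) / 38.56,
      beta = abs(f$beta - 0.55) / 0.55)
  }))
  expect_lt(median(rel_err[, "alpha"]), 0.10)
  expect_lt(median(rel_err[, "beta"]), 0.10)
})

test_that("failure type follows the shape parameter's confidence interval", {
  mk <- function(ci) structure(list(beta_ci = ci), class = "weibull_fit")
  expect_equal(classify_failure(mk(c(0.53, 0.57))), "early")
  expect_equal(classify_failure(mk(c(0.9, 1.1))), "random")
  expect_equal(classify_failure(mk(c(1.2, 1.6))), "wear-out")
})

test_that("end-to-end onset lags reproduce the generating Weibull on synthetic data", {
  cfg <- synthetic_config(n_reports = 8000, seed = 404,
                          p_missing_event_date = 0.3, p_invalid_date = 0.02,
                          p_duplicate_case = 0)
  parts <- synth_assembled(cfg)
  target <- identify_drug_reports(parts$assembled, etoposide_query())
  tto <- compute_tto(target, etoposide_query())
  expect_gt(length(tto$values), 200)
  fit <- fit_weibull(tto)
  expect_gt(fit$beta, 0.45)
  expect_lt(fit$beta, 0.65)
  expect_equal(classify_failure(fit), "early")
  expect_equal(length(tto$values) + tto$n_excluded_missing +
                 tto$n_excluded_invalid + tto$n_excluded_negative,
               nrow(target$demo))
})
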