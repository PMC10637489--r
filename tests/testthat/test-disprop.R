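test_that("the 2x2 construction partitions the pair database", {
  all_pairs <- tibble::tibble(
    primaryid = c("1", "1", "2", "2"),
    pt = c("PT1", "PT2", "PT1", "PT2")
  )
  target_pairs <- all_pairs[all_pairs$primaryid == "1", ]
  tab <- build_contingency(all_pairs, target_pairs, "PT1")
  expect_equal(unlist(tab), c(a = 1, b = 1, c = 1, d = 1))

  # event absent everywhere and absent from the target drug
  none <- build_contingency(all_pairs, target_pairs, "PT99")
  expect_equal(none$a, 0)
  expect_equal(none$c, 0)
  only_other <- build_contingency(
    dplyr::bind_rows(all_pairs, tibble::tibble(primaryid = "3", pt = "PT3")),
    target_pairs, "PT3"
  )
  expect_equal(only_other$a, 0)
  expect_equal(only_other$b, nrow(target_pairs))
})

test_that("vectorized contingency counts agree with per-event brute force on synthetic data", {
  parts <- synth_assembled(synthetic_config(n_reports = 600, seed = 19))
  asm <- parts$assembled
  target <- identify_drug_reports(asm, etoposide_query())
  all_pairs <- extract_case_pairs(asm)
  target_pairs <- extract_case_pairs(target)

  counts <- contingency_counts(all_pairs, target_pairs)
  expect_true(all(counts$a + counts$b + counts$c + counts$d ==
                    nrow(all_pairs)))
  expect_true(all(counts$a + counts$b == nrow(target_pairs)))
  for (ev in sample(counts$term, 10)) {
    want <- build_contingency(all_pairs, target_pairs, ev)
    got <- counts[counts$term == ev, c("a", "b", "c", "d")]
    expect_equal(unlist(got), unlist(want), ignore_attr = TRUE)
  }
})

test_that("the four estimators reproduce direct arithmetic on a reference table", {
  st <- compute_signal_stats(10, 90, 100, 9800)
  # independent arithmetic, written out from first principles
  a <- 10; b <- 90; c <- 100; d <- 9800; n <- a + b + c + d
  s <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  expect_equal(st$ror, (a * d) / (b * c))
  expect_equal(st$ror_lo, exp(log(a * d / (b * c)) - 1.96 * s))
  expect_equal(st$ror_hi, exp(log(a * d / (b * c)) + 1.96 * s))
  expect_equal(st$prr, a * (c + d) / (c * (a + b)))
  expect_equal(st$chi2, (a * d - b * c)^2 * n /
                 ((a + b) * (c + d) * (a + c) * (b + d)))
  expect_equal(st$ebgm, a * n / ((a + c) * (a + b)))
  expect_equal(st$ic, log2(a * n / ((a + c) * (a + b))))

  # frozen reference values
  expect_equal(round(st$ror, 3), 10.889)
  expect_equal(round(st$ror_lo, 3), 5.503)
  expect_equal(round(st$ror_hi, 3), 21.545)
  expect_equal(st$prr, 9.9)
  expect_equal(round(st$chi2, 2), 73.55)
  expect_equal(round(st$ic, 3), 3.184)
  expect_equal(round(st$ebgm, 3), 9.091)
  expect_equal(round(st$ebgm05, 3), 4.595)
})

test_that("a null table yields unit estimators and zero chi-squared", {
  st <- compute_signal_stats(5, 5, 5, 5)
  expect_equal(st$ror, 1)
  expect_equal(st$prr, 1)
  expect_equal(st$chi2, 0)
  expect_equal(st$ic, 0)
  expect_equal(st$ebgm, 1)
})

test_that("algebraic identities hold across random tables", {
  set.seed(99)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    st <- compute_signal_stats(cells[1], cells[2], cells[3], cells[4])
    expect_equal(2^st$ic, st$ebgm, tolerance = 1e-12)
    expect_lte(st$ror_lo, st$ror)
    expect_lte(st$ebgm05, st$ebgm)
  }
  # ad = bc implies all four estimators are exactly 1
  st <- compute_signal_stats(6, 30, 20, 100)
  expect_equal(c(st$ror, st$prr, st$ebgm, 2^st$ic), rep(1, 4))
})

test_that("PRR is determined by a, b, and the ROR alone when d is chosen to fix the ROR", {
  set.seed(7)
  a <- 874; b <- 29723 - 874; ror <- 30.34
  expected_prr <- (a + ror * b) / (a + b)
  for (c_cell in sample(50:50000, 12)) {
    d <- ror * b * c_cell / a
    st <- compute_signal_stats(a, b, c_cell, d)
    expect_equal(st$ror, ror, tolerance = 1e-12)
    expect_equal(st$prr, expected_prr, tolerance = 1e-10)
  }
})

test_that("estimators increase strictly in a with the other cells fixed", {
  prev <- compute_signal_stats(1, 200, 300, 10000)
  for (a in c(5, 20, 80, 320)) {
    cur <- compute_signal_stats(a, 200, 300, 10000)
    expect_gt(cur$ror, prev$ror)
    expect_gt(cur$prr, prev$prr)
    expect_gt(cur$ic, prev$ic)
    expect_gt(cur$ebgm, prev$ebgm)
    prev <- cur
  }
})

test_that("zero cells yield undefined sentinels unless the Haldane correction is requested", {
  st <- compute_signal_stats(0, 100, 50, 9000)
  expect_true(all(is.na(c(st$ror, st$ror_lo, st$prr, st$chi2, st$ic,
                          st$ebgm, st$ebgm05))))
  sth <- compute_signal_stats(0, 100, 50, 9000, haldane = TRUE)
  expect_true(all(is.finite(c(sth$ror, sth$prr, sth$ebgm))))
  fl <- apply_criteria(st)
  expect_false(any(fl$ror_pos, fl$prr_pos, fl$bcpnn_pos, fl$mgps_pos))
})

test_that("positivity criteria implement the four thresholds and the minimum case rule", {
  fl <- apply_criteria(compute_signal_stats(10, 90, 100, 9800))
  expect_true(fl$prr_pos) # PRR 9.9 >= 2, chi2 73.55 >= 4, a >= 3
  expect_true(fl$mgps_pos) # EBGM05 4.595 > 2
  expect_true(fl$ror_pos)
  expect_true(fl$all_four)

  # strong ratios but only 2 cases: frequency-based flags off
  fl2 <- apply_criteria(compute_signal_stats(2, 10, 5, 5000))
  expect_false(fl2$ror_pos)
  expect_false(fl2$prr_pos)

  fl3 <- apply_criteria(compute_signal_stats(5, 5, 5, 5))
  expect_false(any(fl3$ror_pos, fl3$prr_pos, fl3$bcpnn_pos, fl3$mgps_pos))

  # a result failing a single algorithm is not retained
  stats <- dplyr::bind_rows(
    compute_signal_stats(10, 90, 100, 9800),
    compute_signal_stats(40, 60, 3000, 7000) # elevated but EBGM05 <= 2
  )
  stats$term <- c("keep", "drop")
  flagged <- apply_criteria(stats)
  expect_false(flagged$all_four[2])
  kept <- suppressMessages(screen_signals(flagged))
  expect_equal(kept$term, "keep")
  expect_equal(nrow(suppressMessages(screen_signals(flagged[0, ]))), 0)
})

test_that("ranking keeps a > min_a and orders by EBGM05, case count, then term", {
  sig <- tibble::tibble(
    term = c("p1", "p2", "p3", "p4", "p5"),
    a = c(31L, 30L, 120L, 120L, 45L),
    ebgm05 = c(4.2, 7.1, 5.0, 5.0, 5.0)
  )
  out <- rank_and_filter(sig, min_a = 30)
  expect_false("p2" %in% out$term) # a = 30 fails the strict threshold
  expect_equal(out$ebgm05, sort(out$ebgm05, decreasing = TRUE))
  # among the 5.0 ties, larger a first, then alphabetical term
  expect_equal(out$term, c("p3", "p4", "p5", "p1"))
})

test_that("SOC-level tables aggregate PT records within each organ class", {
  # toy database in which every PT belongs to one SOC
  all_pairs <- tibble::tibble(
    primaryid = c("1", "1", "2", "3", "3", "4"),
    pt = c("PT1", "PT2", "PT1", "PT1", "PT3", "PT2")
  )
  map <- tibble::tibble(pt = c("PT1", "PT2", "PT3"), soc = "SOC-A")
  target_pairs <- all_pairs[all_pairs$primaryid %in% c("1", "2"), ]
  soc <- soc_level_signals(
    suppressMessages(map_pt_to_soc(all_pairs, map)),
    suppressMessages(map_pt_to_soc(target_pairs, map))
  )
  pt_counts <- contingency_counts(all_pairs, target_pairs)
  expect_equal(soc$a, sum(pt_counts$a))
  expect_equal(soc$a + soc$b, nrow(target_pairs))

  # a SOC absent from the target drug: a = 0, no flags
  map2 <- tibble::tibble(pt = c("PT1", "PT2", "PT3"),
                         soc = c("SOC-A", "SOC-A", "SOC-B"))
  soc2 <- soc_level_signals(
    suppressMessages(map_pt_to_soc(all_pairs, map2)),
    suppressMessages(map_pt_to_soc(target_pairs[0, ], map2))
  )
  expect_equal(nrow(soc2), 0)
})

test_that("novelty flags mark PTs absent from the label list", {
  sig <- tibble::tibble(term = c("Thrombocytopenia", "Ovarian failure"))
  out <- flag_unexpected(sig, c("THROMBOCYTOPENIA", "Nausea"))
  expect_equal(out$unexpected, c(FALSE, TRUE))
  all_new <- flag_unexpected(sig, character(0))
  expect_true(all(all_new$unexpected))
})

test_that("null data rarely passes the four-way screen (false-positive calibration)", {
  cfg <- synthetic_config(
    n_reports = 20000, seed = 555,
    planted_signals = default_planted_signals()[0, ],
    p_duplicate_case = 0, p_missing_event_date = 1
  )
  parts <- synth_assembled(cfg)
  asm <- parts$assembled
  all_pairs <- extract_case_pairs(asm)

  n_pairs <- 0L
  n_all_four <- 0L
  n_ror <- 0L
  for (k in seq_len(nrow(cfg$drug_catalog))) {
    q <- drug_query(c(cfg$drug_catalog$name[k], cfg$drug_catalog$prod_ai[k],
                      cfg$drug_catalog$synonyms[[k]]),
                    roles = c("PS", "SS", "C", "I"))
    target <- identify_drug_reports(asm, q)
    st <- apply_criteria(signal_stats(
      contingency_counts(all_pairs, extract_case_pairs(target))
    ))
    n_pairs <- n_pairs + nrow(st)
    n_all_four <- n_all_four + sum(st$all_four)
    n_ror <- n_ror + sum(st$ror_pos)
  }
  expect_gte(n_pairs, 200)
  expect_lte(n_all_four / n_pairs, 0.05)
  expect_lte(n_ror / n_pairs, 0.10)
})
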