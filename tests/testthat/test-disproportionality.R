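test_that("2x2 construction counts reports once regardless of event multiplicity", {
  uni <- as.character(1:4)
  tab <- build_table(uni, target_ids = c("1", "2"), event_ids = c("1", "3"))
  expect_equal(unclass(tab)[c("a", "b", "c", "d")], list(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_error(build_table(character(), "1", "1"), "empty")

  tab0 <- build_table(uni, target_ids = c("1", "2"), event_ids = character())
  expect_equal(tab0$a, 0L)
  expect_equal(tab0$c, 0L)
})

test_that("ROR point estimate and CI follow the log-Wald formula", {
  res <- ror_with_ci(contingency_table(10, 90, 100, 9900))
  expect_equal(res$ror, 11.0, tolerance = 1e-12)
  expect_equal(res$ci_low, exp(log(11) - 1.959964 * sqrt(0.1 + 1 / 90 + 0.01 + 1 / 9900)),
    tolerance = 1e-12
  )
  expect_equal(res$ci_low, 5.56, tolerance = 2e-3)
  expect_equal(res$ci_high, 21.77, tolerance = 2e-3)

  sym <- ror_with_ci(contingency_table(1, 1, 1, 1))
  expect_equal(sym$ror, 1)
  expect_lt(sym$ci_low, 1)
  expect_gt(sym$ci_high, 1)

  expect_equal(ror_with_ci(contingency_table(5, 995, 5, 995))$ror, 1)

  # zero cell: absent by default, Haldane-Anscombe on request
  z <- ror_with_ci(contingency_table(0, 10, 5, 100))
  expect_true(is.na(z$ror))
  zc <- ror_with_ci(contingency_table(0, 10, 5, 100), correction = TRUE)
  expect_equal(zc$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("ROR engine agrees with an independent logistic-regression oracle", {
  set.seed(101)
  for (i in 1:200) {
    cells <- as.integer(sample(1:400, 4, replace = TRUE))
    mine <- ror_with_ci(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    oracle <- glm_or_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(mine$ror, unname(oracle["or"]), tolerance = 1e-9)
    expect_equal(mine$ci_low, unname(oracle["low"]), tolerance = 1e-9)
    expect_equal(mine$ci_high, unname(oracle["high"]), tolerance = 1e-9)
  }
})

test_that("ROR invariances: reciprocity under axis swap, CI shrinks with scale", {
  r1 <- ror_with_ci(contingency_table(12, 40, 7, 300))
  r2 <- ror_with_ci(contingency_table(40, 12, 300, 7))
  expect_equal(r1$ror, 1 / r2$ror, tolerance = 1e-12)
  expect_equal(r1$ci_low, 1 / r2$ci_high, tolerance = 1e-12)

  w1 <- log(r1$ci_high) - log(r1$ci_low)
  r4 <- ror_with_ci(contingency_table(48, 160, 28, 1200))
  expect_lt(log(r4$ci_high) - log(r4$ci_low), w1)
})

test_that("signal detection applies the CI>1 and n>=5 rule and sorts output", {
  # planted strong association at moderate n -> must flag
  sim <- simulate_faers(sim_config(n_reports = 6000L, seed = 31L))
  uni <- suppressWarnings(annotate_soc(
    deduplicate(sim$reports), synthetic_meddra_map()
  ))
  spec <- cohort_spec("QUETIAPINE", "SEROQUEL")
  sig <- detect_signals(uni, spec)
  tach <- sig[sig$term == "Tachycardia", ]
  expect_true(tach$significant)
  expect_gte(tach$n, 5)
  expect_gt(tach$ci_low, 1)
  # planted odds ratio inside the interval
  expect_true(tach$ci_low < 11 && 11 < tach$ci_high)
  # sorted by case count descending
  expect_true(all(diff(sig$n) <= 0))

  # significance boundary: 4 cases cannot be significant however large the ROR
  demo <- tibble::tibble(primaryid = as.character(1:2000))
  names_vec <- c(rep("QUETIAPINE", 40), rep("OTHER", 1960))
  drugs <- tibble::tibble(
    primaryid = demo$primaryid, drug_seq = "1",
    drugname = names_vec, prod_ai = names_vec,
    role_cod = "PS", start_dt = "", indi_pt = NA_character_
  )
  reacs <- tibble::tibble(
    primaryid = c(as.character(1:4), as.character(41:42)),
    pt = "Tachycardia"
  )
  uni2 <- suppressWarnings(annotate_soc(
    make_reports(demo, drugs = drugs, reacs = reacs), synthetic_meddra_map()
  ))
  sig2 <- detect_signals(uni2, cohort_spec("QUETIAPINE"))
  expect_equal(sig2$n, 4L)
  expect_gt(sig2$ci_low, 1)
  expect_false(sig2$significant)
})

test_that("SOC-level signal equals the PT-level signal for a single-PT SOC", {
  demo <- tibble::tibble(primaryid = as.character(1:400))
  drugs <- tibble::tibble(
    primaryid = demo$primaryid, drug_seq = "1",
    drugname = c(rep("QUETIAPINE", 100), rep("OTHER", 300)),
    prod_ai = c(rep("QUETIAPINE", 100), rep("OTHER", 300)),
    role_cod = "PS", start_dt = "", indi_pt = NA_character_
  )
  # Insomnia is the only PT mapped to Psychiatric disorders in the map
  reacs <- tibble::tibble(
    primaryid = as.character(c(1:20, 101:120)), pt = "Insomnia"
  )
  uni <- suppressWarnings(annotate_soc(
    make_reports(demo, drugs = drugs, reacs = reacs), synthetic_meddra_map()
  ))
  spec <- cohort_spec("QUETIAPINE", soc_of_interest = "Psychiatric disorders")
  pt_sig <- detect_signals(uni, spec)
  soc_sig <- soc_level_signal(uni, spec)
  expect_equal(soc_sig$ror, pt_sig$ror)
  expect_equal(soc_sig$ci_low, pt_sig$ci_low)
  expect_equal(soc_sig[, c("a", "b", "c", "d")], pt_sig[, c("a", "b", "c", "d")])
})

test_that("subgroups restrict both cases and non-cases before the 2x2", {
  n <- 3000L
  demo <- tibble::tibble(
    primaryid = as.character(1:n),
    sex = rep(c("female", "male", NA), length.out = n)
  )
  target <- as.character(1:300)
  drugs <- tibble::tibble(
    primaryid = demo$primaryid, drug_seq = "1",
    drugname = ifelse(demo$primaryid %in% target, "QUETIAPINE", "OTHER"),
    prod_ai = ifelse(demo$primaryid %in% target, "QUETIAPINE", "OTHER"),
    role_cod = "PS", start_dt = "", indi_pt = NA_character_
  )
  # enrich cardiac events among female target reports only
  set.seed(9)
  fem_target <- demo$primaryid[demo$primaryid %in% target & demo$sex %in% "female"]
  enriched <- sample(fem_target, floor(0.5 * length(fem_target)))
  others <- setdiff(demo$primaryid, fem_target)
  reacs <- tibble::tibble(
    primaryid = c(enriched, sample(others, 150)),
    pt = "Tachycardia"
  )
  uni <- suppressWarnings(annotate_soc(
    make_reports(demo, drugs = drugs, reacs = reacs), synthetic_meddra_map()
  ))
  spec <- cohort_spec("QUETIAPINE")
  sub <- subgroup_signals(uni, spec, strata = "sex")
  fem <- sub[sub$stratum == "female", ]
  mal <- sub[sub$stratum == "male", ]
  expect_gt(fem$ror, mal$ror)
  expect_true(is.na(mal$ror) || mal$ci_low <= 1 || !mal$significant)
  # stratum sizes exclude missing-sex reports
  expect_equal(fem$a + fem$b + fem$c + fem$d, sum(demo$sex %in% "female"))
})

test_that("sensitivity exclusion removes exactly the flagged case reports", {
  sim <- simulate_faers(sim_config(n_reports = 4000L, seed = 51L))
  uni <- suppressWarnings(annotate_soc(
    deduplicate(sim$reports), synthetic_meddra_map()
  ))
  spec <- cohort_spec("QUETIAPINE", "SEROQUEL")
  res <- sensitivity_exclude(uni, spec,
    excluded_drugs = c("ARIPIPRAZOLE", "RISPERIDONE", "OLANZAPINE")
  )
  # count flagged case reports independently
  cases <- restrict_to_soc(match_target_reports(uni, spec), "Cardiac disorders")
  con <- cases$case_reports$drugs
  flagged <- unique(con$primaryid[
    con$role_cod %in% c("SS", "C", "I") &
      con$drugname %in% c("ARIPIPRAZOLE", "RISPERIDONE", "OLANZAPINE")
  ])
  expect_equal(res$n_removed, length(flagged))
  expect_equal(res$n_cases_before - res$n_cases_after, length(flagged))

  # excluding a drug no case report carries changes nothing
  res2 <- sensitivity_exclude(uni, spec, excluded_drugs = "NOSUCHDRUG")
  base <- detect_signals(uni, spec)
  expect_equal(res2$signals, base)
  expect_equal(res2$n_removed, 0L)
})

test_that("concomitant ranking counts report-level mentions with stable ties", {
  demo <- tibble::tibble(primaryid = as.character(1:3))
  dn <- c("QUETIAPINE", "LORAZEPAM", "LORAZEPAM", "QUETIAPINE", "ASPIRIN", "QUETIAPINE")
  drugs <- tibble::tibble(
    primaryid = c("1", "1", "1", "2", "2", "3"),
    drug_seq = c("1", "2", "3", "1", "2", "1"),
    drugname = dn, prod_ai = dn,
    role_cod = c("PS", "C", "SS", "PS", "C", "PS"),
    start_dt = "", indi_pt = NA_character_
  )
  rank <- concomitant_ranking(make_reports(demo, drugs = drugs))
  # LORAZEPAM twice on one report counts once; tie with ASPIRIN breaks alphabetically
  expect_equal(rank$n, c(1L, 1L))
  expect_equal(rank$drug, c("ASPIRIN", "LORAZEPAM"))
  expect_equal(rank$percent, c(100 / 3, 100 / 3))
})

test_that("null tables keep the false-positive rate at the nominal level", {
  set.seed(77)
  n_sim <- 400L
  n_per <- 2000L
  p_drug <- 0.1
  p_event <- 0.05
  hits <- 0L
  for (i in seq_len(n_sim)) {
    drug <- runif(n_per) < p_drug
    event <- runif(n_per) < p_event
    tab <- contingency_table(
      sum(drug & event), sum(drug & !event),
      sum(!drug & event), sum(!drug & !event)
    )
    est <- ror_with_ci(tab)
    if (!is.na(est$ci_low) && est$ci_low > 1) hits <- hits + 1L
  }
  rate <- hits / n_sim
  expect_lte(rate, 0.05 + 2 * sqrt(0.025 * 0.975 / n_sim))
})
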