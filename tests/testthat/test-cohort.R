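toy_universe <- function() {
  demo <- tibble::tibble(primaryid = as.character(1:6))
  drugs <- tibble::tibble(
    primaryid = as.character(c(1, 2, 3, 4, 5, 6, 6)),
    drug_seq = c("1", "1", "1", "1", "1", "1", "2"),
    drugname = c(
      "QUETIAPINE FUMARATE 100MG", "SEROQUEL", "SEROQUEL", "LORAZEPAM",
      "IBUPROFEN", "LORAZEPAM", "QUETIAPINE"
    ),
    prod_ai = c(
      "QUETIAPINE FUMARATE", "QUETIAPINE FUMARATE", "QUETIAPINE FUMARATE",
      "LORAZEPAM", "IBUPROFEN", "LORAZEPAM", "QUETIAPINE"
    ),
    role_cod = c("PS", "PS", "C", "PS", "PS", "PS", "C"),
    start_dt = "", indi_pt = NA_character_
  )
  reacs <- tibble::tibble(
    primaryid = as.character(c(1, 1, 2, 3, 4, 5, 6)),
    pt = c(
      "Tachycardia", "Dizziness", "Nausea", "Tachycardia", "Tachycardia",
      "Nausea", "Dizziness"
    )
  )
  make_reports(demo, drugs = drugs, reacs = reacs)
}

test_that("target matching honours names, columns and role filter", {
  uni <- toy_universe()
  spec <- cohort_spec("QUETIAPINE", "SEROQUEL")
  matched <- match_target_reports(uni, spec)
  # 1: generic substring + PS; 2: trade + PS; 3: trade but role C -> out;
  # 6: generic but role C -> out
  expect_setequal(matched$demo$primaryid, c("1", "2"))

  # widening the role filter brings the concomitant mentions in
  spec_all <- cohort_spec("QUETIAPINE", "SEROQUEL", role_filter = c("PS", "SS", "C", "I"))
  expect_setequal(
    match_target_reports(uni, spec_all)$demo$primaryid, c("1", "2", "3", "6")
  )

  # whole-word: QUETIAPINE must not match inside another token
  uni2 <- toy_universe()
  uni2$drugs$drugname[1] <- "NOTQUETIAPINEX"
  uni2$drugs$prod_ai[1] <- "SOMETHING ELSE"
  expect_setequal(
    match_target_reports(uni2, spec)$demo$primaryid, "2"
  )
})

test_that("SOC annotation is case-insensitive, multi-SOC and logs unmapped PTs", {
  uni <- toy_universe()
  uni$reacs$pt[1] <- "TACHYCARDIA  " # case + whitespace robustness
  uni$reacs$pt[5] <- "Completely novel event"
  expect_warning(ann <- annotate_soc(uni, synthetic_meddra_map()), "novel")
  expect_equal(attr(ann, "unmapped_pts"), "Completely novel event")

  # Dizziness maps to two SOCs -> two annotation rows
  dz <- ann$reac_soc[ann$reac_soc$primaryid == "6", ]
  expect_setequal(dz$soc, c("Cardiac disorders", "Nervous system disorders"))
  # normalized lookup still lands
  expect_true(any(ann$reac_soc$primaryid == "1" & ann$reac_soc$soc == "Cardiac disorders"))
})

test_that("SOC restriction separates case reports from case events", {
  uni <- suppressWarnings(annotate_soc(toy_universe(), synthetic_meddra_map()))
  res <- restrict_to_soc(uni, "Cardiac disorders")
  # report 1 has two cardiac PTs: counts once as report, twice as events
  expect_equal(sum(res$case_events$primaryid == "1"), 2L)
  expect_setequal(res$case_reports$demo$primaryid, c("1", "3", "4", "6"))
  expect_gte(nrow(res$case_events), n_reports(res$case_reports))
  # report 5 (Nausea only) excluded
  expect_false("5" %in% res$case_reports$demo$primaryid)
})

test_that("summary bands use inclusive 18-65 and 80-100 bounds", {
  demo <- tibble::tibble(
    primaryid = as.character(1:8),
    age_years = c(17.9, 18, 65, 65.1, NA, 30, 70, 2),
    weight_kg = c(79.9, 80, 100, 100.1, NA, 90, 50, 120)
  )
  s <- summarize_cohort(make_reports(demo))
  expect_equal(s$age$bands$n, c(2L, 3L, 2L)) # 18 and 65 fall inside the band
  expect_equal(s$weight$bands$n, c(2L, 3L, 2L)) # as do 80 and 100
  # band counts sum to available-value count and percents to 100
  expect_equal(sum(s$age$bands$n), 7L)
  expect_equal(sum(s$age$bands$percent), 100)
})

test_that("summary marginals recover the generator's demography", {
  sim <- simulate_faers(sim_config(n_reports = 4000L, seed = 21L))
  s <- summarize_cohort(sim$expected)
  n_sex <- sum(s$sex$n)
  p_female <- s$sex$n[s$sex$group == "female"] / n_sex
  expect_lt(abs(p_female - 0.55), 4 * sqrt(0.55 * 0.45 / n_sex))

  serious_pct <- s$outcomes$percent[s$outcomes$group == "Serious outcome"]
  implied <- 100 * sim$truth$implied_serious_rate
  expect_lt(abs(serious_pct - implied), 3)

  # percentages sit on available-value denominators
  expect_equal(sum(s$sex$percent), 100)
  expect_equal(sum(s$reporters$percent), 100)
})

test_that("empty-variable cohorts emit absent summaries, not numbers", {
  demo <- tibble::tibble(
    primaryid = "1", sex = NA_character_,
    age_years = NA_real_, weight_kg = NA_real_
  )
  s <- summarize_cohort(make_reports(demo))
  expect_equal(s$age$summary$n, 0L)
  expect_true(is.na(s$age$summary$median))
  expect_true(all(is.na(s$sex$percent)))
})
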