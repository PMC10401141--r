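test_that("seriousness is any-of-seven-codes, with unknown codes warned away", {
  demo <- tibble::tibble(primaryid = as.character(1:3))
  outc <- tibble::tibble(
    primaryid = c("1", "1", "3"),
    outc_cod = c("HO", "OT", "ZZ")
  )
  rep <- make_reports(demo, outcomes = outc)
  expect_warning(lab <- classify_seriousness(rep), "ZZ")
  expect_equal(lab$serious, c(TRUE, FALSE, FALSE))
  expect_equal(lab$categories[[1]], c("HO", "OT"))
  expect_equal(lab$categories[[2]], character())
})

test_that("planted outcome probabilities reproduce the serious fraction", {
  sim <- simulate_faers(sim_config(n_reports = 5000L, seed = 61L))
  lab <- classify_seriousness(sim$expected)
  p <- sim$truth$implied_serious_rate
  n <- nrow(lab)
  expect_lt(abs(mean(lab$serious) - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("uncorrected Pearson statistic matches hand-computed values", {
  m <- rbind(c(161, 44), c(706, 93))
  res <- pearson_chi2(m)
  # independent arithmetic: sum((O-E)^2/E) over the four cells
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$statistic, sum((m - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$p, pchisq(res$statistic, df = 1, lower.tail = FALSE))

  expect_equal(pearson_chi2(rbind(c(10, 20), c(10, 20)))$statistic, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 7))), "marginal")

  # transposition and row/column swaps leave the statistic unchanged
  expect_equal(pearson_chi2(t(m))$statistic, res$statistic)
  expect_equal(pearson_chi2(m[2:1, ])$statistic, res$statistic)
  expect_equal(pearson_chi2(m[, 2:1])$statistic, res$statistic)
})

test_that("Fisher p equals exhaustive enumeration for random small tables", {
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5))), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(3, 3), c(3, 3))), 1)

  set.seed(202)
  for (i in 1:250) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    m <- matrix(cells, 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m), fisher_enum_oracle(m), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U matches brute-force pair counting on all small splits", {
  # exhaustive over all splits of fixed pooled samples (with ties), n <= 8
  pools <- list(
    c(1, 2, 3, 4, 5, 6, 7, 8),
    c(1, 1, 2, 2, 3, 3, 4, 4),
    c(0, 0, 0, 1, 1, 2, 5, 5)
  )
  for (pool in pools) {
    for (n1 in 2:6) {
      idx <- utils::combn(length(pool), n1)
      for (k in seq_len(ncol(idx))) {
        a <- pool[idx[, k]]
        b <- pool[-idx[, k]]
        got <- mann_whitney(a, b)
        expect_equal(got$u, mw_u_oracle(a, b), tolerance = 1e-12)
      }
    }
  }
})

test_that("Mann-Whitney Z agrees with wilcox.test and the permutation oracle", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  got <- mann_whitney(a, b)
  expect_equal(got$u, 0)
  expect_lt(got$z, 0) # a ranks lower
  # direction and extremity consistent with the exact permutation p
  expect_equal(mw_perm_p_oracle(a, b), 2 / 20, tolerance = 1e-12)

  set.seed(303)
  for (i in 1:50) {
    x <- round(rnorm(12, 50, 10))
    y <- round(rnorm(15, 55, 10))
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    )
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(abs(got$u - length(x) * length(y) / 2),
      abs(unname(ref$statistic) - length(x) * length(y) / 2),
      tolerance = 1e-9
    )
  }

  tied <- mann_whitney(c(2, 2, 2), c(2, 2))
  expect_equal(tied$z, 0)
  expect_equal(tied$p, 1)
})

test_that("Mann-Whitney p is uniform under the null", {
  set.seed(404)
  ps <- replicate(400, {
    mann_whitney(rnorm(30), rnorm(30))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("test selection switches to Fisher when an expected cell drops below 5", {
  # bradycardia-style margins: expected nonserious cell 35*137/1004 = 4.78
  m_fisher <- rbind(c(31, 4), c(836, 133))
  expect_equal(select_prop_test(m_fisher), "fisher_exact")
  # arrhythmia-style margins: smallest expected cell 37*137/1004 = 5.05
  m_chi2 <- rbind(c(34, 3), c(833, 134))
  expect_equal(select_prop_test(m_chi2), "pearson_chi2")
})

test_that("serious/nonserious comparison reproduces known sex and PT statistics", {
  # cohort engineered to the published margins: 867 serious, 137 nonserious;
  # 503/72 female, 300/54 male; dizziness on 161 serious + 44 nonserious
  n <- 1004
  serious <- c(rep(TRUE, 867), rep(FALSE, 137))
  sex <- rep(NA_character_, n)
  sex[1:503] <- "female"
  sex[504:803] <- "male"
  sex[868:939] <- "female"
  sex[940:993] <- "male"
  demo <- tibble::tibble(
    primaryid = as.character(1:n), sex = sex,
    age_years = NA_real_, weight_kg = NA_real_
  )
  outc <- tibble::tibble(primaryid = as.character(1:867), outc_cod = "HO")
  reacs <- tibble::tibble(
    primaryid = as.character(c(1:161, 868:911)), pt = "Dizziness"
  )
  rep <- make_reports(demo, reacs = reacs, outcomes = outc)
  cmp <- compare_serious_nonserious(rep, signal_pts = "Dizziness")

  sex_row <- cmp[cmp$variable == "sex", ]
  expect_equal(sex_row$test_used, "pearson_chi2")
  expect_equal(sex_row$statistic, 1.395, tolerance = 5e-4)

  dz <- cmp[cmp$variable == "Dizziness", ]
  expect_equal(dz$test_used, "pearson_chi2")
  expect_equal(dz$statistic, 13.362, tolerance = 5e-4)
  expect_lt(dz$p_value, 0.001)
})

test_that("comparisons with an empty group are omitted rather than fabricated", {
  demo <- tibble::tibble(
    primaryid = as.character(1:4), sex = c("female", "male", "female", "male"),
    age_years = c(40, 50, 60, 70), weight_kg = NA_real_
  )
  outc <- tibble::tibble(primaryid = as.character(1:4), outc_cod = "HO")
  cmp <- compare_serious_nonserious(make_reports(demo, outcomes = outc))
  expect_equal(nrow(cmp), 0L) # all serious: nothing to compare
})
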