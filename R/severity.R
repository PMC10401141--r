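.serious_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Classify report seriousness from outcome codes
#'
#' A report is serious iff it carries at least one of the seven serious
#' outcome codes (DE death, LT life-threatening, HO hospitalization, DS
#' disability, CA congenital anomaly, RI required intervention, OT other
#' serious). Unknown codes are ignored with a warning.
#'
#' @param reports a [faers_reports].
#' @return tibble with one row per report: `primaryid`, `serious`,
#'   `categories` (list column of codes present).
#' @export
classify_seriousness <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  outc <- reports$outcomes
  unknown <- setdiff(unique(outc$outc_cod), .serious_codes)
  if (length(unknown)) {
    warning("ignoring unknown outcome code(s): ", paste(unknown, collapse = ", "))
    outc <- dplyr::filter(outc, .data$outc_cod %in% .serious_codes)
  }
  per_report <- outc |>
    dplyr::distinct(.data$primaryid, .data$outc_cod) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(categories = list(sort(.data$outc_cod)), .groups = "drop")
  out <- tibble::tibble(primaryid = reports$demo$primaryid)
  out$categories <- per_report$categories[match(out$primaryid, per_report$primaryid)]
  none <- vapply(out$categories, is.null, logical(1))
  out$categories[none] <- list(character())
  out$serious <- !none
  out[, c("primaryid", "serious", "categories")]
}

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2x2 table of counts")
  storage.mode(m) <- "double"
  m
}

#' Pearson chi-squared test without continuity correction
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` on a 2x2 count
#' table, with the p-value from the chi-squared distribution on 1 df.
#' No Yates correction is applied anywhere in this package: the corrected
#' statistic is a different quantity and the serious/nonserious comparison
#' convention here is the plain Pearson statistic.
#'
#' @param table 2x2 matrix (or coercible) of counts.
#' @return list with `statistic` and `p`.
#' @export
pearson_chi2 <- function(table) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal in 2x2 table; chi-squared statistic undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities, over all
#' tables with the observed margins, of tables no more probable than the
#' observed one.
#'
#' @param table 2x2 matrix (or coercible) of counts.
#' @return the p-value.
#' @export
fisher_exact <- function(table) {
  m <- as_2x2(table)
  stats::fisher.test(m)$p.value
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' U is computed from midranks of the pooled sample; the Z statistic uses
#' the normal approximation with the tie-corrected variance and no
#' continuity correction; the p-value is two-sided. Z is signed so that a
#' negative value means group `a` tends to rank lower than group `b`. With
#' every value tied across both groups the test degenerates to Z = 0,
#' p = 1.
#'
#' @param a,b numeric samples (both nonempty).
#' @return list with `z`, `p`, and `u` (the U statistic of group `a`).
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(z = 0, p = 1, u = u))
  }
  z <- (u - mu) / sqrt(sigma2)
  list(z = z, p = 2 * pnorm(-abs(z)), u = u)
}

# Test-selection rule: Fisher's exact test when any expected cell count is
# below 5, else the uncorrected Pearson chi-squared test.
select_prop_test <- function(m) {
  m <- as_2x2(m)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) "fisher_exact" else "pearson_chi2"
}

prop_comparison <- function(variable, m) {
  test <- select_prop_test(m)
  if (test == "pearson_chi2") {
    res <- pearson_chi2(m)
    stat <- res$statistic
    p <- res$p
  } else {
    stat <- NA_real_
    p <- fisher_exact(m)
  }
  tibble::tibble(
    variable = variable, test_used = test,
    serious_n = m[1, 1], nonserious_n = m[1, 2],
    statistic = stat, p_value = p
  )
}

#' Compare serious versus nonserious case reports
#'
#' The risk-factor comparison panel for a case cohort: sex proportions,
#' age and weight distributions (Mann-Whitney U on the non-normal
#' continuous variables), and, for every signal PT, the serious/nonserious
#' split of reports carrying that PT against all other case reports.
#' Proportions use the uncorrected Pearson chi-squared test unless any
#' expected cell is below 5, in which case Fisher's exact test is used
#' (`test_used` records the choice; `statistic` is `NA` for Fisher and the
#' Z value for Mann-Whitney).
#'
#' @param case_reports a [faers_reports] of case reports.
#' @param signal_pts PTs (typically the significant signal list) to compare.
#' @return tibble with columns `variable`, `test_used`, `serious_n`,
#'   `nonserious_n`, `statistic`, `p_value`.
#' @export
compare_serious_nonserious <- function(case_reports, signal_pts = character()) {
  stopifnot(inherits(case_reports, "faers_reports"))
  ser <- classify_seriousness(case_reports)
  demo <- dplyr::left_join(
    case_reports$demo, ser[, c("primaryid", "serious")],
    by = "primaryid"
  )

  rows <- list()

  sex_m <- rbind(
    female = c(
      sum(demo$serious & demo$sex %in% "female"),
      sum(!demo$serious & demo$sex %in% "female")
    ),
    male = c(
      sum(demo$serious & demo$sex %in% "male"),
      sum(!demo$serious & demo$sex %in% "male")
    )
  )
  if (all(colSums(sex_m) > 0) && all(rowSums(sex_m) > 0)) {
    rows[["sex"]] <- prop_comparison("sex", sex_m)
  }

  for (v in c("age_years", "weight_kg")) {
    xs <- demo[[v]][demo$serious]
    ys <- demo[[v]][!demo$serious]
    xs <- xs[!is.na(xs)]
    ys <- ys[!is.na(ys)]
    if (length(xs) && length(ys)) {
      mw <- mann_whitney(xs, ys)
      rows[[v]] <- tibble::tibble(
        variable = v, test_used = "mann_whitney",
        serious_n = length(xs), nonserious_n = length(ys),
        statistic = mw$z, p_value = mw$p
      )
    }
  }

  if (length(signal_pts)) {
    reac <- dplyr::distinct(case_reports$reacs, .data$primaryid, .data$pt)
    serious_ids <- demo$primaryid[demo$serious]
    n_ser <- length(serious_ids)
    n_nonser <- nrow(demo) - n_ser
    for (pt in signal_pts) {
      ids <- unique(reac$primaryid[reac$pt == pt])
      s <- sum(ids %in% serious_ids)
      ns <- length(ids) - s
      m <- rbind(with_pt = c(s, ns), without_pt = c(n_ser - s, n_nonser - ns))
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
        rows[[pt]] <- prop_comparison(pt, m)
      }
    }
  }

  dplyr::bind_rows(rows)
}
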