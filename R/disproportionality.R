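#' Build the case/non-case 2x2 contingency table
#'
#' The case/non-case design cross-tabulates reports (the counting unit is
#' the deduplicated report, never the report-event pair) by two axes:
#' whether the report mentions the target drug and whether it mentions the
#' target event. Cell `a` counts target-drug reports with at least one
#' qualifying event; a report with several qualifying PTs still counts
#' once.
#'
#' @param universe_ids primaryids of every report in the analysis universe.
#' @param target_ids primaryids of target-drug reports.
#' @param event_ids primaryids of reports with the target event.
#' @return list of class `contingency_table` with integer cells
#'   `a`, `b`, `c`, `d`.
#' @export
build_table <- function(universe_ids, target_ids, event_ids) {
  if (!length(universe_ids)) stop("empty analysis universe")
  target_ids <- intersect(target_ids, universe_ids)
  event_ids <- intersect(event_ids, universe_ids)
  a <- length(intersect(target_ids, event_ids))
  b <- length(target_ids) - a
  c_ <- length(event_ids) - a
  d <- length(universe_ids) - a - b - c_
  contingency_table(a, b, c_, d)
}

#' @rdname build_table
#' @param a,b,c,d non-negative integer cell counts: `a` target drug with
#'   event, `b` target drug without, `c` other drugs with event, `d` other
#'   drugs without.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  structure(
    list(
      a = as.integer(cells[["a"]]), b = as.integer(cells[["b"]]),
      c = as.integer(cells[["c"]]), d = as.integer(cells[["d"]])
    ),
    class = "contingency_table"
  )
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' ROR = (a d)/(b c); the CI is computed on the log scale,
#' `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell the
#' estimate is returned as `NA` by default (a signal cannot reach the
#' five-report threshold with `a = 0`, and the Wald interval is undefined);
#' setting `correction = TRUE` applies the Haldane-Anscombe +0.5 to every
#' cell instead.
#'
#' @param table a `contingency_table` (or list with `a`, `b`, `c`, `d`).
#' @param z normal quantile for the interval (default two-sided 95%).
#' @param correction apply +0.5 continuity correction to zero-cell tables.
#' @return tibble with columns `ror`, `ci_low`, `ci_high`.
#' @export
ror_with_ci <- function(table, z = 1.959964, correction = FALSE) {
  a <- table$a
  b <- table$b
  c_ <- table$c
  d <- table$d
  if (min(a, b, c_, d) == 0) {
    if (!correction) {
      return(tibble::tibble(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    a <- a + 0.5
    b <- b + 0.5
    c_ <- c_ + 0.5
    d <- d + 0.5
  }
  log_ror <- log(a) + log(d) - log(b) - log(c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  tibble::tibble(
    ror = exp(log_ror),
    ci_low = exp(log_ror - z * se),
    ci_high = exp(log_ror + z * se)
  )
}

# deaths per PT among a set of case reports: number of reports carrying the
# PT that have outcome DE
death_counts <- function(reports, event_tab) {
  dead_ids <- unique(reports$outcomes$primaryid[reports$outcomes$outc_cod == "DE"])
  event_tab |>
    dplyr::group_by(.data$pt) |>
    dplyr::summarise(deaths = sum(unique(.data$primaryid) %in% dead_ids), .groups = "drop")
}

empty_signal_tbl <- function() {
  tibble::tibble(
    level = character(), term = character(),
    a = integer(), b = integer(), c = integer(), d = integer(),
    ror = numeric(), ci_low = numeric(), ci_high = numeric(),
    n = integer(), deaths = integer(), significant = logical()
  )
}

signal_row <- function(level, term, tab, deaths, min_cases, correction) {
  est <- ror_with_ci(tab, correction = correction)
  significant <- !is.na(est$ci_low) && est$ci_low > 1 && tab$a >= min_cases
  tibble::tibble(
    level = level, term = term,
    a = tab$a, b = tab$b, c = tab$c, d = tab$d,
    ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
    n = tab$a, deaths = deaths, significant = significant
  )
}

#' Detect PT-level disproportionality signals under one SOC
#'
#' For every PT mapped to `soc` that appears on at least one target-drug
#' report, builds the case/non-case table against the whole universe,
#' computes the ROR and its 95% CI, tallies deaths (reports with the PT and
#' outcome DE), and flags significance by the standard threshold: CI lower
#' bound above 1 with at least `min_cases` reports. Results are sorted by
#' case count descending, then PT name.
#'
#' @param universe SOC-annotated deduplicated [faers_reports]: the whole
#'   reporting universe (target and non-target reports).
#' @param spec a [cohort_spec()].
#' @param soc SOC name; defaults to the spec's `soc_of_interest`.
#' @param min_cases minimum report count for significance (default 5).
#' @param correction passed to [ror_with_ci()].
#' @return tibble with columns `level`, `term`, `a`, `b`, `c`, `d`, `ror`,
#'   `ci_low`, `ci_high`, `n`, `deaths`, `significant`.
#' @export
detect_signals <- function(universe, spec, soc = spec$soc_of_interest,
                           min_cases = 5L, correction = FALSE) {
  stopifnot(inherits(universe, "faers_reports"))
  if (is.null(universe$reac_soc)) {
    stop("universe is not SOC-annotated; run annotate_soc() first")
  }
  universe_ids <- universe$demo$primaryid
  target_ids <- target_primaryids(universe, spec)

  events <- universe$reac_soc |>
    dplyr::filter(.data$soc == !!soc) |>
    dplyr::distinct(.data$primaryid, .data$pt)
  case_events <- dplyr::filter(events, .data$primaryid %in% target_ids)
  pts <- sort(unique(case_events$pt))
  if (!length(pts)) {
    return(empty_signal_tbl())
  }
  deaths <- death_counts(universe, case_events)

  rows <- lapply(pts, function(pt) {
    ev_ids <- unique(events$primaryid[events$pt == pt])
    tab <- build_table(universe_ids, target_ids, ev_ids)
    dth <- deaths$deaths[match(pt, deaths$pt)]
    signal_row("PT", pt, tab, ifelse(is.na(dth), 0L, dth), min_cases, correction)
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$term)
}

#' SOC-level disproportionality signal
#'
#' As [detect_signals()] but with the event defined as *any* PT under the
#' SOC, yielding one row at `level = "SOC"`.
#'
#' @inheritParams detect_signals
#' @return one-row signal tibble (same schema as [detect_signals()]).
#' @export
soc_level_signal <- function(universe, spec, soc = spec$soc_of_interest,
                             min_cases = 5L, correction = FALSE) {
  stopifnot(inherits(universe, "faers_reports"))
  if (is.null(universe$reac_soc)) {
    stop("universe is not SOC-annotated; run annotate_soc() first")
  }
  universe_ids <- universe$demo$primaryid
  target_ids <- target_primaryids(universe, spec)
  ev_ids <- unique(universe$reac_soc$primaryid[universe$reac_soc$soc == soc])
  tab <- build_table(universe_ids, target_ids, ev_ids)
  case_ids <- intersect(target_ids, ev_ids)
  dead <- unique(universe$outcomes$primaryid[universe$outcomes$outc_cod == "DE"])
  signal_row("SOC", soc, tab, sum(case_ids %in% dead), min_cases, correction)
}

# stratum variable values per report, NA = not available
stratum_values <- function(demo, variable) {
  switch(variable,
    sex = demo$sex,
    age_band = ifelse(
      is.na(demo$age_years), NA_character_,
      ifelse(demo$age_years < 18, "<18",
        ifelse(demo$age_years <= 65, "18-65", ">65")
      )
    ),
    weight_band = ifelse(
      is.na(demo$weight_kg), NA_character_,
      ifelse(demo$weight_kg < 80, "<80",
        ifelse(demo$weight_kg <= 100, "80-100", ">100")
      )
    ),
    reporter = ifelse(
      demo$reporter %in% c("health_professional", "consumer"),
      demo$reporter, NA_character_
    ),
    stop("unknown stratification variable: ", variable)
  )
}

#' Subgroup (stratified) SOC-level signals
#'
#' Restricts both cases and non-cases to each stratum before building the
#' 2x2 table, so every stratum gets its own self-contained case/non-case
#' analysis. Reports missing the stratification variable are excluded from
#' that variable's strata. Strata with zero target-drug reports yield no
#' row (they are listed in `attr(x, "empty_strata")`).
#'
#' @inheritParams detect_signals
#' @param strata stratification variables among `sex`, `age_band`,
#'   `weight_band`, `reporter`.
#' @return signal tibble with leading columns `variable` and `stratum`.
#' @export
subgroup_signals <- function(universe, spec, soc = spec$soc_of_interest,
                             strata = c("sex", "age_band", "weight_band", "reporter"),
                             min_cases = 5L, correction = FALSE) {
  stopifnot(inherits(universe, "faers_reports"))
  target_ids <- target_primaryids(universe, spec)
  rows <- list()
  empty <- character()
  for (variable in strata) {
    vals <- stratum_values(universe$demo, variable)
    for (lev in sort(unique(vals[!is.na(vals)]))) {
      ids <- universe$demo$primaryid[!is.na(vals) & vals == lev]
      if (!length(intersect(ids, target_ids))) {
        empty <- c(empty, paste(variable, lev, sep = "="))
        next
      }
      sub <- filter_reports(universe, ids)
      row <- soc_level_signal(sub, spec, soc, min_cases, correction)
      rows[[length(rows) + 1L]] <- tibble::add_column(
        row,
        variable = variable, stratum = lev, .before = 1
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "empty_strata") <- empty
  out
}

#' Sensitivity analysis excluding co-reported suspect drugs
#'
#' Drops from the universe every target-drug *case* report (a report of the
#' target drug with at least one event under `soc`) on which any of
#' `excluded_drugs` is co-reported in a non-primary-suspect role (SS, C or
#' I — the conventional definition of concomitant therapy), then re-runs
#' the PT-level signal detection. The case-count change is reported
#' alongside.
#'
#' @inheritParams detect_signals
#' @param excluded_drugs drug names to exclude (matched like cohort names).
#' @return list with `signals` (as [detect_signals()]), `n_cases_before`,
#'   `n_cases_after`, `n_removed`.
#' @export
sensitivity_exclude <- function(universe, spec, soc = spec$soc_of_interest,
                                excluded_drugs, min_cases = 5L,
                                correction = FALSE) {
  stopifnot(length(excluded_drugs) > 0)
  target_ids <- target_primaryids(universe, spec)
  case_ids <- intersect(
    target_ids,
    unique(universe$reac_soc$primaryid[universe$reac_soc$soc == soc])
  )

  drugs <- universe$drugs
  dn <- normalize_term(drugs$drugname)
  ai <- normalize_term(drugs$prod_ai)
  hit <- rep(FALSE, nrow(drugs))
  for (ex in normalize_term(excluded_drugs)) {
    hit <- hit | match_whole_word(dn, ex) | match_whole_word(ai, ex)
  }
  hit <- hit & drugs$role_cod %in% c("SS", "C", "I")
  excluded_ids <- intersect(unique(drugs$primaryid[hit]), case_ids)

  reduced <- filter_reports(
    universe, setdiff(universe$demo$primaryid, excluded_ids)
  )
  list(
    signals = detect_signals(reduced, spec, soc, min_cases, correction),
    n_cases_before = length(case_ids),
    n_cases_after = length(case_ids) - length(excluded_ids),
    n_removed = length(excluded_ids)
  )
}

#' Rank concomitant drugs among case reports
#'
#' Counts, for each normalized drug name, the case reports on which it
#' appears in a non-primary-suspect role; a drug listed twice on one report
#' counts once. Percentages are over all case reports; ties in count break
#' alphabetically.
#'
#' @param case_reports a [faers_reports] of case reports.
#' @param top_k number of rows to return (default 20).
#' @return tibble with `drug`, `n`, `percent`.
#' @export
concomitant_ranking <- function(case_reports, top_k = 20L) {
  stopifnot(inherits(case_reports, "faers_reports"))
  n_cases <- nrow(case_reports$demo)
  con <- case_reports$drugs |>
    dplyr::filter(.data$role_cod %in% c("SS", "C", "I")) |>
    dplyr::mutate(drug = normalize_term(.data$drugname)) |>
    dplyr::distinct(.data$primaryid, .data$drug)
  con |>
    dplyr::count(.data$drug, name = "n") |>
    dplyr::mutate(percent = pct_of(.data$n, n_cases)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$drug) |>
    head(top_k)
}
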