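#' Cohort specification: which drug, which roles, which organ class
#'
#' Defines how target-drug reports are selected: generic names are matched
#' against both `drugname` and `prod_ai`, trade names against `drugname`
#' only, and only drug entries whose role is in `role_filter` qualify
#' (default primary suspect only, which is the conventional choice for
#' strengthening the drug-event attribution). Matching is case-insensitive
#' whole-word substring matching on normalized strings, because FAERS
#' `drugname` entries carry salt forms and dose text.
#'
#' @param generic_names character, e.g. `"QUETIAPINE"`.
#' @param trade_names character, e.g. `"SEROQUEL"`.
#' @param role_filter subset of `c("PS", "SS", "C", "I")`.
#' @param soc_of_interest MedDRA System Organ Class the analysis restricts
#'   to, e.g. `"Cardiac disorders"`.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(generic_names, trade_names = character(),
                        role_filter = "PS",
                        soc_of_interest = "Cardiac disorders") {
  if (!length(generic_names) && !length(trade_names)) {
    stop("cohort_spec needs at least one drug name")
  }
  stopifnot(all(role_filter %in% c("PS", "SS", "C", "I")))
  structure(
    list(
      generic_names = normalize_term(generic_names),
      trade_names = normalize_term(trade_names),
      role_filter = role_filter,
      soc_of_interest = soc_of_interest
    ),
    class = "cohort_spec"
  )
}

# Logical vector over drug-entry rows: does this entry match the spec's
# drug names (any role)?
drug_entry_matches <- function(drugs, spec) {
  dn <- normalize_term(drugs$drugname)
  ai <- normalize_term(drugs$prod_ai)
  hit <- rep(FALSE, nrow(drugs))
  for (g in spec$generic_names) {
    hit <- hit | match_whole_word(dn, g) | match_whole_word(ai, g)
  }
  for (tr in spec$trade_names) {
    hit <- hit | match_whole_word(dn, tr)
  }
  hit
}

# primaryids of reports with >= 1 qualifying (name AND role) drug entry
target_primaryids <- function(reports, spec) {
  drugs <- reports$drugs
  hit <- drug_entry_matches(drugs, spec) & drugs$role_cod %in% spec$role_filter
  unique(drugs$primaryid[hit])
}

#' Select reports of the target drug
#'
#' Keeps reports having at least one drug entry whose role is in the
#' spec's `role_filter` and whose name matches (see [cohort_spec()]).
#'
#' @param reports a deduplicated [faers_reports].
#' @param spec a [cohort_spec()].
#' @return the matching subset, a [faers_reports].
#' @export
match_target_reports <- function(reports, spec) {
  stopifnot(inherits(reports, "faers_reports"), inherits(spec, "cohort_spec"))
  filter_reports(reports, target_primaryids(reports, spec))
}

#' Load a PT-to-SOC mapping table
#'
#' Two-column delimited text (`pt`, `soc`), standing in for a licensed
#' MedDRA dictionary. A PT may map to several SOCs (one row each); lookups
#' are case-insensitive after whitespace normalization.
#'
#' @param path file path; comma- or tab-delimited with a header.
#' @return tibble of class `meddra_map` with columns `pt`, `soc` and a
#'   normalized key column `pt_key`.
#' @export
read_meddra_map <- function(path) {
  tab <- readr::read_delim(
    path,
    delim = if (grepl("\\.tsv$", path)) "\t" else ",",
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE
  )
  names(tab) <- tolower(names(tab))
  if (!all(c("pt", "soc") %in% names(tab))) {
    stop("MedDRA map must have columns pt, soc: ", path)
  }
  meddra_map(tab)
}

#' @rdname read_meddra_map
#' @param table data frame with columns `pt`, `soc`.
#' @export
meddra_map <- function(table) {
  tab <- tibble::as_tibble(table)[, c("pt", "soc")]
  tab$pt_key <- normalize_term(tab$pt)
  tab <- dplyr::distinct(tab, .data$pt_key, .data$soc, .keep_all = TRUE)
  class(tab) <- c("meddra_map", class(tab))
  tab
}

#' Synthetic PT-to-SOC map shipped with the package
#'
#' Covers the PTs of the default synthetic event pool (the 31 cardiac
#' signal PTs plus a handful of non-cardiac terms), with a few PTs mapped
#' to more than one SOC as in a real MedDRA hierarchy. A synthetic
#' stand-in for licensed dictionary content, usable for tests and demos.
#'
#' @return a [meddra_map()].
#' @export
synthetic_meddra_map <- function() {
  read_meddra_map(system.file("extdata", "synthetic_meddra_pt_soc.csv",
    package = "faersror"
  ))
}

#' Attach SOC annotations to every reaction PT
#'
#' Adds a `reac_soc` table (`primaryid`, `pt`, `soc`) to the report
#' collection. A PT mapped to several SOCs contributes one row per SOC, so
#' SOC-level tallies count it under each; unmapped PTs contribute no rows
#' and are listed in `attr(x, "unmapped_pts")` with a warning.
#'
#' @param reports a [faers_reports].
#' @param map a [meddra_map()].
#' @return `reports` with the `reac_soc` component added.
#' @export
annotate_soc <- function(reports, map) {
  stopifnot(inherits(reports, "faers_reports"), inherits(map, "meddra_map"))
  reac <- reports$reacs
  reac$pt_key <- normalize_term(reac$pt)
  joined <- dplyr::inner_join(
    reac,
    dplyr::select(tibble::as_tibble(map), "pt_key", "soc"),
    by = "pt_key",
    relationship = "many-to-many"
  )
  unmapped <- sort(unique(reac$pt[!reac$pt_key %in% map$pt_key]))
  if (length(unmapped)) {
    warning(
      length(unmapped), " PT(s) not in the MedDRA map, e.g. ",
      paste(head(unmapped, 3), collapse = "; ")
    )
  }
  reports$reac_soc <- dplyr::select(joined, "primaryid", "pt", "soc")
  attr(reports, "unmapped_pts") <- unmapped
  reports
}

#' Restrict an annotated collection to one System Organ Class
#'
#' Separates the two counting units the analysis reports: *case reports*
#' (reports with at least one event under the SOC) and *case events*
#' (distinct report-PT pairs under the SOC) — one patient can contribute
#' several events.
#'
#' @param reports a SOC-annotated [faers_reports] (see [annotate_soc()]).
#' @param soc SOC name.
#' @return list with `case_reports` ([faers_reports]) and `case_events`
#'   (tibble `primaryid`, `pt`).
#' @export
restrict_to_soc <- function(reports, soc) {
  stopifnot(inherits(reports, "faers_reports"))
  if (is.null(reports$reac_soc)) {
    stop("reports are not SOC-annotated; run annotate_soc() first")
  }
  events <- reports$reac_soc |>
    dplyr::filter(.data$soc == !!soc) |>
    dplyr::distinct(.data$primaryid, .data$pt)
  list(
    case_reports = filter_reports(reports, unique(events$primaryid)),
    case_events = events
  )
}

#' Default indication keywords counted as psychiatric
#'
#' FAERS indication PTs whose normalized form contains any of these words
#' are grouped under "Psychiatric disorders" in the descriptive summary.
#' The grouping is configurable because no authoritative enumeration is
#' shipped.
#' @export
psychiatric_indication_keywords <- function() {
  c(
    "SCHIZOPHRENIA", "SCHIZOAFFECTIVE", "BIPOLAR", "DEPRESSION", "DEPRESSIVE",
    "ANXIETY", "PSYCHOTIC", "PSYCHOSIS", "MANIA", "MANIC", "INSOMNIA",
    "MOOD", "AGITATION", "OBSESSIVE", "PANIC", "POST TRAUMATIC", "PTSD"
  )
}

median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
}

band_table <- function(x, breaks_fun, levels) {
  avail <- x[!is.na(x)]
  bands <- breaks_fun(avail)
  counts <- table(factor(bands, levels = levels))
  tibble::tibble(
    band = levels,
    n = as.integer(counts),
    percent = pct_of(as.integer(counts), length(avail))
  )
}

#' Descriptive summary of a case cohort
#'
#' The standard clinical-characteristics panel for a spontaneous-report
#' cohort: sex, age bands (<18, 18-65 inclusive, >65) with median and IQR,
#' weight bands (<80, 80-100 inclusive, >100 kg), countries, indications
#' grouped into psychiatric vs other, outcome categories (serious defined
#' as any of the seven serious outcome codes; categories overlap so their
#' percentages may exceed 100), reporter types (health professional vs
#' consumer, over the reports where one of the two applies), reporting
#' quarter-year, and — when a TTO sample is supplied — time-to-onset.
#' All percentages use the available-value denominator of their panel.
#'
#' @param case_reports a [faers_reports].
#' @param tto optional `tto_sample` from [compute_tto()].
#' @param psychiatric_keywords keyword list for the indication grouping.
#' @return named list of tibbles of class `cohort_summary`.
#' @export
summarize_cohort <- function(case_reports, tto = NULL,
                             psychiatric_keywords = psychiatric_indication_keywords()) {
  stopifnot(inherits(case_reports, "faers_reports"))
  demo <- case_reports$demo
  n_total <- nrow(demo)

  sex_avail <- demo$sex[!is.na(demo$sex)]
  sex <- tibble::tibble(
    group = c("female", "male"),
    n = c(sum(sex_avail == "female"), sum(sex_avail == "male")),
    percent = pct_of(
      c(sum(sex_avail == "female"), sum(sex_avail == "male")),
      length(sex_avail)
    )
  )

  age_bands <- band_table(
    demo$age_years,
    function(x) ifelse(x < 18, "<18", ifelse(x <= 65, "18-65", ">65")),
    c("<18", "18-65", ">65")
  )
  weight_bands <- band_table(
    demo$weight_kg,
    function(x) ifelse(x < 80, "<80", ifelse(x <= 100, "80-100", ">100")),
    c("<80", "80-100", ">100")
  )

  country_avail <- demo$country[!is.na(demo$country)]
  ctab <- table(country_avail)
  countries <- tibble::tibble(
    country = as.character(names(ctab)),
    n = as.integer(ctab),
    percent = pct_of(as.integer(ctab), length(country_avail))
  ) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$country)

  # indication of the matched (or first PS) drug, one per report
  indi <- case_reports$drugs |>
    dplyr::filter(!is.na(.data$indi_pt)) |>
    dplyr::distinct(.data$primaryid, .keep_all = TRUE)
  indi_norm <- normalize_term(indi$indi_pt)
  is_psy <- Reduce(
    `|`,
    lapply(psychiatric_keywords, function(k) match_whole_word(indi_norm, k)),
    accumulate = FALSE
  )
  indications <- tibble::tibble(
    group = c("Psychiatric disorders", "Others"),
    n = c(sum(is_psy), sum(!is_psy)),
    percent = pct_of(c(sum(is_psy), sum(!is_psy)), nrow(indi))
  )

  ser <- classify_seriousness(case_reports)
  code_labels <- c(
    DE = "Death", LT = "Life-threatening", HO = "Hospitalization",
    DS = "Disability", CA = "Congenital anomaly",
    RI = "Required intervention", OT = "Other serious outcomes"
  )
  per_code <- vapply(
    names(code_labels),
    function(code) {
      length(unique(
        case_reports$outcomes$primaryid[case_reports$outcomes$outc_cod == code]
      ))
    },
    integer(1)
  )
  outcomes <- tibble::tibble(
    group = c("Nonserious outcome", "Serious outcome", unname(code_labels)),
    n = c(sum(!ser$serious), sum(ser$serious), unname(per_code)),
    percent = c(
      pct_of(c(sum(!ser$serious), sum(ser$serious)), n_total),
      pct_of(unname(per_code), sum(ser$serious))
    )
  )

  rep_avail <- demo$reporter[demo$reporter %in% c("health_professional", "consumer")]
  reporters <- tibble::tibble(
    group = c("health_professional", "consumer"),
    n = c(
      sum(rep_avail == "health_professional"),
      sum(rep_avail == "consumer")
    ),
    percent = pct_of(
      c(sum(rep_avail == "health_professional"), sum(rep_avail == "consumer")),
      length(rep_avail)
    )
  )

  ptab <- table(demo$quarter)
  years <- tibble::tibble(
    period = as.character(names(ptab)),
    n = as.integer(ptab),
    percent = pct_of(as.integer(ptab), n_total)
  ) |>
    dplyr::arrange(.data$period)

  out <- list(
    n_reports = n_total,
    sex = sex,
    age = list(bands = age_bands, summary = median_iqr(demo$age_years)),
    weight = list(bands = weight_bands, summary = median_iqr(demo$weight_kg)),
    countries = countries,
    indications = indications,
    outcomes = outcomes,
    reporters = reporters,
    reporting_period = years
  )
  if (!is.null(tto)) {
    out$tto <- median_iqr(tto$durations_raw)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_reports, " case reports\n", sep = "")
  cat(
    "  serious: ",
    x$outcomes$n[x$outcomes$group == "Serious outcome"], " (",
    sprintf("%.2f%%", x$outcomes$percent[x$outcomes$group == "Serious outcome"]),
    ")\n",
    sep = ""
  )
  invisible(x)
}
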