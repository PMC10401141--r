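#' Configuration for a full pipeline run
#'
#' Collects everything [run_all()] needs: where the quarterly files live,
#' how to select the cohort, which PT-to-SOC map and DME/IME/evidence
#' inputs to use, the priority rubric, stratification variables, the
#' sensitivity exclusion list and numerical options. All referenced paths
#' are validated here, before any data are read.
#'
#' @param input_root directory of quarter subdirectories (as written by
#'   [write_quarters()]).
#' @param output_dir directory for the result bundle (created if needed).
#' @param generic_names,trade_names,role_filter,soc_of_interest cohort
#'   selection, see [cohort_spec()].
#' @param meddra_map_path PT-to-SOC table ([read_meddra_map()]); `NULL`
#'   uses the synthetic map shipped with the package.
#' @param dme_terms_path,ime_terms_path one-term-per-line files; `NULL`
#'   uses the package's fixture lists.
#' @param evidence_path CSV with columns `pt`, `grade`; `NULL` means every
#'   PT falls back to `default_evidence_grade`.
#' @param default_evidence_grade grade for PTs without an evidence entry
#'   (`NULL` makes a missing grade an error).
#' @param rubric a [priority_rubric()].
#' @param strata stratification variables for the subgroup analysis.
#' @param excluded_drugs sensitivity exclusion list (may be empty).
#' @param zero_epsilon zero-day TTO replacement, days.
#' @param min_cases signal-significance case threshold.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_root, output_dir,
                       generic_names, trade_names = character(),
                       role_filter = "PS",
                       soc_of_interest = "Cardiac disorders",
                       meddra_map_path = NULL,
                       dme_terms_path = NULL, ime_terms_path = NULL,
                       evidence_path = NULL, default_evidence_grade = "+",
                       rubric = priority_rubric(),
                       strata = c("sex", "age_band", "weight_band", "reporter"),
                       excluded_drugs = character(),
                       zero_epsilon = 0.5, min_cases = 5L) {
  if (!dir.exists(input_root)) stop("input_root does not exist: ", input_root)
  for (p in c(meddra_map_path, dme_terms_path, ime_terms_path, evidence_path)) {
    if (!is.null(p) && !file.exists(p)) stop("configured path does not exist: ", p)
  }
  structure(
    list(
      input_root = input_root, output_dir = output_dir,
      spec = cohort_spec(generic_names, trade_names, role_filter, soc_of_interest),
      meddra_map_path = meddra_map_path,
      dme_terms_path = dme_terms_path, ime_terms_path = ime_terms_path,
      evidence_path = evidence_path,
      default_evidence_grade = default_evidence_grade,
      rubric = rubric, strata = strata, excluded_drugs = excluded_drugs,
      zero_epsilon = zero_epsilon, min_cases = as.integer(min_cases)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields mirror the arguments of [run_config()]; the rubric is
#' given as `rubric: {case_count_edges: [10, 50], ...}`. Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) {
      return(NULL)
    }
    if (file.exists(p) || dir.exists(p)) p else file.path(base, p)
  }
  rubric <- if (is.null(y$rubric)) {
    priority_rubric()
  } else {
    priority_rubric(
      case_count_edges = y$rubric$case_count_edges %||% c(10, 50),
      ror025_edges = y$rubric$ror025_edges %||% c(2, 5),
      death_fraction_edges = y$rubric$death_fraction_edges %||% c(0.25, 0.50)
    )
  }
  run_config(
    input_root = resolve(y$input_root),
    output_dir = resolve(y$output_dir) %||% y$output_dir,
    generic_names = y$generic_names,
    trade_names = y$trade_names %||% character(),
    role_filter = y$role_filter %||% "PS",
    soc_of_interest = y$soc_of_interest %||% "Cardiac disorders",
    meddra_map_path = resolve(y$meddra_map_path),
    dme_terms_path = resolve(y$dme_terms_path),
    ime_terms_path = resolve(y$ime_terms_path),
    evidence_path = resolve(y$evidence_path),
    default_evidence_grade = y$default_evidence_grade %||% "+",
    rubric = rubric,
    strata = y$strata %||% c("sex", "age_band", "weight_band", "reporter"),
    excluded_drugs = y$excluded_drugs %||% character(),
    zero_epsilon = y$zero_epsilon %||% 0.5,
    min_cases = y$min_cases %||% 5L
  )
}

flatten_cohort_summary <- function(s) {
  row <- function(panel, group, n, percent = NA_real_, median = NA_real_,
                  q1 = NA_real_, q3 = NA_real_) {
    tibble::tibble(
      panel = panel, group = group, n = n, percent = percent,
      median = median, q1 = q1, q3 = q3
    )
  }
  dplyr::bind_rows(
    row("total", "reports", s$n_reports),
    row("sex", s$sex$group, s$sex$n, s$sex$percent),
    row("age", s$age$bands$band, s$age$bands$n, s$age$bands$percent),
    row(
      "age", "median_iqr", s$age$summary$n, NA_real_,
      s$age$summary$median, s$age$summary$q1, s$age$summary$q3
    ),
    row("weight", s$weight$bands$band, s$weight$bands$n, s$weight$bands$percent),
    row(
      "weight", "median_iqr", s$weight$summary$n, NA_real_,
      s$weight$summary$median, s$weight$summary$q1, s$weight$summary$q3
    ),
    row("country", s$countries$country, s$countries$n, s$countries$percent),
    row("indication", s$indications$group, s$indications$n, s$indications$percent),
    row("outcome", s$outcomes$group, s$outcomes$n, s$outcomes$percent),
    row("reporter", s$reporters$group, s$reporters$n, s$reporters$percent),
    row("period", s$reporting_period$period, s$reporting_period$n, s$reporting_period$percent),
    if (!is.null(s$tto)) {
      row(
        "tto", "median_iqr", s$tto$n, NA_real_,
        s$tto$median, s$tto$q1, s$tto$q3
      )
    }
  )
}

#' Run the complete signal-detection pipeline
#'
#' Executes every stage in order — ingestion and deduplication, cohort
#' selection and SOC annotation, descriptive summary, PT- and SOC-level
#' ROR signal detection, serious/nonserious comparison, clinical-priority
#' scoring, pooled time-to-onset Weibull analysis, subgroup analysis,
#' concomitant-drug ranking and (when an exclusion list is configured)
#' the sensitivity analysis — and writes the result bundle to
#' `output_dir`:
#' `table1_cohort.csv`, `table2_serious_vs_nonserious.csv`,
#' `table3_priority.csv`, `table4_tto_weibull.csv`,
#' `table5_concomitant.csv`, `signals.csv` (forest-plot-ready, all PTs),
#' `soc_signal.csv`, `subgroup_signals.csv`, `sensitivity_signals.csv`,
#' and `run_summary.json` with every dedup/exclusion counter. The run is
#' fully deterministic: identical inputs give identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all in-memory results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  map <- if (is.null(config$meddra_map_path)) {
    synthetic_meddra_map()
  } else {
    read_meddra_map(config$meddra_map_path)
  }
  dme <- if (is.null(config$dme_terms_path)) {
    dme_terms()
  } else {
    readr::read_lines(config$dme_terms_path, progress = FALSE)
  }
  ime <- if (is.null(config$ime_terms_path)) {
    ime_terms()
  } else {
    readr::read_lines(config$ime_terms_path, progress = FALSE)
  }
  evidence <- if (is.null(config$evidence_path)) {
    NULL
  } else {
    readr::read_csv(config$evidence_path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }

  raw <- read_quarters(config$input_root)
  assembled <- assemble_reports(raw)
  universe <- deduplicate(assembled)
  dedup_log <- attr(universe, "dedup_log")

  universe <- suppressWarnings(annotate_soc(universe, map))
  spec <- config$spec
  soc <- spec$soc_of_interest

  cases <- restrict_to_soc(match_target_reports(universe, spec), soc)
  case_reports <- cases$case_reports
  tto <- compute_tto(case_reports, spec, config$zero_epsilon)
  summary_tab <- summarize_cohort(case_reports, tto = tto)

  signals <- detect_signals(universe, spec, soc, config$min_cases)
  soc_signal <- soc_level_signal(universe, spec, soc, config$min_cases)
  significant <- dplyr::filter(signals, .data$significant)

  severity_tab <- compare_serious_nonserious(case_reports, significant$term)
  scored <- score_all(
    significant, evidence, dme, ime, config$rubric,
    default_grade = config$default_evidence_grade
  )
  tto_tab <- tto_by_priority(case_reports, scored, spec, config$zero_epsilon)
  subgroup <- subgroup_signals(universe, spec, soc, config$strata, config$min_cases)
  concomitant <- concomitant_ranking(case_reports)
  sensitivity <- NULL
  if (length(config$excluded_drugs)) {
    sensitivity <- sensitivity_exclude(
      universe, spec, soc, config$excluded_drugs, config$min_cases
    )
  }

  out <- function(name) file.path(config$output_dir, name)
  readr::write_csv(flatten_cohort_summary(summary_tab), out("table1_cohort.csv"))
  readr::write_csv(severity_tab, out("table2_serious_vs_nonserious.csv"))
  readr::write_csv(scored, out("table3_priority.csv"))
  readr::write_csv(tto_tab, out("table4_tto_weibull.csv"))
  readr::write_csv(concomitant, out("table5_concomitant.csv"))
  readr::write_csv(signals, out("signals.csv"))
  readr::write_csv(soc_signal, out("soc_signal.csv"))
  readr::write_csv(subgroup, out("subgroup_signals.csv"))
  if (!is.null(sensitivity)) {
    readr::write_csv(sensitivity$signals, out("sensitivity_signals.csv"))
  }

  counters <- list(
    reports_read = dedup_log$n_input,
    deleted_removed = dedup_log$n_deleted_removed,
    duplicates_removed = dedup_log$n_duplicates_removed,
    universe_reports = dedup_log$n_output,
    target_reports = length(target_primaryids(universe, spec)),
    case_reports = n_reports(case_reports),
    case_events = nrow(cases$case_events),
    signals_detected = nrow(signals),
    signals_significant = nrow(significant),
    tto_available = length(tto$durations),
    tto_excluded_missing = tto$n_excluded_missing,
    tto_excluded_negative = tto$n_excluded_negative,
    tto_zero_adjusted = tto$n_zero_adjusted,
    priority_levels = as.list(attr(scored, "level_counts")),
    sensitivity_cases_before = sensitivity$n_cases_before %||% NA,
    sensitivity_cases_after = sensitivity$n_cases_after %||% NA
  )
  jsonlite::write_json(counters, out("run_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    universe = universe, case_reports = case_reports,
    summary = summary_tab, signals = signals, soc_signal = soc_signal,
    severity = severity_tab, scored = scored, tto = tto, tto_table = tto_tab,
    subgroup = subgroup, concomitant = concomitant,
    sensitivity = sensitivity, counters = counters
  ))
}

#' Simulate a synthetic universe and write it as quarterly files
#'
#' Convenience wrapper chaining [simulate_faers()] and [write_quarters()];
#' this is the `simulate` subcommand of the command-line interface.
#'
#' @param config a [sim_config()].
#' @param root_directory output root (one subdirectory per quarter).
#' @return the simulation result of [simulate_faers()], invisibly.
#' @export
simulate_to_directory <- function(config, root_directory) {
  sim <- simulate_faers(config)
  write_quarters(sim$reports, root_directory)
  invisible(sim)
}
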