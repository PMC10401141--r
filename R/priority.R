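#' Rubric for the five-feature semiquantitative clinical-priority score
#'
#' Each detected signal is scored 0-2 on five features and the points are
#' summed (maximum 10): number of case reports, lower limit of the ROR 95%
#' CI (ROR025), proportion of deaths among the cases, membership of the
#' regulator-curated designated/important medical event lists (DME scores
#' 2, IME-only 1), and an expert literature-evidence grade ("++" strong,
#' "+" some, "-" none). Composite 0-4 is weak, 5-7 moderate, 8-10 strong
#' clinical priority.
#'
#' Default thresholds: case count `< 10 -> 0`, `10-49 -> 1`, `>= 50 -> 2`;
#' ROR025 `< 2 -> 0`, `2 to < 5 -> 1`, `>= 5 -> 2`; death fraction
#' `< 0.25 -> 0`, `0.25 to < 0.50 -> 1`, `>= 0.50 -> 2`. All edges use a
#' closed lower bound.
#'
#' @param case_count_edges two increasing thresholds for the case-count
#'   points.
#' @param ror025_edges two increasing thresholds for the ROR025 points.
#' @param death_fraction_edges two increasing thresholds for the
#'   death-proportion points.
#' @return list of class `priority_rubric`.
#' @export
priority_rubric <- function(case_count_edges = c(10, 50),
                            ror025_edges = c(2, 5),
                            death_fraction_edges = c(0.25, 0.50)) {
  check_edges <- function(e, what) {
    if (length(e) != 2L || !(e[1] < e[2])) {
      stop(what, " must be two strictly increasing thresholds")
    }
  }
  check_edges(case_count_edges, "case_count_edges")
  check_edges(ror025_edges, "ror025_edges")
  check_edges(death_fraction_edges, "death_fraction_edges")
  structure(
    list(
      case_count_edges = case_count_edges,
      ror025_edges = ror025_edges,
      death_fraction_edges = death_fraction_edges
    ),
    class = "priority_rubric"
  )
}

edge_points <- function(x, edges) {
  ifelse(x >= edges[2], 2L, ifelse(x >= edges[1], 1L, 0L))
}

priority_level <- function(score) {
  ifelse(score <= 4, "weak", ifelse(score <= 7, "moderate", "strong"))
}

normalize_evidence <- function(grade) {
  g <- gsub("−", "-", trimws(grade)) # unicode minus
  if (!all(g %in% c("++", "+", "-"))) {
    bad <- unique(g[!g %in% c("++", "+", "-")])
    stop("unknown evidence grade(s): ", paste(bad, collapse = ", "))
  }
  g
}

#' Score one signal on the five-feature priority scale
#'
#' @param features list or one-row data frame with `n_cases`, `ror025`,
#'   `deaths`, `is_dme`, `is_ime`, `evidence_grade` (`"++"`, `"+"` or
#'   `"-"`).
#' @param rubric a [priority_rubric()].
#' @return list with integer `score` (0-10) and `level`
#'   (`weak`/`moderate`/`strong`).
#' @export
score_signal <- function(features, rubric = priority_rubric()) {
  f <- as.list(features)
  stopifnot(f$deaths <= f$n_cases)
  pts <- edge_points(f$n_cases, rubric$case_count_edges) +
    edge_points(f$ror025, rubric$ror025_edges) +
    edge_points(
      if (f$n_cases > 0) f$deaths / f$n_cases else 0,
      rubric$death_fraction_edges
    ) +
    (if (isTRUE(f$is_dme)) 2L else if (isTRUE(f$is_ime)) 1L else 0L) +
    switch(normalize_evidence(f$evidence_grade), "++" = 2L, "+" = 1L, "-" = 0L)
  list(score = as.integer(pts), level = priority_level(pts))
}

#' Score every detected signal and band by clinical priority
#'
#' Assembles the five features per PT from the signal table (`n`, `ci_low`
#' as ROR025, `deaths`), the DME/IME term lists and the expert evidence
#' table, scores them under the rubric, and appends the level. A PT with
#' no row in the evidence table is an error (the grade is an expert input
#' that cannot be defaulted silently) unless `default_grade` is given.
#'
#' @param signals signal tibble from [detect_signals()] (typically the
#'   significant subset).
#' @param evidence data frame with columns `pt`, `grade`; or `NULL` to use
#'   `default_grade` throughout.
#' @param dme_terms,ime_terms character vectors of designated / important
#'   medical event PTs (matched case-insensitively).
#' @param rubric a [priority_rubric()].
#' @param default_grade grade for PTs absent from `evidence`, or `NULL`
#'   (strict).
#' @return tibble with one row per signal: features, `score`, `level`;
#'   level counts in `attr(x, "level_counts")`.
#' @export
score_all <- function(signals, evidence = NULL,
                      dme_terms = character(), ime_terms = character(),
                      rubric = priority_rubric(), default_grade = NULL) {
  if (!nrow(signals)) {
    out <- tibble::tibble(
      pt = character(), n_cases = integer(), ror025 = numeric(),
      deaths = integer(), is_dme = logical(), is_ime = logical(),
      evidence_grade = character(), score = integer(), level = character()
    )
    attr(out, "level_counts") <- c(weak = 0L, moderate = 0L, strong = 0L)
    return(out)
  }
  pt_key <- normalize_term(signals$term)
  grades <- rep(default_grade %||% NA_character_, nrow(signals))
  if (!is.null(evidence)) {
    m <- match(pt_key, normalize_term(evidence$pt))
    grades[!is.na(m)] <- evidence$grade[m[!is.na(m)]]
  }
  if (anyNA(grades)) {
    stop(
      "no evidence grade for PT(s): ",
      paste(signals$term[is.na(grades)], collapse = ", ")
    )
  }
  feats <- tibble::tibble(
    pt = signals$term,
    n_cases = signals$n,
    ror025 = signals$ci_low,
    deaths = signals$deaths,
    is_dme = pt_key %in% normalize_term(dme_terms),
    is_ime = pt_key %in% normalize_term(ime_terms),
    evidence_grade = normalize_evidence(grades)
  )
  scored <- lapply(seq_len(nrow(feats)), function(i) score_signal(feats[i, ], rubric))
  feats$score <- vapply(scored, `[[`, integer(1), "score")
  feats$level <- vapply(scored, `[[`, character(1), "level")
  attr(feats, "level_counts") <- c(
    weak = sum(feats$level == "weak"),
    moderate = sum(feats$level == "moderate"),
    strong = sum(feats$level == "strong")
  )
  feats
}

#' Published quetiapine cardiac signal feature table
#'
#' The 31 quetiapine-associated cardiac signals detected in FAERS
#' 2018Q1-2022Q1 with their five scoring features and published composite
#' score/level, shipped as a golden fixture for the priority rubric. The
#' DME/IME assignments in it also serve as the package's default term
#' lists (`dme_terms()`, `ime_terms()`); they are a fixture, not an
#' authoritative regulatory list.
#'
#' @return tibble with columns `pt`, `n`, `ror025`, `deaths`, `ime_dme`
#'   (`"DME"`/`"IME"`/`"NA"`), `evidence`, `published_score`,
#'   `published_level`.
#' @export
published_signal_features <- function() {
  path <- system.file("extdata", "quetiapine_cardiac_signal_features.csv",
    package = "faersror"
  )
  # na = "": the literal string "NA" in ime_dme means "on neither list"
  readr::read_csv(path, col_types = "cidiccic", na = "", progress = FALSE)
}

#' @rdname published_signal_features
#' @export
dme_terms <- function() {
  tab <- published_signal_features()
  tab$pt[tab$ime_dme == "DME"]
}

#' @rdname published_signal_features
#' @export
ime_terms <- function() {
  tab <- published_signal_features()
  tab$pt[tab$ime_dme == "IME"]
}
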