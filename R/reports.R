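#' Construct a report-level FAERS data model
#'
#' The pipeline represents a collection of safety reports relationally, the
#' way FAERS itself does: one demographics row per report plus child tables
#' of drug mentions, reaction (MedDRA PT) mentions and outcome codes, all
#' keyed by `primaryid`. This is the container every analysis stage consumes.
#'
#' @param demo tibble with columns `primaryid`, `caseid`, `quarter`,
#'   `event_dt` (raw partial-date string, `""` when absent), `sex`
#'   (`"female"`/`"male"`/`NA`), `age_years`, `weight_kg`, `country`,
#'   `reporter` (`"health_professional"`/`"consumer"`/`"other"`).
#' @param drugs tibble with `primaryid`, `drug_seq`, `drugname`, `prod_ai`,
#'   `role_cod` (PS/SS/C/I), `start_dt` (partial-date string), `indi_pt`.
#' @param reacs tibble with `primaryid`, `pt`.
#' @param outcomes tibble with `primaryid`, `outc_cod`.
#' @return an object of class `faers_reports`.
#' @export
faers_reports <- function(demo, drugs = NULL, reacs = NULL, outcomes = NULL) {
  demo <- tibble::as_tibble(demo)
  need <- c(
    "primaryid", "caseid", "quarter", "event_dt", "sex", "age_years",
    "weight_kg", "country", "reporter"
  )
  missing_cols <- setdiff(need, names(demo))
  if (length(missing_cols)) {
    stop("demo table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  empty <- function(cols) {
    tibble::as_tibble(setNames(
      lapply(cols, function(.) character()), cols
    ))
  }
  drugs <- tibble::as_tibble(
    drugs %||%
      empty(c("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod", "start_dt", "indi_pt"))
  )
  reacs <- tibble::as_tibble(reacs %||% empty(c("primaryid", "pt")))
  outcomes <- tibble::as_tibble(outcomes %||% empty(c("primaryid", "outc_cod")))
  structure(
    list(demo = demo, drugs = drugs, reacs = reacs, outcomes = outcomes),
    class = "faers_reports"
  )
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(
    "<faers_reports> ", nrow(x$demo), " reports, ",
    nrow(x$drugs), " drug rows, ", nrow(x$reacs), " reaction rows, ",
    nrow(x$outcomes), " outcome rows\n",
    sep = ""
  )
  if (!is.null(x$reac_soc)) {
    cat("  SOC-annotated (", nrow(x$reac_soc), " PT-SOC rows)\n", sep = "")
  }
  invisible(x)
}

#' Number of reports in a `faers_reports` collection
#' @param x a `faers_reports` object.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "faers_reports"))
  nrow(x$demo)
}

# Subset a faers_reports object to a set of primaryids, carrying all child
# tables (and the SOC annotation, if present) along.
filter_reports <- function(x, primaryids) {
  stopifnot(inherits(x, "faers_reports"))
  out <- x
  out$demo <- dplyr::filter(x$demo, .data$primaryid %in% primaryids)
  keep <- out$demo$primaryid
  out$drugs <- dplyr::filter(x$drugs, .data$primaryid %in% keep)
  out$reacs <- dplyr::filter(x$reacs, .data$primaryid %in% keep)
  out$outcomes <- dplyr::filter(x$outcomes, .data$primaryid %in% keep)
  if (!is.null(x$reac_soc)) {
    out$reac_soc <- dplyr::filter(x$reac_soc, .data$primaryid %in% keep)
  }
  out
}
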