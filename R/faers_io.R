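#' Read one quarter of FAERS Quarterly Data Extract ASCII files
#'
#' The Quarterly Data Extract ships one `$`-delimited ASCII file per table
#' kind (DEMO, DRUG, REAC, OUTC, THER, INDI) with a single header line, plus
#' a deleted-case list of one `caseid` per line. `read_quarter()` locates
#' each file in `directory` by its kind prefix (case-insensitive), reads it
#' with all fields as trimmed character (no type coercion), lower-cases the
#' column names, and validates that the key columns for that kind are
#' present. Historical FAERS files are not valid UTF-8, so files are read
#' as Latin-1.
#'
#' @param directory path containing the quarter's files.
#' @param quarter_label label such as `"2018Q1"` attached to every report.
#' @return a list of class `faers_raw_quarter` with elements `tables`
#'   (named list of tibbles keyed `demo`, `drug`, ...), `deleted`
#'   (character vector of caseids) and `quarter`.
#' @export
read_quarter <- function(directory, quarter_label) {
  if (!dir.exists(directory)) {
    stop("directory not found: ", directory)
  }
  kinds <- c("demo", "drug", "reac", "outc", "ther", "indi")
  key_columns <- list(
    demo = c("primaryid", "caseid"),
    drug = c("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    ther = c("primaryid", "dsg_drug_seq", "start_dt"),
    indi = c("primaryid", "indi_drug_seq", "indi_pt")
  )
  files <- list.files(directory, full.names = TRUE)
  find_file <- function(kind) {
    hit <- files[grepl(paste0("^", kind, ".*\\.txt$"), tolower(basename(files)))]
    if (length(hit) > 1L) {
      stop("multiple ", toupper(kind), " files in ", directory)
    }
    if (length(hit)) hit else NULL
  }

  tables <- list()
  for (kind in kinds) {
    path <- find_file(kind)
    if (is.null(path)) next
    tab <- readr::read_delim(
      path,
      delim = "$",
      col_types = readr::cols(.default = readr::col_character()),
      locale = readr::locale(encoding = "latin1"),
      trim_ws = TRUE,
      na = character(),
      progress = FALSE
    )
    names(tab) <- tolower(names(tab))
    absent <- setdiff(key_columns[[kind]], names(tab))
    if (length(absent)) {
      stop(
        "format error in ", basename(path), ": missing key column(s) ",
        paste(absent, collapse = ", ")
      )
    }
    tables[[kind]] <- tab
  }
  if (is.null(tables$demo)) {
    stop("no DEMO file found in ", directory)
  }

  deleted <- character()
  del_path <- find_file("delete")
  if (is.null(del_path)) del_path <- find_file("deleted")
  if (!is.null(del_path)) {
    deleted <- trimws(readr::read_lines(del_path, progress = FALSE))
    deleted <- deleted[nzchar(deleted) & tolower(deleted) != "caseid"]
  }

  structure(
    list(tables = tables, deleted = deleted, quarter = quarter_label),
    class = "faers_raw_quarter"
  )
}

# Age-to-years factors keyed by FAERS age_cod. DEC = decades; HR uses the
# mean Julian-year hour count. Unknown codes yield NA (age treated missing).
.age_factor <- c(
  DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18, DY = 1 / 365.25,
  HR = 1 / 8766
)
.weight_factor <- c(KG = 1, LBS = 0.453592, GMS = 1 / 1000)

normalize_age_years <- function(age, age_cod) {
  val <- suppressWarnings(as.numeric(age))
  fac <- .age_factor[toupper(trimws(age_cod))]
  out <- unname(val * fac)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

normalize_weight_kg <- function(wt, wt_cod) {
  val <- suppressWarnings(as.numeric(wt))
  fac <- .weight_factor[toupper(trimws(wt_cod))]
  out <- unname(val * fac)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

map_reporter <- function(occp_cod) {
  code <- toupper(trimws(occp_cod))
  out <- rep("other", length(code))
  out[code %in% c("MD", "PH", "HP", "OT")] <- "health_professional"
  out[code %in% "CN"] <- "consumer"
  out
}

map_sex <- function(sex) {
  code <- toupper(trimws(sex))
  out <- rep(NA_character_, length(code))
  out[code == "F"] <- "female"
  out[code == "M"] <- "male"
  out
}

col_or_na <- function(tab, col) {
  if (col %in% names(tab)) tab[[col]] else rep("", nrow(tab))
}

#' Assemble raw quarterly tables into the report-level data model
#'
#' Joins DRUG/REAC/OUTC rows to DEMO by `primaryid`, attaches therapy start
#' dates to drug entries by matching `dsg_drug_seq` to `drug_seq`, attaches
#' indication PTs analogously, and normalizes demographics: age to years and
#' weight to kg via their unit-code columns, sex to `female`/`male`,
#' reporter occupation codes to
#' `health_professional`/`consumer`/`other`. Values that cannot be
#' normalized become `NA` — never a sentinel number. Child rows whose
#' `primaryid` has no DEMO row are orphans: they are dropped and counted in
#' the assembly log (`attr(x, "assembly_log")`).
#'
#' Note this performs no deduplication; run [deduplicate()] on the result.
#'
#' @param quarters a `faers_raw_quarter` or list of them (one per quarter).
#' @return a [faers_reports] object covering all quarters, with the union
#'   of the quarters' deleted-case lists in `attr(x, "deleted_caseids")`.
#' @export
assemble_reports <- function(quarters) {
  if (inherits(quarters, "faers_raw_quarter")) {
    quarters <- list(quarters)
  }
  demo_list <- list()
  drug_list <- list()
  reac_list <- list()
  outc_list <- list()
  deleted <- character()
  orphans <- c(drug = 0L, reac = 0L, outc = 0L, ther = 0L, indi = 0L)

  for (q in quarters) {
    stopifnot(inherits(q, "faers_raw_quarter"))
    t <- q$tables
    demo_raw <- t$demo
    demo <- tibble::tibble(
      primaryid = trimws(demo_raw$primaryid),
      caseid = trimws(demo_raw$caseid),
      quarter = q$quarter,
      event_dt = col_or_na(demo_raw, "event_dt"),
      sex = map_sex(col_or_na(demo_raw, "sex")),
      age_years = normalize_age_years(
        col_or_na(demo_raw, "age"), col_or_na(demo_raw, "age_cod")
      ),
      weight_kg = normalize_weight_kg(
        col_or_na(demo_raw, "wt"), col_or_na(demo_raw, "wt_cod")
      ),
      country = dplyr::na_if(trimws(col_or_na(demo_raw, "reporter_country")), ""),
      reporter = map_reporter(col_or_na(demo_raw, "occp_cod"))
    )
    ids <- demo$primaryid

    drugs <- NULL
    if (!is.null(t$drug)) {
      drugs <- tibble::tibble(
        primaryid = trimws(t$drug$primaryid),
        drug_seq = trimws(t$drug$drug_seq),
        drugname = t$drug$drugname,
        prod_ai = t$drug$prod_ai,
        role_cod = toupper(trimws(t$drug$role_cod))
      )
      orphans["drug"] <- orphans["drug"] + sum(!drugs$primaryid %in% ids)
      drugs <- dplyr::filter(drugs, .data$primaryid %in% ids)
      if (!is.null(t$ther)) {
        ther <- tibble::tibble(
          primaryid = trimws(t$ther$primaryid),
          drug_seq = trimws(t$ther$dsg_drug_seq),
          start_dt = t$ther$start_dt
        )
        orphans["ther"] <- orphans["ther"] + sum(!ther$primaryid %in% ids)
        ther <- dplyr::filter(ther, .data$primaryid %in% ids)
        ther <- dplyr::distinct(ther, .data$primaryid, .data$drug_seq, .keep_all = TRUE)
        drugs <- dplyr::left_join(drugs, ther, by = c("primaryid", "drug_seq"))
      }
      if (!"start_dt" %in% names(drugs)) drugs$start_dt <- NA_character_
      if (!is.null(t$indi)) {
        indi <- tibble::tibble(
          primaryid = trimws(t$indi$primaryid),
          drug_seq = trimws(t$indi$indi_drug_seq),
          indi_pt = t$indi$indi_pt
        )
        orphans["indi"] <- orphans["indi"] + sum(!indi$primaryid %in% ids)
        indi <- dplyr::filter(indi, .data$primaryid %in% ids)
        indi <- dplyr::distinct(indi, .data$primaryid, .data$drug_seq, .keep_all = TRUE)
        drugs <- dplyr::left_join(drugs, indi, by = c("primaryid", "drug_seq"))
      }
      if (!"indi_pt" %in% names(drugs)) drugs$indi_pt <- NA_character_
      drugs$start_dt[is.na(drugs$start_dt)] <- ""
    }

    reacs <- NULL
    if (!is.null(t$reac)) {
      reacs <- tibble::tibble(
        primaryid = trimws(t$reac$primaryid),
        pt = trimws(t$reac$pt)
      )
      orphans["reac"] <- orphans["reac"] + sum(!reacs$primaryid %in% ids)
      reacs <- dplyr::filter(reacs, .data$primaryid %in% ids, nzchar(.data$pt))
    }

    outc <- NULL
    if (!is.null(t$outc)) {
      outc <- tibble::tibble(
        primaryid = trimws(t$outc$primaryid),
        outc_cod = toupper(trimws(t$outc$outc_cod))
      )
      orphans["outc"] <- orphans["outc"] + sum(!outc$primaryid %in% ids)
      outc <- dplyr::filter(outc, .data$primaryid %in% ids, nzchar(.data$outc_cod))
    }

    demo_list[[length(demo_list) + 1L]] <- demo
    if (!is.null(drugs)) drug_list[[length(drug_list) + 1L]] <- drugs
    if (!is.null(reacs)) reac_list[[length(reac_list) + 1L]] <- reacs
    if (!is.null(outc)) outc_list[[length(outc_list) + 1L]] <- outc
    deleted <- union(deleted, q$deleted)
  }

  out <- faers_reports(
    demo = dplyr::bind_rows(demo_list),
    drugs = if (length(drug_list)) dplyr::bind_rows(drug_list) else NULL,
    reacs = if (length(reac_list)) dplyr::bind_rows(reac_list) else NULL,
    outcomes = if (length(outc_list)) dplyr::bind_rows(outc_list) else NULL
  )
  attr(out, "deleted_caseids") <- deleted
  attr(out, "assembly_log") <- list(orphans_dropped = orphans)
  out
}

#' Deduplicate FAERS reports by deleted-case removal, then highest primaryid
#'
#' FAERS accumulates multiple versions of the same case across quarters.
#' Deduplication first removes every report whose `caseid` appears in the
#' deleted-case lists, then keeps, for each remaining `caseid`, only the
#' report with the largest `primaryid` (numeric comparison when all ids
#' parse as numbers, zero-padded lexicographic otherwise — the fallback is
#' recorded in the log). Output order is ascending `caseid`. The operation
#' is idempotent.
#'
#' @param reports a [faers_reports] object.
#' @param deleted_caseids caseids to drop; defaults to the
#'   `deleted_caseids` attribute set by [assemble_reports()].
#' @return deduplicated [faers_reports]; counters in
#'   `attr(x, "dedup_log")`.
#' @export
deduplicate <- function(reports, deleted_caseids = NULL) {
  stopifnot(inherits(reports, "faers_reports"))
  deleted_caseids <- deleted_caseids %||%
    attr(reports, "deleted_caseids") %||% character()

  demo <- reports$demo
  n_input <- nrow(demo)
  demo <- dplyr::filter(demo, !.data$caseid %in% deleted_caseids)
  n_deleted_removed <- n_input - nrow(demo)

  ord <- primaryid_order_key(demo$primaryid)
  demo$.pid_key <- ord$key
  demo <- demo |>
    dplyr::group_by(.data$caseid) |>
    dplyr::slice_max(.data$.pid_key, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  n_duplicates_removed <- (n_input - n_deleted_removed) - nrow(demo)

  case_ord <- primaryid_order_key(demo$caseid)
  demo <- demo[order(case_ord$key), , drop = FALSE]
  demo$.pid_key <- NULL

  out <- filter_reports(reports, demo$primaryid)
  out$demo <- demo
  attr(out, "deleted_caseids") <- character()
  attr(out, "dedup_log") <- list(
    n_input = n_input,
    n_deleted_removed = n_deleted_removed,
    n_duplicates_removed = n_duplicates_removed,
    n_output = nrow(demo),
    primaryid_fallback = ord$fallback
  )
  out
}
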