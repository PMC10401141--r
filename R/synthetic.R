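#' Configuration for the synthetic FAERS generator
#'
#' Describes a simulated spontaneous-reporting universe: a target drug
#' reported as primary suspect in a fraction of reports, a pool of
#' background drugs, a MedDRA PT event pool with planted drug-event
#' associations of known odds ratio, demographics with realistic
#' missingness, outcome-code probabilities, a Weibull time-to-onset model,
#' and the FAERS warts that the ingestion stage must survive: duplicate
#' case versions, deleted cases, partial dates and concomitant drugs.
#'
#' The defaults emulate the case mix of an atypical-antipsychotic cardiac
#' safety question: quetiapine as target drug, the 31 cardiac PTs of its
#' published signal list as event pool (one of them planted with odds
#' ratio about 11), roughly 5% target-drug share, about 85% serious
#' reports, a short-latency Weibull(scale 5 d, shape 0.3) onset model with
#' 25% date availability, 5% duplicated caseids and 1% deleted cases.
#'
#' @param n_reports number of base reports (before duplication).
#' @param seed integer RNG seed; the whole simulation is deterministic in it.
#' @param quarters quarter labels reports are spread over uniformly.
#' @param target_drug_names `drugname` strings used for the target drug
#'   (generic and trade forms).
#' @param target_prod_ai active-ingredient string for the target drug.
#' @param background_drug_pool `drugname` pool for non-target reports and
#'   concomitant medication.
#' @param event_pool tibble with columns `pt`, `soc`: the PT universe.
#' @param planted_assoc tibble with columns `pt`, `p1`, `p0`: occurrence
#'   probability of `pt` given a target-drug report (`p1`) versus a
#'   background report (`p0`).
#' @param p_background_event occurrence probability of every non-planted
#'   pool PT (identical in both groups, i.e. null association).
#' @param filler_pts PTs assigned when a report would otherwise have no
#'   reaction (FAERS reports always carry at least one).
#' @param p_target_drug probability the primary-suspect drug is the target.
#' @param demography list of marginals and missingness rates (see defaults).
#' @param outcome_probs named per-code probabilities for the seven serious
#'   outcome codes; drawn independently per report.
#' @param tto_model list with `scale` (days), `shape`, and `p_dates`, the
#'   fraction of reports with day-precision start and event dates.
#' @param p_negative_tto fraction of dated reports given an event date
#'   before therapy start (input errors the TTO stage must exclude).
#' @param dup_fraction fraction of caseids emitted twice under a larger
#'   primaryid (a revised report version).
#' @param deleted_fraction fraction of caseids put on the deleted list
#'   (sampled after duplication, so every version vanishes).
#' @param concomitant_rate Poisson mean of non-primary-suspect drugs per
#'   report.
#' @param indication_pool named probabilities for the target drug's
#'   indication PT; `p_indication_missing` reports carry none.
#' @param p_indication_missing see above.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_reports = 20000L,
    seed = 1L,
    quarters = default_quarters(),
    target_drug_names = c("QUETIAPINE FUMARATE", "SEROQUEL"),
    target_prod_ai = "QUETIAPINE FUMARATE",
    background_drug_pool = default_background_drugs(),
    event_pool = default_event_pool(),
    planted_assoc = tibble::tibble(pt = "Tachycardia", p1 = 0.10, p0 = 0.01),
    p_background_event = 0.008,
    filler_pts = c("Nausea", "Headache", "Fatigue"),
    p_target_drug = 0.05,
    demography = list(
      p_female = 0.55, p_sex_missing = 0.075,
      age_meanlog = log(44), age_sdlog = 0.55, p_age_missing = 0.21,
      wt_mean = 75, wt_sd = 18, p_wt_missing = 0.72,
      countries = c(
        US = 0.30, GB = 0.16, DE = 0.10, CA = 0.10, IT = 0.06, FR = 0.05,
        JP = 0.04, AU = 0.04, BR = 0.03, ES = 0.12
      ),
      reporters = c(health_professional = 0.65, consumer = 0.27, other = 0.08)
    ),
    outcome_probs = c(
      DE = 0.14, LT = 0.11, HO = 0.40, DS = 0.045, CA = 0.004, RI = 0.004,
      OT = 0.62
    ),
    tto_model = list(scale = 5, shape = 0.3, p_dates = 0.25),
    p_negative_tto = 0.01,
    dup_fraction = 0.05,
    deleted_fraction = 0.01,
    concomitant_rate = 2,
    indication_pool = c(
      "Schizophrenia" = 0.35, "Bipolar disorder" = 0.30, "Depression" = 0.20,
      "Insomnia" = 0.10, "Pain" = 0.05
    ),
    p_indication_missing = 0.5) {
  cfg <- list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    quarters = quarters, target_drug_names = target_drug_names,
    target_prod_ai = target_prod_ai,
    background_drug_pool = background_drug_pool,
    event_pool = tibble::as_tibble(event_pool),
    planted_assoc = tibble::as_tibble(planted_assoc),
    p_background_event = p_background_event, filler_pts = filler_pts,
    p_target_drug = p_target_drug, demography = demography,
    outcome_probs = outcome_probs, tto_model = tto_model,
    p_negative_tto = p_negative_tto, dup_fraction = dup_fraction,
    deleted_fraction = deleted_fraction, concomitant_rate = concomitant_rate,
    indication_pool = indication_pool,
    p_indication_missing = p_indication_missing
  )
  if (cfg$n_reports < 0L) stop("config error: n_reports must be >= 0")
  if (!length(cfg$target_drug_names)) stop("config error: empty target_drug_names")
  if (!length(cfg$background_drug_pool)) stop("config error: empty background_drug_pool")
  if (!nrow(cfg$event_pool)) stop("config error: empty event_pool")
  if (anyDuplicated(cfg$event_pool$pt)) stop("config error: event_pool PTs must be unique")
  probs <- c(
    cfg$p_background_event, cfg$p_target_drug, cfg$dup_fraction,
    cfg$deleted_fraction, cfg$planted_assoc$p1, cfg$planted_assoc$p0,
    cfg$outcome_probs, cfg$tto_model$p_dates, cfg$p_negative_tto
  )
  if (any(probs < 0 | probs > 1)) stop("config error: probabilities must be in [0, 1]")
  if (cfg$tto_model$scale <= 0 || cfg$tto_model$shape <= 0) {
    stop("config error: Weibull scale and shape must be positive")
  }
  if (!all(cfg$planted_assoc$pt %in% cfg$event_pool$pt)) {
    stop("config error: planted PTs must be drawn from event_pool")
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_quarters <- function() {
  c(
    paste0(rep(2018:2021, each = 4), "Q", rep(1:4, times = 4)),
    "2022Q1"
  )
}

#' @rdname sim_config
#' @export
default_background_drugs <- function() {
  c(
    "LORAZEPAM", "SERTRALINE HYDROCHLORIDE", "MIRTAZAPINE", "ARIPIPRAZOLE",
    "LAMOTRIGINE", "VENLAFAXINE HYDROCHLORIDE", "CLONAZEPAM", "ASPIRIN",
    "RISPERIDONE", "DIAZEPAM", "OLANZAPINE", "TRAZODONE HYDROCHLORIDE",
    "ACETAMINOPHEN", "ESCITALOPRAM OXALATE", "GABAPENTIN", "PREGABALIN",
    "LEVOTHYROXINE SODIUM", "METFORMIN HYDROCHLORIDE", "ZOPICLONE",
    "FLUOXETINE HYDROCHLORIDE", "IBUPROFEN", "OMEPRAZOLE", "LISINOPRIL",
    "METOPROLOL TARTRATE", "WARFARIN SODIUM", "SIMVASTATIN", "AMLODIPINE",
    "PREDNISONE", "CITALOPRAM", "ATORVASTATIN CALCIUM"
  )
}

#' @rdname sim_config
#' @export
default_event_pool <- function() {
  cardiac <- c(
    "Dizziness", "Tachycardia", "Cardiorespiratory arrest", "Palpitations",
    "Syncope", "Sinus tachycardia", "Cardiac arrest", "Arrhythmia",
    "Bradycardia", "Myocarditis", "Atrial septal defect", "Cardiogenic shock",
    "Torsade de pointes", "Cardiomyopathy", "Dizziness postural",
    "Ventricular extrasystoles", "Cyanosis", "Cardiovascular disorder",
    "Ventricular tachycardia", "Long QT syndrome", "Ventricular fibrillation",
    "Ventricular septal defect", "Congestive cardiomyopathy",
    "Brugada syndrome", "Tricuspid valve incompetence",
    "Supraventricular tachycardia", "Patent ductus arteriosus",
    "Ventricular arrhythmia", "Tachyarrhythmia", "Bundle branch block right",
    "Extrasystoles"
  )
  other <- tibble::tibble(
    pt = c("Nausea", "Vomiting", "Headache", "Insomnia", "Rash", "Fatigue"),
    soc = c(
      "Gastrointestinal disorders", "Gastrointestinal disorders",
      "Nervous system disorders", "Psychiatric disorders",
      "Skin and subcutaneous tissue disorders",
      "General disorders and administration site conditions"
    )
  )
  dplyr::bind_rows(
    tibble::tibble(pt = cardiac, soc = "Cardiac disorders"),
    other
  )
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate a FAERS-shaped reporting universe with known ground truth
#'
#' Draws `n_reports` independent safety reports per the configuration:
#' exactly one primary-suspect drug each (the target drug with probability
#' `p_target_drug`), Poisson-many concomitant drugs, reaction PTs drawn per
#' the planted and background probabilities (at least one PT per report),
#' independent outcome codes, demographics with missingness, and — for a
#' configured fraction — day-precision therapy-start and event dates whose
#' difference is a rounded Weibull draw. A fraction of caseids is then
#' re-emitted under a larger primaryid (with an edited weight, simulating a
#' report revision) and a fraction is placed on the deleted-case list.
#'
#' @param config a [sim_config()].
#' @return list with elements `reports` (a [faers_reports] including the
#'   duplicate versions, with the deleted list in
#'   `attr(reports, "deleted_caseids")`), `truth` (planted 2x2 cell
#'   probabilities and implied odds ratios, duplicate lineage, deleted
#'   caseids, true time-to-onset values, target flags, implied serious
#'   rate) and `expected` (the deduplicated [faers_reports] a correct
#'   ingestion stage must recover).
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  dem <- config$demography

  if (n == 0L) {
    empty <- faers_reports(tibble::tibble(
      primaryid = character(), caseid = character(), quarter = character(),
      event_dt = character(), sex = character(), age_years = numeric(),
      weight_kg = numeric(), country = character(), reporter = character()
    ))
    attr(empty, "deleted_caseids") <- character()
    return(list(
      reports = empty, expected = empty,
      truth = list(
        planted = planted_truth(config), duplicates = tibble::tibble(),
        deleted = character(), tto = tibble::tibble(),
        target = tibble::tibble(), implied_serious_rate = implied_serious_rate(config)
      )
    ))
  }

  caseid <- as.character(100000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")
  quarter <- sample(config$quarters, n, replace = TRUE)

  sex <- ifelse(runif(n) < dem$p_female, "female", "male")
  sex[runif(n) < dem$p_sex_missing] <- NA_character_
  age <- pmin(pmax(round(rlnorm(n, dem$age_meanlog, dem$age_sdlog)), 1), 100)
  age[runif(n) < dem$p_age_missing] <- NA_real_
  wt <- round(pmin(pmax(rnorm(n, dem$wt_mean, dem$wt_sd), 30), 200), 1)
  wt[runif(n) < dem$p_wt_missing] <- NA_real_
  country <- sample_cat(n, dem$countries)
  reporter <- sample_cat(n, dem$reporters)

  is_target <- runif(n) < config$p_target_drug

  # --- dates and time-to-onset -------------------------------------------
  has_dates <- runif(n) < config$tto_model$p_dates
  start_date <- as.Date("2018-01-01") + floor(runif(n, 0, 1400))
  tto_true <- rweibull(n, shape = config$tto_model$shape, scale = config$tto_model$scale)
  is_negative <- has_dates & runif(n) < config$p_negative_tto
  event_date <- start_date + round(tto_true)
  event_date[is_negative] <- start_date[is_negative] - sample(1:30, sum(is_negative), replace = TRUE)

  event_dt <- rep("", n)
  start_dt <- rep("", n)
  event_dt[has_dates] <- format(event_date[has_dates], "%Y%m%d")
  start_dt[has_dates] <- format(start_date[has_dates], "%Y%m%d")
  # undated reports: some carry degraded event-date precision, no start date
  degraded <- !has_dates & runif(n) < 0.4
  month_prec <- degraded & runif(n) < 0.75
  event_dt[month_prec] <- format(event_date[month_prec], "%Y%m")
  event_dt[degraded & !month_prec] <- format(event_date[degraded & !month_prec], "%Y")

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, quarter = quarter,
    event_dt = event_dt, sex = sex, age_years = age, weight_kg = wt,
    country = country, reporter = reporter
  )

  # --- drugs --------------------------------------------------------------
  ps_name <- character(n)
  ps_ai <- character(n)
  n_t <- sum(is_target)
  ps_name[is_target] <- sample(config$target_drug_names, n_t, replace = TRUE)
  ps_ai[is_target] <- config$target_prod_ai
  bg <- sample(config$background_drug_pool, n - n_t, replace = TRUE)
  ps_name[!is_target] <- bg
  ps_ai[!is_target] <- bg

  indi <- rep(NA_character_, n)
  with_indi <- runif(n) >= config$p_indication_missing
  indi[with_indi] <- sample_cat(sum(with_indi), config$indication_pool)

  ps_rows <- tibble::tibble(
    primaryid = primaryid, drug_seq = "1", drugname = ps_name,
    prod_ai = ps_ai, role_cod = "PS", start_dt = start_dt, indi_pt = indi
  )

  n_con <- rpois(n, config$concomitant_rate)
  con_idx <- rep.int(seq_len(n), n_con)
  con_rows <- NULL
  if (length(con_idx)) {
    con_rows <- tibble::tibble(
      primaryid = primaryid[con_idx],
      drug_seq = as.character(unlist(lapply(n_con[n_con > 0], function(k) seq_len(k) + 1L))),
      drugname = sample(config$background_drug_pool, length(con_idx), replace = TRUE),
      prod_ai = NA_character_,
      role_cod = sample(c("SS", "C", "I"), length(con_idx), replace = TRUE, prob = c(0.25, 0.6, 0.15)),
      start_dt = "", indi_pt = NA_character_
    )
    con_rows$prod_ai <- con_rows$drugname
  }
  drugs <- dplyr::bind_rows(ps_rows, con_rows) |>
    dplyr::arrange(.data$primaryid, as.integer(.data$drug_seq))

  # --- reactions ----------------------------------------------------------
  planted <- config$planted_assoc
  reac_list <- vector("list", nrow(config$event_pool))
  for (i in seq_len(nrow(config$event_pool))) {
    pt_i <- config$event_pool$pt[i]
    j <- match(pt_i, planted$pt)
    p <- if (!is.na(j)) {
      ifelse(is_target, planted$p1[j], planted$p0[j])
    } else if (pt_i %in% config$filler_pts) {
      rep(0.12, n)
    } else {
      rep(config$p_background_event, n)
    }
    hit <- runif(n) < p
    if (any(hit)) {
      reac_list[[i]] <- tibble::tibble(primaryid = primaryid[hit], pt = pt_i)
    }
  }
  reacs <- dplyr::bind_rows(reac_list)
  none <- !primaryid %in% reacs$primaryid
  if (any(none)) {
    reacs <- dplyr::bind_rows(reacs, tibble::tibble(
      primaryid = primaryid[none],
      pt = sample(config$filler_pts, sum(none), replace = TRUE)
    ))
  }
  reacs <- dplyr::arrange(reacs, .data$primaryid, .data$pt)

  # --- outcomes ------------------------------------------------------------
  oc <- config$outcome_probs
  outc_list <- lapply(names(oc), function(code) {
    hit <- runif(n) < oc[[code]]
    tibble::tibble(primaryid = primaryid[hit], outc_cod = code)
  })
  outcomes <- dplyr::bind_rows(outc_list) |>
    dplyr::arrange(.data$primaryid, .data$outc_cod)

  # --- duplicate versions and deleted cases --------------------------------
  n_dup <- floor(config$dup_fraction * n)
  dup_idx <- sort(sample.int(n, n_dup))
  dup_caseid <- caseid[dup_idx]
  dup_map <- tibble::tibble(
    caseid = dup_caseid,
    primaryid_v1 = primaryid[dup_idx],
    primaryid_v2 = paste0(dup_caseid, "2")
  )

  clone_rows <- function(tab) {
    cl <- dplyr::inner_join(
      tab, dplyr::select(dup_map, primaryid = "primaryid_v1", "primaryid_v2"),
      by = "primaryid"
    )
    cl$primaryid <- cl$primaryid_v2
    dplyr::select(cl, -"primaryid_v2")
  }
  demo_v2 <- clone_rows(demo)
  # the revision edits a field: weight re-measured
  demo_v2$weight_kg <- ifelse(is.na(demo_v2$weight_kg), NA_real_, demo_v2$weight_kg + 0.5)

  reports <- faers_reports(
    demo = dplyr::bind_rows(demo, demo_v2),
    drugs = dplyr::bind_rows(drugs, clone_rows(drugs)),
    reacs = dplyr::bind_rows(reacs, clone_rows(reacs)),
    outcomes = dplyr::bind_rows(outcomes, clone_rows(outcomes))
  )

  n_del <- floor(config$deleted_fraction * n)
  deleted <- sort(sample(caseid, n_del))
  attr(reports, "deleted_caseids") <- deleted

  # expected post-dedup collection: deleted cases out, v2 wins where present
  surv <- demo
  surv$primaryid[match(dup_map$caseid, surv$caseid)] <- dup_map$primaryid_v2
  surv <- dplyr::filter(surv, !.data$caseid %in% deleted)
  expected <- filter_reports(reports, surv$primaryid)
  expected$demo <- expected$demo[order(as.numeric(expected$demo$caseid)), ]
  attr(expected, "deleted_caseids") <- character()

  truth <- list(
    planted = planted_truth(config),
    duplicates = dup_map,
    deleted = deleted,
    tto = tibble::tibble(
      primaryid = primaryid, caseid = caseid, has_dates = has_dates,
      is_negative = is_negative, tto_true = tto_true,
      tto_recorded = as.numeric(event_date - start_date)
    ),
    target = tibble::tibble(
      primaryid = primaryid, caseid = caseid, is_target = is_target
    ),
    implied_serious_rate = implied_serious_rate(config)
  )
  list(reports = reports, truth = truth, expected = expected)
}

planted_truth <- function(config) {
  pl <- config$planted_assoc
  pt_share <- config$p_target_drug
  tibble::tibble(
    pt = pl$pt, p1 = pl$p1, p0 = pl$p0,
    implied_or = (pl$p1 / (1 - pl$p1)) / (pl$p0 / (1 - pl$p0)),
    p_a = pt_share * pl$p1, p_b = pt_share * (1 - pl$p1),
    p_c = (1 - pt_share) * pl$p0, p_d = (1 - pt_share) * (1 - pl$p0)
  )
}

implied_serious_rate <- function(config) {
  1 - prod(1 - config$outcome_probs)
}

# ---- serialization -------------------------------------------------------

fmt_num <- function(x) ifelse(is.na(x), "", as.character(x))

#' Write reports as FAERS Quarterly Data Extract ASCII files
#'
#' Serializes one quarter's reports into the `$`-delimited dialect that
#' [read_quarter()] ingests: `demo.txt`, `drug.txt`, `reac.txt`,
#' `outc.txt`, `ther.txt`, `indi.txt` and `deleted.txt`. Fields are written
#' losslessly: partial dates at their stored precision, sex as `F`/`M`,
#' age in years (`age_cod` `YR`), weight in kg (`wt_cod` `KG`), reporter
#' as occupation code (`MD`/`CN`/`LW`), missing values as empty fields.
#' Therapy rows are emitted only for drug entries with a start date,
#' indication rows only for entries with an indication PT.
#'
#' @param reports a [faers_reports] object.
#' @param directory output directory (created if needed).
#' @param quarter_label which quarter of `reports` to write.
#' @param deleted_caseids caseids for `deleted.txt`; defaults to the
#'   attribute on `reports`, intersected with the quarter's caseids.
#' @return `directory`, invisibly.
#' @export
write_quarter <- function(reports, directory, quarter_label,
                          deleted_caseids = NULL) {
  stopifnot(inherits(reports, "faers_reports"))
  deleted_caseids <- deleted_caseids %||%
    attr(reports, "deleted_caseids") %||% character()
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)

  demo <- dplyr::filter(reports$demo, .data$quarter == quarter_label)
  ids <- demo$primaryid
  sub <- filter_reports(reports, ids)

  demo_out <- tibble::tibble(
    primaryid = demo$primaryid, caseid = demo$caseid,
    event_dt = demo$event_dt,
    sex = dplyr::case_match(demo$sex, "female" ~ "F", "male" ~ "M", .default = ""),
    age = fmt_num(demo$age_years),
    age_cod = ifelse(is.na(demo$age_years), "", "YR"),
    wt = fmt_num(demo$weight_kg),
    wt_cod = ifelse(is.na(demo$weight_kg), "", "KG"),
    reporter_country = ifelse(is.na(demo$country), "", demo$country),
    occp_cod = dplyr::case_match(
      demo$reporter,
      "health_professional" ~ "MD", "consumer" ~ "CN", .default = "LW"
    )
  )
  wd <- function(tab, file) {
    readr::write_delim(tab, file.path(directory, file), delim = "$", na = "",
                       progress = FALSE)
  }
  wd(demo_out, "demo.txt")
  wd(
    dplyr::select(sub$drugs, "primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    "drug.txt"
  )
  wd(dplyr::select(sub$reacs, "primaryid", "pt"), "reac.txt")
  wd(dplyr::select(sub$outcomes, "primaryid", "outc_cod"), "outc.txt")
  ther <- sub$drugs |>
    dplyr::filter(!is.na(.data$start_dt), nzchar(.data$start_dt)) |>
    dplyr::select("primaryid", dsg_drug_seq = "drug_seq", "start_dt")
  wd(ther, "ther.txt")
  indi <- sub$drugs |>
    dplyr::filter(!is.na(.data$indi_pt)) |>
    dplyr::select("primaryid", indi_drug_seq = "drug_seq", "indi_pt")
  wd(indi, "indi.txt")
  readr::write_lines(
    intersect(deleted_caseids, demo$caseid),
    file.path(directory, "deleted.txt")
  )
  invisible(directory)
}

#' Write every quarter of a simulated universe under one root directory
#'
#' One subdirectory per quarter label, each laid out as by [write_quarter()].
#'
#' @param reports a [faers_reports] object.
#' @param root_directory output root.
#' @return `root_directory`, invisibly.
#' @export
write_quarters <- function(reports, root_directory) {
  for (q in sort(unique(reports$demo$quarter))) {
    write_quarter(reports, file.path(root_directory, q), q)
  }
  invisible(root_directory)
}

#' Read every quarter directory under a root
#'
#' Companion to [write_quarters()]: each subdirectory name is taken as the
#' quarter label.
#'
#' @param root_directory directory of quarter subdirectories.
#' @return list of `faers_raw_quarter` objects.
#' @export
read_quarters <- function(root_directory) {
  dirs <- list.dirs(root_directory, recursive = FALSE)
  if (!length(dirs)) stop("no quarter directories under ", root_directory)
  lapply(sort(dirs), function(d) read_quarter(d, basename(d)))
}
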