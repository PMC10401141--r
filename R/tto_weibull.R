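#' Compute time-to-onset samples for target-drug case reports
#'
#' TTO is the event date minus the therapy start date of the matched
#' target drug, in whole days. Only day-precision dates enter: reports
#' with a missing or partial event or start date are excluded and counted,
#' as are input errors (event before start). When a report carries several
#' matched target-drug therapy rows, the earliest day-precision start date
#' is used. Because the Weibull support excludes zero but same-day onsets
#' are real and common, exact zeros are shifted to `zero_epsilon` days in
#' the fitting sample (`durations`); the pre-adjustment values are kept in
#' `durations_raw` so a "median 0 days" remains expressible.
#'
#' @param case_reports a [faers_reports] of case reports.
#' @param spec a [cohort_spec()] identifying the target drug entries.
#' @param zero_epsilon replacement for zero-day onsets (default 0.5).
#' @return list of class `tto_sample`: `durations` (positive, adjusted),
#'   `durations_raw`, `primaryid`, `n_excluded_missing`,
#'   `n_excluded_negative`, `n_zero_adjusted`.
#' @export
compute_tto <- function(case_reports, spec, zero_epsilon = 0.5) {
  stopifnot(inherits(case_reports, "faers_reports"), inherits(spec, "cohort_spec"))
  demo <- case_reports$demo
  n_input <- nrow(demo)

  drugs <- case_reports$drugs
  matched <- drugs[
    drug_entry_matches(drugs, spec) & drugs$role_cod %in% spec$role_filter,
  ]
  matched$start_date <- partial_date_to_date(matched$start_dt)
  starts <- matched |>
    dplyr::filter(!is.na(.data$start_date)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_date = min(.data$start_date), .groups = "drop")

  event_date <- partial_date_to_date(demo$event_dt)
  tab <- tibble::tibble(primaryid = demo$primaryid, event_date = event_date) |>
    dplyr::inner_join(starts, by = "primaryid") |>
    dplyr::filter(!is.na(.data$event_date))
  tab$tto <- as.numeric(tab$event_date - tab$start_date)

  n_missing <- n_input - nrow(tab)
  neg <- tab$tto < 0
  n_negative <- sum(neg)
  tab <- tab[!neg, , drop = FALSE]

  raw <- tab$tto
  adjusted <- ifelse(raw == 0, zero_epsilon, raw)
  structure(
    list(
      durations = adjusted,
      durations_raw = raw,
      primaryid = tab$primaryid,
      n_excluded_missing = n_missing,
      n_excluded_negative = n_negative,
      n_zero_adjusted = sum(raw == 0)
    ),
    class = "tto_sample"
  )
}

#' @export
print.tto_sample <- function(x, ...) {
  cat(
    "<tto_sample> n=", length(x$durations),
    " (excluded: ", x$n_excluded_missing, " missing/partial dates, ",
    x$n_excluded_negative, " negative; ", x$n_zero_adjusted,
    " zero-day onsets adjusted)\n",
    sep = ""
  )
  invisible(x)
}

#' Maximum-likelihood Weibull fit with Wald CIs on the log-parameters
#'
#' Fits the two-parameter Weibull
#' `f(t) = (beta/alpha) (t/alpha)^(beta-1) exp(-(t/alpha)^beta)` by
#' maximum likelihood and derives 95% confidence intervals for the scale
#' `alpha` (days) and shape `beta` by the Wald method on the log scale,
#' using standard errors from the observed information matrix. A shape CI
#' entirely below 1 indicates a decreasing hazard (early-failure onset
#' profile); see [classify_failure()].
#'
#' @param sample a `tto_sample` from [compute_tto()], or a numeric vector
#'   of positive durations.
#' @param conf confidence level (default 0.95).
#' @return list of class `weibull_fit`: `alpha`, `beta`, `alpha_ci`,
#'   `beta_ci`, `failure_type`, `n`.
#' @export
weibull_mle <- function(sample, conf = 0.95) {
  x <- if (inherits(sample, "tto_sample")) sample$durations else as.numeric(sample)
  if (length(x) < 3) stop("Weibull fit needs at least 3 durations")
  if (any(x <= 0)) stop("durations must be positive")
  if (stats::sd(x) == 0) {
    stop("degenerate sample (zero variance); Weibull fit cannot converge")
  }
  # tight optimizer tolerance so scale equivariance holds to ~1e-6
  fit <- tryCatch(
    fitdistrplus::fitdist(x, "weibull", control = list(reltol = 1e-12)),
    error = function(e) stop("Weibull MLE did not converge: ", conditionMessage(e))
  )
  est <- fit$estimate # shape, scale
  se <- fit$sd
  if (anyNA(se) || any(se <= 0)) {
    stop("Weibull MLE did not yield a usable information matrix")
  }
  z <- qnorm(1 - (1 - conf) / 2)
  ci_log <- function(theta, se_theta) {
    exp(log(theta) + c(-1, 1) * z * se_theta / theta)
  }
  out <- structure(
    list(
      alpha = unname(est["scale"]),
      beta = unname(est["shape"]),
      alpha_ci = ci_log(est[["scale"]], se[["scale"]]),
      beta_ci = ci_log(est[["shape"]], se[["shape"]]),
      n = length(x)
    ),
    class = "weibull_fit"
  )
  out$failure_type <- classify_failure(out)
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n=%d  alpha=%.3g (%.3g-%.3g)  beta=%.3g (%.3g-%.3g)  %s\n",
    x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], x$failure_type
  ))
  invisible(x)
}

#' Classify the hazard profile from the Weibull shape CI
#'
#' Early failure (hazard decreasing over time) when the 95% CI of the
#' shape lies entirely below 1; wear-out (increasing hazard) when it lies
#' entirely above 1; random (roughly constant hazard) when the CI contains
#' 1. Exactly one label applies to any valid CI.
#'
#' @param fit a `weibull_fit`, or a length-2 numeric CI for the shape.
#' @return `"early"`, `"random"` or `"wear_out"`.
#' @export
classify_failure <- function(fit) {
  ci <- if (inherits(fit, "weibull_fit")) fit$beta_ci else as.numeric(fit)
  stopifnot(length(ci) == 2, all(ci > 0), ci[1] <= ci[2])
  if (ci[2] < 1) {
    "early"
  } else if (ci[1] > 1) {
    "wear_out"
  } else {
    "random"
  }
}

#' Pooled time-to-onset analysis by clinical-priority level
#'
#' Pools the TTO values of all signal PTs within each priority level (a
#' report whose PTs span both levels contributes to both) and reports the
#' sample size, median and IQR, range, and — when at least `min_fit`
#' durations are available — the Weibull fit and its failure-type label.
#'
#' @param case_reports a [faers_reports] of case reports.
#' @param scored output of [score_all()] (needs `pt` and `level`).
#' @param spec a [cohort_spec()].
#' @param zero_epsilon passed to [compute_tto()].
#' @param min_fit minimum sample size for fitting (default 3).
#' @return tibble with one row per level: `level`, `n`, `median`, `q1`,
#'   `q3`, `min`, `max`, `alpha`, `alpha_low`, `alpha_high`, `beta`,
#'   `beta_low`, `beta_high`, `failure_type`.
#' @export
tto_by_priority <- function(case_reports, scored, spec, zero_epsilon = 0.5,
                            min_fit = 3L) {
  stopifnot(inherits(case_reports, "faers_reports"))
  tto <- compute_tto(case_reports, spec, zero_epsilon)
  have <- tibble::tibble(
    primaryid = tto$primaryid,
    raw = tto$durations_raw,
    adj = tto$durations
  )
  reac <- dplyr::distinct(case_reports$reacs, .data$primaryid, .data$pt)

  rows <- lapply(c("weak", "moderate", "strong"), function(lev) {
    pts <- scored$pt[scored$level == lev]
    if (!length(pts)) {
      return(NULL)
    }
    ids <- unique(reac$primaryid[reac$pt %in% pts])
    sub <- have[have$primaryid %in% ids, , drop = FALSE]
    if (!nrow(sub)) {
      return(NULL)
    }
    q <- unname(quantile(sub$raw, c(0.25, 0.5, 0.75), type = 7))
    row <- tibble::tibble(
      level = lev, n = nrow(sub),
      median = q[2], q1 = q[1], q3 = q[3],
      min = min(sub$raw), max = max(sub$raw),
      alpha = NA_real_, alpha_low = NA_real_, alpha_high = NA_real_,
      beta = NA_real_, beta_low = NA_real_, beta_high = NA_real_,
      failure_type = NA_character_
    )
    if (nrow(sub) >= min_fit && stats::sd(sub$adj) > 0) {
      fit <- weibull_mle(sub$adj)
      row$alpha <- fit$alpha
      row$alpha_low <- fit$alpha_ci[1]
      row$alpha_high <- fit$alpha_ci[2]
      row$beta <- fit$beta
      row$beta_low <- fit$beta_ci[1]
      row$beta_high <- fit$beta_ci[2]
      row$failure_type <- fit$failure_type
    }
    row
  })
  dplyr::bind_rows(rows)
}
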