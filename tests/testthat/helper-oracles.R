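# Independent oracles used across the suite. Each one recomputes a quantity
# by a route disjoint from the implementation it checks.

# Two-sided Fisher exact p by exhaustive enumeration: condition on the
# observed margins, enumerate every feasible table, and sum the
# hypergeometric probabilities of tables no more probable than the observed
# one (with a small relative tolerance against floating-point ties, as is
# conventional).
fisher_enum_oracle <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U of sample a by brute-force pair counting (ties count 1/2).
mw_u_oracle <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# Exact permutation p-value for the Mann-Whitney U: enumerate all splits of
# the pooled sample into groups of the observed sizes.
mw_perm_p_oracle <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  u_obs <- mw_u_oracle(a, b)
  mu <- n1 * length(b) / 2
  us <- apply(idx, 2, function(i) mw_u_oracle(pool[i], pool[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Odds ratio and Wald CI from a saturated logistic regression: an
# independent route to the same estimand as the ROR engine.
glm_or_oracle <- function(a, b, c, d, z = 1.959964) {
  df <- data.frame(
    event = c(1, 0, 1, 0),
    drug = c(1, 1, 0, 0),
    w = c(a, b, c, d)
  )
  # saturated model: start IRLS at the exact MLE (the observed logits) so
  # the information matrix is evaluated at the optimum to machine precision
  fit <- stats::glm(
    event ~ drug,
    family = stats::binomial(), data = df, weights = df$w,
    start = c(log(c / d), log(a / b) - log(c / d)),
    control = stats::glm.control(epsilon = 1e-14, maxit = 100)
  )
  co <- stats::coef(fit)[["drug"]]
  se <- sqrt(stats::vcov(fit)["drug", "drug"])
  c(or = exp(co), low = exp(co - z * se), high = exp(co + z * se))
}

# Small literal report collection for join/dedup unit tests.
make_reports <- function(demo, drugs = NULL, reacs = NULL, outcomes = NULL) {
  defaults <- tibble::tibble(
    primaryid = demo$primaryid,
    caseid = if ("caseid" %in% names(demo)) demo$caseid else demo$primaryid,
    quarter = "2018Q1",
    event_dt = "",
    sex = NA_character_,
    age_years = NA_real_,
    weight_kg = NA_real_,
    country = NA_character_,
    reporter = "other"
  )
  for (col in names(demo)) defaults[[col]] <- demo[[col]]
  faers_reports(defaults, drugs = drugs, reacs = reacs, outcomes = outcomes)
}

# Arrange every component table so two collections can be compared
# field-by-field regardless of storage order.
sort_reports <- function(x) {
  x$demo <- x$demo[order(as.numeric(x$demo$primaryid)), ]
  x$drugs <- x$drugs[order(as.numeric(x$drugs$primaryid), as.integer(x$drugs$drug_seq)), ]
  x$reacs <- x$reacs[order(as.numeric(x$reacs$primaryid), x$reacs$pt), ]
  x$outcomes <- x$outcomes[order(as.numeric(x$outcomes$primaryid), x$outcomes$outc_cod), ]
  x
}
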