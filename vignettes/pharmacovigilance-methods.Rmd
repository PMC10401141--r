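---
title: "Methods: disproportionality signal detection and prioritization for FAERS reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and prioritization for FAERS reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersror)
```

## The problem and the data model

Spontaneous adverse-event reporting systems such as FAERS collect safety
reports submitted by health professionals, consumers and manufacturers.
Because there is no denominator of exposed patients, incidence cannot be
estimated; instead, *disproportionality analysis* asks whether a target
event is reported relatively more often with a target drug than with all
other drugs. faersror implements that analysis end to end for the FAERS
Quarterly Data Extract dialect: `$`-delimited ASCII tables (DEMO, DRUG,
REAC, OUTC, THER, INDI) plus per-quarter deleted-case lists.

Reports are held relationally (`faers_reports`): one demographics row per
report and child tables of drug mentions, MedDRA preferred-term (PT)
reaction mentions and outcome codes, keyed by `primaryid`. This mirrors
the source format, keeps joins explicit, and makes the counting unit of
every downstream statistic — the report, never the report-event pair —
easy to enforce.

Two ingestion conventions matter and are worth stating precisely:

* **Deduplication.** FAERS re-publishes revised versions of a case across
  quarters. `deduplicate()` first removes every report whose `caseid` is
  on a deleted-case list, then keeps the version with the largest
  `primaryid` per remaining `caseid`. The order matters: removal first
  guarantees a deleted case can never be resurrected by a later, larger
  version. Comparison is numeric when all ids parse as numbers, with a
  zero-padded lexicographic fallback (logged) otherwise.
* **Partial dates.** FAERS dates are 4/6/8-digit numerics. They are
  parsed to an explicit precision (`year`/`month`/`day`); malformed
  values become missing rather than errors, and every analysis that needs
  day arithmetic (time-to-onset) excludes and counts anything below day
  precision rather than imputing. A month-midpoint imputation would
  inflate the short-latency signal this kind of analysis typically looks
  for, so the conservative exclusion is the default.

Demographic unit codes are normalized at assembly time (age DEC/YR/MON/WK/
DY/HR to years; weight KG/LBS/GMS to kg); unknown codes map to missing,
never to a sentinel. Occupation codes MD/PH/HP/OT map to
`health_professional` (OT is FAERS's *other health professional*), CN to
`consumer`, anything else to `other`.

## Reporting odds ratio

For a target drug and a target event, reports are cross-tabulated as

|            | event | no event |
|------------|-------|----------|
| target     | a     | b        |
| other drug | c     | d        |

and the reporting odds ratio is ROR = (a·d)/(b·c) with the Wald interval
exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d)), z = 1.959964. A *signal* is a
PT whose 95% CI lower bound (ROR₀₂₅) exceeds 1 with at least five
reports; the five-report floor is the conventional guard against
small-count false positives. Zero-cell tables return no estimate by
default — the significance rule already requires a ≥ 5, so nothing is
lost — with an optional Haldane–Anscombe +0.5 correction for users who
want an estimate anyway. No multiplicity adjustment is applied across
PTs; this is the field's convention for hypothesis-generating screens,
and the documentation says so rather than hiding it.

The universe for the 2×2 is *all* deduplicated reports in the loaded
window, and non-cases are all non-target-drug reports; the target drug's
reports without the event stay in cell b, as the case/non-case design
prescribes. Subgroup analyses restrict both cases and non-cases to the
stratum before building the table, so each stratum is a self-contained
case/non-case study. The sensitivity analysis removes target-drug case
reports that co-report any drug on the exclusion list in a
non-primary-suspect role (SS/C/I) and recomputes the signal list.

## Serious versus nonserious comparison

A report is serious iff it carries any of the seven FAERS outcome codes
(DE, LT, HO, DS, CA, RI, OT). Proportions are compared with the
*uncorrected* Pearson chi-squared statistic; Yates' continuity correction
is deliberately not applied anywhere, because the corrected statistic is
a different quantity from the plain Σ(O−E)²/E this comparison reports.
When any expected cell falls below 5 the comparison switches to Fisher's
exact test (two-sided, by summation of hypergeometric probabilities no
larger than the observed one). Continuous non-normal variables (age,
weight) use the Mann–Whitney U test. Base R's `wilcox.test` does not
expose the Z statistic, so U and the tie-corrected normal-approximation Z
are computed directly (no continuity correction); the p-value is
cross-checked against `wilcox.test` and the U statistic against a
brute-force pair-counting oracle in the test suite.

## Clinical-priority scoring

Each significant signal is scored 0–2 on five features and the points
summed (maximum 10): case count, ROR₀₂₅, death fraction among cases,
designated/important medical event (DME/IME) membership, and an expert
literature-evidence grade. Composite 0–4 is weak, 5–7 moderate, 8–10
strong priority. The default thresholds are case count <10/10–49/≥50,
ROR₀₂₅ <2/2–<5/≥5, and death fraction <0.25/0.25–<0.50/≥0.50, with
DME = 2, IME = 1, and "++"/"+"/"−" = 2/1/0. The quantitative edges are
validated against a shipped 31-row golden feature table whose published
scores they reproduce exactly. The death-fraction cut-offs are the least
constrained by that table (the data bracket them only to (0.171, 0.297]
and (0.40, 0.556]); 0.25 and 0.50 are round values inside those feasible
intervals and are exposed in `priority_rubric()` for users who know the
exact scheme they want. Evidence grades are expert inputs: `score_all()`
refuses to invent one for a PT missing from the evidence table unless the
caller explicitly supplies a default grade (the pipeline defaults to
"+", a deliberate middling choice for synthetic runs). The shipped
DME/IME assignments are a fixture for tests and demos, not an
authoritative regulatory list.

## Time-to-onset and the Weibull shape test

TTO is the whole-day difference between the event date and the earliest
day-precision therapy start date of the matched target drug. Negative
differences are input errors and are excluded (and counted), as are
reports without both dates at day precision. The two-parameter Weibull is
fitted by maximum likelihood (`fitdistrplus::fitdist`, optimizer
tolerance tightened to 1e−12 so scale equivariance holds to ~1e−6), with
95% CIs by the Wald method on log(α), log(β) using the observed
information, which keeps the bounds positive. The shape CI classifies the
hazard: entirely below 1 → early failure (risk decreases with time on
drug), containing 1 → random, entirely above 1 → wear-out. Correctness of
the interval is established by a coverage property (95% ± 4 pp over 200
simulations at n = 200) rather than by matching any published fit, since
published analyses rarely state their CI method.

Two numerical choices deserve note. Exact zero-day onsets (event on the
day therapy started) are real data, but the Weibull support excludes 0;
they are shifted to 0.5 day before fitting (configurable
`zero_epsilon`), and the pre-adjustment median/IQR is reported so
"median 0 days" remains expressible. An interval-censored likelihood
treating day 0 as (0, 1) would be the fuller model and is a noted
extension. Second, TTO samples are pooled across the PTs within each
priority level rather than fitted per PT; a report whose PTs span both
levels contributes its onset to both pools.

## The synthetic generator

`simulate_faers()` draws an entire reporting universe with known ground
truth so every stage is testable without downloads: one primary-suspect
drug per report (the target with probability 0.05, emulating a
moderately reported drug), Poisson(2) concomitant drugs, reaction PTs
with planted occurrence probabilities (default: one cardiac PT at
p₁ = 0.10 versus p₀ = 0.01, an implied odds ratio of 11), independent
outcome codes tuned to an ~85% serious case mix, demographics with
realistic missingness (age 21%, weight 72% missing), Weibull(scale 5 d,
shape 0.3) onsets with 25% date availability, 5% duplicated caseids
re-emitted under a larger primaryid with an edited field, and 1% deleted
cases sampled after duplication so both versions must vanish. The
generator returns the duplicate lineage, the planted 2×2 cell
probabilities and implied odds ratio, the true onset values, and the
exact post-deduplication survivor set, which the ingestion tests compare
field-by-field.

What it does *not* emulate — and what passing tests therefore do not
show about real data: drug-name misspellings and free-text noise,
correlated missingness, reporting trends over time, country- or
indication-specific case mixes, multiple primary-suspect drugs on one
report, and event-event correlations. Tests on this generator establish
that the statistical machinery is correct under the stated model, not
that FAERS data are clean.

## Problem sizes and determinism

All analysis stages are deterministic; randomness exists only in the
generator and flows from a single seed (fixed seed ⇒ byte-identical
quarterly files). The test suite exercises the pipeline at 20,000
synthetic reports end to end, ROR oracle equivalence on 1,000 random
tables, type-I control on 1,000 null tables of ~2,000 reports, planted-OR
coverage on 100 replicate universes of 2,000 reports, and Weibull
coverage on 200 replicates at n = 200 — sizes chosen to give the
binomial tolerances quoted in the tests while keeping a full run around
a minute.

## Known limitations

* ROR only; PRR, IC and EBGM are out of scope by design.
* No multiplicity control across PTs (stated, not silently absent).
* The Wald ROR interval is asymptotic; with a < 5 it is not relied upon.
* Partial dates are excluded from TTO, biasing the sample toward
  well-documented reports; no imputation is offered.
* The evidence grades and DME/IME lists are inputs, not computations;
  label-based "new signal" determination is likewise out of scope.
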