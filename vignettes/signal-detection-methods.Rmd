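---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
unsolicited case reports linking drugs to coded adverse events. Because
there is no denominator of exposed patients, safety questions are asked
*disproportionally*: is an event reported together with the index drug more
often than the database as a whole would predict? pvsignal implements this
workflow end to end for FAERS-style quarterly ASCII extracts: ingestion and
case deduplication, four disproportionality statistics with a disjunctive
signal gate, subgroup and sensitivity re-analyses, and Weibull modelling of
time to onset. A synthetic corpus generator with a ground-truth sidecar
makes every stage testable without access to the real database.

## Data model and ingestion

A quarterly extract consists of `$`-delimited tables DEMO (one row per case
version), DRUG (drugs with role codes PS/SS/C/I), REAC (coded events as
MedDRA-style preferred terms, PTs), THER (therapy episodes) and optionally
INDI (indications). `read_faers_quarter()` keeps every field as text; dates
stay in their raw 8/6/4-digit form so partial dates remain visible
(`date_completeness()`).

**Deduplication.** Cases are submitted repeatedly as they are amended. Among
rows sharing a CASEID only the version with the most recent FDA receive
date survives; on ties the highest PRIMARYID wins. The operation is
idempotent, and child tables are restricted to surviving versions. When the
receive date is missing within a cluster, ordering falls back to PRIMARYID
with a warning.

**Normalisation.** Drug names are upper-cased, stripped of punctuation, and
resolved through an exact-match synonym table — deliberately no fuzzy
matching, so results are deterministic and auditable. Ages are converted to
years with the standard unit codes (YR x1, MON /12, WK /52.143, DY /365.25,
DEC x10, HR /8766); a present age with a missing unit is treated as years
with a warning. Age bins are half-open — [0,18), [18,65), [65,85),
[85, Inf) — so an exact 85th birthday lands in the top bin; this is the only
free choice the published bin labels leave open. Occupation codes MD, PH,
HP, RN, OT map to healthcare professionals and CN, LW to
non-healthcare professionals. Events are collapsed to a *set* of PTs per
report; PTs absent from the user-supplied PT-to-SOC hierarchy go into an
explicit `UNMAPPED` bucket and are counted, never dropped silently.

**Counting unit.** All downstream 2x2 tables count (report, term) pairs: a
report with k distinct PTs contributes k pairs at PT level and one pair per
distinct system organ class (SOC) at SOC level. The one-pair-per-SOC rule
prevents a report with several PTs in the same organ class from being
counted multiply within that class. Pair-level totals are what make the
reporting odds ratio and proportional reporting ratio of a published table
mutually consistent, which is also what the package's desk-scale validation
exploits (see `scripts/acceptance.R`).

**Indication restriction.** Restricting the index cohort to a target
indication (e.g. one tumour type) is exposed as an optional filter over the
INDI table and is off by default, since how such a restriction is
operationalised varies between studies.

## The four statistics

For a term with cells a (index & term), b (index & other terms), c
(background & term), d (background & other terms), N = a+b+c+d:

* **ROR** = (a d)/(b c), with a Wald 95% interval on the log scale,
  `exp(log ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell triggers
  the Haldane–Anscombe 0.5 correction on all four cells and flags the row,
  keeping every term reportable and the correction auditable.
* **PRR** = [a/(a+b)] / [c/(c+d)], paired with the Pearson chi-square
  `N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`. The Yates continuity correction is
  available behind a flag but off by default. When c = 0 the ratio is
  reported as a flagged infinity with the chi-square computed on corrected
  cells.
* **BCPNN information component** IC = log2((a+0.5)/(E+0.5)) with expected
  count E = (a+b)(a+c)/N, and the lower 2.5% credibility bound via Norén's
  asymptotic approximation IC025 = IC − 3.3(a+0.5)^(−1/2) −
  2.0(a+0.5)^(−3/2). The closed-form shrinkage IC with this bound is used
  rather than the full prior-propagation network; the approximation
  reproduces published (a, IC, IC025) triples to the printed precision, and
  a full posterior implementation is a documented extension point.
* **MGPS / EBGM**, described next.

A useful algebraic identity: ROR > PRR exactly when ROR > 1 (both are
equivalent to ad > bc), with equality at 1. The test suite asserts it on
every computed table; it also explains why published tables show ROR
slightly above PRR for elevated terms and slightly below for deficits.

## The gamma-Poisson shrinker

The empirical-Bayes model treats each observed count as
a ~ Poisson(lambda E) with the relative reporting rate lambda drawn from a
two-component gamma mixture prior. The prior is fitted once per hierarchy
level by maximising the negative-binomial mixture marginal across all
tables, starting from the canonical initial point (0.2, 0.1, 2.0, 4.0,
w = 1/3) and optimising in log-parameter (logit-weight) space with L-BFGS-B,
which enforces positivity and keeps the fit deterministic. Non-convergence
returns the best iterate with a flag.

The posterior for one table is again a two-gamma mixture,
Gamma(alpha_j + a, beta_j + E) with weights updated by the marginal
likelihood ratio. EBGM is reported as the posterior *geometric* mean
`exp(E[ln lambda | a])`, i.e. `exp(q [psi(s1) − ln r1] + (1−q) [psi(s2) − ln
r2])` with psi the digamma function; EBGM05 solves the posterior mixture CDF
= 0.05 by bracketed root finding between the two component quantiles
(tolerance 1e-10). A brute-force quadrature oracle — numerical integration
of the unnormalised posterior on a log-spaced grid with a step-size cap of
5e-4 in log lambda — verifies the closed form to better than 1e-6 relative
error in the test suite; it is test-only and not part of the analysis path.

Published disproportionality tables sometimes print an EBGM column that
coincides with 2^IC, i.e. a simplified transform of the information
component rather than a fitted shrinker. Both conventions are therefore
available: `ebgm_method = "mgps"` (default, method-faithful) and
`ebgm_method = "ic"` (EBGM = 2^IC, EBGM05 = 2^IC025), so a user can either
follow the method or reproduce such a table. Expected counts are not
stratified by demographics; subgroup questions are handled by corpus
subsetting instead.

## Signal gating

A term is declared a potential signal when **at least one** method exceeds
its positivity criterion. The default thresholds are the standard published
ones — ROR lower bound > 1; PRR >= 2 with chi-square >= 4 and a >= 3;
IC025 > 0; EBGM05 > 2 — all behind a support floor of a >= 3, with the
combination switchable to conjunctive. No multiple-testing adjustment is
applied: the gate is threshold-based by design, and its null behaviour is
characterised empirically (on a null synthetic corpus the gated-positive
rate stays below ~10%, the disjunction of four roughly 2.5%-level one-sided
rules on correlated statistics). Output tables are sorted by a descending
to support top-N frequency reporting.

## Time to onset

TTO is the interval in days from the earliest primary-suspect therapy start
of the index drug to the event onset date. Only full 8-digit dates enter;
partial dates, missing dates, and non-positive intervals (onset on or
before the start day) are excluded and counted by reason — the Weibull has
positive support and same-day onsets are not half-day observable in
day-granular data, so exclusion is preferred over an arbitrary offset. No
censoring model is used: spontaneous reports are events by construction.

Shape and scale are estimated by maximum likelihood (BFGS on log
parameters), with 95% intervals from the observed information matrix via
the delta method on the log scale — a deterministic default, with bootstrap
left to the user. The shape classifies the hazard: CI entirely below 1 is
early failure (decreasing hazard), entirely above 1 wear-out, otherwise
random. The closed-form median scale·(ln 2)^(1/shape) is exposed for
consistency checks, and a fixed-shape mode (shape = 1 reduces the ML scale
to the sample mean) supports the exponential special case.

## Subgroups and sensitivity

Sex and age strata each get their own index/background partition; reports
missing the stratifying variable are excluded from all levels and counted.
The comparator is **within-stratum** by default — male index reports are
compared with male background reports — because a global comparator would
confound the stratum effect with the stratum's overall reporting profile;
the global option remains available. Strata with an empty index cohort *or*
no comparator reports are skipped with a warning rather than producing
degenerate tables. An age preset merges the two upper bins into a single
>= 65 level, since both binnings are common in reporting.

The sensitivity analysis retains index reports whose co-medications all
belong to a named partner allowlist (or that have none), which realises
"excluding reports with additional concomitant medications" while keeping
the recognised combination partners. The filter is monotone in the
allowlist, a property the tests assert.

## The synthetic corpus generator

`generate_corpus()` emulates the structural features the analysis relies
on: case versions sharing a CASEID with earlier receive dates (so the dedup
rule has real work to do, and its effect can be checked against the truth
sidecar exactly); missingness in sex, age, dates, country and occupation;
mixed age units; a primary-suspect drug plus allowlisted and off-list
concomitants; events drawn independently per PT with a Zipf-like background
frequency profile; and onset dates back-computed from a Weibull draw
(default scale 51.72 days, shape 0.78 — an early-failure onset profile
typical of cytotoxic chemotherapy).

Defaults were chosen once to mirror a carboplatin-style oncology corpus: a
mean of about 3.1 distinct events per report, sex mix 60/40 male among
observed with ~23% missing, ~30% missing age centred at 66 (SD 13.3)
years, and an index-drug share of 25% of reports so a 20,000-report corpus
yields an index cohort of a few thousand reports. Planted signals multiply
a PT's inclusion probability in matching index reports by a relative risk,
optionally restricted by sex or age; probabilities are renormalised per
report so the expected event count is unchanged, which keeps RR = 1
configurations exactly null. At low event prevalence the pair-level ROR is
then a consistent estimator of the planted RR, a property the suite checks
across 100 replicates.

What the generator does **not** emulate: within-report event correlation
(events are conditionally independent given the drug), realistic
co-prescription networks, country- or era-specific reporting dynamics, and
free-text fields. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean generating model, not robustness to
the full messiness of real spontaneous-report data.

All randomness flows from the single `seed` field; identical configurations
produce byte-identical files, and the generator restores the caller's RNG
state. The ground-truth sidecar (index membership, planted effects,
duplicate clusters) is mandatory output, and tests compare against it
rather than re-deriving truth from the generated files.

## Numerical choices and problem sizes

* Zero cells: 0.5 continuity add, always flagged.
* GPS prior optimisation: L-BFGS-B in transformed space, bounds ±12 on log
  parameters, max 500 iterations.
* EBGM05: bracketed `uniroot` between component 5% quantiles with a 1e-8
  relative pad against quantile/CDF round-off at the endpoints.
* Weibull MLE: BFGS, relative tolerance 1e-12, moment-based start (shape
  from the spread of log values, scale from the mean); degenerate samples
  (zero variance) and samples under 10 observations are refused.
* Default test problem sizes: corpora of 1,500–20,000 reports over a
  200-PT / 20-SOC vocabulary, 100-replicate estimator checks at 3,000
  reports, 200-replicate Weibull bias checks at n = 1,848, chosen so the
  whole suite runs in about a minute while keeping Monte-Carlo error well
  inside the asserted tolerances.

## Known limitations

Disproportionality statistics measure reporting imbalance, not incidence or
causality; nothing here adjusts for confounding by indication or
co-medication beyond the stratified and allowlist re-analyses. The BCPNN
bound is an asymptotic approximation (excellent for a >= ~10, conservative
below). The MGPS prior is fitted on possibly non-null tables, as in
standard practice; grossly contaminated corpora would bias the prior. The
Weibull fit ignores interval censoring from day-granular dates, a
negligible effect at onset scales of weeks but visible for same-week
onsets.
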