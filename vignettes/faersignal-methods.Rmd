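---
title: "Methods: designated-control disproportionality on FAERS reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designated-control disproportionality on FAERS reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as FAERS have no denominator: reports are
a biased, voluntary sample, so absolute risks cannot be estimated. What can
be estimated is *disproportionality* — whether a drug's share of reports for
one adverse event exceeds its share elsewhere. This package implements a
case/non-case design with a **designated control event**: instead of
comparing one event against all other events, the comparison set is pinned
to a single, deliberately common preferred term (PT). Using the most
reported PT in the cohort (diarrhoea, for the adolescent extract this
package targets) as the control stabilises the comparison and gives every
scanned drug the same reference outcome.

## ETL model and assumptions

A FAERS quarter is seven `$`-delimited tables keyed on `primaryid`
(DEMO, DRUG, REAC, OUTC, RPSR, THER, INDI). The reader (`read_quarter()`)
accepts both the post-2014 and legacy column spellings through an alias
map, decodes Latin-1, trims fields, and *drops* (with a count, never
silently) rows whose field count disagrees with the header — legacy
quarters contain such rows and aborting on them would make whole quarters
unusable. Linking (`link_tables()`) attaches child rows by exact
`primaryid`; orphans are counted and excluded. Cases with zero drugs or
zero reactions are excluded because no statistic in this package can use
them; the counts appear in the parse report so nothing disappears
unaccounted.

**Duplicate resolution.** FAERS accumulates versions of the same case
(`caseid`) across quarters. The source analyses this package re-implements
say only that duplicates were removed, so a rule had to be fixed: keep the
highest `caseversion` across all pooled quarters, break ties by latest
receipt date, then by highest `primaryid`. This matches FDA guidance for
quarterly-file users and makes `deduplicate()` deterministic and
idempotent; it is an assumption, and it is surfaced as such here.

**Drug names.** Normalization is deliberately minimal: uppercase, trim,
collapse whitespace, optional user synonym map. No salt stripping — a base
compound and its fumarate salt can carry entirely different signals in the
raw data, and collapsing them is an analysis decision the user must make
explicitly via the synonym map.

**Exposure roles.** All four FAERS roles (primary suspect, secondary
suspect, concomitant, interacting) count as exposure by default, with a
`roles = "suspect"` switch. The source analyses do not state which roles
they counted; counting all roles is the more conservative default for a
drug-interaction-oriented scan, where concomitant medication is exactly
what is of interest.

## Cohort definition

Ages arrive in six units (`DEC`, `YR`, `MON`, `WK`, `DY`, `HR`);
`normalize_age()` converts to real-valued years and maps anything
unparseable, unknown, or outside [0, 130] to missing. "12–17 years old" is
implemented as the half-open window **[12, 18)** on the normalized age: a
17.8-year-old is 17 years old. Missing-age cases are excluded by default
(an option admits them for users who trust FAERS age-group codes); this
choice is conservative and is recorded in the cohort's filter provenance.

Percentages in sex breakdowns are rounded half-up to one decimal, matching
the printed precision of the tables this package reproduces; frequency
percentages use two decimals.

## Two denominator conventions

Published FAERS frequency tables are internally inconsistent about
denominators (e.g. a top drug printed at 10.64% of 6,141 cases alongside a
raw count of 788, which is 12.8%). Rather than guess, both conventions are
implemented and labelled:

* `frequency_table()` — **cohort-cases** denominator: a case counts once
  per distinct item; `pct = 100·count/n_cases`. Percentages need not sum
  to 100.
* `drug_drilldown()` — **mention** denominator on the drug's sub-cohort:
  `pct = 100·count/(total distinct (case, item) mentions)`, so the
  untruncated percentages sum to 100.

Every output carries a `convention` attribute and the CSV column semantics
follow it. Relatedly, the printed cohort totals this package was checked
against do not sum (6,141 stated vs 6,143 by addition of the sex counts);
the cohort summary always reports the computed sum and leaves
reconciliation to the reader.

## The 2×2 design and estimators

Eligible reports mention the case PT **xor** the control PT
(case-insensitive exact match). Both-event reports are excluded and
counted: in a case/non-case design they have no defined outcome, and
keeping the count visible guards against a control PT that co-occurs
heavily with the case PT.

For the table (a, b, c, d) (exposed-case, exposed-control, unexposed-case,
unexposed-control):

* **ROR** (closed form): ad/bc, SE on the log scale
  √(1/a+1/b+1/c+1/d), CI exp(log ROR ± 1.96·SE), two-sided normal p.
  The 1.96 is exact by design — the target is the printed 95% intervals,
  not a re-derived quantile.
* **ROR** (logistic): binomial GLM of outcome (case = 1) on the exposure
  indicator, fitted by IRLS on the weighted four-row representation of the
  table, which has the same likelihood as the per-report fit for a single
  binary predictor. On all-positive tables it equals the closed form to
  numerical tolerance (the suite enforces 1e-6 on the estimate); with a
  zero margin the fit is separated, the result is flagged `unstable`, and
  the Haldane-corrected closed form is attached.
* **Zero cells**: Haldane–Anscombe +0.5 on all four cells, always flagged.
  This keeps every scanned drug reportable; the flag lets users drop
  corrected rows if they prefer.
* **PRR** and **RRR** use whole-cohort margins (the "all other reports"
  frame) and the standard SEs, √(1/a − 1/(a+b) + 1/c − 1/(c+d)) and √(1/a)
  respectively. The three estimators converge when both margins are small:
  the event rare *and* the drug's reports a small share of the cohort (RRR
  compares against the whole cohort, the drug's own reports included, so a
  drug with a large report share separates RRR from PRR at any event
  rate). The suite checks 5% agreement at <1% event prevalence and 1%
  drug share — the regime of the published confirmation triple this
  mirrors.

`scan_drugs()` runs the logistic route per drug (univariable, one drug at
a time — the scan reading; a joint fit across drugs answers a different
question and is intentionally not the default), skips drugs with no
exposed eligible report, and sorts by estimate. Estimates below 1 indicate
association with the control event. No multiplicity correction is applied,
matching the analyses being reproduced; scans report raw p-values and a
`significant` flag at 0.05.

A note on published intervals: a Wald interval's point estimate is the
geometric mean of its bounds, which is how the acceptance script
reconstructs published ORs from their printed CIs. One published interval
(1.17 with CI 1.13–1.32) is not Wald-symmetric — its geometric mean is
≈ 1.22 — so its computation cannot be inferred; it is documented here and
deliberately not reproduced.

## The synthetic world

`synthetic_config()` fixes a stated world emulating the adolescent FAERS
extract: sex probabilities (0.478, 0.492, 0.030); a drug catalog headed by
risperidone at 10.6% marginal prevalence; event baselines at the printed
reaction frequencies (diarrhoea 4.6%, hyperglycaemia ~4.4% scaled to a
plausible per-case rate, pneumothorax 0.4%); a 10% duplicate-version rate;
ages drawn in mixed units (78% years, plus months, days, weeks, decades,
and 3% missing) spanning 6–20 years so the [12, 18) filter is exercised on
both sides. Default injected signals place log-ORs of ln 6–ln 12 on the
drug–event pairs the package's scans target. Where the emulated analyses
state no value, the choice was made once on field-realism grounds and not
revisited.

Events are per-case Bernoulli under
logit P(event) = logit(baseline) + Σ exposures × log-OR, independent
across events given exposures — the simplest structure under which ROR
recovery is well-defined. `truth_table()` and the sampler share one code
path, so recovery tests compare against exactly what was generated. Two
reserved mechanisms keep invariants honest without distorting marginals: a
case that draws no catalog drug receives a uniformly chosen *background*
drug (no injected signal; disjoint from the catalog by validation), and a
case with no catalog event receives the reserved filler reaction. Catalog
marginals therefore stay exactly Bernoulli(p), which the 3-SD marginal
test depends on.

What the generator does **not** emulate: free-text drug-name noise,
real MedDRA coding drift, reporting-date clustering, therapy dates and
dose text, country/reporter structure, and correlated event syndromes. A
green recovery test therefore establishes estimator correctness under the
stated model, not robustness to real-world coding mess.

Under the XOR eligibility rule the designated-control ROR is unbiased for
an injected log-OR provided the control event carries no drug effect — the
control-event odds cancel from the cross-ratio. The coverage study in the
acceptance suite (1000 replicates, ~2000 eligible reports each, injected
ln 8) runs on a purpose-built two-event configuration with that property
and checks 95% Wald coverage lands in [93%, 97%] and that the signal drug
ranks first in a 10-drug scan in ≥95% of replicates; a 500-replicate null
study checks the Wald test's size at 3–7%. These run in-memory via
`simulate_cases(tables = FALSE)`; the on-disk path is exercised separately
(byte-determinism, zero dropped rows, exact unique-case recovery after
dedup).

## Numerical and degenerate-input choices

* Rounding of printed percentages is half-up (`round_half_up()`), not
  banker's rounding.
* Frequency ordering is a deterministic total order: count descending,
  item ascending.
* Gene ranking (`rank_genes()`): score descending, symbol ascending; a
  `k` beyond the table returns the full sorted table. The relevance-score
  table is user-supplied (the shipped TSV is a synthetic example); no web
  resource is queried.
* Empty cohorts, header-only tables, and missing ages are values, not
  errors; genuinely contradictory configuration (control PT among case
  PTs, inverted age window, signals referencing unknown catalog entries)
  fails fast with a config-classed error the CLI maps to exit code 1.
* GLM convergence uses epsilon 1e-12 so the logistic/closed-form
  equivalence holds at 1e-6 on the estimate; the standard error inherits
  the IRLS stopping rule and matches slightly less tightly.

## Known limitations

* Duplicate resolution beyond the caseversion rule (probabilistic record
  linkage on demographics) is out of scope.
* PT matching is exact (case-insensitive); no MedDRA hierarchy traversal,
  which would require a licence.
* The headline estimates of the analyses this package re-implements were
  computed on the full 2014Q3–2017Q3 FAERS extract; without those archives
  the package validates against worked examples recoverable from printed
  numbers plus simulation-based properties, not against the full-data
  estimates themselves.
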