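---
title: "Disproportionality screening on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) collect voluntary reports linking drugs to suspected adverse events.
Because there is no denominator of exposed patients, association is assessed
by *disproportionality*: for a drug--event pair, the observed co-reporting
count is compared with what independence within the database would predict.
`faersignal` implements this workflow for a single target event (the
motivating use case is dizziness under postoperative analgesia): ingestion
and deduplication of quarterly report files, cohort filtering, descriptive
baseline tables, four disproportionality statistics under three published
decision rule sets, sex-by-age stratified screening, and pairwise
drug-correlation ranking. A synthetic-report generator with controlled
marginals and planted association strengths makes every stage testable
without access to the live database.

## The statistics

All metrics derive from the 2x2 table for one drug--event pair within a
background population of `N` reports: `a` reports with both drug and event,
`b` with the drug only, `c` with the event only, `d` with neither. The
expected co-reporting count under independence is
`E = (a + b)(a + c) / N`.

* **Reporting odds ratio.** `ROR = (a d) / (b c)` with a Wald 95% interval
  `exp(log ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero,
  0.5 is added to all four cells (Haldane--Anscombe) and the result is
  flagged; unmodified tables stay exact. The accompanying p-value is a
  two-sided Fisher exact test on the *uncorrected* integer table — a Fisher
  test needs integer counts, so the continuity correction applies only to
  the ratio and its interval. The published forest table this design
  follows prints p-values without naming a test (including a "P = 0.2"
  beside an interval excluding 1); those printed p-values are not
  reproduced.
* **Relative reporting ratio.** `RRR = a / E`, the observed/expected ratio
  that online mining tools label "relative risk". It is 0 when `a = 0` and
  `Inf` when `E = 0` with `a > 0`.
* **Safety signal.** The source tooling for this metric publishes no
  formula, so the package defines its own operationalization:
  `signal = log2((a + 0.5)/(E + 0.5))`, a signed shrunk log2
  observed/expected that is finite at `a = 0` and zero exactly at `a = E`,
  making the published "> 0" criterion meaningful and continuous.
* **Information component (BCPNN).** The default `"gamma-shrinkage"` method
  takes `IC = log2((a + 0.5)/(E + 0.5))` with exact credible bounds from
  the Gamma(a + 0.5, 1) posterior quantiles divided by `E + 0.5`. It was
  chosen as the default because it has a clean Monte-Carlo oracle (draw
  from the gamma, take quantiles) against which the tests verify the bounds
  to 0.02. The classical closed-form posterior-moment approximation with
  uniform-marginal priors and a normal ±1.96 sd interval is available as
  `"bate1998"`. Under the default method the IC point estimate and the
  safety signal share one shrinkage kernel and are numerically equal; the
  two metrics differ only in their decision rules (interval versus point).

Three rule sets flag a pair as a signal, with strict inequalities exactly
as published: count/signal/ratio (`a >= 2` and `signal > 0` and
`RRR > 2`), ROR (Wald lower limit `> 1`), and BCPNN (`a >= 3` and IC
credible lower limit `> 0`). No multiple-testing adjustment is applied by
default, matching the published analysis; Benjamini--Hochberg on the Fisher
p-values is available behind `adjust = TRUE`.

### A note on monotonicity

ROR is strictly increasing in `a` at fixed `b, c, d`. The
observed/expected family (RRR, safety signal, IC point) is strictly
increasing in `a` whenever `a <= min(b, c)` — the sparse-signal regime
every real screen lives in — because the derivative of `log RRR` in `a` is
`1/a + 1/N - 1/(a+b) - 1/(a+c)`. When a margin is nearly saturated the
ratio can *decrease* in `a` (e.g. (300, 2, 2, 300)); the test suite pins
both the property and the counterexample.

## Background choice

The published screen never states whether its 2x2 tables were built within
the postoperative cohort or the full database. `build_contingency()`
therefore computes the table within whatever report set it is given, and
`screen_signals(background = )` (or `run_config(background_mode = )`)
selects between the cohort itself and a larger deduplicated set. Neither
choice is asserted as "the" published one.

## The synthetic world

`generator_config()` defaults encode the published baseline:

* **Demographics.** Sex, age-band and reporter-type marginals are the exact
  published counts over their own total (498,876), e.g. 61.92% female;
  ages are drawn uniformly within the selected band (86--100 for the open
  "more than 85" band, missing for "not specified"), because downstream
  logic keys on bands and the adult/elderly cut points, not exact ages.
* **Yearly volume** ramps linearly from 2004 to a 2015 peak, then plateaus
  at 70% of peak — high but clearly below it, so the peak year is
  identifiable from ~2,500 event reports.
* **Outcomes** are mostly non-serious (42%), with hospitalization (18%)
  and other-serious (20%) the common serious categories; no outcome table
  was published, so these are round figures chosen once for realism.
* **Drugs.** Each report carries 1--3 distinct drugs sampled without
  replacement proportional to vocabulary weights (an exponential race,
  which is exactly successive weighted sampling — the tests check observed
  inclusion frequencies against an enumeration oracle). One drug per
  report, chosen uniformly, is the primary suspect: the published filter
  keys on "primary suspect" but never defines multiplicity. Non-suspect
  mentions get secondary-suspect/concomitant/interacting roles in
  proportions 30/55/15.
* **Events** are per-term independent Bernoulli draws whose odds are
  multiplied by every applicable planted effect
  (`planted_signal(drug, event, effect, ...)`, optionally restricted to a
  demographic stratum). This is the simplest model under which the
  relative reporting ratio has a closed-form oracle. Reports that draw no
  event model the database's incomplete submissions: they are excluded
  (and counted) at assembly, exactly as event-less cases are excluded from
  the real cohort.
* **Duplicates** are injected at a configurable rate (default 5%), split
  evenly between a version-increment resubmission and a bit-identical
  copy — both occur in FAERS and exercise both deduplication branches.
  Deduplication keeps, per case, the highest version, breaking ties by
  latest receipt year and then by latest row provenance: a documented
  total order, so the operation is deterministic and idempotent.
* The **postoperative-analgesia context** has no structured FAERS field; it
  is modelled as an indication marker on the primary-suspect mention,
  attached with probability `indication_probability`. This makes the
  published case definition ("analgesic use after surgery") operational
  and testable.

What a green test on this world does *not* establish: the generator has no
drug co-prescription correlation structure, no free-text name noise beyond
what a mapping table exercises, no dose or regimen fields, and its
independence assumptions are exactly what real reporting data violate.
Green tests establish that the *machinery* is correct, not that any
particular real-world signal is.

### Calibration of the recovery experiment

The acceptance suite plants odds effects of 2, 5 and 10 and requires the
3-seed median RRR to land within 30% of each. Two attenuations separate
the RRR from the planted odds factor: the logistic odds-to-probability
bend, and inflation of the background event rate by the planted drug's own
reports. Both are available in closed form, which fixed the design before
any test seed was chosen: effects are planted on *separate* event terms
(sharing one term couples the biases), per-term baselines are 1%, and the
planted drugs carry marginal weights 0.05, 0.015 and 0.006 within a
77-drug formulary at n = 50,000, keeping the expected attenuation well
inside the band.

## Cohort filtering and denominators

`apply_cohort_filter()` applies age, event and drug-role/indication
criteria in a fixed order and attributes each exclusion to the first
failing criterion, so tallies plus the kept count always equal the input
count. A report with missing age fails an active minimum-age criterion by
default (an unverifiable age cannot satisfy "18 and above");
`keep_missing_age = TRUE` reverses this. The published baseline reports
two mutually inconsistent totals for the same cohort (166,292 reports
against category counts summing to 498,876, of which 61.92% is quoted as
308,892); the package takes no side — every summary states its own
denominator, and percentages are computed over the summary's own total,
rounded half-up to two decimals to match the printed precision. The drug
ranking denominator (reports versus distinct-per-report mentions) is
likewise explicit in the output, because the published overall ranking
uses report totals while its postoperative ranking implies a mention
denominator of 67.

## Subgroups and correlations

The four default strata follow the published definition: adult = age 25 to
65 inclusive, elderly = above 65, crossed with sex. Ages 18--24 fall in no
stratum — a gap in the published definition, preserved deliberately — and
missing ages join no stratum. Each stratum is its own background: a drug
cell in a stratum with no reports is *missing*, not zero. Pairwise drug
correlations are Pearson correlations of metric profiles; the published
figures never state the profile axis, so the default is the four strata
(matching the heatmap-to-correlation flow) with a yearly-counts axis
available via `cell_col = "year"`. With 4-point profiles |r| is noisy:
pairs sharing fewer than 3 non-missing cells or with zero variance are
excluded with an explicit reason, and a warning flags short axes rather
than silently reporting.

## Reproducibility

Every random step is governed by one seed: the generator is deterministic
given its configuration, and `run_pipeline()` derives fixed per-stage
sub-seeds from the master seed, so one integer reproduces byte-identical
TSVs and a manifest carrying row counts, exclusion tallies and an md5
checksum per output file.

```{r example}
cfg <- generator_config(
  n_reports = 5000, seed = 42,
  planted_signals = list(planted_signal("KETAMINE", "DIZZINESS", 6))
)
reports <- generate_reports(cfg) |> deduplicate_reports()
screen <- screen_signals(reports, "DIZZINESS")
head(tidy(screen)[, c("drug", "a", "ror", "ror_ci_low", "ror_ci_high",
                      "rrr", "ic", "ic_ci_low", "flag_ror", "flag_bcpnn")])
glance(screen)
```

## Known limitations

Exact-duplicate detection is structural (same case id), not probabilistic
record linkage; name standardization is exact lookup after normalization,
trading recall for reproducibility; the Fisher p-value is reported but the
published p-values are not reproducible; and desk-scale synthetic data
cannot reproduce database-scale published counts (166,292 reports, the
77-drug screen's specific estimates), which depend on the live database
and unstated queries.
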