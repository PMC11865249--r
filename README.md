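# faersignal

Disproportionality signal screening for FAERS-style spontaneous
adverse-event reports, built tidyverse-style: tibbles in, tibbles out,
`tidy()`/`glance()` on fitted screens, `autoplot()` for forest plots.

Spontaneous-report databases (the FDA Adverse Event Reporting System being
the canonical one) have no exposure denominator, so drug–event association
is assessed by comparing the observed co-reporting count `a` of a 2×2 table

|              | event | no event |
|--------------|-------|----------|
| **drug**     | a     | b        |
| **no drug**  | c     | d        |

against its expectation under independence `E = (a+b)(a+c)/N`. The package
computes, per drug against one target event (the motivating case is
dizziness under postoperative analgesia):

* the **reporting odds ratio** `ROR = ad/bc` with a Wald 95% CI
  `exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))`, Haldane–Anscombe 0.5
  correction on zero cells, and a two-sided Fisher exact p-value;
* the **relative reporting ratio** `RRR = a/E` (observed/expected);
* a shrunk log2 **safety signal** `log2((a+0.5)/(E+0.5))`;
* the BCPNN **information component** with exact gamma-posterior credible
  bounds (default) or the classical 1998 closed-form moment approximation;

and applies three published decision rule sets with strict inequalities:
`a ≥ 2 ∧ signal > 0 ∧ RRR > 2`; ROR CI lower limit `> 1`; and
`a ≥ 3 ∧ IC` CI lower limit `> 0`. Around that core sit quarterly-file
ingestion (`$`-delimited DEMO/DRUG/REAC/OUTC tables) with reject lists,
version-aware deduplication, exact drug-name standardization, cohort
filters with conservation-checked exclusion tallies, baseline
demographics/outcome/yearly summaries, sex-by-age stratified metric
matrices with top-k rankings, pairwise drug-correlation ranking, and a
synthetic FAERS-like generator with controlled marginals and planted
association strengths so the whole pipeline is testable offline.

## Worked example

```r
library(faersignal)

cfg <- generator_config(
  n_reports = 5000, seed = 42,
  planted_signals = list(planted_signal("KETAMINE", "DIZZINESS", 6))
)
reports <- generate_reports(cfg) |> deduplicate_reports()
screen  <- screen_signals(reports, "DIZZINESS")
head(tidy(screen)[, c("drug", "a", "ror", "ror_ci_low", "ror_ci_high",
                      "rrr", "ic", "ic_ci_low", "flag_ror", "flag_bcpnn")], 5)
#> # A tibble: 5 × 10
#>   drug            a   ror ror_ci_low ror_ci_high   rrr      ic ic_ci_low flag_ror flag_bcpnn
#> 1 KETAMINE      127  5.93      4.67         7.54  3.41 1.76        1.49  TRUE     TRUE
#> 2 HYDROCODONE    30  1.11      0.751        1.63  1.09 0.123      -0.439 FALSE    FALSE
#> 3 ONDANSETRON    33  1.09      0.754        1.59  1.08 0.108      -0.427 FALSE    FALSE
#> 4 PARACETAMOL    36  1.05      0.733        1.50  1.04 0.0561     -0.454 FALSE    FALSE
#> 5 LIDOCAINE      49  1.01      0.736        1.38  1.01 0.00724    -0.425 FALSE    FALSE
```

The planted drug is the only flagged one: 127 of its reports mention
dizziness against an expected ~37 under independence, giving ROR 5.9
(CI 4.7–7.5, lower limit above 1), observed/expected 3.4, and an IC whose
credible interval sits entirely above zero. The other drugs hover at
ROR ≈ 1 with intervals straddling the null, as they should on null data.

```r
glance(screen)
#> # A tibble: 1 × 8
#>   event     n_drugs n_background n_event ic_method       n_flag_aersmine n_flag_ror n_flag_bcpnn
#> 1 DIZZINESS      20         5000     359 gamma-shrinkage               1          1            1
```

Downstream: `stratified_metrics()` rebuilds the tables inside the four
adult/elderly × male/female subgroups, `top_k_per_stratum()` ranks drugs
per subgroup, `pairwise_drug_correlation()` + `rank_negative_pairs()`
produce the correlation ranking, and `run_pipeline(run_config(...))`
executes everything with one seed, writing TSVs and a checksummed
manifest. A thin CLI (`inst/scripts/faersignal-cli`, subcommands
`simulate`, `describe`, `screen`, `subgroups`, `run-all`) wraps the same
functions. See `vignettes/faersignal-methods.Rmd` for the model, its
assumptions and the design choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end on the synthetic world against the
installed package — generation with planted dizziness signals, duplicate
injection, deduplication, the adult primary-suspect cohort filter, the
full-background screen, subgroup matrices and correlations — and writes
its JSON report to `--out`.
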