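# oncovalue

Scoring oncology regimens with the ASCO advanced-disease value framework.

Health-technology assessors, hospital pharmacy committees and
health-economics researchers increasingly need a transparent, reproducible
way to turn a randomized two-arm trial into a value judgement: how much
net health benefit does the new regimen add over the standard, and what
does each point of benefit cost per month of treatment? `oncovalue`
implements the American Society of Clinical Oncology (ASCO) value
framework for advanced disease as a fully tested scoring pipeline, with
the published assessments of enzalutamide and apalutamide in early
prostate cancer (the PROSPER, SPARTAN, ARCHES and TITAN trials) shipped
as validated fixtures.

## The score

The **net health benefit** (NHB) is the sum of three components:

* **Clinical benefit** — from a strict evidence hierarchy; with a death
  hazard ratio available, `(1 − HR) × 100`; otherwise median overall
  survival, the progression HR (×0.8), median progression-free survival
  (×0.8) or the response-rate difference (×0.7).
* **Toxicity** — per-adverse-event points by grade band (grade 1–2: 0.5
  below 10% frequency, 1 at/above; grade 3–4: 1.5 below 5%, 2 at/above),
  summed per arm into totals `T_t, T_c`, then `(1 − T_t/T_c) × 20`
  (negative when the test regimen is more toxic).
* **Bonus points** — tail of the survival curve (up to 20 when the test
  arm's surviving proportion at twice the comparator's median is ≥50%
  greater, with >20% surviving on the standard), plus 10 each for
  significant palliation, quality-of-life gain and treatment-free
  interval.

Step 5 prices the regimen per 30-day month from its regulated price per
mg, and Step 6 reports **cost per NHB point** = monthly cost / NHB.

## Worked example

```r
library(oncovalue)
card <- build_scorecard(builtin_fixture("arches"),   # enzalutamide, mHSPC
                        builtin_dosing("enzalutamide"))
card
#> <value_scorecard> ARCHES / enzalutamide
#>   clinical benefit 34 (rung 1.A), toxicity -2, bonus 20
#>   NHB 52 of 180; monthly cost 10,383,984 COP (2652.16 USD)
#>   cost per NHB point 199,692 COP (51 USD)
#>   config 7a054a76
```

The clinical benefit 34 comes from the reported death HR 0.66
(`(1 − 0.66) × 100`); the −2 toxicity score from the arm totals 49.5 vs
45; the 20 bonus points from significant palliation and quality-of-life
findings. Acquiring one of the 52 NHB points costs 199,692 Colombian
pesos per month. `render_stepwise(card)` prints the full six-step report
with the intermediate arithmetic.

The PROSPER fixture intentionally carries a quirk of its source: printed
toxicity totals that imply −6.05 alongside a reported score of −4.64.
Scoring it warns about the disagreement, and
`build_scorecard(..., toxicity_source = "recomputed")` switches sides;
both values always appear in the provenance.

Beyond scoring, the package simulates two-arm trials with known ground
truth (`simulate_trial()`, `recovery_experiment()`) and propagates
hazard-ratio confidence intervals into NHB and cost-per-point intervals
(`nhb_interval()`). A command-line front-end with `score`, `compare`,
`simulate` and `fixtures` subcommands is installed at
`inst/cli/oncovalue.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/oncovalue.R", package="oncovalue"))')" \
  score --fixture arches --dosing enzalutamide
```

See `vignette("value-framework")` for the model, its numerical
conventions (including the 4-decimal ratio truncation and 2-decimal
component rounding the published arithmetic uses) and limitations.

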