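---
title: "Scoring advanced-disease regimens with the ASCO value framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring advanced-disease regimens with the ASCO value framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(oncovalue)
```

## The model

The American Society of Clinical Oncology (ASCO) value framework for
advanced disease condenses a randomized two-arm trial into a single **net
health benefit** (NHB) score, and relates it to the monthly cost of
acquiring the drug. `oncovalue` implements the framework as a deterministic
six-step pipeline:

1. **Clinical benefit.** A five-rung evidence hierarchy. When the hazard
   ratio (HR) for death is reported, the score is $(1 - HR) \times 100$.
   When it is not, lower rungs engage in strict order — median overall
   survival ($100 \,(m_t - m_c)/m_c$), the progression HR
   ($0.8\,(1 - HR)\times 100$), median progression-free survival (with the
   same 0.8 multiplier), and finally the response-rate difference (with a
   0.7 multiplier). Lower rungs are ignored whenever a higher one is
   available, even if reported. The rung actually used is part of every
   scorecard's provenance.
2. **Toxicity.** Each graded adverse event contributes points by band and
   frequency: grade 1–2 events score 0.5 below a 10% frequency and 1 at or
   above it; grade 3–4 events score 1.5 below 5% and 2 at or above (both
   thresholds inclusive on the high side). Arm totals $T_t, T_c$ yield the
   score $(1 - T_t/T_c) \times 20$ — negative when the test regimen is the
   more toxic one.
3. **Bonus points.** Tail of the survival curve (up to 20 points when,
   at twice the comparator's median, the test arm's surviving proportion is
   at least 50% greater in relative terms, provided more than 20% survive
   on the standard), and 10 points each for statistically significant
   palliation of symptoms, quality-of-life improvement and treatment-free
   interval prolongation.
4. **Net health benefit** is the exact sum of the three components.
5. **Monthly cost** is drug acquisition only:
   price per mg × daily dose (mg) × 30 days.
6. **Cost per NHB point** is the monthly cost divided by the NHB.

All framework constants live in a single `scoring_config()` object whose
hash is stamped into every scorecard, so a result can always be traced to
the constants that produced it.

## Worked example

```{r}
arches <- builtin_fixture("arches")          # enzalutamide + ADT, mHSPC
card <- build_scorecard(arches, builtin_dosing("enzalutamide"))
card
```

`render_stepwise(card)` prints the same scorecard as a six-step markdown
report with the intermediate arithmetic spelled out.

## Numerical conventions

Two rounding conventions are load-bearing and deliberately explicit in the
configuration:

* **The toxicity ratio is truncated to 4 decimal places** before the
  multiplication by 20 (`ratio_decimals`). The published worked examples
  compute 27/22 as 1.2272 — truncation, since half-up rounding of
  1.22727… would give 1.2273 and a score of −4.55 rather than the
  published −4.54. Truncation reproduces all four published toxicity
  scores (−4.54, −2.25, −2.0, −6.05).
* **Components are rounded to 2 decimals before summation**
  (`component_decimals`). This reproduces published NHBs such as
  22 − 4.54 + 16 = 33.46, where unrounded arithmetic gives 33.4545….

Costs are rounded to whole Colombian pesos (COP), USD equivalents to
cents. The default exchange rate, 3,915.3 COP/USD, was back-solved from
the published COP/USD pairs (the source states no rate or date) and is
configurable. Monthly costs use a 30-day month, consistent with the
published 120 tablets/month at 4 tablets/day; calendar-month costing is
out of scope.

## Design choices where the framework is open

* **Negative clinical benefit** (HR > 1) is reported with a warning, not
  clamped to zero. The framework text does not address harm; clamping
  would hide it.
* **Tail-of-curve magnitude.** The framework awards *up to* 20 points but
  states no formula for fewer; the published assessments award 16 without
  derivation. Eligibility is therefore computed from the rule, while the
  magnitude comes from the evidence's `awarded_points` (clamped to
  [0, 20]), defaulting to the full 20 when the assessor supplied none.
* **"Percentage difference" in the toxicity step** is pinned to
  $1 - T_t/T_c$ (a ratio-based difference) by the worked examples; the
  alternative reading, a difference of percentages, is rejected because it
  reproduces none of them.
* **The PROSPER toxicity discrepancy.** One fixture's printed point
  totals (49.5 vs 38) imply a toxicity score of −6.05, but its published
  score and NHB (48.36) use −4.64. The fixture stores both;
  `build_scorecard(..., toxicity_source =)` selects
  `"reported"` (default, reproducing the published NHB) or
  `"recomputed"`, and a warning plus provenance entries surface the
  disagreement either way. Neither value is silently preferred.
* **The 180-point nominal maximum.** The framework describes the NHB as
  "out of 180 possible points", yet the component caps used here sum to
  100 + 20 + 10 + 10 + 10 = 150 (or 170 with a benefit score reaching
  120 under the median rung). `max_nhb` is configurable, a score above it
  warns, and the discrepancy is documented rather than resolved.
* **Frequencies are proportions.** Adverse-event frequencies are stored
  in [0, 1]; readers accept a percent flag and convert on load, removing
  the 10-vs-0.10 ambiguity.

## What the synthetic generator emulates — and what it does not

`simulate_trial()` generates two-arm trials with known ground truth:
exponential event times in each arm (test hazard = `true_hr` × comparator
hazard), no censoring, HR estimated by Cox partial likelihood with a Wald
95% CI, adverse-event frequencies as binomial proportions, and tail
proportions measured at twice the comparator's empirical median. Survival
and adverse-event draws use separate seeded streams, so changing the AE
specification never perturbs the survival draws.

The exponential, censoring-free model is chosen for its closed forms: the
comparator's surviving fraction at twice its own median is exactly
$0.5^2 = 0.25$, the test arm's is $0.25^{HR}$, and the 50%-improvement
tail rule is satisfied exactly for
$HR \le \ln(0.375)/\ln(0.25) \approx 0.7075$
(`tail_eligibility_boundary()`). These closed forms are the oracles the
test suite checks the pipeline against.

What the generator does **not** emulate: censoring and accrual patterns,
non-proportional hazards, correlated adverse events, informative
missingness in quality-of-life instruments, and assessor judgement in the
bonus categories. Passing simulation-based tests therefore demonstrates
the arithmetic and statistical estimation machinery, not robustness to
those features of real trial data.

Problem sizes used by the test suite were chosen to make sampling noise
negligible relative to the tolerances: hazard-ratio recovery uses 5,000
patients per arm and 100 replicates (mean estimated HR within 5% of
truth); the tail-eligibility boundary is located from a grid of true HRs
(0.64–0.78, step 0.02, 50 replicates of 2,000 per arm at each point) via
binomial regression, expected within 0.02 of 0.7075.

## Propagating hazard-ratio uncertainty

The published assessments report 95% CIs but score only point estimates.
`nhb_interval()` is a clearly-labelled extension (off by default in the
command-line interface) that samples the HR from the standard
meta-analytic lognormal — $\ln HR \sim N(\ln \hat{HR}, \sigma)$ with
$\sigma = (\ln ci_{high} - \ln ci_{low})/(2 \times 1.959964)$ — and maps
each draw through the scorecard with toxicity, bonus and cost held fixed
(no uncertainty distributions exist for them; a documented limitation).
Because NHB is then a strictly decreasing affine map of the HR, the NHB
quantile at probability $p$ equals the scorecard at the HR quantile at
$1 - p$; quantiles use the inverse empirical CDF (`type = 1`) so this
identity holds exactly per draw set. Note that a reported CI that is
asymmetric on the log scale (as 0.61–0.89 around 0.73 mildly is) is
reproduced by the sampler only up to that asymmetry: the empirical
2.5/97.5 percentiles converge to
$\exp(\ln \hat{HR} \mp 1.96\,\sigma)$, within about 1% of the reported
bounds for the fixtures shipped here.

## Known limitations

* Toxicity for the four shipped fixtures rests on the published per-arm
  point totals; the underlying adverse-event itemization is not available,
  so those totals are inputs, not recomputed quantities. Itemized scoring
  is fully supported (and property-tested) for user-supplied and synthetic
  data.
* The cost model covers drug acquisition only — no administration,
  monitoring or out-of-pocket costs.
* The curative-setting variant of the framework is out of scope; only the
  advanced-disease framework is implemented.
* Bonus awards encode assessor judgement (which published assessments of
  the same trials have disagreed on); the package reproduces recorded
  judgements, it does not make them.
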