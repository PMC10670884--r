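---
title: "A stage-shift microsimulation of mammography screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stage-shift microsimulation of mammography screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammosim)
```

## What the model is

`mammosim` simulates individual life histories of women from birth to at
most age 110 and tallies, per screening regimen, the outcomes that drive
screening policy debates: breast-cancer deaths before a reporting horizon,
life years, stage at diagnosis, screens, false-positive recalls and
negative biopsies. It follows the architecture of national breast-screening
microsimulation models in the OncoSim-Breast / CISNET tradition: cancers
are initiated from an age-dependent hazard, grow and spread according to a
stochastic natural history, are found either by symptomatic (clinical)
surfacing or by mammography, and post-diagnosis survival depends on the
stage at which the cancer was found. Competing mortality comes from a life
table. All updates happen on a yearly grid.

The package deliberately separates two layers:

* a **simulator** with fully synthetic parameters, used to demonstrate and
  test the mechanics (stage shift, overdetection, competing mortality,
  burden scaling) at a realistic scale; and
* a **reporting layer** whose arithmetic (mortality reductions, relative
  reductions, number needed to screen, national scalings, participation
  mixtures) can also be applied in *printed-values mode* to a published
  per-regimen outcome table (`reference_outcomes()`), reproducing a
  calibrated model's published comparisons exactly without pretending this
  package is calibrated.

The synthetic absolute levels are of the same order as published Canadian
figures (about 12 breast-cancer deaths per 1000 unscreened women by age 76
here, versus a published 15.7) but are *not* a calibration; any agreement
beyond direction and order of magnitude is incidental.

## Natural history

**Onset.** A woman's age at cancer initiation is drawn by inverse transform
from a piecewise-constant hazard $\lambda(a)$ on ages $0..109$. The default
is a Gaussian-shaped profile peaking at age 68 with maximum
$3.8\times10^{-3}$/year, giving a cumulative onset risk to age 80 of about
12% — the familiar "one in nine" lifetime-risk scale. The peak location and
width are synthetic stand-ins; the published source model does not state
its onset form.

**Growth.** Invasive tumors grow deterministically by Gompertz growth
$d(t) = d_{max}(d_0/d_{max})^{\exp(-\gamma t)}$ from $d_0 = 2$ mm towards
$d_{max} = 128$ mm, standard in breast natural-history modeling because it
is bounded and has a single interpretable rate. The per-woman rate
$\gamma$ is lognormal (median 0.25/year, $\sigma_{\log} = 0.6$),
right-skewed so that a slow tail of tumors remains small for decades —
the pool from which overdetection arises. The median tumor takes about
3.2 years to grow from 2 mm to 20 mm.

**In situ disease.** A new cancer starts in situ with probability 0.25 and
converts to invasive with probability 0.2 per year thereafter. Because the
conversion probability is below one, some lesions never become invasive:
non-progressive in situ disease is represented implicitly rather than as a
separate class. In situ lesions cannot surface clinically and can only be
found by screening (with a fixed sensitivity of 0.5, since a size-based
curve is meaningless for stage 0 in this representation).

**Spread and staging.** Nodal and then distant spread are annual Bernoulli
events whose probabilities increase with current diameter (logistic in
$d$, saturating at 0.35 and 0.25 respectively); distant spread can only
follow nodal spread, which enforces the stage ordering. Stage at any
moment comes from a decision table with AJCC-like cut-offs (20 mm, 50 mm):
in situ is 0; $\le 20$ mm node-negative is 1; $\le 20$ mm node-positive or
20–50 mm node-negative is 2A; 20–50 mm node-positive is 2B; $> 50$ mm is
3; distant spread is 4. The cut-offs are configurable constants, not
estimates. Substages are tracked internally so the early-invasive
(stage 1 or 2A) fraction is computable even though coarse tables merge 2A
and 2B.

**Detection.** Clinical surfacing accumulates a diameter-proportional
hazard $c_0\, d(t)/d_{ref}$ ($c_0 = 0.25$/year at $d_{ref} = 15$ mm) on
the yearly grid; mammographic sensitivity is logistic in diameter
(maximum 0.95, half-maximum at 10 mm, slope 0.4/mm). A woman without
detectable cancer is recalled after a screen with probability 0.055 —
about 55 recalls per 1000 screens, the scale implied by published recall
burdens — and a recalled cancer-free woman is biopsied with probability
0.09; such biopsies are negative by construction.

**Survival.** Post-diagnosis survival is a per-stage cure fraction plus an
exponential death rate for the non-cured (cure 0.98, 0.92, 0.84, 0.74,
0.55, 0.05 and rate 0.02–0.35/year across stages 0, 1, 2A, 2B, 3, 4). The
validator *enforces* that cure decreases and the rate increases strictly
with stage; this ordering is what makes stage shift a benefit.

## The two decisions that define the model

**Survival is anchored at the clinical surfacing age.** Breast-cancer
survival time is measured from the age at which the tumor would have
surfaced clinically in the absence of screening, not from the diagnosis
age. Earlier screen detection therefore changes only the *stage* entering
the survival draw, never the clock it runs on. This removes lead-time bias
by construction: a regimen cannot look beneficial merely by moving
diagnosis earlier, and the entire mortality benefit flows through the
stage distribution — which is exactly the mechanism a stage-shift analysis
reports.

**Never-surfacing cancers cannot kill.** A cancer that would not surface
clinically before age 110 contributes to diagnoses (if screened) but never
to breast-cancer mortality: it is the overdetection pool. A plausible
alternative — letting screen-detected never-surfacing cancers carry
stage-specific mortality anchored at the detection age — would make
screening *create* a small number of deaths among women it could never
harm in the baseline scenario, breaking the per-woman benefit ordering.
With both decisions together, the following is a theorem of the
implementation, not a statistical tendency: under common random numbers, a
regimen that detects the same tumor at an equal-or-lower stage never
yields an earlier death, from any cause, for any woman. The test suite
asserts this on 10,000 paired histories and, in aggregate, as exact
monotone orderings of deaths, early-stage counts and total diagnoses
across nested regimens.

## Common random numbers

Every draw is a deterministic hash of `(seed, purpose, counter, woman)` —
a counter-based stream built on the 32-bit MurmurHash3 finalizer (verified
against an independent implementation, and uniform to Kolmogorov distance
< 0.01 at $n = 10^5$). Consequences:

* natural history is *identical* across regimens — between-regimen
  differences contain no natural-history Monte-Carlo noise;
* screen draws are keyed by screen *age*, so nested regimens (e.g.
  biennial 50–74 $\subset$ biennial 40–74 $\subset$ annual 40–74) share
  draws at shared ages and couple exactly;
* cohort aggregation is order-independent and a single woman's history can
  be reproduced in isolation (`run_history()`).

Attendance under partial participation is all-or-none per woman
(Bernoulli with the regimen's participation fraction, drawn once per
woman from a shared stream). A simulated 70%-participation cohort is
therefore *exactly* the 70:30 row-wise mixture of the full-participation
and no-screening cohorts, which is also how the reporting layer's
participation weighting treats published values.

## Event order and numerical conventions

Within a simulated year: other-cause death first, then tumor
growth/progression, then any scheduled screen (if attending and
undiagnosed), then clinical surfacing, then survival resolution. A screen
in the surfacing year counts as screen detection. Exact ties between
breast-cancer and other-cause death resolve to other-cause. Deaths at
exactly the horizon age are inside the reporting window. Onset and death
ages are continuous (uniform within their year); progression, surfacing
and screening operate on the yearly grid. Death ages are capped at 109.

The reporting window defaults to ages 40–76, emulating the fixed
calendar-year truncation of published analyses; life years are truncated
at the horizon by default, with `life_years = "lifetime"` available in
`build_report()`. Rates use women alive at the entry age as denominator.
NNS identities (`nns * reduction = 1000`) are algebraic and hold exactly;
relative reductions recomputed from rounded printed inputs agree with
published percentages only to about half a percentage point, because
published tables used unrounded model output — the tests assert that
tolerance explicitly rather than absorbing it.

## What the synthetic cohort does and does not show

Default problem sizes are 100,000 women for cohort-level checks (the
published analyses used 1.53 million) and 10,000–50,000 for
distributional law checks; at these sizes the binomial standard error on,
for example, total cancers per 100,000 is about 90, and all asserted
orderings are exact under common random numbers, so they carry no
Monte-Carlo risk at all.

Passing tests demonstrate that the *mechanics* are right: inverse
transforms match closed-form CDFs, waiting times match geometric laws,
hand-traced histories match the engine, stage shift moves the
distributions in the published direction, and the reporting layer
reproduces published arithmetic exactly. They do *not* demonstrate
calibration to any population: incidence, sensitivity, recall rates and
survival here are synthetic, single-valued (no age dependence in recall
rates, no subtype-specific growth or survival), and the model carries at
most one primary cancer per woman. Cost-effectiveness, risk-stratified
cohorts and calendar-time entry of successive birth cohorts are out of
scope; national figures come from the reporting layer's scaling constants,
not from simulating a nation.

## A worked comparison

```{r, eval = FALSE}
params <- make_default_params(seed = 1)
outcomes <- compare_regimens(params, default_regimens(), n_women = 100000)
stage_table(outcomes)
build_report(outcomes)
autoplot(outcomes) # stacked stage distribution, ordered by screen count
```

And the printed-values mode, which needs no simulation:

```{r}
build_report(reference_outcomes())[, c("regimen", "reduction_per_1000",
                                       "relative_reduction",
                                       "nns_per_death", "nns_per_ly")]
```
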