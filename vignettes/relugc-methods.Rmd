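---
title: "Methods: event-level urinary glucocorticoid analysis"
author: "relugc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-level urinary glucocorticoid analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relugc)
```

## The measurement problem

Urine integrates the hormonal state over the interval since the previous
void, and glucocorticoid (GC) metabolites reach urine only after a
clearance lag of roughly 2–4.8 hours. An event-level analysis of the GC
response to a single behavioural event (an aggressive interaction, or a
resting control) must therefore decide, for every voided sample, whether
its content reflects the hormonal state *before* the event or the
*response to* the event, and must normalize away urine dilution and the
diurnal decline of baseline GC secretion. `relugc` packages that analysis
chain: window assignment, sample QC, creatinine-corrected uGC
quantification, the event-level relative-uGC ratio, and mixed-model
inference, plus a forward simulator for validating the chain end to end.

## Window assignment

For an event starting at $t_0$ (duration $d$ minutes), the pre-event
window is $[t_0, t_1)$ with $t_1 = t_0 + 135$ and the peak-clearance
window is $[t_1, t_2)$ with $t_2 = t_0 + d + 270$. The 135-minute
boundary splits the difference between the onset of urinary appearance of
a GC pulse and its peak, given urination intervals averaging 78 ± 32 min.

Numerical conventions, chosen once and applied everywhere:

* **Half-open intervals.** A sample voided exactly at a boundary belongs
  to the period starting there ($s = t_1$ is peak; $s = t_2$ is past the
  study window). Verbal closed ranges double-count boundaries; the
  overlap rule below governs the boundary neighbourhood anyway.
* **Overlap zones.** A sample voided in $(t, t + 30]$ for
  $t \in \{t_1, t_2\}$ may contain mostly urine accumulated before $t$.
  Let $p$ be the latest void strictly before $t$. If $p$ exists and
  $s - t < t - p$, the sample is relabelled to the period ending at $t$;
  otherwise it keeps the period in which it was excreted. For the $t_2$
  zone, "keeps its period" means *excluded*: only two analysis periods
  are defined and the study window ends at $t_2$.
* **Ties.** $s - t = t - p$ keeps the excretion period: the relabelling
  condition is strictly "smaller than".
* **No previous void.** Without $p$ the latency comparison is undefined;
  the sample keeps its excretion period.
* **QC-failed voids still anchor latencies.** A failed sample is still a
  urination, so it participates in the $\Delta t$ comparison; it is only
  barred from the hormone means. Series completeness (at least one
  QC-passing sample in each window) is what gates the ratio.

The test suite checks the production assignment against an independent
case-analysis oracle: exhaustively for all 1- and 2-sample configurations
on a 5-minute grid over the full study window, exhaustively for 3-sample
configurations on the boundary neighbourhoods, and on thousands of random
configurations of up to 6 samples across event durations from 1 to 125
minutes. (A fully exhaustive sweep of all 6-sample configurations on the
5-minute grid would take on the order of $10^8$ cases and adds nothing
over the stratified sweep.)

## QC and quantification

Samples fail QC when the internal-standard recovery deviates by 50% or
more from its expected value (`fail_recovery`; the laboratory's
re-measure/re-extract escalation is collapsed into the final recovery
deviation, since the lab loop is not reproducible in software), or when
creatinine is below 0.05 mg/ml (`fail_creatinine`). The two filters are
independent predicates, so their order cannot change the surviving set.

Total uGC is the arithmetic sum of cortisol, tetrahydrocortisol,
tetrahydrocortisone, 5β-androstane and 11-oxoetiocholanolone (ng/ml),
divided by creatinine (mg/ml). The event statistic is

$$\text{relative uGC} = 100 \times
  \frac{\overline{\text{uGC}}_{\text{peak}}}
       {\overline{\text{uGC}}_{\text{pre}}}$$

with unweighted arithmetic means over QC-passing whole samples. Whole
samples — not interpolated overlap fractions — are averaged: urine
volumes per void are not recorded in the field, so any volume weighting
would be invented. The ratio is kept at full precision internally;
reporting rounds half-up to one decimal.

## Mixed models

All models are Gaussian linear mixed models with a single random
intercept per subject, fitted by **maximum likelihood** (not REML):
likelihood-ratio tests on fixed effects require ML, and the reported
standard errors use the ML $1/n$ variance scaling. The log-likelihood is
profiled over the variance ratio
$\lambda = \sigma^2_{\text{subject}} / \sigma^2_{\text{resid}}$: given
$\lambda$, $\hat\beta$ and $\hat\sigma^2$ have closed forms through the
Woodbury identity on the block-diagonal marginal covariance, so fitting
reduces to a bounded 1-D optimization over $\log\lambda$ (tolerance
$10^{-10}$, search interval $e^{\pm 15}$) plus an explicit evaluation at
the $\lambda = 0$ boundary, taking whichever is better. At the boundary
the fit provably coincides with OLS under ML scaling, which the tests
verify to $10^{-6}$ against a closed-form oracle; interior optima are
cross-checked against `lme4::lmer(..., REML = FALSE)`. A residual sum of
squares below $10^{-14}$ of the response's scale is snapped to the exact
degenerate fit (all variances zero).

Categorical predictors use treatment contrasts with `resting` as the
reference for the behaviour and role models and `non_contact` for the
intensity model; dominance rank (1 = highest) enters as a numeric slope.
LRT p-values use the plain $\chi^2$ reference distribution without a
boundary correction, as the compared models share the random-effect
structure. Collinearity is screened with VIFs from auxiliary ordinary
regressions excluding the random effect (single predictor: VIF 1 by
definition; perfect collinearity: `Inf`, not an error — implemented
in-package because the usual tooling raises errors on exactly those two
edge cases, and cross-checked against `car::vif` where both are defined).
"Model stability" is operationalized as: every leave-one-subject-out
refit is estimable, converges, and flips no fixed-effect sign relative to
the all-data fit.

### Which rows enter which model

The reference suite fits behaviour, role and rank on all 24 events, and
duration and intensity on the 14 aggression events only. Two choices here
were genuinely open:

* **Duration** uses aggression events only: resting "durations" are an
  order of magnitude longer and measure how long the control lasted, not
  how much was fought — pooling them would conflate two quantities.
* **Rank** uses all 24 events. Relative uGC after any event may vary with
  rank, the 24-row table stabilizes the slope considerably, and on the
  embedded dataset only this choice reproduces the reference estimates
  (β = −5.13, SE = 2.12, χ² = 5.25); the aggression-only fit lands on the
  variance boundary at β = −6.22, χ² = 5.08.
* The **role** model is additionally re-run with `aggressor` as the
  reference level, which re-parametrizes the fit without changing its
  likelihood; the aggressor–victim contrast is checked by magnitude,
  since it equals the difference of the two main-model estimates by
  construction.

## The forward simulator

`simulate_study()` generates studies from a mechanistic secretion model:

* **Baseline.** $B(\tau) = B_0 (1 - s)^{\tau/60}$ with $B_0 = 150$ ng/mg
  at the 07:00 start of the observation day and $s = 0.07$/h — a decline
  that places diurnal-only relative uGC near the low-80s, matching the
  resting condition's sub-100 mean. Events start 60–180 min into the day,
  as in a morning-focused follow protocol.
* **Event pulse.** Secretion is multiplied by the role's effect
  multiplier for 30 min from event onset (an acute HPA activation, not
  just the 1–3 min of fighting); the excess mass reaches urine through a
  gamma kernel with shape 4.75 and scale 40 min (mode 150 min, mean 190
  min), inside the observed 2–4.8 h peak-recovery window. The kernel has
  appreciable mass before 135 min, so pre-window samples receive part of
  the pulse — a deliberate feature mirroring early metabolite excretion.
* **Rank modulation.** Pulse amplitude gains
  `rank_effect_slope × (mean rank − rank)`, centred so the marginal
  aggression effect is unchanged, floored at zero.
* **Voids.** A renewal process with truncated-normal intervals
  (floor 15 min; the pre-truncation location is solved numerically so the
  realized mean is exactly the 78-min target; the realized SD is then
  slightly below the nominal 32). Each void's concentration is the
  integral of excreted concentration since the previous void divided by
  the elapsed time — a well-mixed bladder.
* **Noise and QC.** Mean-one lognormal assay noise (CV 10%, a typical
  LC-MS/MS panel precision); lognormal creatinine with median 0.5 mg/ml
  and ~2% mass below the 0.05 QC floor, plus a 1% chance of an
  ultra-dilute void; 5% recovery failures; a Dirichlet split of total uGC
  into the five analytes around the 9/37/35/5/14% average composition.

The default effect multipliers (aggressor 3.44, victim 4.31, rank slope
0.74) were set, once, so that the ground-truth marginal shifts emulate
the embedded study's group responses (≈ +23 points for aggressors,
≈ +28 for victims, ≈ −5 points per rank step); they are generator
conditions, not fitted quantities.

**Calibration.** `calibrate_effect()` finds the multiplier whose
expected ground-truth aggression−resting shift equals a target. The shift
is *not* linear in the amplitude — early pulse mass inflates the
pre-window denominator too — so the calibration root-solves the shift on
one large simulated study held fixed under common random numbers, making
the objective smooth and deterministic.

**Controlled scenarios.** `sim_scenario(shift)` builds validation
scenarios with identical aggressor/victim multipliers, no rank
modulation, and **no diurnal slope**. With the slope active, the longer
resting events place their peak windows later in the day, which induces a
few points of systematic behaviour difference with no hormonal effect at
all — realistic, but a confound when the goal is to isolate an injected
effect or to measure the test's size under an exact null.

**What the simulator does not emulate:** HPA feedback dynamics, plasma
compartment kinetics beyond the single transfer kernel, correlated
repeated aggression within a day, seasonal or social-instability effects,
and volume-dependent mixing across void boundaries. Passing recovery
tests therefore show that the pipeline's logic is sound under the stated
physiology, not that field data meet these assumptions.

## Validation problem sizes

The packaged validation suite runs parameter recovery at 200 replicate
studies of 24 events each (the embedded study's size) for the
+25-point-shift scenario, and 200 replicates under the exact null for
the size of the likelihood-ratio test; the windowing oracle sweep covers
roughly 7,000 configurations. These sizes keep the suite's Monte Carlo
error small relative to the tolerance bands its assertions use, while
staying desk-scale.

## Known limitations

* The mixed-model machinery covers exactly one random intercept — the
  design this analysis needs — not crossed or nested structures.
* Wald 95% intervals from ML fits undercover slightly at 24 events
  (~93% in the recovery runs); the package reports LRTs, not Wald tests,
  for significance.
* With 4 aggressors among 14 aggression events, role- and
  intensity-level contrasts are fragile; the stability check exists
  precisely to flag this (and does, for the intensity model).
* `relative_ugc` requires at least one QC-passing sample per window;
  events failing this are reported as incomplete rather than imputed.
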