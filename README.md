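# relugc

Event-level analysis of urinary glucocorticoid (uGC) responses to single
behavioural events in wild primates.

## The problem

Does a single aggressive interaction raise a wild male chimpanzee's
glucocorticoid level, whether he is the aggressor or the victim? Blood
sampling is impossible in the field, and urine reports the hormonal state
with a delay: GC metabolites appear in urine mostly 2–4.8 h after the
triggering event, urine accumulates in the bladder between voids, and
baseline uGC declines through the day. `relugc` implements the full
analysis chain that deals with these complications:

1. **Window assignment.** For an event starting at `t0` with duration `d`,
   urine voided in `[t0, t1)` with `t1 = t0 + 135` min reflects the
   *pre-event* hormonal state, and urine voided in `[t1, t2)` with
   `t2 = t0 + d + 270` min reflects the *event response* (peak clearance
   window). A sample voided within 30 min after `t1` or `t2` may contain
   urine from both sides of the boundary; it is assigned by comparing its
   latency past the boundary with the latency from the previous void to
   the boundary.
2. **Sample QC.** Internal-standard recovery must deviate by less than
   ±50% from its expected value, and creatinine must be ≥ 0.05 mg/ml.
3. **Quantification.** Total uGC is the sum of cortisol,
   tetrahydrocortisol, tetrahydrocortisone, 5β-androstane and
   11-oxoetiocholanolone (ng/ml), divided by creatinine (mg/ml) to correct
   for urine dilution.
4. **The event-level statistic.**
   `relative uGC = 100 × mean(peak-window uGC) / mean(pre-window uGC)`,
   a within-event ratio that cancels diurnal and between-subject baseline
   differences.
5. **Statistics.** Gaussian linear mixed models of relative uGC with a
   random intercept per subject, fitted by maximum likelihood (profiled
   over the single variance ratio), compared against intercept-only nulls
   by likelihood-ratio tests, with VIF collinearity checks and
   leave-one-subject-out stability diagnostics.
6. **Forward simulation.** A generative model of GC secretion (diurnal
   baseline, event pulse, gamma transfer kernel into urine, bladder
   accumulation over a renewal process of voids, creatinine and assay
   noise, QC failures) for end-to-end validation with known ground truth.

The package embeds its canonical worked example: 24 complete event series
(14 aggressive interactions, 10 resting controls) from nine wild adult
male chimpanzees, available as `budongo_ugc()`.

## Worked example

```r
library(relugc)
reference_models()
```

```
Relative uGC reference analysis

Group summaries (relative uGC, %):
      group  n  mean   sd
 aggression 14 111.6 28.5
    resting 10  84.7 26.6
  aggressor  4 107.7 12.6
     victim 10 113.2 33.3

Model comparisons (LMM vs intercept-only null, ML):
     model                term  beta    se     t chi2 df     p stable
 behaviour behaviouraggression 26.91 10.99  2.45 5.35  1 0.021     NA
      role      role3aggressor 22.99 15.66  1.47 5.48  2 0.065     NA
      role         role3victim 28.47 11.84  2.41 5.48  2 0.065     NA
      rank                rank -5.13  2.12 -2.42 5.25  1 0.022     NA
  duration            duration -6.11  9.04 -0.68 0.45  1 0.500     NA
 intensity    intensitycontact -2.15 15.29 -0.14 0.02  1 0.890  FALSE

note: the intensity model is unstable under leave-one-subject-out refits
```

Reading the table: relative uGC after aggression averages 112% of the
pre-event level versus 85% after resting — the behaviour effect is
β = 26.91 percentage points (SE 10.99) and the model beats the
intercept-only null (χ² = 5.35, df = 1, p = 0.021). Both victims
(β = 28.47) and aggressors (β = 22.99) drive the effect. Higher-ranking
males (rank 1 = highest) show larger responses (−5.13 points per rank
step), while aggression duration has no detectable effect and the
contact/non-contact model is too unstable to interpret.

A single fit:

```r
fit <- fit_lmm(relative_ugc ~ behaviour, budongo_ugc(), group = "subject_id")
null <- fit_lmm(relative_ugc ~ 1, budongo_ugc(), group = "subject_id")
lrt(fit, null)
#> likelihood ratio test: chi2 = 5.354, df = 1, p = 0.02067
```

Simulation-based validation of the whole pipeline:

```r
params <- sim_scenario(25)          # calibrated +25-point injected effect
recover_parameters(params, n_replicates = 200, seed = 100)
```

A command-line front end (`reproduce` / `simulate` / `process` / `fit`)
is installed at `system.file("scripts", "relugc", package = "relugc")`.

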