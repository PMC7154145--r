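# vonfrey

Simulation and signal-detection analysis of von Frey tactile threshold
studies.

## The scientific problem

Light-touch detection thresholds measured with von Frey filaments are widely
used to ask whether a clinical group (for example, autistic children) has a
*sensory* difference. But a yes/no detection task confounds two things:

* **sensitivity** — how well the observer separates signal from noise, and
* **response criterion** — how much evidence the observer demands before
  saying "yes".

A participant who is conservative (says "no" when unsure) will show an
elevated method-of-limits threshold with perfectly normal sensory function.
Signal detection theory separates the two using catch trials. From a
participant's hit proportion *H* (over stimulus trials) and false-alarm
proportion *F* (over catch trials):

```
Az = Φ( (Φ⁻¹(H) − Φ⁻¹(F)) / 2 )        equal-variance ROC area (sensitivity)
c  = −( Φ⁻¹(H) + Φ⁻¹(F) ) / 2          criterion; positive = conservative
```

with Φ the standard normal CDF. Extreme proportions are corrected before the
quantile transform: *H* = 1 becomes (hits + 0.5)/(trials + 1), *F* = 0
becomes 0.5/(catch + 1) (and mirrored for the opposite extremes).

The package provides, for researchers running or re-analysing such studies:

* a **protocol engine** for the method of limits: four alternating
  ascending/descending blocks over a 10-filament ladder (0.008–2.0 g),
  two-consecutive-response termination, 3 catch trials per ascending and 7
  per descending block, false-alarm feedback logging, a catch-trial
  exclusion rule, and block/session threshold computation;
* a **simulator** of equal-variance Gaussian observers with known
  psychometric function and internal criterion, plus cohort generation with
  realistic covariates (age, sex, IQ, SRS-2 T-scores);
* the **statistical battery** such studies use: Cliff's delta with
  consistent-variance confidence intervals, Spearman correlations, Zou's
  interval for comparing independent correlations, uncorrected 2×2
  chi-square, ICC(3,k); and
* a **cumulative probability model** (CPM): proportional-odds regression
  treating a continuous threshold as ordinal, with likelihood-ratio and Wald
  inference, Nagelkerke R², and best-subset selection by BIC with BIC
  weights and approximate Bayes factors.

Together these let you demonstrate and stress-test the core mechanism: *a
group gap in response criterion, with equal sensitivity, produces an
apparent group difference in thresholds that regression on the estimated
criterion `c` explains away*.

## Worked example

Simulate a child cohort — 35 neurotypical (NT) and 55 autistic (ASD)
participants, equal sensitivity, a criterion gap — run every session through
the staircase protocol, and score it:

```r
library(vonfrey)

d <- simulate_study(study_config(cohort_spec = default_cohort_spec("child")),
                    seed = 42)
dplyr::summarise(dplyr::group_by(d, diagnosis),
                 n = dplyr::n(), threshold = mean(threshold_g, na.rm = TRUE),
                 az = mean(az), c = mean(c))
#>   diagnosis     n threshold    az     c
#> 1 ASD          55    0.121  0.836 0.751
#> 2 NT           35    0.0601 0.828 0.505
```

The ASD group's mean threshold is twice the NT group's — with *equal*
generating sensitivity — because its observers hold a more conservative
criterion. The group difference is large by Cliff's delta:

```r
cliffs_delta(d$threshold_g[d$diagnosis == "NT"],
             d$threshold_g[d$diagnosis == "ASD"])
#>    delta    se ci_low ci_high         p   n_x   n_y
#> 1 -0.456 0.110 -0.672  -0.239 0.0000368    35    55
```

(negative delta: the comparison group, ASD, tends to exceed the NT
reference). The mechanism regression tells the real story:

```r
mechanism_scenario(d)
#> p_diag_base   = 0.0003   aor_diag_base = 4.57    # diagnosis "effect"
#> c_selected    = TRUE                             # BIC adds c to the model
#> p_diag_with_c = 0.023    aor_diag_with_c = 2.72  # shrinks once c enters
#> wald_c        = 14.8     aor_c = 27.0            # c is the top predictor
#> bic_weight_best = 1.00   bf10 = 1.7e11
```

In the baseline CPM (threshold on diagnosis, age, sex, counterbalance) the
diagnosis odds ratio is 4.6; adding the estimated criterion `c` — which
best-subset BIC selects decisively — cuts it nearly in half and makes `c`
the strongest predictor. Across 200 replicate cohorts
(`mechanism_battery(200)`), diagnosis is significant in the baseline model
in ~94% of replicates, `c` is selected and carries the largest Wald χ² in
all of them, and the full supplanting pattern (significant baseline effect
that loses significance once `c` is included) appears in about two thirds.

`autoplot(fit)`, `plot_staircase(trials)` and `plot_group_distributions(d)`
draw odds-ratio forests, per-block staircases, and group distributions; a
thin CLI (`exec/vonfrey`) exposes `simulate`, `score`, `compare`, `regress`,
`run` and `mechanism` verbs over the same functions.

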