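---
title: "Criterion, not sensitivity: methods behind the vonfrey package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criterion, not sensitivity: methods behind the vonfrey package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the observer
model, the method-of-limits protocol engine and the decisions taken where
the procedure is ambiguous, the statistical machinery, how the default
cohort parameters were calibrated, and what the simulation does and does not
establish about real data.

## 1. The question the package operationalises

Elevated light-touch thresholds in a clinical group are routinely read as a
sensory deficit. A yes/no detection task, however, rewards conservatism: an
observer who answers "yes" only when certain will look insensitive on a
method-of-limits staircase while discriminating signal from noise perfectly
well. Signal detection theory (SDT) separates the two contributions using
catch trials. The package exists to make that separation executable end to
end: simulate observers whose sensitivity and criterion are *known*, push
them through the exact field protocol, and check that the analysis pipeline
attributes group differences to the component that actually generated them.

## 2. Generative observer model

Each simulated observer is an equal-variance Gaussian SDT observer. A
filament of force $f$ grams elicits a latent signal strength, in SD units
above the noise distribution,

$$d(f) = \max\{0,\; \beta\,(\log_{10} f - \log_{10}\alpha) + 1\},$$

so that $d(\alpha) = 1$: $\alpha$ is the force at which the signal sits one
SD above noise, and $\beta$ is the psychometric slope per decade of force.
On every trial the observer draws evidence $X \sim N(d, 1)$ ($d = 0$ on
catch trials) and answers "yes" iff $X > \lambda$, where $\lambda$ is the
internal criterion on the evidence axis. With probability `lapse`
(default 0.02, capped at 0.05) the response is instead uniform at random.

This is deliberately the *same* model family under which the $A_z$ and $c$
estimators are unbiased, which makes parameter-recovery experiments
interpretable: any distortion the pipeline shows is attributable to the
protocol (finite trials, adaptive stimulus placement, termination rules),
not to model mismatch.

Two facts about the latent criterion matter throughout:

* $\lambda$ lives on the evidence axis; the estimated statistic $c$ is
  computed from one session's corrected $(H, F)$ and is **not** the same
  quantity. The mapping $\lambda \mapsto E[\hat c]$ depends on the stimulus
  mix the staircase happens to present and is established by simulation
  (`score_sessions` over a $\lambda$ grid), never assumed to be identity.
  Under the default protocol it is monotone with slope roughly 0.5–0.7 and
  an offset of about one SD: e.g. $\lambda = 1.63$ yields $E[\hat c]
  \approx 0.55$.
* The observer's theoretical false-alarm rate is $\Phi(-\lambda)$ (lapse
  aside), so realistic catch-trial behaviour (a few percent false alarms)
  requires $\lambda$ in the 1.5–2 range, not the 0.5–0.8 range in which
  estimated $c$ values are typically reported.

## 3. The protocol engine

`run_block()` / `simulate_sessions()` implement the method of limits:

* **Ladder.** Ten forces log-spaced from 0.008 g to 2.0 g
  (`filament_ladder()`); the endpoints and count are fixed by convention,
  the interior rungs are configurable.
* **Blocks.** Four blocks alternate direction; whether a session starts
  ascending or descending is counterbalanced across participants
  (alternating assignment over a seeded random order, groups within one of
  each other). Descending blocks start at 2.0 g and step down one filament
  per stimulus trial until the participant answers "no" twice in a row;
  ascending blocks start at 0.008 g and run to two consecutive "yes".
  Catch-trial responses never advance, reset, or terminate the staircase —
  termination is defined on stimulus responses only.
* **Catch trials.** Three per ascending and seven per descending block
  (descending runs invite a "yes" bias, so more catches are spent there).
  Placement is uniform at random among the realized stimulus trials, never
  after the final stimulus trial. A "yes" on a catch trial is logged as
  having received false-positive feedback; by default feedback does not
  alter the observer (whether real participants shift criterion after
  feedback is unknowable from threshold data — the hook exists, off).
* **Block threshold.** The mean of the force last responded to before the
  first terminating response and the force of that first terminating
  response (`threshold_rule = "first"`). The reading in which the whole
  terminating pair is bracketed (mean of the force before the first and the
  force of the second) is implemented as `threshold_rule = "pair"`; the
  phrase "values before and after" is genuinely ambiguous and the choice is
  exposed rather than guessed. If the first terminating response is the
  block's very first trial there is no preceding force and the extreme
  filament value is used.
* **Non-termination.** If the ladder is exhausted without two consecutive
  terminating responses, the block threshold is pinned at the extreme
  filament reached and the block flagged; sessions with flagged blocks are
  reported, not auto-excluded.
* **Exclusion.** A session is excluded when any contiguous 10-trial window
  within a block contains more than three catch trials answered "yes"
  (`exclusion_rule = "window"`; strictly more than three — exactly three is
  kept). The per-block-total reading is available as
  `exclusion_rule = "block"`. Excluded sessions carry no threshold but keep
  their SDT counts.
* **Scoring.** One $(H, F)$ pair per session: hits over *all* stimulus
  trials across the four blocks, false alarms over all 20 catch trials
  (2×3 + 2×7). Counting every stimulus trial in the denominator couples
  $H$ — and therefore $\hat A_z$ and $\hat c$ — to the staircase's adaptive
  stimulus placement: near-threshold trials deflate $H$, and
  higher-threshold observers are shown relatively more detectable stimuli.
  This is faithful to how a single per-participant hit rate must be formed
  from this task, and it is the reason simulated $\hat A_z$ can even
  *increase* slightly with a more conservative criterion. Analyses should
  treat $\hat A_z$ as the protocol's sensitivity estimate, not as ground
  truth.

Extreme proportions are corrected before the quantile transform ($H = 1
\to (n_\text{hits}+0.5)/(n_\text{stim}+1)$, $F = 0 \to
0.5/(n_\text{catch}+1)$); the mirrored corrections for $H = 0$ and $F = 1$
use the same $\pm 0.5/(n+1)$ rule so that $\Phi^{-1}$ stays finite for any
count vector.

## 4. Cohort generation and the calibration of its defaults

`default_cohort_spec()` defines four groups — diagnosis (NT/ASD) crossed
with age band (child/adult) — with group sizes (35/55/24/33), age, sex, IQ
and SRS-2 T-score distributions drawn as truncated normals (rejection
sampling, 1000-attempt cap) at the values such a study reports. SRS scores
are generated with a configurable correlation (default 0.3) to the latent
criterion so that symptom–criterion correlation analyses have signal to
find. The study design encoded in the defaults is: a *criterion* gap
confined to the child band with equal child sensitivity
($\lambda$: NT 1.63 vs ASD 2.04, same $\alpha$ and $\beta$), similar adult
criteria (both 1.93), and a mild adult *sensitivity* deficit carried by
$\alpha$ (0.014 vs 0.010 g).

These latent values were **calibrated once, by simulation inversion,
against the printed summaries such a study reports** — estimated $c$ group
means near 0.55 (NT child), 0.76 (ASD child), 0.71/0.77 (adults), mean
thresholds a few hundredths of a gram with the ASD-child mean roughly
double the NT-child mean, false-alarm rates of a few percent, and exclusion
rates around one percent. Plugging reported $\hat c$ values directly into
$\lambda$ would be a category error: it implies false-alarm rates near
30%, floods the staircase with spurious ascending terminations, and
excludes 8–15% of simulated participants. The calibrated defaults
reproduce the reported scale of every summary simultaneously:

```{r}
library(vonfrey)
d <- simulate_study(study_config(cohort_spec = default_cohort_spec("child")),
                    seed = 42)
dplyr::summarise(dplyr::group_by(d, diagnosis),
                 thr = mean(threshold_g, na.rm = TRUE),
                 c = mean(c), az = mean(az), excluded = sum(excluded))
```

The criterion SDs keep the reported dispersions (0.19–0.29); since measured
$\hat c$ adds estimation noise on top, simulated $\hat c$ SDs run slightly
high — accepted rather than deconvolved. Age affects simulated thresholds
only through the band-level parameter differences (adults hold higher
$\lambda$), not continuously within band; a continuous age model would be
pure invention.

## 5. Statistical battery

* **Cliff's delta** (`cliffs_delta`): $\hat\delta = \sum_{ij}
  \mathrm{sign}(x_i - y_j)/(n_x n_y)$, ties contributing zero. The variance
  is Cliff's consistent estimator from the row/column dominance means,
  $$s^2 = \frac{n_y^2\sum_i(d_{i\cdot}-d)^2 + n_x^2\sum_j(d_{\cdot j}-d)^2
  - \sum_{ij}(d_{ij}-d)^2}{n_x n_y (n_x - 1)(n_y - 1)},$$
  floored at $(1-\hat\delta^2)/(n_x n_y - 1)$ in degenerate cases (complete
  separation); the CI is the normal interval truncated to $[-1,1]$ and its
  ~95% coverage is verified empirically in the test suite. The first
  argument is the reference group: with NT as reference, a higher-scoring
  ASD group yields negative delta, matching the sign convention of group
  tables in this literature.
* **Spearman** via Pearson on average ranks with the $t$ approximation;
  **Zou's interval** for a difference of independent correlations from the
  two back-transformed Fisher-z intervals; **2×2 chi-square** without
  continuity correction (`stats::chisq.test(correct = FALSE)`);
  **ICC(3,k)** (two-way mixed, consistency, average measures)
  $(MS_B - MS_E)/MS_B$ with the F-based interval, used on the four
  log block thresholds to justify pooling them. Group-comparison p-values
  are reported unadjusted, as is conventional for these exploratory tables.

## 6. The cumulative probability model

`cpm()` fits the proportional-odds model treating every distinct outcome
value as an ordered category:
$\Pr(Y \ge y_j \mid X) = \mathrm{logit}^{-1}(\alpha_j + X\beta)$, one
intercept per distinct value beyond the first, ties sharing a category.
This is the semi-parametric regression that generalises the
Wilcoxon–Mann–Whitney test to multiple predictors; slopes are invariant to
any strictly increasing transform of the outcome, which is exactly what a
heavily skewed threshold variable needs.

Numerics: the log-likelihood is concave; it is maximised by Newton–Raphson
with analytic gradient and Hessian, step-halving, a gradient max-norm
tolerance of $10^{-8}$, and the empirical-margin null as starting point
(the exact MLE of the intercept-only model, which therefore needs no
iteration at all). The intercept block of the Hessian is tridiagonal, so
the Newton step and the slope covariance are computed through the Schur
complement with a sparse banded solve — fits with thousands of distinct
outcome values take tens of milliseconds. A non-positive-definite system
falls back to a ridged solve; non-convergence is flagged on the fit, and
the pipeline reports flagged rows rather than failing.

Inference follows the field's reporting conventions: model LR $\chi^2$
against the intercept-only null, per-slope Wald $\chi^2 = (b/\mathrm{se})^2$
with adjusted odds ratios $e^b$ and Wald intervals, Nagelkerke
$R^2 = \frac{1-\exp\{-\frac2n(\ell-\ell_0)\}}{1-\exp\{\frac2n \ell_0\}}$.

**Best-subset selection** (`best_subset_cpm`) enumerates all subsets of at
most 15 candidate predictors added to a forced baseline (the baseline terms
appear in every candidate model; a joint search is available via
`force_base = FALSE`), ranks by BIC, and reports BIC weights
$w_i \propto e^{-\Delta_i/2}$ and the approximate Bayes factor
$BF_{10} = e^{(BIC_\text{base} - BIC_\text{best})/2}$. The BIC penalty
counts **slope parameters only**: every candidate model shares the same
outcome and hence the same intercept set, so intercept counts cancel from
all BIC differences; including them would only shift every model's BIC by
the same amount. This convention is stated because published analyses
rarely say which they used.

## 7. The mechanism experiment

`mechanism_scenario()` runs the two-step analysis on one scored cohort:
baseline CPM (threshold on diagnosis, age, sex, counterbalance), best-subset
over SDT candidates (default $A_z$ and $c$), and the baseline-plus-$c$
model. It reports whether diagnosis is significant at baseline, whether $c$
is selected, whether diagnosis survives $c$, and whether $c$ carries the
largest Wald $\chi^2$. `mechanism_battery()` replicates this over
independent cohorts; with the default child spec (criterion gap, equal
sensitivity, n = 90) the supplanting pattern — significant baseline
diagnosis effect, $c$ selected, diagnosis non-significant with $c$ in the
model, $c$ the top predictor — appears in roughly two thirds of 200
replicates, and the matched null (no criterion gap) rejects the baseline
diagnosis effect at the nominal 5% rate. The residual diagnosis effect in
the other third is exactly what measurement noise predicts: $\hat c$ is an
attenuated proxy of $\lambda$ (session-level reliability well below 1), so
conditioning on it cannot remove the whole group gap — a caution that
applies verbatim to real studies.

## 8. Validation experiments and problem sizes

The test suite fixes seeds and uses these scales, chosen to give the
relevant Monte-Carlo error a comfortable margin:

* SDT oracle equivalence over all 441 count pairs at 20 stimulus / 20 catch
  trials, tolerance $10^{-12}$, against a literal transcription of the two
  printed equations.
* Cliff's delta against brute-force enumeration on 200 random small
  samples; CI coverage over 2000 normal-shift replicates at n = 30 per
  group (target band 93–97%).
* CPM vs Wilcoxon: LR p-values within 0.02 of the normal-approximation
  Wilcoxon test on 100 datasets of n = 40; slope invariance under monotone
  transforms to $10^{-6}$; MLE agreement with an independent ordinal fitter
  (`MASS::polr`) on discretised data.
* LR null calibration: 1000 single-noise-predictor fits at n = 100,
  Kolmogorov–Smirnov against $\chi^2_1$.
* BIC consistency: mean weight of the true model over n ∈ {100, 400, 1600}
  (8 replicates each), strictly increasing.
* Criterion sweep: 11 λ values in [0.2, 1.2] × 200 sessions each, with the
  catch-trial exclusion disabled so the estimand is the protocol mapping
  itself rather than a selected subpopulation; mean $\hat c$ and mean
  threshold both strictly increasing. Recovery regression of $\hat c$ on
  λ across 500 participants at the calibrated operating point.
* Mechanism battery: 200 replicate cohorts plus 200 matched-null cohorts.

## 9. What passing these tests does and does not show

The generator emulates: the staircase and its termination/exclusion rules,
catch-trial structure, counterbalancing, SDT scoring with corrections, and
cohort covariate structure with a criterion-only child gap. It does *not*
emulate: reaction times, learning or feedback-driven criterion drift within
a session, block-direction-dependent criteria (a config hook exists,
default off), developmental trajectories beyond the two age bands,
tactile-specific questionnaire structure beyond a single criterion–SRS
correlation, or unequal-variance evidence distributions. Consequently the
simulations validate the *pipeline* — that the estimators and regressions
attribute effects to the component that generated them under the model the
estimators assume — and quantify protocol-induced biases (the $H$-denominator
coupling, staircase noise, attenuation of the supplanting pattern). They
cannot show that real groups differ in criterion rather than sensitivity;
they show that when they do, this analysis finds it, and how often noise
would mask it.
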