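---
title: "Batch-aware construction and validation of prognostic survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch-aware construction and validation of prognostic survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchsurv)
```

## The problem

A prognostic survival model combines a few candidate biomarkers — here
RT-qPCR gene-expression measurements on the normalized Ct scale — with
clinical covariates into a Cox proportional-hazards linear predictor
$M_i = Z_i\beta$ that orders patients by their risk of death within a
clinically relevant horizon (day 14 after septic-shock onset in the
motivating application, with day 7 as the primary read-out). Samples are
processed in batches: one RT run / PCR plate shares reagents, operator
and drift, so measurements within a batch are more alike than
measurements across batches. Any internal validation scheme that splits
patients without regard to the plate layout lets this shared technical
variability flow from training folds into test folds and returns an
optimistic picture of how the model will behave on data acquired later.

`batchsurv` implements the complete workflow: fold construction under a
patient-level outcome-stratified scheme (strategy A) and a batch-level
scheme (strategy B); a catalogue of model-building strategies; censored
performance indicators with two cross-validation estimation schemes;
selection diagnostics; and final-fit validation on an independent test
set.

## Assumptions

* Proportional hazards on the covariates actually entering the model;
  censoring the follow-up at the clinical horizon (day 14) is part of the
  design precisely to keep this tenable.
* Censoring independent of the event time given the covariates. The
  administrative day-14 cut satisfies this trivially.
* Batches are the unit of technical variability and never span the
  train/test split (enforced by the data container).
* Delta-Ct normalization is sample-wise, so it is applied once, outside
  the cross-validation loop; every other model-building step (variable
  selection, functional form, fitting, shrinkage) is re-run inside each
  training fold.

## Resampling strategies

Both schemes are N-times k-fold with defaults $k = 5$, $N = 20$.

**Strategy A** deals events and non-events separately into folds after
independent shuffles, so per-fold event counts differ by at most one.
This operationalizes "the proportion of events is the same in each fold"
up to integer rounding.

**Strategy B** partitions whole batches into folds. Nothing in the
batch-level scheme dictates how unequal batch sizes are balanced; we
balance
total patient counts greedily (largest batch first, into the currently
smallest fold, ties broken by a per-repetition shuffle). Event
proportions are deliberately left unbalanced — that imbalance is the
phenomenon the scheme is designed to expose. Training folds that end up
with zero events are skipped and logged, never imputed.

## Performance indicators and their estimation

* **Graf IPCW Brier score** at $t$: deaths by $t$ contribute
  $\hat\pi(t|Z)^2/\hat G(T_i^-)$, patients followed past $t$ contribute
  $(1-\hat\pi(t|Z))^2/\hat G(t)$, censored-before-$t$ patients contribute
  0, with $\hat G$ the reverse Kaplan–Meier estimate of the censoring
  survival computed **on the evaluation set itself** (the test fold for
  averaging; the pooled repetition set for pooling). Where
  $\hat G(t) = 0$ the score is returned missing with a warning.
* **Harrell's C**: usable pairs are those where the earlier observed time
  is an event time; tied event times make a pair unusable; tied markers
  count one half. These tie conventions are stated because the source
  methodology leaves them open.
* **Cumulative/dynamic sensitivity/specificity**: cases at $t$ are
  patients with $T \le t$, controls those with $T > t$. Under censoring
  we estimate by Bayes inversion with Kaplan–Meier survival inside the
  two marker strata, clipped to $[0,1]$. This variant is deterministic and
  parameter-free, and reduces *exactly* to empirical fractions when no
  censoring occurs before $t$ — which is why the test suite can check it
  against direct counting and the Mann–Whitney statistic. A
  nearest-neighbour smoothed variant exists in the literature; we chose
  the unsmoothed one to keep the estimator free of a bandwidth parameter.
  Note one boundary convention: a marker exactly equal to the threshold
  counts as negative ($M \le c$), so at a threshold tied with a control's
  marker the specificity includes that control.
* **Time-dependent AUC**: trapezoidal area over the ROC traversed in
  threshold order (from $+\infty$ down), not re-sorted by false-positive
  rate — re-sorting is unstable when floating-point jitter breaks ties at
  staircase corners.
* **Pooling vs averaging**: pooling concatenates the test-fold scores of
  one repetition and evaluates once; averaging evaluates per fold and
  averages. Both then average over repetitions and retain per-repetition
  values for dispersion. Pooled *linear-predictor* scores are comparable
  across folds; pooled *predicted-survival* scores are not when fold
  baselines differ (batch-level resampling with unbalanced event rates),
  and `aggregate_cv()` emits an explicit bias warning in that situation
  rather than refusing the computation.
* **Linear-predictor centering**: all reported linear predictors are
  centered at the training-fold mean, $Z\hat\beta - \bar Z\hat\beta$ (the
  `coxph` convention). Predicted survival is invariant to this, but
  pooled cross-fold comparisons are not: uncentered predictors carry a
  fold-specific location term $\bar Z\hat\beta_f$ that adds pure noise to
  pooled rankings. With centering, pooled and averaged AUC agree to
  within 0.02 on balanced synthetic cohorts, as they should.
* **Optimism** is apparent (training-fold) minus test-fold performance,
  averaged over folds and repetitions — zero for the null model by
  construction, increasing with model complexity.

## Model-building strategies

All fits use the Breslow tie convention, for both the partial likelihood
and the baseline cumulative hazard, so that
$\hat\pi(t|z) = \exp(-\hat\Lambda_0(t) e^{z\hat\beta})$ is internally
consistent. Iteration stops at a relative convergence tolerance of
$10^{-10}$; monotone-likelihood fits (infinite coefficients) raise errors
that the cross-validation loop converts into logged fold skips.

* **Backward AIC** drops the covariate whose removal most decreases
  $-2\log PL + 2p$, stopping when no removal helps. Note the calibration
  this implies: a pure-noise 1-df covariate is dropped with probability
  $P(\chi^2_1 < 2) \approx 0.84$, not more.
* **Fractional polynomials** use the conventional 8-power set
  $\{-2,-1,-0.5,0,0.5,1,2,3\}$ with $x^0 \equiv \ln x$ and repeated
  powers $(p,p) \mapsto (x^p, x^p\ln x)$; covariates are shifted by
  `fp_shift()` (minimum plus the smallest observed spacing) when not
  strictly positive. The MFP closed test per covariate: best-FP2 vs null
  at level `select` (4 df exclusion test), then FP2 vs linear (3 df) and
  FP2 vs FP1 (2 df) at level `alpha`, cycling to stabilization (at most 5
  cycles). Binary or few-valued covariates only face the 1-df in/out
  test. The `select` grid {0.05, 0.10, 0.15} and `alpha` grid
  {0.05, 0.1, 0.2, 0.3, 0.4} span the catalogue; models are named by the
  (`select`, `alpha`) pair rather than by an opaque suffix.
* **Penalized Cox**: the objective is
  $\log PL(\beta) - \lambda \sum_j w_j |\beta_j|$ with covariates
  standardized to unit variance internally and coefficients reported on
  the original scale; $\lambda \in \{0.01, 0.1, 1, 10, 100\}$ (larger =
  sparser; a bare λ grid is otherwise scale-ambiguous, so fixing the
  standardized per-likelihood scale makes it reproducible). Lasso:
  $w_j = 1$. Adaptive lasso: $w_j \propto 1/|\tilde\beta_j|$ from a
  lightly ridge-penalized initial fit (ridge penalty 0.01 on the
  standardized scale), with the weights rescaled to mean 1 — the weight
  scale is arbitrary (absorbable into $\lambda$), and mean-1 scaling
  keeps $\lambda$ comparable with the plain lasso. SCAD: local linear
  approximation, i.e. up to three iterations of weighted lasso with
  weights $p'_{SCAD}(|\beta_j|;\lambda)/\lambda$ and the customary second
  constant $a = 3.7$; these weights keep their absolute scale since
  $w \in [0,1]$ is meaningful (0 = large coefficient, unpenalized).
  The selection-then-refit family re-fits an unpenalized Cox model on the
  penalized fit's support.
* Whether the original application standardized covariates before
  penalization is unknown; we standardize, and say so here rather than
  leave it implicit.

## Selection diagnostics

The Kuncheva index $(r - s^2/N)/(s - s^2/N)$ is reported only when the
selected-set size $s$ is constant across folds (it is undefined
otherwise); all strategies additionally get per-covariate selection
frequencies. The omitted-covariate screens follow two routes: averaged
Martingale residuals $\delta_i - \hat\Lambda_0(T_i)e^{Z_i\hat\beta}$
against the omitted covariate, summarized by a Spearman rank test (chosen
as a parameter-free complement to the purely visual smooth; the lowess
curve is exported for plotting but is never a test statistic), and
per-repetition logistic models for $P(M>c \mid \text{dead by } t)$ and
$P(M\le c \mid \text{alive after } t)$ on the omitted covariate,
restricted to patients with known vital status at $t$. The cutoff grid
defaults to the inner deciles (10%–90%) of the pooled linear predictor.
Raw p-values and the proportion below 0.05 are reported without
multiplicity correction — the screen is an indicator, not a formal test —
and the package's calibration tests verify the ~5% false-positive rate
under independence.

## Sample-size planning

`schoenfeld_events()` returns
$\lceil (z_\beta + z_{1-\alpha})^2 / (p_A p_B (\ln\Delta_0)^2) \rceil$
with a one-sided $\alpha$ as written; pass $\alpha/2$ for a two-sided
design. For training-set sizing the 5–10 events-per-variable rule of
thumb applies (the study design this package emulates kept 9 candidates
for 44 training events by omitting, e.g., patient age — which is exactly
what the omitted-covariate screens are for).

## The synthetic cohort generator

No public accession exists for the motivating cohort, so the generator
is a first-class, tested module that emulates the study design:

* 156 training patients over 14 batches, 95 test patients over 9
  batches, 6 gene + 3 clinical candidates, administrative censoring at
  day 14, target event proportion 0.28.
* Event times come from a Weibull-baseline proportional-hazards law
  $S(t|Z) = \exp(-(t/\text{scale})^{\text{shape}} e^{Z\beta})$ by inverse
  transform. The data-generating family of the real study is unknown;
  Weibull was chosen because it contains the exponential (shape 1, the
  default) and allows non-constant hazards. The scale is calibrated by
  root-finding on the realized linear predictors so the *expected* event
  proportion at the censoring horizon equals the target within ±0.03
  (disable with `calibrate_scale = FALSE` when a fixed baseline is wanted,
  e.g. for closed-form checks).
* Default true effects: $\beta_{G2} = -0.5$, $\beta_{G3} = 0.5$,
  $\beta_{C1} = 0.15$, $\beta_{C2} = 0.35$, remaining candidates null —
  magnitudes in the range of the hazard ratios reported for the
  motivating study's final model.
* **Batch structure.** Gene covariates are biological signal plus a
  batch-shared technical shift (one scalar per batch, scaled by a
  per-gene loading in $[0.5, 1.5]$) plus measurement noise (sd 0.25 Ct);
  the hazard depends on the signal only, so batch shifts are pure
  technical confounding. Clinical covariates are batch-free. The shift
  sd (`batch_sd`, default 0.5 Ct) is arbitrary: the real between-batch
  technical variance was never quantified. `test_batch_sd` lets the test
  dataset's batches carry larger shifts, emulating acquisition in a
  separate period.
* **Unbalanced batch event rates** come from per-batch log-hazard
  frailties with sd `batch_event_dispersion` (default 0.6, chosen once so
  the interquartile spread of per-batch event proportions resembles the
  0.15–0.31 reported for the motivating study).

What the generator does **not** emulate: raw amplification curves and
crossing-point calling (generation starts at the Ct value), missing
values, competing risks, non-proportional hazards, informative dropout
(a uniform-dropout option exists but is off by default), and correlation
structure between gene signals beyond independence. Tests passing on
these cohorts therefore certify the estimators and the resampling
machinery, not robustness to every failure mode of real RT-qPCR data.

## Numerical and degenerate-input conventions

* Kaplan–Meier and cumulative hazards are right-continuous step
  functions; $\hat\Lambda_0(0) = 0$; $\hat G(T^-)$ is evaluated as the
  left limit.
* C-index with no usable pairs raises an error; a constant marker gives
  exactly 0.5 by the tie convention, which is also why the null model's
  cross-validated C-index is 0.5.
* Calibration groups collapse automatically when predictions are heavily
  tied; a group with no follow-up to $t$ reports KM at its last observed
  time, flagged.
* Bootstrap intervals are percentile intervals; resamples where an
  indicator is undefined are skipped and counted, and an interval with
  more than 20% skips is flagged unstable. The bootstrap unit is the
  patient by default (a batch-level option exists).
* All fold plans, generated cohorts and pipeline outputs are pure
  functions of their seeds; the demo pipeline is byte-identical across
  repeated runs.

## Problem sizes used by the test suite

The package's own validation runs at deliberately modest scale: cohorts
of 80–250 patients, 50-replicate simulations for stochastic properties,
$N \le 5$ repetitions inside replicated cross-validations, and 100–500
bootstrap resamples. These sizes keep every property detectable at the
asserted thresholds (Monte-Carlo error well below the tested margins)
while the entire suite stays inexpensive to run.

## Known limitations

* The validation-surprise comparison (batch-level CV tracking the
  external test set better than patient-level CV) is subtler than the
  other properties. When the test set is drawn from *exactly* the same
  law as the training set, the external test AUC tends to land between
  the two CV estimates: patient-level CV is inflated by batch-level
  chance confounding but deflated by training folds being smaller than
  the full training set, and the two errors partly cancel. The property
  emerges under the conditions the method was designed for — technical
  and outcome variability between batches large relative to the signal,
  and leave-one-batch-out folding so fold-size pessimism is minimal.
  The acceptance suite tests it under those conditions and the margin is
  modest; on real paired train/test datasets with genuine between-period
  drift the effect should be more pronounced than in this same-law
  synthetic world.
* The 0.632+ bootstrap error estimator is deliberately out of scope: the
  batch sampling scheme does not transfer to bootstrap resampling (batch
  inclusion probabilities are no longer 0.632).
* No multiple-imputation support for missing predictors; inputs are
  required complete.
* No IPCW compensation inside the omitted-covariate logistic screen;
  patients censored before the evaluation day are excluded, which
  inflates its variance under heavy censoring.
* Expert dichotomization cutoffs (the `-Fac` covariate variants) are
  user-supplied configuration, never inferred from data.
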