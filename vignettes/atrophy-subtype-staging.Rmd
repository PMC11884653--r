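---
title: "Modelling spatiotemporal atrophy subtypes with sustainr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatiotemporal atrophy subtypes with sustainr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Language-led dementias such as primary progressive aphasia (PPA) are
clinically heterogeneous, and two of the three canonical variants
(non-fluent/agrammatic and logopenic) are hard to tell apart on structural
MRI. `sustainr` implements an unsupervised route to this problem: given
regional brain volumes for a patient cohort and a cognitively normal control
cohort, it discovers *data-driven subtypes*, each defined by an ordered
sequence in which regions become abnormal, and places every scan at a
*stage* along its subtype's sequence. The model family is subtype and stage
inference (SuStaIn) in its threshold ("z-score") event variant.

## From volumes to abnormality: w-scores

For each region of interest (ROI), an ordinary least-squares regression is
fitted on the controls with covariates sex, age at scan, total intracranial
volume (TIV) and scanner type. A patient visit's w-score (covariate-adjusted
z-score) for ROI $b$ is

$$ w_b = -\,\frac{\text{observed}_b - \text{predicted}_b}{\hat\sigma_b}, $$

where $\hat\sigma_b$ is the sample standard deviation of the control
residuals. Two implementation choices deserve a note:

* **Denominator.** We use the residual standard deviation, not the residual
  variance: only then is the score unit-scaled, making integer severity
  thresholds (1, 2, 3) meaningful. With the $n-1$ (sample SD) convention,
  in-sample control w-scores have mean exactly 0 and SD exactly 1 per ROI —
  the calibration the tests assert.
* **Sign.** Atrophy *lowers* volume; scores are negated so that abnormality
  is positive and increasing, matching ascending thresholds. `sign_flip =
  FALSE` recovers the raw convention.

Scanner enters as a categorical fixed effect with reference-level encoding;
an unseen scanner category at scoring time is an explicit error, never an
extrapolation. Follow-up visits are scored with the baseline-fitted control
model using the visit's own age and scanner values. No mixed-effects or
site-harmonization model is used, by design: the upstream analysis uses
plain covariate regression.

## The progression model

Each ROI contributes one *event* per severity threshold; with 19 ROIs and
thresholds (1, 2, 3) the model has $N = 57$ events. A *subtype* is a
permutation $S_c$ of all events (its sequence), with within-ROI threshold
events constrained to ascending order (trajectories are monotone, so a
descending order is physically meaningless). The expected w-score of
biomarker $b$ at stage $k$ is piecewise linear: 0 at stage 0, exactly $z$ at
the position of event $(b, z)$, and rising from the last threshold to
$z_{\max}$ (top threshold + 2, i.e. 5 for thresholds 1/2/3 and 7 for the
2/4/5 sensitivity configuration) at stage $N$.

A subject's likelihood under subtype $c$ and stage $k$ is a product of
Gaussians centred on the expected trajectory with SD $\sigma_b = 1$ w-score
unit (the data are standardized by construction; $\sigma_b$ is
configurable). The data log-likelihood is the mixture

$$ \sum_i \log \sum_{c} f_c \, \frac{1}{N+1} \sum_{k=0}^{N}
   p(x_i \mid S_c, k), $$

with a uniform stage prior that includes stage 0, so "no events yet" is
always reachable.

### Fitting

* $C = 1$: greedy event-relocation ascent — every event is tried at every
  other position (restoring within-ROI threshold order) and the best
  improving relocation is applied until a local optimum — over one
  data-driven start (events ranked by exceedance frequency) plus random
  restarts. On instances small enough to enumerate, the tests verify the
  greedy optimum equals the global optimum.
* $C > 1$: hierarchical initialisation by cluster splitting. Each subtype of
  the fitted $(C-1)$-model is split by random bipartition of its
  hard-assigned subjects; both halves are refitted and the best of `n_split`
  attempts initialises expectation-maximization. EM alternates exact
  responsibilities, exact fraction updates ($f_c$ = mean responsibility) and
  responsibility-weighted greedy sequence re-optimisation. The sequence
  M-step runs on the subjects carrying non-negligible responsibility
  (floor $10^{-3}$) and a candidate sequence is accepted only if it improves
  the full-data mixture log-likelihood, so the EM trace is non-decreasing by
  construction; the tests assert this per iteration.
* Ties in any argmax break to the smallest index, and every stochastic step
  takes an explicit seed, so fits are bit-reproducible.

Numerical care: all posteriors are computed in log space with
logsumexp; stage terms more than 37 log-units below the per-subject maximum
are skipped (below double-precision relevance); degenerate control fits are
guarded by a residual-SD floor of $10^{-8}$.

### Uncertainty and model selection

Model uncertainty uses a Metropolis sampler over sequences: per iteration,
one subtype, one randomly chosen event, one uniformly random target
position (with threshold order restored), accepted with the likelihood
ratio of the full mixture (fractions fixed). Because the chain starts at the
EM-initialised optimum, no burn-in is discarded: all iterations (default
10&nbsp;000) are retained. On a 6-sequence instance the tests verify the
sampled posterior is within total-variation 0.05 of the exactly enumerated
posterior.

The number of subtypes is chosen by a cross-validation information
criterion: random folds, per-fold refit of the full hierarchy, and
$\mathrm{CVIC}(C) = \sum_{\text{folds}} -2 \ell_{\text{held-out}}(C)$,
minimised over candidates (default 1–5). Held-out likelihood uses the
point-estimate sequences, not MCMC averages — a declared choice where the
upstream description is silent. Inside
cross-validation the fitting controls are lighter than a final fit (fewer
restarts and split attempts, looser EM tolerance), since each fold refits
the hierarchy.

A parsimony caveat: when the per-fold fits recover the true sequences only
approximately (local greedy/EM optima), an extra subtype can partially
compensate the residual sequence misfit, so held-out likelihood — and hence
CVIC — can keep improving slightly *past* the true number of subtypes. On
clearly one-dimensional data CVIC is decisive (it rises monotonically with
every redundant subtype), but near the true count it should be read
together with the between-subtype similarity analysis below: genuinely
distinct subtypes sit far below the randomized reference distance, whereas
a redundant split of one subtype produces two highly similar positional
variance distributions.

## Subtyping and staging of individuals

The joint posterior $P(c, k \mid x) \propto f_c\, p(x \mid S_c, k)$ is
normalised per visit. The default assignment is two-step: stage = argmax of
the subtype-marginal stage posterior; if that stage is 0 the visit is *not
subtypable* (its volumes are compatible with controls) and carries no
subtype; otherwise subtype = argmax of the stage-marginal subtype posterior.
The joint-cell argmax is available as `mode = "joint"`. External cohorts are
w-scored against their *own* controls and assigned with the trained model,
with no refitting.

One identifiability caveat documented by the tests: at the terminal stage
$N$ every subtype trajectory has converged to the same fully saturated
profile, so subtype identity is undefined there even for noise-free data.
Consistency checks that require perfect subtype stability therefore draw
baseline stages from the early/middle course (uniform over 1–35 of 57),
which also mirrors the observation that real baseline scans do not occupy
the terminal stages.

## Similarity between subtype models

The positional variance distribution (PVD) of a fitted subtype is the
$N \times N$ matrix of posterior probabilities that event $e$ sits at stage
position $s$, estimated from the MCMC samples; rows and columns each sum
to 1. Two models are compared by the Hellinger distance
$H(P,Q) = \sqrt{1 - \sum_i \sqrt{p_i q_i}}$ between corresponding PVD rows,
aggregated by unweighted mean over events (configurable to max; the
aggregation is a declared choice). $H$ is 0 for identical distributions and
1 for disjoint support.

Observed distances are judged against a randomized reference. Two schemes
ship, and the scheme identifier is stored with every reference value so
results are never compared across schemes:

* `delta-permutation`: pairs of independent uniformly random event
  permutations, treated as delta PVDs. By symmetry each event lands on the
  same position with probability $1/N$, so the mean distance converges to
  $1 - 1/N$ (≈ 0.9825 for 57 events) — an analytic anchor the tests check.
* `permuted-data`: each biomarker's rows of the w-score matrix are permuted
  independently (destroying the cross-regional correlation that carries the
  progression signal), a one-subtype model is refitted with a short MCMC,
  and two such refits are compared.

## Longitudinal consistency

Follow-up visits are assigned with the trained model and summarised per
subject: subtype stability between baseline and first follow-up (per subtype
and overall), a three-way staging outcome (advanced / same / regressed)
among stable-subtype subjects, the same-or-advanced staging consistency,
multi-visit counts (always-same-subtype, monotone stage), and a
baseline-to-follow-up transition matrix with a stage-zero sink column.
Subjects unsubtypable at baseline are excluded from all denominators; stage
"regression" means strictly decreasing, "same" exact equality.

## The synthetic cohort generator

No patient data are distributable, so the generator is a first-class,
tested module that emulates the study design end-to-end:

* 270 patients across four subtypes with mixture fractions
  (82, 71, 59, 52)/264, 121 controls, 19 largely left-lateralised ROIs.
* Truth sequences: four orderings with temporal-first, insula-first,
  temporoparietal-first and frontal-first progression, built from ROI
  priority lists with thresholds lagging 6 positions apart.
* Forward model: volume = covariate predictor − $\sigma_{ROI}$ ×
  abnormality, with $\sigma_{ROI}$ = 5% of the ROI's baseline volume.
  Patient abnormality is the planted trajectory value plus Gaussian noise
  (SD 1 by default); control abnormality is unit-variance noise, so the
  fitted control residual SD recovers $\sigma_{ROI}$ and w-scoring inverts
  the forward model. `true_covariate_model()` exposes the exact generating
  regression, which makes noise-free cohorts invert to machine precision —
  the round-trip the tests exploit.
* Covariates: age (patients 66.1 ± 7.9 y, controls 61.7 ± 11.1 y), sex,
  TIV (1.45 ± 0.13 L), three scanner types; effect sizes −25 mm³/y (age),
  +300 mm³ (male), 0.004 mm³/mm³ (TIV), ±150 mm³ (scanner offsets).
* Baseline stages: uniform over 0..57 by default. The upstream cohort's
  stage distribution is unpublished; uniform maximises stage coverage in
  tests. Diagnosis labels are drawn conditionally on the true subtype with
  probabilities taken from the published subtype-by-diagnosis table, so the
  subtype–phenotype contingency analysis has planted signal.
* Longitudinal design: 137/270 subjects receive 1–3 follow-ups (counts
  71/43/23), intervals 1.1 ± 0.6 years truncated at &gt; 0, true stage
  advancing by round(4 × interval) stages (4 stages/year is a modelling
  choice, not a published value — it makes most subjects advance a
  handful of stages per ~1.1-year interval), scanner switching with
  probability 0.2.

What the generator does **not** emulate: measurement artefacts correlated
across regions, scanner-specific variance differences, non-Gaussian residual
tails, diagnosis-dependent covariate distributions, and stage-dependent
dropout. Passing tests therefore demonstrate correctness of the machinery
under the stated generative assumptions, not robustness of the scientific
conclusions to violations of them.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen once: the parameter-recovery
and model-selection checks use a 300-patient, 121-control cohort with all
57 events, 1000 MCMC iterations and 5 cross-validation folds over
candidates 1–5; brute-force oracles run on 3-event instances where all 6
sequences can be enumerated; the randomized reference uses 2000 pairs. A
full-scale analysis would raise MCMC iterations to 10&nbsp;000 and folds to
10 (the package defaults).

## Known limitations

* The greedy/EM schedule is a local optimiser; different seeds can land in
  different local optima, which is why restarts and split attempts are
  exposed and fit metadata records them.
* $\sigma_b$ is fixed rather than estimated; no mixture-of-Gaussians event
  model, no parallel-tempered or Hamiltonian samplers.
* Subtype identity is undefined at the saturated terminal stage (see
  above), and weakly constrained very-late event orderings can tie.
* The randomized reference schemes are declared constructions; the
  reference value depends on the scheme and is only comparable within one.

## Reproducing a full run

```r
library(sustainr)
cfg <- pipeline_config(synthetic = TRUE, n_subtypes = 4, seed = 1)
res <- run_pipeline(cfg, "run1")
res$model          # fitted sequences, fractions, log-likelihood
res$stability      # longitudinal stability report
res$contingency    # subtype-by-diagnosis chi-square
```

Every artifact (volumes, w-scores, model, PVD matrices, assignments,
stability, contingency, manifest) is a delimited text or YAML file; rerunning
with the same configuration reproduces them byte for byte.
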