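# sustainr

Data-driven discovery of **spatiotemporal atrophy subtypes** from regional
brain volumes, in R. `sustainr` implements the threshold ("z-score") event
variant of subtype and stage inference (SuStaIn) for the setting of the
primary progressive aphasias (PPA): a patient cohort and a cognitively
normal control cohort are measured on a panel of regional volumes, and the
package

1. converts volumes to **w-scores** (covariate-adjusted z-scores) against a
   control regression with sex, age, TIV and scanner covariates:
   `w = -(observed - predicted) / residual SD`;
2. fits a **mixture of event sequences**: each subtype *c* is an ordering
   `S_c` of (region, threshold) events — with 19 regions and w-score
   thresholds (1, 2, 3), 57 events — and each subject sits at a stage
   `k ∈ 0..57` along its subtype's piecewise-linear expected trajectory,
   with likelihood `Σ_c f_c (N+1)⁻¹ Σ_k Π_b N(x_b; E_b(S_c,k), σ²)`;
3. quantifies sequence uncertainty by **Metropolis MCMC** over orderings
   (no burn-in; the chain starts at the EM-initialised optimum) and selects
   the number of subtypes by a **cross-validation information criterion**
   (CVIC = Σ folds −2 × held-out log-likelihood);
4. assigns each scan a **stage and subtype posterior** (stage 0 ⇒ "not
   subtypable"), compares subtype models by the **Hellinger distance**
   between positional-variance distributions with randomized reference
   values, and summarises **longitudinal stability** and subtype-by-diagnosis
   contingency.

Because the motivating cohorts are not publicly distributable, the package
ships a first-class **synthetic cohort generator** that emulates the study
design (270 patients in four planted subtypes, 121 controls, covariate
effects, 1.1 ± 0.6-year follow-ups), so every stage of the pipeline is
testable end to end. See the methods vignette
(`vignettes/atrophy-subtype-staging.Rmd`) for the model, assumptions and
design choices.

## Worked example

```r
library(sustainr)

cfg <- synthetic_config(seed = 1)          # the default four-subtype design
sim <- simulate_cohort(cfg)
ctl <- sim$table[sim$table$group == "control", ]
pat <- sim$table[sim$table$group == "patient", ]

W   <- compute_wscores(pat, fit_control_model(ctl))
es  <- build_event_set(ppa_roi_names(), c(1, 2, 3))
Wb  <- subset_wscores(W, W$meta$visit_index == 1)

fit <- fit_sustain(Wb, es, C = 4, n_restarts = 5, n_split = 2, seed = 2)
fit <- sustain_mcmc(fit, Wb, n_iter = 1000, seed = 3)
fit
#> Subtype-and-stage model: 4 subtype(s), 57 events, log-lik -8154.29
#>   fractions: 0.232 0.289 0.323 0.156
#>   MCMC: 1000 samples, acceptance 0.17

asg <- assign_visits(W, fit)
stability_metrics(asg)
#> Longitudinal stability over 134 subjects:
#>   subtype stability 79.1% (per subtype: S1 88%, S2 64%, S3 79%, S4 94%)
#>   staging: 69 advanced / 11 same / 26 regressed (consistency 75.5%)

contingency_report(asg)
#>        diagnosis
#> subtype lvPPA nfvPPA PPA-nos svPPA
#>      S1    33     22       0     6
#>      S2     1     13       7    57
#>      S3    13     40       6    27
#>      S4     1     34       0     5
#> chi-square(9, n = 265) = 149.2, P = 1.27e-27
```

This is a quick desk-scale fit (five greedy restarts, two split attempts,
1000 MCMC iterations): the four planted subtypes are found approximately,
most subjects keep their subtype across visits, staging mostly advances
over follow-up, and the subtype-by-diagnosis table is strongly associated
because the generator plants diagnosis labels conditionally on the true
subtype. Heavier settings (`n_restarts`, `n_split`, `n_em_starts`,
`mcmc_iter`) sharpen all of these at proportional cost.

The end-to-end pipeline (simulate → w-score → fit → MCMC → assign →
similarity → longitudinal → reports, with every artifact as delimited
text/YAML plus a run manifest) is one call:

```r
run_pipeline(pipeline_config(synthetic = TRUE, n_subtypes = 4, seed = 1),
             out_dir = "run1")
```

A thin CLI wrapper lives at `inst/cli/run_pipeline.R`.

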