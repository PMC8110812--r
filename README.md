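# chacomed

Structural-disconnection scoring and counterfactual mediation analysis
for randomized stroke thrombolysis trials.

## What problem this solves

Thrombolysis improves 90-day functional outcome (mRS 0–1) after acute
ischemic stroke, yet lesion *volume* often fails to explain the benefit.
`chacomed` implements the full analysis chain for the sharper hypothesis
that the treatment effect travels through **preserved structural
connectivity**:

* **ChaCo (Change of Connectivity) scoring** — a binary lesion mask is
  embedded in reference whole-brain tractograms from healthy subjects;
  for each grey-matter region *r* the score is the fraction of
  streamlines connected to *r* that pass through the lesion, averaged
  over reference subjects (0 = intact, 1 = completely disconnected).
  Computed at baseline (T1) and follow-up (T2) against the same
  reference set, the difference is within-subject connectivity loss.
* **Progression models** — two-part mixture for semicontinuous ChaCo:
  logistic for any disconnection, Gaussian linear mixed model for
  `log(ChaCo+) ~ time * treatment + region * (time + log(volume)) + (1 | subject)`,
  with type-II per-term chi-square tests and per-arm geometric T2/T1
  ratios.
* **Mediator selection** — regions ranked by treatment-responsiveness
  (standardized beta of treatment on ΔChaCo) and clinical eloquence
  (standardized OR of favorable outcome per SD of ΔChaCo); threshold
  sweeps generate a family of candidate mediation models.
* **Counterfactual mediation** — natural direct/indirect/total effects on
  the odds-ratio scale by inverse-probability weighting
  (ratio-of-mediator-probability weights, simple logistic exposure
  models):

  ```
  NDE = odds(P_T,M|P) / odds(P_P,M|P)
  NIE = odds(P_T,M|T) / odds(P_T,M|P)
  TE  = NIE × NDE,   proportion mediated = log(NIE) / log(TE)
  ```

  with joint subject-level bootstrap, bias-corrected 95% CIs, a
  step-down FDR procedure across correlated models, the joint-vs-growth
  NIE ratio, and a random-subset null distribution.
* **Synthetic cohort generator + Monte-Carlo oracle** — a fully
  specified causal model (randomization → lesion growth → regional
  disconnection → outcome) with voxel-level "imaging" and fast
  reduced-form "tabular" modes, and a brute-force counterfactual oracle
  providing ground-truth natural effects for estimator validation.
* **Real-data path** — minimal NIfTI-1 and MRtrix `.tck` readers/writers
  (validated against nibabel), cohort CSV I/O, and a staged pipeline
  with JSON configuration and a CLI.

## Worked example

```r
library(chacomed)
params <- cohort_params(seed = 42)              # the stated synthetic world
cohort <- generate_cohort(params, n = 800, seed = 42)

ranking <- qualify_and_rank(responsiveness_scan(cohort),
                            eloquence_scan(cohort))
specs  <- enumerate_models(ranking, i_max = 4, j_max = 4)
labels <- vapply(specs, function(s) s$label, "")
est    <- setNames(lapply(specs, function(s) estimate_mediation(cohort, s)),
                   labels)
nies   <- vapply(est, function(e) e$nie, 0)
boot   <- bootstrap_effects(cohort, specs, k = 1000, seed = 42)
for (lb in labels) {
  ci <- bc_interval(boot$nie[, lb], est[[lb]]$nie)
  cat(sprintf("%-12s NIE %.3f [%.3f, %.3f]  PM %5.1f%%\n", lb,
      est[[lb]]$nie, ci[["lo"]], ci[["hi"]], 100 * est[[lb]]$pm))
}
nr <- nie_ratio(boot, nies, joint = "model_01")
sd_res <- stepdown_fdr(nies[-1], boot, q = 0.05)
```

prints (exact output of the code above):

```
growth_only  NIE 1.282 [1.143, 1.467]  PM  29.2%
model_01     NIE 1.487 [1.211, 1.857]  PM  46.6%
model_02     NIE 1.416 [1.074, 1.944]  PM  40.9%
model_03     NIE 1.169 [0.821, 1.691]  PM  18.3%
```

Reading: infarct growth alone carries an indirect effect of 1.28 (29% of
the total log-odds effect); adding disconnection change in the selected
region (`model_01` = growth + region 3) raises the NIE to 1.49 and the
proportion mediated to 47%. The excess ratio `nr$ratio` is 1.16
(CI [0.96, 1.39]), and the step-down procedure at 5% FDR rejects the
no-mediation null for `model_01` and `model_02`. All numbers are
synthetic — the generator's ground truth is known, and
`oracle_natural_effects(params)` returns it.

An end-to-end run (synthetic imaging cohort → ChaCo → scans → models →
selection → mediation, with CSV/JSON outputs):

```r
cfg <- pipeline_config(mode = "synthetic", seed = 1, out_dir = "out",
                       n = 40, k_bootstrap = 200)
bundle <- run_pipeline(cfg)
```

or from a shell:
`Rscript -e 'chacomed::cli_main()' run-all --config cfg.json --seed 1`.

## Documentation

`vignettes/chacomed-methods.Rmd` describes the model and its
assumptions, the weighting estimator and truncation trade-off, the
synthetic world's calibration, the step-down construction, and known
limitations.
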