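---
title: "Disconnection scoring and counterfactual mediation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disconnection scoring and counterfactual mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chacomed)
```

# The scientific problem

Thrombolysis with alteplase improves functional outcome after acute
ischemic stroke, but infarct volume alone is a poor surrogate for that
benefit: trials repeatedly find clinical treatment effects without
commensurate differences in lesion size. `chacomed` implements the
analysis chain needed to ask a sharper question — *how much of the
treatment effect travels through preserved structural connectivity, over
and above reduced lesion growth?* — in four stages:

1. **Indirect disconnection mapping.** A patient's binary lesion mask is
   embedded in reference whole-brain tractograms from healthy subjects.
   For a grey-matter region $r$ and one reference tractogram, the
   disconnection proportion is the number of streamlines connected to $r$
   that pass through the lesion, divided by the total connectivity of $r$
   (the number of streamlines with $r$ among their endpoints). The
   Change-of-Connectivity (ChaCo) score of $r$ is the mean of these
   proportions over the reference set: 0 means no reconstructed fibre of
   the region touches the lesion, 1 means complete disconnection.
   Computing the score at two time points against the *same* reference
   set makes the difference interpretable as within-subject loss of
   connectivity.
2. **Progression models.** ChaCo scores are semicontinuous (an atom at
   zero plus a skewed positive part), so progression is modelled as a
   two-part mixture: a logistic model for being disconnected at all, and
   a Gaussian linear mixed model for log positive scores,
   `log(ChaCo+) ~ time * treatment + region * (time + log(volume)) + (1 | subject)`.
   The time-by-treatment interaction is the quantity of interest: whether
   disconnection grows more slowly under treatment after adjusting for
   lesion volume and regional heterogeneity.
3. **Mediator selection.** Regions are ranked twice — by
   *treatment-responsiveness* (standardized coefficient of treatment in a
   linear model of the change in ChaCo) and by *clinical eloquence*
   (standardized odds ratio of favorable outcome per SD of change) — and
   qualify as candidate mediators when both 95% CIs exclude the null.
   Sweeping the two inclusion thresholds over a grid yields a small
   family of distinct mediator sets.
4. **Counterfactual mediation.** For each mediator set $M$ (always
   containing infarct growth), natural effects on the odds-ratio scale
   are estimated by inverse-probability weighting:
   $$\mathrm{NDE} = \frac{\mathrm{odds}(P_{T,M|P})}{\mathrm{odds}(P_{P,M|P})},\qquad
     \mathrm{NIE} = \frac{\mathrm{odds}(P_{T,M|T})}{\mathrm{odds}(P_{T,M|P})},\qquad
     \mathrm{TE} = \mathrm{NIE}\times\mathrm{NDE},$$
   with proportion mediated $\log(\mathrm{NIE})/\log(\mathrm{TE})$.
   Inference uses a joint subject-level bootstrap across all models,
   bias-corrected percentile intervals, a step-down false-discovery-rate
   procedure on the correlated model family, and a random-subset null
   distribution that asks whether the *selected* regions mediate more
   than arbitrary ones.

# The weighting estimator

$P_{T,M|T}$ and $P_{P,M|P}$ are Hájek-weighted outcome means in the
respective arms with weights $1/\hat P(A=a\mid C)$. The cross-world term
$P_{T,M|P}$ — the favorable-outcome probability the treated would have had
if their mediators had followed the placebo distribution — reweights
treated subjects by
$$w = \frac{\hat P(A=P \mid M, C)}{\hat P(A=T \mid M, C)}\cdot
      \frac{1}{\hat P(A=P \mid C)},$$
the ratio-of-mediator-probability construction. Both exposure models are
plain logistic regressions with linear mediator and covariate terms;
weights are normalized to mean one within arm. This estimator never
requires a model per mediator, handles non-rare binary outcomes, and is
valid under randomized or covariate-confounded exposure; a
covariate-dependent exposure switch in the generator exists precisely to
test the latter. A connectivity-only indirect effect is **not identified**
in this design (growth confounds the mediator-outcome relation), so the
API only ever reports joint (growth + regions) and growth-only effects
and their ratio.

**Weight truncation.** By default weights are truncated at their 1st/99th
percentiles, a variance-control choice for trial-sized samples (n ≈ 263)
with heavy-tailed cross-world weights. Truncation buys variance at the
price of a small bias: at n = 20,000 we measure ≈ −0.07 on the NIE
(about two bootstrap SEs). The estimator-consistency checks against the
Monte-Carlo oracle therefore run with truncation disabled
(`truncate = NULL`); every default analysis keeps it on. Both switches
are part of the public API.

# The synthetic cohort: a stated world

Real trial imaging is not redistributable, so all quantitative validation
runs against a synthetic cohort whose causal structure mirrors the
analysis target: randomization → lesion growth → regional disconnection →
binary favorable outcome (mRS 0–1), with age, NIHSS and baseline volume
as covariates. Parameter defaults were fixed once, before any test was
run, on these grounds:

| parameter | default | rationale |
|---|---|---|
| baseline volume | LogNormal(log 3, 1.3) ml | reported median 3.0 ml, IQR [1.0, 9.9]; sdlog 1.3 reproduces the IQR spread while keeping the upper tail below hemisphere capacity on the default grid |
| log2 growth ratio | N(0.8, 0.8) placebo, N(0.4, 0.8) alteplase | medians of reported volume trajectories imply log2 ratios ≈ 0.5–0.7 with treatment attenuation; the shared σ makes the expected share of shrinking patients (negative draws) (Φ(−1)+Φ(−0.5))/2 ≈ 0.24, matching the reported 24.5% lesion-reversal rate — shrinkage is emergent, not a separate dial |
| age | N(65.5, 11) years | reported arm means 66.0/65.2 ± 11 |
| NIHSS | round(Gamma(3.5, scale 2)) | median ≈ 6.5, IQR ≈ [4, 9], matching reported medians 6–7 |
| mediator law | ΔChaCo_r = 0.02 + 0.05·g + δ_A·1[A] + ε, ε ~ N(0, 0.03) | couples disconnection change to growth (the dominant real-data association) with region-level noise; δ_A = −0.02 in four designated "eloquent" regions encodes treatment-responsive disconnection beyond volume |
| outcome | logit P = 3.4 + log(1.5)·1[A] + log(0.77)·g − 2·ΣΔChaCo_elo − 0.03·age − 0.1·NIHSS − 0.2·log v₁ | log(0.77) is the reported adjusted OR per doubling of the growth ratio; log(1.5) direct benefit and −2 per unit eloquent ΔChaCo produce arm-wise favorable rates ≈ 45%/66% and a total OR ≈ 2, the scale of the reported 41.4%/59.3% and OR 1.98 |
| missing outcome | 6/269 | the reported missing-endpoint count |

Two generation modes share this outcome law. *Imaging mode* grows
voxel-level lesions (Eden growth: random boundary accretion, giving
connected clusters with exact volume control; random boundary erosion for
negative growth draws) and computes ChaCo mechanically against generated
reference tractograms. *Tabular mode* draws ΔChaCo from the reduced-form
law directly; it is what the estimator-validation suites use at
n = 20,000 and 200-cohort scale, and it is the law the Monte-Carlo oracle
reproduces exactly.

**The oracle.** `oracle_natural_effects()` computes the true NDE/NIE/TE
by brute-force counterfactual simulation: mediators are drawn under both
arms for each Monte-Carlo subject and the three counterfactual outcome
probabilities are averaged analytically through the logistic law. Its
mediator set is the full vector (growth + all regions); this coincides
with the estimand of any model that contains growth and every region with
a nonzero outcome coefficient, which is why validation specs use the
four eloquent regions.

**What a green test does not establish.** The generator has independent
Gaussian region noise, a single lesion per patient, symmetric
hemispheres, linear mediator–growth coupling, and exactly logistic
outcomes. Real data have spatially correlated disconnection, atlas
asymmetries, and arbitrary link misspecification. Green suites establish
that the *estimators* are correct under their stated assumptions — not
that those assumptions hold in any particular trial.

# Inference machinery

**Joint bootstrap.** All model specs are re-estimated on the *same*
subject-level resample in every replicate, preserving the joint
distribution of effects across models — required by both the NIE-ratio
comparison and the step-down procedure. Degenerate resamples (single arm,
boundary probabilities, non-overlap) are redrawn and counted.

**BC intervals.** Bias-corrected percentile intervals without
acceleration: $z_0 = \Phi^{-1}(\#\{\hat\theta^* < \hat\theta\}/B)$,
endpoints at percentiles $\Phi(2z_0 \pm z_{0.975})$. The bias fraction is
clamped to $[1/(B{+}1), B/(B{+}1)]$ and flagged when the estimate falls
outside the replicate range.

**Step-down FDR.** Bootstrap step-down procedures over correlated
statistics are a family, not a single algorithm, so the package
specifies its own concrete member and validates it by simulation: order models by decreasing
empirical NIE; centre the joint bootstrap draws
($\log \mathrm{NIE}^* - \log \widehat{\mathrm{NIE}}$ per model) as the
joint null; at step $s$ the threshold is the smallest $c$ such that the
expected number of null exceedances among the not-yet-rejected models is
at most $q\,s$; rejection stops at the first non-exceedance. Under the
global null this bounds the false discovery rate by construction
(expected exceedances ≤ q), and the all-null calibration simulation in
the acceptance suite measures an empirical FDR of ≈ 0.025 at q = 0.05 —
conservative, as expected from an expected-exceedance bound. Threshold
uncertainty is reported by resampling the replicate matrix (default 100
outer draws).

**Random-subset null.** Uniformly drawn region sets (sizes uniform on
1..4, the observed model-family range) are fitted jointly with growth,
building the distribution of NIEs attainable by *arbitrary* regions; a
genuinely mediating selection should land in its upper tail, while
without region effects the distribution centres on the growth-only NIE.

# Numerical and degenerate-input choices

* Zero volumes are floored at half a 1 mm voxel (5·10⁻⁴ ml) before logs.
* Surprisal is reported in bits (−log₂ p); the convention the S-value
  literature uses. The descriptive per-region scans report unadjusted
  p-values by design (no formal testing is intended there).
* A streamline counts once for a region even when both endpoints lie in
  it, keeping every proportion ≤ 1; regions with zero total connectivity
  are *undefined* (NA + diagnostic), never silently 0, because 0 claims
  "intact".
* Bilateral lesions raise an error (mirroring the analysis population's
  exclusion rule); hemisphere restriction drops contralateral *regions*
  only — cross-hemisphere streamlines keep contributing hits and totals.
* Evidence ranking breaks p-value ties by larger |standardized effect|,
  then region id: deterministic and scale-free. Threshold sweeps restrict
  to qualified regions *after* intersecting the two top-k lists; each
  model records every generating (i, j) pair.
* Type-II per-term chi-squares for the mixture model come from ML
  likelihood-ratio model comparison respecting marginality (the term and
  everything containing it are removed from the reference model); the
  1-df time-by-treatment Wald z² from the full fit is reported alongside.
  The zero-part logistic mixed model drops its region-by-volume term on
  convergence failure and records the fallback.
* The step-down variant and the exact weight algebra are this package's
  own constructions (the methodological literature names the ideas, not a
  reproducible algorithm); both are validated against simulation and the
  counterfactual oracle rather than against a reference implementation.

# File formats and environment limits

No NIfTI, streamline or YAML R package is available in the target
environment, so the package ships minimal readers/writers for
uncompressed or gzipped single-file NIfTI-1 volumes and MRtrix `.tck`
tractograms (nearest-voxel rounding under the mask's diagonal affine;
bit-reproducible and validated against `nibabel` in the test suite), and
the pipeline configuration is JSON rather than YAML.

# Known limitations

* Lesion geometry is Eden growth on a rectangular grid — no vascular
  territories, no MNI anatomy.
* The mediator law is linear-Gaussian; no zero-inflation in ΔChaCo.
* The tabular generator pools left and right strokes by homologous
  region index.
* Weight truncation's bias-variance trade-off is documented but not
  adaptively tuned.
* The step-down procedure is a validated stand-in, not a reproduction of
  any specific published algorithm.
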