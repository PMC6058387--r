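---
title: "Cell-type-resolved EWAS: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved EWAS: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctewas)
```

## The problem

Bulk brain tissue is a mixture of neurons and glia whose composition varies
across individuals and shifts with age and neurodegeneration. In an
epigenome-wide association study (EWAS) on bulk methylation array data, this
heterogeneity both masks cell-type-specific signals and manufactures spurious
ones: a CpG that never changes within any cell type will still track disease
if the cell proportions do. `ctewas` implements the analysis strategy for
cohorts in which nuclei have been sorted into NeuN-positive (neuronal) and
NeuN-negative (glial) fractions before 450k-style beta-value profiling, and
pairs it with a synthetic-cohort generator so that every stage of the
pipeline can be validated against known ground truth at desk scale.

## Statistical models

**Cell-type markers.** Neuron-versus-glia differential methylation is tested
per probe with a two-sided two-sample t-test on control samples. The Welch
(unequal-variance) statistic is the default; the tests are typically so far
from the null that the pooled/Welch distinction is immaterial, but a
`pooled = TRUE` flag provides the classical test. A probe is called a
cell-type differentially methylated CpG (ct-DMCG) when it is autosomal, its
Bonferroni-adjusted p-value is below 0.05, and the absolute mean beta
difference is at least 0.20 — the conventional "20% methylation difference"
rule. We read that rule as a difference of beta values, not a percentage of
baseline. Direction (hyper-/hypomethylated in neurons) is the sign of the
effect.

**Association scans.** Within each cell fraction the per-probe model is

\[
\beta_{CpG} = b_0 + b_1\,\mathrm{Braak} + b_2\,\mathrm{Age} +
b_3\,\mathrm{Sex} + b_4\,\mathrm{PC1} + \varepsilon ,
\]

fit by ordinary least squares on beta values (not M-values), with two-sided
p-values on \(n - k\) degrees of freedom. Braak stage enters as a numeric
0–6 score, so one coefficient summarizes stage progression; sex is coded
female = 0, male = 1. PC1 is the leading principal component of the
probe-centered combined sorted matrix, included as a technical batch
covariate. Its batch association is verified rather than assumed:
`pick_batch_component()` reorders the score matrix so the component most
associated with batch (one-way ANOVA) is the one the model adjusts for. This
matters: in a bulk cohort with a coherent disease axis and no dominant
cell-type axis, the top-variance component can *be* the disease signal, and
adjusting for it blindly would erase the association being tested. Aging
scans default to control samples only (a flag includes AD samples, with
Braak as an additional covariate); Braak scans use all samples. Probes with
zero variance in a subset are retained with p = 1 to preserve the
multiple-testing denominator; rank ties are broken by probe id for
determinism.

**Meta-analysis.** Neuron and glia p-values for the same predictor are
combined per probe by Fisher's method, \(X = -2\sum \ln p\), referred to a
chi-square distribution with \(2k = 4\) degrees of freedom. The survival
probability is evaluated in log space (`pchisq(..., log.p = TRUE)`), so
combinations far below the double underflow threshold remain ordered via the
retained `log_p`; component p-values are clamped at a configurable floor
(default 1e-300) with a warning. For \(k = 2\) the closed form
\(e^{-X/2}(1 + X/2)\) serves as an internal cross-check. Benjamini–Hochberg
FDR is attached everywhere (delegating to `p.adjust` when the family is the
supplied vector, with an explicit step-up implementation for enlarged
families), and Bonferroni is used for marker calling.

**Deconvolution.** The neuronal content of a bulk sample is estimated by
projecting its betas at reference marker CpGs onto the neuron/glia mean
reference profiles under the constraints \(w \ge 0\), \(\sum w \le 1\)
(the remainder is unexplained signal). Markers are the top-600 probes of the
control neuron-versus-glia t-test, ranked by raw p-value without balancing
directions (a `balanced` flag splits markers by effect sign). Because only
two cell types are involved the quadratic program is solved exactly by
enumerating every active set and keeping the feasible candidate with the
smallest residual — deterministic, tolerance-free, and verified against a
0.001-step grid search. Whether marker CpGs should additionally pass the
0.20 effect-size filter is left open by convention; we rank by p only, and
on the default synthetic design over 95% of selected markers are planted
cell-type probes regardless.

## What the synthetic generator emulates

`make_default_design()` draws per-probe generative parameters once from a
single seed; cohorts generated from the same design and seed are identical.

* **Cell-type structure:** 12% of probes differ by at least 0.20 beta
  between cell types (|Δμ| drawn uniformly from 0.25–0.60), 54% of them
  hypermethylated in neurons. Remaining probes carry small sub-threshold
  differences (SD 0.03, truncated at |0.15| so ground-truth labels are
  unambiguous).
* **Aging:** 1% of probes per cell type carry linear age slopes of
  magnitude 0.002 beta/year, 60% negative (hypomethylation dominates).
  A quarter of them have opposite-sign slopes in the two cell types, and a
  quarter sit on cell-type-marker probes. For opposing slopes on markers,
  the `ct_age_converging` parameter (default 0.7) makes the slopes
  preferentially erode the neuron–glia contrast over lifetime — the
  "differences fade in old individuals" structure. Without that alignment,
  randomly-signed slope perturbations cancel in any projection and no
  systematic reference-age bias can exist.
* **Braak effects:** 0.5% of probes per cell type at 0.02 beta/stage,
  cell-type-exclusive by default (a `frac_braak_shared` option plants equal
  effects in both cell types), disjoint from marker and aging probes.
* **Covariates:** effects act additively on the beta scale around centered
  covariates, \(m = \mu + s_{age}(\mathrm{age} - 62.5) +
  s_{braak}(\mathrm{braak} - 3) + \dots\), clipped to [0.01, 0.99]. Centering
  keeps \(\mu\) interpretable as the mid-cohort baseline and ensures planted
  effects survive clipping; fitted slopes and p-values are unaffected (it is
  a reparameterization of the intercept). Probes carrying effects are
  anchored at intermediate baselines (0.2–0.8), where dynamic CpGs live.
* **Cohort structure:** donor ages uniform on 30–95; Braak stage is a
  7-level equal-mass binning of a latent normal correlated 0.5 with age, so
  age and stage are confounded as in real cohorts (low stages young, mid/high
  stages old); AD diagnosis is Braak ≥ IV. Sex is balanced; donors rotate
  through 3 batches with per-probe batch offsets (SD 0.01). Each donor
  contributes one neuron and one glia sample sharing all covariates.
* **Noise:** beta-distributed with mean \(m\) and concentration
  \(\phi = 200\) (SD ≈ 0.035 at beta 0.5, typical array replicate noise);
  \(\phi \ge 10^6\) is the exact noise-free limit.
* **Bulk mixtures:** linear mixing on the beta scale (the physically correct
  model for pooled cell populations) with neuronal weight
  \(w = \mathrm{clip}(0.55 - 0.002\,\mathrm{age} - 0.015\,\mathrm{braak} +
  \mathcal{N}(0, 0.05), 0, 1)\): mean content ≈ 0.38, declining with age and
  pathology, matching the minority neuronal share of cortical nuclei. The
  true \(w\) is recorded for every sample. Note that at an exactly 50/50
  average mixture the reference-age bias below would cancel by symmetry —
  the projection pivots around \(w = 0.5\) — so the realistic off-center
  composition is load-bearing for that experiment.

The generator does **not** emulate Infinium I/II probe-chemistry differences,
spatial correlation between neighboring CpGs, cross-reactive probes,
detection failures (beyond an optional uniform mask), or population
stratification. Passing recovery tests therefore demonstrate the statistical
machinery, not robustness to those artifacts.

## The experiments the package reproduces qualitatively

**Sorted versus bulk power.** `power_comparison()` generates matched sorted
and bulk cohorts (default 60 donors, about the size of a combined sorted
cohort after pooling with an external reference set), scans for Braak
association in each arm, and compares the fraction of planted Braak probes
reaching Bonferroni significance. Under the default design — cell-type-
exclusive effects plus age/disease-driven composition drift — the sorted
design detects essentially all planted probes while the bulk design detects
few: the bulk signal is attenuated by the ~0.4 neuronal weight and buried
under composition noise. With drift disabled and effects planted equally in
both cell types, the gap collapses, confirming that the advantage comes from
resolving composition, not from the arithmetic of the comparison.

**Reference-age bias.** `reference_age_bias_experiment()` builds one marker
panel from a young reference cohort (ages 30–50) and one from an old cohort
(70–95), estimates the neuronal content of the same bulk cohort with each,
and reports the per-sample paired difference. When marker CpGs carry
contrast-eroding age slopes (the experiment's default design concentrates
opposing slopes on markers, 5% of probes), the two panels disagree
systematically — mean paired difference ≈ 0.02, stable in sign across seeds
— and the bias shrinks monotonically to zero as the slopes are scaled to
zero. This is the in-silico counterpart of the observation that deconvolution
against references of mismatched age is systematically biased.

## Numerical and design choices

* Analysis sizes in the test suite are scaled for desk verification:
  10,000 probes and 40 donors for marker-recovery checks, 4,000 probes and
  60 donors per arm for power comparisons, 20 seeds for null calibration.
  The generator is linear in probes × samples, so full 450k-scale runs only
  change runtime.
* Quantile normalization delegates to `limma::normalizeQuantiles`
  (rank means, ties averaged); it is idempotent to 1e-12 and is applied to
  the combined sorted matrix before PCA, mirroring the merged-cohort
  workflow.
* PCA signs are fixed by forcing each component's largest-magnitude loading
  positive, so scores are reproducible across runs.
* ComBat-style empirical-Bayes batch adjustment is deliberately not
  implemented; the verified batch-associated principal component is the
  supported batch correction. Whether a PC covariate alone reproduces a
  ComBat-then-PC pipeline on real data cannot be settled synthetically and
  is left open.
* Detection-p filtering is optional (synthetic data has none); probes with
  missing betas are dropped before normalization/PCA, consistent with
  >99% call rates making the choice immaterial.
* The multiple-testing denominator for the meta-analysis FDR is the full
  set of combined probes; the bundled worked examples confirm the published
  FDR column reproduces as \(p \cdot m / \mathrm{rank}\) with
  \(m = 478{,}416\) at the verifiable ranks.
* All tabular artifacts are UTF-8 TSV (comma accepted on read); Braak
  stages are accepted as 0–6 or Roman 0, I–VI and stored as integers;
  "ch."-prefixed non-CpG probes are ordinary opaque identifiers.
* Known limitations: only two cell types are supported in deconvolution
  (no glial subtypes); regressions are ordinary least squares (no robust or
  mixed models); the generator's effects are linear in age and stage.

## A small end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1, n_probes = 2000, n_sorted = 30,
                       n_bulk = 30, k_markers = 200, top_k = 500)
res <- run_pipeline(cfg, out_dir = tempfile("ctewas_demo_"))
res$manifest$counts
```

The output directory contains the simulated matrices, every result table,
and `manifest.json` recording seed, thresholds and per-stage counts — enough
to reproduce every output byte-identically.
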