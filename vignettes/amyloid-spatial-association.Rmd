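---
title: "Methods: cross-modal spatial association of amyloid PET load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal spatial association of amyloid PET load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyspace)
```

## The question and the pipeline

In cognitively intact older adults, does the spatial distribution of
cerebral beta-amyloid (measured as PET standardised uptake value ratios,
SUVR) follow the spatial distribution of amyloid-precursor-protein mRNA
expression, and how does it relate to microstructural, perfusion and
functional MRI maps and to clinical characteristics? `amyspace` implements
the full analysis as a reusable, testable pipeline:

1. **SUVR normalisation** — each PET uptake volume is divided by the mean
   uptake over a cerebellar-like reference mask, so the reference-region
   SUVR mean is exactly 1.
2. **ROI mask logic** — high-resolution anatomical masks are decimated to
   the 2-mm analysis grid as exact volume-fraction "probability of
   inclusion" maps and thresholded at `tau = 0.9` (inclusive), mitigating
   partial-volume contamination at region borders.
3. **Metric maps** — ReHo, fALFF and weighted degree centrality from 4D
   BOLD-like series; FA and MD from diffusion-weighted series via a
   constrained weighted linear least-squares tensor fit; framewise-motion
   screening at two voxels.
4. **Association** — per subject, ROI and modality, the voxel-wise Pearson
   correlation `r` between the amyloid map and the target map, Fisher
   transformed to `z = atanh(r)`.
5. **Inference** — a one-sided one-sample sign-flip permutation test of
   whether `|z|` exceeds the medium effect size `atanh(0.3)`; permutation
   tests for clinical correlations; Storey FDR within each aim;
   correlation-matrix ("profile") similarity between each metric and
   amyloid.

Because the original cohort is not redistributable, every stage is
exercised against a **synthetic multimodal cohort generator** whose ground
truth is known exactly.

## The effect-size permutation test

For one (ROI, modality) cell with per-subject Fisher values
`z_1, ..., z_n`, define `d_i = |z_i| - atanh(r0)` with `r0 = 0.3`. The
statistic is the one-sample t value `T = mean(d) / (sd(d) / sqrt(n))`; the
null distribution is generated by independently negating the `d_i`, which
is valid when `d` is symmetric about zero under the null — an assumption
the calibration suite constructs explicitly and that users should keep in
mind with real data. The rejection region is one-sided (`T* >= T`),
matching the directional question "larger than the medium effect size".

Numerical choices:

* The null threshold is placed on the Fisher-z scale (`atanh(0.3) ~ 0.3095`)
  because the statistic is built from z values; thresholding `|r|` at 0.3
  before transformation would differ by less than 0.01 in the statistic's
  location but would mix scales.
* For `n <= 20` all `2^n` sign patterns are enumerated and
  `p = #{T* >= T} / 2^n` (the identity pattern makes `p > 0`); otherwise
  `n_perm` random sign vectors are drawn with the smoothed estimate
  `p = (1 + #{T* >= T}) / (1 + n_perm)`, which is conservative and keeps
  q-values well defined.
* The observed `T` is evaluated on the same floating-point path as the
  enumerated null (it *is* the identity pattern), and comparisons carry a
  `1e-12` relative tolerance, so structurally tied nulls — all `|d_i|`
  equal, where the null lattice is discrete — are counted as extreme. This
  keeps the test valid (conservative) under ties; with, say, five `d_i = +c`
  and five `-c`, the exhaustive p is ~0.62 rather than the 0.5 a continuous
  null would give.
* If every `d_i` is exactly zero, `T = 0` and `p = 1` by definition.

Type-I calibration at the boundary (symmetric `d`, `n = 35`) lands within
[0.03, 0.07] at `alpha = 0.05` in the test suite, and power is
non-decreasing in the true correlation beyond 0.3.

## Storey false-discovery-rate estimation

Q-values estimate the null proportion `pi0` from the p-value distribution:
`pi0(lambda) = #{p > lambda} / (m (1 - lambda))` on the grid
`lambda = 0.05, ..., 0.95`, smoothed by a cubic spline (df = 3) and read
off at the largest lambda, capped at 1 and floored at `1/m`. Setting
`pi0 = 1` reduces exactly to Benjamini–Hochberg step-up values (verified
against an independent step-up oracle and `p.adjust`). Batching follows
the aims: one FDR batch for the atlas arm, one for the clinical arm, one
across all (ROI, metric) cells.

Two behaviours deserve emphasis. With small batches (the atlas arm has 7
tests) the smoother is noisy — an accepted property of the estimator. And
when *every* hypothesis in a batch is non-null (which the synthetic
defaults produce by design), `pi0` is legitimately estimated near zero and
q-values shrink well below their p-values; the false-discovery proportion
among the rejections is still controlled because there are no true nulls
to discover falsely.

## The similarity statistic

For each metric, the matrix of Pearson correlations between per-subject
ROI-mean metric values and clinical variables (ROIs x variables) is
vectorised and correlated with the amyloid counterpart (`r_sim`).
Significance comes from permuting the amyloid ROI-mean rows across
subjects and recomputing the amyloid matrix each draw (two-sided on
`|r_sim|`). The subject-level relabelling scheme is this package's
construction — the design was open — chosen because it preserves the
clinical table's internal correlation structure while breaking only the
amyloid-to-subject assignment. Its calibration under independence is
verified by simulation in the test suite.

## The synthetic cohort generator

The generator's defaults are the emulated study conditions: 35 subjects;
clinical marginals age 73.17 (9.07), BMI 26.56 (4.45), grip strength
101.81 (15.49, n = 31), fluid cognition 112.71 (15.28), crystallised
cognition 109.85 (11.54, n = 34); a 24/11 negative/positive amyloid
reading split and 22/13 female/male; two subjects without DWI and one
without perfusion data (sampling mode); 488-volume TR 0.8 s BOLD; DWI with
b = 1500/3000 s/mm^2 over 93 directions plus 7 b0 volumes; ROI masks
spanning 50 to 4096 analysis-grid voxels; mask threshold 0.9; effect-size
null 0.3; 10,000 permutations; alpha 0.05.

**Grids.** The high-resolution grid is 64^3 decimated by an integer factor
2 to a 32^3 "2-mm" analysis grid. A true 0.8-mm-to-2-mm ratio (2.5) is not
integral; the integer factor makes volume-fraction resampling exactly
computable, which is what the mask-logic contracts test. Real spacings
remain configurable.

**Forced correlation.** The central primitive standardises a base vector,
residualises fresh Gaussian noise against it (and the constant), and mixes
with weights `rho` and `sqrt(1 - rho^2)`; the sample correlation of output
and base equals `rho` to ~1e-15. In *exact* mode every within-ROI
(amyloid, target) pair is built this way, giving bit-checkable oracles; in
*sampling* mode the population analogue is used, so the sample correlation
fluctuates with sd ~ `(1 - rho^2)/sqrt(V)` — the mode used for
calibration studies. Voxel-wise targets default to a pattern mirroring the
emulated study's qualitative findings (entorhinal-atlas 0.5 with a
basal-ganglia anti-correlation; positive FA/T1w-T2w associations
everywhere; negative MD/ODI/free-water; weak rs-fMRI associations except
basal ganglia).

**Subject-level structure.** A 13-variable correlation matrix (eight
ROI-mean amyloid loads + five clinical variables) is imposed on the
subject level — exactly in exact mode via whitening-and-recolouring of the
sample covariance, or as the population matrix in sampling mode. ROI-mean
amyloid targets become per-subject constants added to the (zero-mean)
within-ROI patterns, so voxel-level and subject-level contracts hold
simultaneously. Each metric map additionally receives per-subject ROI-mean
offsets coupled to the amyloid profile (configurable per modality, strong
for FA and T1w/T2w), without which the similarity statistic would be
degenerate under exact forcing.

**BOLD spectra.** Series are synthesised in the frequency domain with the
total spectral amplitude split `band_fraction : 1 - band_fraction` between
0.01–0.1 Hz and the rest. In-band amplitude sits one Fourier bin inside
the band edges, and each spectral group is orthogonalised against the mean
and linear trend within its own span — so the fALFF pipeline (detrend,
periodic Hann taper, DFT) reads back exactly the requested fraction. A
volume-wide shared component with weight `coupling` makes ReHo monotone in
coupling.

**DWI.** Signals follow the monoexponential tensor model
`S = S0 exp(-b g' D g)` from positive-semidefinite tensor fields built by
rotation of random eigenvalue triples at physiological diffusivities. At
zero noise the WLLS fit recovers tensors to < 1e-10 (tested), closing the
loop between generator and fitter.

What the generator does **not** emulate: anatomically realistic geometry,
registration error, PET partial-volume spill-in, scanner artefacts, or
non-Gaussian marginals (per-subject map distributions are Gaussian, with
no claim of realism — the original distributions are unpublished).
Passing tests therefore demonstrate the correctness of the computations
and the calibration of the inference under the stated assumptions, not
robustness to real-data pathologies.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `r0` | 0.3 | correlation | medium effect-size null for the sign-flip test |
| `tau` | 0.9 | probability | inclusive ROI inclusion threshold, partial-volume mitigation |
| `n_perm` | 10000 | draws | permutations for every test |
| `alpha` | 0.05 | — | significance level on q-values |
| fALFF band | 0.01–0.1 | Hz | low-frequency fluctuation range |
| wDeCe sparsity | 0.1 | fraction | top fraction of positive edges retained |
| ReHo neighbourhood | 27 | voxels | full 3x3x3 cube incl. centre (configurable: 7/19/27) |
| DTI iterations | 2 | rounds | WLLS reweighting rounds |
| motion threshold | 2 | voxels | strict framewise RMS displacement limit |

The quoted "28 neighbouring voxels" convention for ReHo matches no
standard cubic neighbourhood (6/18/26 neighbours; 27 including the
centre); the package defaults to the 27-voxel cube and exposes the choice
as a parameter rather than guessing. The motion boundary itself passes
(strict inequality), and is documented as such.

## Degenerate inputs and tie-breaks

* Constant series in a ReHo neighbourhood (or fewer than two available
  voxels): W is undefined; the voxel emits 0 and is counted.
* Zero-variance voxels in wDeCe: excluded from the graph with a count;
  retained edges are exactly `ceiling(sparsity x #positive)`, ties broken
  deterministically by edge index.
* Constant maps over an ROI: `voxelwise_pearson` errors ("zero variance in
  ROI") rather than returning NA silently.
* `|r|` within 1e-12 of 1 is clamped before `atanh` with a warning.
* Non-positive DWI signals are clipped to `1e-6 x max(signal)` before the
  log transform; negative fitted eigenvalues are clipped at zero (a
  simpler constraint than Cholesky reparameterisation, and exact at zero
  noise).
* Clinical correlation cells with fewer than 3 complete pairs are flagged
  missing, never zero.

## Problem sizes and reproducibility

The test suite runs exact-mode cohorts of 10–14 subjects on 8^3 analysis
grids, a 35-subject sampling-mode recovery study at 512 voxels per ROI,
1000-replicate type-I calibration at 2000 permutations, and exhaustive
enumeration up to 2^14 sign patterns — sizes chosen so the full suite
completes in well under a minute while still pinning every contract. All
randomness descends from one root seed through a documented hash
(`derive_seed`), and two pipeline runs with the same configuration and
seed produce byte-identical output tables.

The `analysis/` directory holds the numbered drivers (simulate, metric
maps, association, inference) that reproduce the full three-aim analysis
on the synthetic cohort; `scripts/acceptance.R` recomputes the headline
quantities from scratch. A shell CLI wrapper is deliberately absent: the
package functions and these scripts are the interface of an analysis
pipeline, not of a standalone tool.
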