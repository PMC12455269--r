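# amyspace

Cross-modal spatial-association analysis of cerebral β-amyloid PET load
against a transcriptome atlas and multimodal MRI metric maps, as a tested,
reusable R pipeline.

## The problem

β-amyloid PET scans of cognitively intact older adults frequently show
elevated tracer binding, and its clinical meaning is contested. One way to
probe the origin and correlates of this load is spatial: within anatomical
regions of interest, does the voxel pattern of amyloid SUVR (standardised
uptake value ratio) track the spatial pattern of amyloid-precursor-protein
mRNA expression, of microstructural metrics (FA, MD, T1w/T2w, NODDI),
perfusion (CBF), or resting-state activity (ReHo, fALFF, weighted degree
centrality)? And do regional amyloid loads correlate with age, BMI, grip
strength, and cognition across subjects?

`amyspace` implements that analysis end to end for anyone who has
co-registered NIfTI volumes and a clinical table — and, because the
motivating cohort (35 subjects, ¹⁸F-florbetaben PET + multimodal MRI) is
not redistributable, it ships a synthetic multimodal cohort generator with
exactly known ground truth so that every stage is verifiable without any
download.

## The statistics at the core

For subject *s*, ROI *R* and target map *M*, the package computes the
voxel-wise Pearson correlation over the thresholded ROI mask and its
Fisher transform,

```
r_{s,R,M} = corr({SUVR_s(v)}, {M_s(v)} : v ∈ R),   z = atanh(r).
```

The cell-level test asks whether the absolute association exceeds a medium
effect size r₀ = 0.3: with dᵢ = |zᵢ| − atanh(r₀), the one-sample statistic
T = mean(d) / (sd(d)/√n) is referred to a sign-flip permutation null
(exhaustive 2ⁿ enumeration for n ≤ 20, otherwise 10,000 random flips with
Phipson–Smyth smoothing), one-sided on T* ≥ T. Clinical correlations use
two-sided permutation tests on |r|; multiplicity is handled per aim with
Storey q-values (π₀ from the λ-grid smoother; π₀ = 1 reduces exactly to
Benjamini–Hochberg). Profile similarity between a metric and amyloid is the
Pearson correlation of their vectorised (ROI × clinical) association
matrices, with a subject-relabelling permutation null.

Upstream of the statistics: SUVR maps are PET volumes normalised by the
mean over a reference-region mask; ROI masks are decimated to the analysis
grid as exact volume-fraction inclusion probabilities and thresholded at
τ = 0.9 (inclusive); ReHo is Kendall's W over a cubic neighbourhood of
within-voxel time ranks; fALFF is the in-band (0.01–0.1 Hz) fraction of
spectral amplitude after detrending and tapering; wDeCe sums the top 10% of
positive pairwise-correlation edges incident to each voxel; FA/MD come from
a constrained weighted linear least-squares tensor fit.

## Worked example

```r
library(amyspace)

cfg <- run_config(mode = "synthetic",
                  cohort = cohort_config(mode = "sampling"),
                  n_perm = 2000, seed = 42)
report <- run_pipeline(cfg)
print(report)
#> Three-aim association pipeline report
#>   Aim 1 (atlas): 7 ROIs, 2 significant
#>   Aim 2 (clinical): 40 cells, 6 significant
#>   Aim 3 (metrics): 80 cells, 22 significant

report$aim1[, c("roi_id", "n", "mean_r", "t_stat", "p", "q", "significant")]
#>                          roi_id  n   mean_r  t_stat     p       q significant
#> 1                    entorhinal 35  0.50047   10.09 5e-04 0.00175        TRUE
#> 2            limbic_subcortical 35 -0.08473  -17.34 1e+00 1.00000       FALSE
#> 3                      temporal 35 -0.00354  -50.06 1e+00 1.00000       FALSE
#> 4            anterior_cingulate 35 -0.14266  -11.54 1e+00 1.00000       FALSE
#> 5 precuneus_posterior_cingulate 35 -0.08682  -21.10 1e+00 1.00000       FALSE
#> 6                  whole_cortex 35  0.05274 -100.61 1e+00 1.00000       FALSE
#> 7                 basal_ganglia 35 -0.34618    6.14 5e-04 0.00175        TRUE
```

The generator imposed an entorhinal–atlas correlation of 0.5 and a
basal-ganglia anti-correlation of −0.35; the pipeline recovers the group
mean r per cell (0.50047 and −0.34618 here, sampling noise ~1/√V), and the
sign-flip test flags exactly the two cells whose |r| truly exceeds 0.3 —
note the basal-ganglia row is significant on |z| despite its negative mean.
`mean_r` is the group-average voxel-wise correlation, `t_stat` the
effect-size statistic against atanh(0.3), and `q` the Storey-adjusted
p-value within the aim.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (cohort + mask-size and clinical summaries),
`02_map_metrics.R` (ReHo/fALFF/wDeCe/FA/MD from raw 4D series),
`03_association.R` (SUVR → ROI extraction → voxel-wise correlation,
compared with the imposed ground truth), `04_inference.R` (the three aim
tables under `results/aims/`).

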