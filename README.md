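# scsnet

Graph-theoretical analysis of synchronized EEG–fNIRS recordings around
epidural spinal cord stimulation (SCS), for researchers studying
stimulation-induced network reorganization in disorders of consciousness.
The package implements the full chain from raw sensor data to group
statistics — and, because clinical recordings of this kind are not publicly
deposited, a seeded synthetic-data generator with planted ground-truth
effects that makes every stage verifiable.

## What it computes

For each subject, stimulation phase (`pre` / `on` / `post`) and modality:

1. **Conditioning.** EEG: zero-phase 1–45 Hz band-pass, downsampling to
   256 Hz, 2-s epochs with ±100 µV rejection, robust bad-channel detection
   and spherical-spline interpolation, common average reference. fNIRS:
   optical density, temporal-derivative motion repair, zero-phase
   0.01–0.1 Hz Butterworth, modified Beer–Lambert inversion
   (ΔOD = (ε_HbO·ΔHbO + ε_HbR·ΔHbR)·d·DPF at 730/850 nm, d = 3 cm).
2. **Source estimation** on analytic toy leadfields: sLORETA
   (Ĵ = Kᵀ(KKᵀ+λH)⁺V standardized by the resolution-matrix diagonal;
   exact zero localization error for single noiseless sources) and
   depth-weighted MNE (weights ‖k_s‖^(−2γ), γ = 0.5), aggregated into the
   46 Desikan–Killiany regions shared by both modalities.
3. **Connectivity.** Band-wise phase-locking value
   PLV = |⟨e^{i(φ_i−φ_j)}⟩| per 2-s epoch, averaged (delta–gamma); Pearson
   correlation with Fisher r-to-z for ΔHbO/ΔHbR.
4. **Graph topology.** Proportional thresholding across sparsities
   0.09–0.50 (step 0.01); clustering coefficient, characteristic path
   length, global/nodal/local efficiency, degree, betweenness;
   small-world index σ = (C/C_null)/(L/L_null) against 100
   degree-preserving null networks; every metric integrated to its area
   under the sparsity curve.
5. **Inference.** Network-based statistic (edge screening at p < 0.001,
   connected-component size, sign-flip permutation null of the maximal
   component, p = (1+#{null ≥ obs})/(1+n_perm), component α = 0.05/3) and
   one-way repeated-measures ANOVA with BH-FDR over the 46 ROIs and
   Bonferroni-corrected pairwise post hocs.

## Worked example

Simulate a small study with a planted theta-band coupling increase during
stimulation, run the pipeline, and look at the group contrast:

```r
library(scsnet)

cfg <- run_config(
  design = list(n_subjects = 6, phases = c("pre", "on"),
                phase_durations = c(pre = 24, on = 24), eeg_rate = 256),
  bands = "theta", modalities = "eeg",
  effects = default_effects(46, effect_size = 0.7),
  graph = list(n_null = 20),
  stats = list(n_perm = 1000, contrast = c("pre", "on")),
  seed = 42)
res <- run_study(cfg)
print(res)
#> <study_result> 1 connectivity families, 48 metric rows, 1 NBS analyses (config 331f7488)
subset(res$anova_global, metric == "cc")
#>    modality metric        F df1 df2          p epsilon mean_diff_on_pre
#> 1 plv-theta     cc 7.645396   1   5 0.03959778       1       0.01786939
```

The planted within-community coupling increase shows up as a higher
clustering coefficient AUC during stimulation (`mean_diff_on_pre > 0`,
here p ≈ 0.04 at n = 6) and as a phase-locking increase on the planted
edges. `export_results(res, "out/")` writes the tidy metric, ANOVA and NBS
component tables plus a provenance manifest (config hash, seeds, exclusion
counts).

A thin command-line wrapper for the same flows is installed at
`inst/cli/scsnet.R` (`simulate` and `run-all` verbs).

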