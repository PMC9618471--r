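# perfusim

Simulation and analysis of dynamic contrast-enhanced CT myocardial
perfusion on a digital heart phantom, in R.

`perfusim` is for researchers developing or validating CT perfusion
postprocessing: it generates 4D perfusion series with exactly known
kinetic ground truth in two modalities — conventional Hounsfield-unit
imaging and spectral (dual-layer) iodine-density imaging — and runs the
complete quantitative analysis chain on them:

1. **Phantom simulation** — a myocardium-like insert with three bands
   (highly affected / unaffected / moderately affected, MTT plateaus
   2.73 / 1.8 / 2.2 s) plus a blood-pool region carrying a gamma-variate
   arterial input function (peak 8 mg/mL ≙ 250 HU, FWHM 10 s), sampled at
   36 ECG-triggered time points over ≈26.9 s, with Gaussian noise
   calibrated to blood-pool ROI SNRs of 7.40 (conventional) and 112.02
   (spectral).
2. **Tracer-kinetic fitting** — the one-compartment model
   `TAC(t) = A · [AIF ⊗ exp(−λt)](t)` fitted voxel-wise by
   bound-constrained L-BFGS-B with analytic gradients; parameter errors
   `Δxᵢ = sqrt(f_tol · (H⁻¹)ᵢᵢ)` from the finite-difference Hessian at the
   optimum.
3. **Perfusion maps** — via the central volume principle for the
   exponential residue: MTT = 1/λ (s), volume fraction = 100·A/λ
   (mL/100 mL), blood flow = 6000·A (mL/min/100 mL), plus propagated
   error maps, row-averaged MTT line profiles and 2.5 s / 2.0 s threshold
   classification.
4. **ROC analysis** — threshold classifier (hypoperfused if MTT exceeds
   the threshold) over highly+moderately affected vs unaffected voxels;
   trapezoidal AUC (= Mann–Whitney concordance) with a 1000-replicate
   percentile bootstrap (5–95 %) confidence interval.
5. **Dose reduction** — uniform 8-of-36 temporal undersampling of all
   TACs including the AIF, and the CT dose arithmetic: DLP = n·CTDIvol·
   coverage = 36·9·4 = 1296 mGy·cm, effective dose = DLP·0.015 =
   19.44 mSv, reduced to 4.32 mSv (≈78 % reduction).

## Worked example

```r
library(perfusim)
cfg <- phantom_config(seed = 42)            # default calibrated phantom
report <- run_pipeline(pipeline_config(phantom = cfg, seed = 42))
print(report)
#> Simulated dynamic perfusion experiment (seed 42)
#>   spectral:     AUC 0.997 [0.996-0.998], ROI SNR 113.33
#>   conventional: AUC 0.581 [0.557-0.603], ROI SNR 7.55
#>   reduced dose: AUC 0.936 [0.928-0.945] (8 frames)
#>   dose: DLP 1296 mGy*cm, 19.44 mSv -> 4.32 mSv (78% reduction)

report$report$spectral$region_stats
#>       region     mean        sd   n
#> 1     highly 2.733692 0.1339040 600
#> 2   moderate 2.199722 0.1257672 600
#> 3 unaffected 1.791753 0.1091233 600
```

Reading the output: the spectral iodine-density series (ROI SNR ≈ 112)
supports near-perfect voxel-wise separation of haemodynamically affected
from unaffected tissue by MTT (AUC 0.997), the same series restricted to
8 of 36 frames — a 78 % dose reduction — still classifies well
(AUC 0.936), and the noisy conventional-HU series does markedly worse.
The per-region MTT means recover the configured plateaus
(2.73 / 2.2 / 1.8 s) and the highly-affected spread (± 0.13 s) matches the
noise calibration. Individual stages are available as plain functions:
`simulate_series()`, `measure_aif()`, `fit_volume()`, `derive_maps()`,
`line_profile()`, `classify_thresholds()`, `roc_curve()`,
`bootstrap_auc_ci()`, `undersample()`, `dose_summary()`, and NIfTI IO via
`write_series()` / `read_series()`.

See `vignettes/perfusion-phantom-methods.Rmd` for the model assumptions,
the calibration rationale, and known limitations.

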