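# musclepdff

Quantitative muscle-composition analysis with chemical-shift-encoded MRI,
implemented end to end on synthetic data with known ground truth.

In wasting conditions such as cancer cachexia, muscle loses volume and
accumulates fat. The proton density fat fraction (PDFF) — the share of
MR-visible protons attributable to fat in a voxel, in % — measured with a
multi-echo gradient-echo acquisition separates these two processes:
combined with a segmentation mask it yields total muscle volume, muscle fat
volume (mean PDFF/100 × total volume), contractile tissue volume
(total − fat), and their distribution along the muscle. This package is for
researchers who want a tested, reproducible reference pipeline for that
analysis: simulation, reconstruction, measurement and cohort statistics,
each independently checkable against ground truth.

## What it implements

* **Digital phantoms + forward simulation** (`generate_phantom()`,
  `simulate_signal()`): a psoas-like strand and an erector-spinae-like
  strand pair with an intermuscular fat streak, depth-varying PDFF per
  lengthwise third, smooth field map, physiological R2*, bipolar
  eddy-current phase, and SNR-controlled complex Gaussian noise. The signal
  model per echo is

  `s_n = (W + F Σ_p a_p e^{i2π f_p TE_n}) · e^{i2π ψ TE_n} · e^{−R2* TE_n} · e^{iφ0} · e^{i(−1)^n θ}`

* **Complex-based water–fat separation** (`fit_voxel()`, `separate()`,
  `estimate_eddy_phase()`): variable projection — (W, F) solved linearly
  per field-map × R2* candidate — over a coarse grid with iterative zoom
  refinement, a median-filter field-map consistency pass against water–fat
  swaps, PDFF = 100·|F|/(|W|+|F|) and T2* = 1000/R2* ms with honest
  flagging at search bounds.

* **Muscle metrics** (`apply_t2star_filter()`, `compute_metrics()`,
  `regional_metrics()`): T2* filtering ([5, 100] ms retained) for the PDFF
  analysis only, exact voxel-count volumetry, and lengthwise
  proximal/middle/distal thirds (`split_thirds()`) with a documented
  remainder rule.

* **Longitudinal analysis** (`max_change()`, `classify_cachexia()`):
  signed largest-magnitude change versus baseline across follow-ups, and
  the Fearon consensus cachexia criteria over 6-month windows.

* **Cohort statistics** (`normality_gate()`, `pearson()`, `spearman()`,
  `partial_correlation()`, `run_study_battery()`): Lilliefors-gated
  log/rank routing, classical t/ANOVA, and age-controlled partial
  correlations over every muscle × section × metric, two-sided and
  uncorrected.

* **A synthetic cohort generator** (`generate_cohort()`) with a commanded
  correlation between baseline psoas fat volume and maximum BMI change
  (marginal and age-controlled partial), used to verify that the battery
  recovers known structure.

## Worked example

```r
library(musclepdff)

protocol <- acquisition_protocol()        # 6 echoes, TE1 1.14 ms, ΔTE 0.8 ms, 3 T
gt <- generate_phantom(c(16, 16, 9), protocol,
                       pdff_profile = c(14.1, 15.2, 22.5), seed = 1)
series <- simulate_signal(gt, protocol, snr = 50, seed = 2)
maps <- separate(series)                  # PDFF / T2* / field maps
regional_metrics(maps$pdff, gt$masks$psoas, maps$t2star)
#>    section mean_pdff_pct total_ml fat_ml contractile_ml n_voxels n_voxels_pdff
#> 1    total         17.34     4.86 0.8425          4.017       90            90
#> 2 proximal         13.97     1.62 0.2263          1.394       30            30
#> 3   middle         15.34     1.62 0.2485          1.371       30            30
#> 4   distal         22.70     1.62 0.3677          1.252       30            30
```

The commanded section PDFFs (14.1 / 15.2 / 22.5%) are recovered from the
noisy simulated acquisition to within a few tenths of a percentage point;
volumes are exact voxel counts × the 3×3×6 mm³ voxel volume, and
fat + contractile always rebuilds the total. Longitudinal change and
cachexia classification work on plain numbers:

```r
max_change(294.1, c(280.2, 266.9), mode = "relative",
           followup_days = c(100, 210))
#> <change_record> relative max change -9.249% at follow-up 2

classify_cachexia(c(80, 75), c(0, 120), height_m = 1.80)
#> <cachexia_call> cachectic (max 6-month loss 6.2%), criterion: weight_loss_5pct
```

`run_pipeline(out_dir)` chains all stages — phantom, simulation,
reconstruction, metrics, cohort, statistics — writing NIfTI maps, CSV
tables and a provenance JSON, bit-reproducibly for a fixed seed.

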