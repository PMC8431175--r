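---
title: "Methods: water-fat separation, muscle metrics and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-fat separation, muscle metrics and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclepdff)
```

# The problem

Skeletal muscle wasting — as in cancer cachexia — changes both the size and
the composition of muscle. Chemical-shift-encoded MRI measures the proton
density fat fraction (PDFF): the proportion of MR-visible protons
attributable to fat, per voxel, in percent. Combined with a segmentation
mask, PDFF maps give total muscle volume, muscle fat volume, contractile
(fat-free) tissue volume, and their regional distribution along the muscle.
`musclepdff` implements this analysis end to end on synthetic data with known
ground truth: a digital phantom and forward signal simulator, a complex-based
water-fat separation, mask-based metrics with regional (proximal/middle/
distal) subdivision, longitudinal maximum-change statistics, a Fearon
consensus cachexia classifier, and the cohort-level correlation battery.

# Signal model and water-fat separation

For echo time $TE_n = TE_1 + (n-1)\Delta TE$ the complex signal in a voxel is

$$ s_n = \left(W + F \sum_p a_p e^{i 2\pi f_p TE_n}\right)
  e^{i 2\pi \psi TE_n} \, e^{-R_2^* TE_n} \, e^{i\phi_0} \, e^{i(-1)^n\theta} $$

with water and fat amplitudes $W, F$, a multi-peak fat spectrum (relative
amplitudes $a_p$, frequency offsets $f_p$ in Hz from the ppm shifts at the
scanner field strength), off-resonance field map $\psi$ (Hz), a single
effective decay rate $R_2^*$ shared by water and fat, an initial phase
$\phi_0$, and — for bipolar readouts — an eddy-current phase $\theta$ of
alternating sign across echoes.

The default acquisition matches a 3 T six-echo bipolar protocol:
$TE_1 = 1.14$ ms, $\Delta TE = 0.8$ ms, voxel size $3\times3\times6$ mm³.
The default fat spectrum is the standard six-peak triglyceride model
(dominant methylene peak at $-3.40$ ppm, amplitude 0.693); any normalised
spectrum can be substituted.

## Estimator

With $\psi$ and $R_2^*$ fixed the model is linear in the complex amplitudes
($\phi_0$ is absorbed into them), so the fit uses **variable projection**:
for each $(\psi, R_2^*)$ candidate the complex least-squares solution for
$(W, F)$ is closed-form via the $2\times2$ normal equations, and the
candidate's misfit is the projection residual. Concretely:

* **Coarse grid.** Default $\psi \in [-150, 150]$ Hz in 4 Hz steps and
  $R_2^* \in [0, 250]$ s$^{-1}$ in 10 s$^{-1}$ steps. The grid stage shares
  each candidate's basis across all voxels, so whole volumes are fit in one
  pass of matrix products.
* **Zoom refinement.** Voxels sharing a best candidate are refined together
  on a $9\times9$ offset grid whose spacing shrinks fourfold per level;
  three levels bring the effective resolution to $4/64 \approx 0.06$ Hz in
  $\psi$ and $0.16$ s$^{-1}$ in $R_2^*$ — well below what a 0.1 pp PDFF
  error requires. Single-voxel fits (`fit_voxel()`) instead polish the grid
  optimum with bounded L-BFGS-B and keep whichever is better, so the
  returned misfit is never worse than the best grid candidate.
* **Swap suppression.** Water-fat swaps are field-map errors, so after the
  per-voxel fit the $\psi$ map is 3D-median-filtered (26-neighbourhood) and
  voxels deviating by more than 30 Hz from the filtered value are re-fit
  around it. This is a deliberately cheap surrogate for region-growing field
  mapping and relies on the phantom field maps being smooth.
* **PDFF** is the magnitude ratio $100\,|F|/(|W|+|F|)$, bounded to
  $[0, 100]$ and defined as 0 where both amplitudes vanish. Magnitude ratios
  carry a small noise bias at very low SNR; this is accepted and documented
  rather than corrected.
* **T2*** is $1000/R_2^*$ ms. Where $R_2^*$ ends on a search bound the value
  is reported but flagged invalid (`t2star_valid`), never silently clamped,
  so the downstream T2* filter sees honest values.
* **Eddy phase.** `estimate_eddy_phase()` scans a global $\theta$ over
  $[-0.75, 0.75]$ rad (coarse 0.05 rad scan, then golden-section polish),
  minimising the pooled misfit of a deterministic subsample of high-signal
  voxels after correcting by $e^{-i(-1)^n\theta}$. For a monopolar protocol
  it returns 0 with a notice. The estimate is invariant to a global
  $\phi_0$ shift; like any bipolar phase model it is identified only up to
  the sign convention stated in the documentation.

The vendor reconstruction the protocol mimics is unpublished, so the
phantom validates this package's own estimator — internal consistency and
oracle equivalence — not equivalence with any scanner's output.

# The digital phantom

`generate_phantom()` builds two muscles running along the slice axis:

* a **psoas-like** single roughly cylindrical strand (intramuscular fat
  only), and
* an **erector-spinae-like** pair of adjacent strands joined by a
  one-voxel-wide intermuscular fat streak, emulating the fatty streaks
  between paraspinal muscle groups.

Each muscle's occupied slice span is divided into lengthwise thirds and the
mask-mean PDFF of each third is set to the commanded profile exactly
(smooth low-amplitude texture on top; the streak voxels carry +25 pp of
concentrated fat, and the section mean is re-centred afterwards). The field
map is a smooth random low-order polynomial (default peak 60 Hz, raised to
100 Hz in the round-trip checks), $R_2^*$ is physiological for muscle at
3 T (about 30 s$^{-1}$, rising mildly with fat), and $\phi_0$ varies
smoothly. Noise is circular complex Gaussian with complex SD equal to the
mean in-mask first-echo magnitude divided by the requested SNR — an
SNR definition anchored to a reproducible, protocol-independent quantity.

The phantom deliberately omits realistic organ anatomy, k-space effects,
coil sensitivities and motion. Passing round trips therefore demonstrate
estimator correctness under the stated signal model, not robustness to
artefacts real abdominal data can contain.

# Muscle metrics and the T2* filter

Volumes are exact voxel counts times the voxel volume — no interpolation,
no partial-volume correction (whole voxels count fully). The T2* filter
removes in-mask voxels with T2* below 5 ms or above 100 ms (bounds
inclusive on retention) *from the PDFF analysis only*: mean PDFF uses the
filtered mask, while total volume uses the full mask, and fat volume is
(filtered-mask mean PDFF / 100) × full-mask volume. Both voxel counts are
reported. Contractile volume is total minus fat, so the two components
always rebuild the total at machine precision.

# Regional thirds

`split_thirds()` partitions the occupied slice span along the annotated
inferior-superior axis — by slices, not by voxel-count terciles or physical
centerline length, because masks are drawn slice-wise at 6 mm thickness.
For spans not divisible by three the default remainder rule is symmetric:
one leftover slice goes to the middle; two go to proximal and distal. The
rule is configurable (`"proximal"`, `"distal"`). The proximal end is the
superior end for both muscles (their anatomical origins are cranial).
Empty intermediate slices still count toward the span: length is
anatomical, not occupancy.

# Longitudinal change and cachexia

`max_change()` computes the change versus baseline at every follow-up and
returns the one of **largest magnitude with its sign preserved** — the only
reading consistent with reporting dominant losses as negative means while
allowing positive maxima for individual subjects. Ties go to the earliest
follow-up. PDFF changes are absolute (percentage points); volume and BMI
changes are relative (% of baseline).

`classify_cachexia()` implements the Fearon consensus over every 6-month
window of the weight history, with 6 months operationalised as 183 days:
(1) >5% loss; (2) >2% loss with BMI < 20 kg/m²; (3) sarcopenia (supplied as
an external flag — appendicular lean mass is out of scope) with >2% loss.
A self-reported pre-baseline loss is accepted as an extra baseline-window
observation, mirroring how baseline cachexia status is typically assigned.

# Cohort statistics

The battery follows common clinical-statistics practice:

* **Normality gate**: Lilliefors-corrected Kolmogorov-Smirnov (parameters
  estimated from the sample, via `nortest`); variables rejected as normal
  but accepted after log transform are analysed on the log scale; variables
  failing both are handled by Spearman rank correlation.
* **t tests** are classical pooled-variance by default (Welch optional);
  ANOVA is the fixed-effects one-way F. All p values are two-sided; no
  multiple-testing correction is applied (explorative analysis); missing
  data are deleted pairwise per test.
* **Spearman** is Pearson on mid-ranks with the t-approximation p on
  $n-2$ degrees of freedom. **Partial correlation** uses the first-order
  formula $r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
  \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$ with $df = n-3$; the rank-based variant
  rank-transforms all three variables first (a residual-regression
  computation is the cross-check in the test suite, since how statistical
  packages compute rank-based partials is not standardised).
* `run_study_battery()` correlates every muscle × section × metric baseline
  value with the maximum BMI change, plain and age-controlled, and emits
  exactly muscles × 4 sections × 4 metrics rows, keeping under-powered
  cells as `NA` rows rather than dropping them.

# The synthetic cohort

`generate_cohort()` emulates the statistical structure the analysis
assumes, not patient images. Defaults reflect an elderly oncological
population: age $63.0 \pm 11.8$ y, baseline BMI $25.4 \pm 4.4$ kg/m²,
maximum BMI change $-2.11 \pm 1.99$ kg/m², follow-ups 44-239 days after
baseline, a mean relative muscle-volume loss of 7.5% per 100 days (SD 4 —
chosen so that typical follow-up intervals produce whole-muscle losses
around $-9\%$), and baseline muscle metrics drawn lognormally around the
published baseline means with plausible section fractions.

The commanded association is built on the log scale: standardised log psoas
fat volume and standardised BMI change are jointly Gaussian with loadings
$a, b$ on standardised age and a residual correlation $\rho$ chosen so the
marginal correlation equals the spec'd target $r$
($r = ab + \rho\sqrt{(1-a^2)(1-b^2)}$); the age-controlled partial
correlation is then exactly $\rho$, reported as attribute
`true_partial_corr`. Defaults $a = 0.3$, $b = 0.2$ make the age-controlled
correlation stronger than the marginal one, the qualitative pattern the
analysis is designed to detect. Because fat volume is lognormal, the
normality gate routes it through the log transform and the battery recovers
$r$ without attenuation.

The generator does not emulate: correlated left/right asymmetries,
scanner or segmentation noise in the metrics (beyond small lognormal
jitter), informative dropout, or treatment effects. Recovery tests on this
cohort therefore validate the statistical pipeline's correctness, not its
behaviour on messy clinical tables.

# Problem sizes and numerical choices

The bundled checks use phantoms of $16\times16\times9$ (unit tests) and
$32\times32\times18$ voxels (round-trip checks: noiseless maximum PDFF
error < 0.1 pp across a 0-45% ladder with field offsets to ±100 Hz; SNR-50
RMSE < 1.5 pp), 100-voxel estimator-vs-exhaustive-grid comparisons
(1 Hz × 2 s$^{-1}$ oracle grid), $10^4$-replicate type-I calibrations, and
5000-subject cohorts for correlation recovery. Degenerate inputs are
contracts, not crashes: all-zero signals return zero amplitudes with
`converged = FALSE`, empty filtered masks make mean PDFF an explicit error,
spans under 3 slices refuse to split, and constant samples refuse the
normality gate.

# Reproducibility

Every stochastic component takes an explicit integer seed and restores the
caller's RNG state; fixed seeds give bit-identical phantoms, signals,
cohorts and pipeline outputs. `run_pipeline()` writes a provenance JSON
(package version, seed, config and its hash) alongside the NIfTI maps and
CSV tables so any stage can be re-run independently.
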