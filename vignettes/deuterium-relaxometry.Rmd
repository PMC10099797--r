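---
title: "Deuterium brain-water relaxometry: models, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deuterium brain-water relaxometry: models, fitting, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DeutRelax)
```

DeutRelax analyses deuterium (²H) HDO signals in human brain during
heavy-water loading: mapping T₁ and T₂\* of brain water compartments from
multi-TR, multi-echo spoiled gradient-echo (MEGE) magnitude images, and
quantifying deuterium enrichment from dose schedules and spectroscopy.
This vignette explains the models, the numerical choices, what the
synthetic phantom does and does not emulate, and the design decisions
that were genuinely open.

## 1. Signal model

A spoiled gradient-echo acquisition in steady state gives, for a voxel
with amplitude $A$, flip angle $\alpha$, relaxation rates $R_1 = 1/T_1$
and $R_2^* = 1/T_2^*$,

$$
S(TR_i, TE_j) \;=\; A \,\sin\alpha\,
\frac{1 - e^{-R_1 TR_i}}{1 - \cos\alpha\, e^{-R_1 TR_i}}\;
e^{-R_2^* TE_j}.
$$

`spgrSignal()` evaluates this with angles in degrees at the interface
(converted internally), rates in 1/s, and times in ms — the convention of
the in-vivo reference values, where T₁/T₂\* are reported in ms.
`satrecSignal()` is its TE-independent factor, the saturation-recovery
model fitted to echo-summed data; `ernstAngle()`
($\alpha_E = \arccos e^{-R_1 TR}$) provides the closed-form maximiser used
as an analytic cross-check in the tests. Signals are magnitude data; the
fitting assumes additive Gaussian error on magnitudes (see §5).

## 2. Two-stage map fitting

The mapping procedure estimates, voxel by voxel:

* **Stage 1, flip-angle map** (`fitFlipAngleMap`). The 5-D dataset is
  summed over echoes at each TR; the TR series is fitted for
  $(A', \alpha, R_1)$ by bounded Levenberg–Marquardt
  ($\alpha \in [1, 120]^\circ$, $R_1 \in [0.2, 20]\,\mathrm{s^{-1}}$,
  $A' \ge 0$). Because the per-TR averaging differs (8/4/2/1/1 in the
  standard scheme), residuals are weighted by $\sqrt{\text{averages}}$:
  unweighted fitting lets the noisy single-average long-TR points dominate
  and measurably worsens the flip-angle bias discussed in §6. Three starts
  at $\{0.85, 1, 1.15\}\times$ nominal flip cover the plausible B1 range
  of a birdcage head coil; wider start spreads let noisy voxels lock onto
  spurious high-flip ridge excursions.
* **Smoothing** (`smoothFlipAngleMap`). The flip-angle map is averaged
  over a 5×5×5 voxel neighbourhood, restricted to valid in-volume voxels
  (the neighbourhood shrinks at the edge; voxels with no valid neighbour
  stay `NA`). Bound-hit voxels (QC flag 2) participate by default:
  excluding them would condition on mid-range estimates and bias the
  neighbourhood mean of an estimator whose single-voxel distribution is
  extremely wide (§6).
* **Stage 2, dual fit** (`fitRelaxationMaps`). With $\alpha$ fixed, the
  full $S(TR_i, TE_j)$ grid is fitted for $(A, R_1, R_2^*)$ by unweighted
  sum-of-squared-residuals minimisation, $R_2^* \in [1, 500]\,\mathrm{s^{-1}}$.
  $R_2^*$ is initialised from a log-linear fit of the TE decay at the
  longest TR, $R_1$ from stage 1, $A$ by linear back-projection; two
  additional $R_1$ starts (×3, ÷3) guard against local minima.

Every voxel ends in exactly one QC state: 0 fitted, 1 below the signal
threshold (default: 5 % of the 99th-percentile echo-summed signal — the
in-vivo analysis masks implicitly via brain extraction, which a package
cannot assume), 2 parameter at a bound, 3 non-converged. A parameter
pinned at a bound is reported with flag 2 even if the optimizer exhausted
its iterations there, because the pinned value (e.g. $R_1$ at its upper
bound for a fully relaxed, TR-independent series) is the informative
outcome of a degenerate fit. Flagged voxels are excluded from ROI
statistics; counts per flag are reported in the fit report.

`fitT2starMonoexp` fits single-TR multi-echo data to
$S_0 e^{-R_2^* TE}$ — the proton-R₂\* route — with the same bounds and
log-linear initialisation.

## 3. The synthetic phantom

`buildPhantom` builds a three-tissue digital brain as nested ellipsoids:
a thin cortical CSF rim, a GM shell, a WM core, two interior ellipsoidal
lateral ventricles and a small CSF-like "superior cistern" blob. Geometry
is parametric rather than atlas-based so the package needs no downloads;
shapes are configurable. Per-voxel T₁/T₂\* are drawn from each tissue's
7T reference mean ± SD (CSF 510 ± 100, GM 320 ± 50, WM 290 ± 30 ms for
T₁; 90 ± 10, 32 ± 1, 30 ± 1 ms for T₂\*; truncated positive), and
amplitudes use a water-fraction scale of 1.0/0.8/0.7 for CSF/GM/WM —
in-vivo image contrast reflects T₂\*-weighting and water fraction, and
these round values are configurable defaults rather than measurements.
The B1 field is a low-order polynomial plus a Gaussian bump, clipped to
[0.5, 1.5]; everything is deterministic per seed.

`synthesizeMEGE` applies the forward model with
$\alpha = B_1 \times \text{nominal flip}$ and adds magnitude noise with
SD $\sigma/\sqrt{\text{averages}}$ per TR. The default noise model is
Rician ($|S + n_1 + i n_2|$), the distribution of magnitude
reconstruction; a Gaussian option exists for fitting-theory tests, since
the estimator itself assumes Gaussian errors.

**Noise calibration.** The study-level SNR figure (~16) refers to the
echo-summed single-TR loading acquisition (20 averages, 7.5 min).
`sigmaForSNR` therefore chooses the single-average $\sigma$ so that this
acquisition's echo-summed image shows the requested
brain-mean / background-SD ratio, and the same $\sigma$ is used when
synthesizing the multi-TR relaxometry series — same hardware, same
voxels. For Rician noise the calibration accounts for the Rayleigh
background SD and the Rician mean bias analytically (exponentially scaled
Bessel functions), so `estimateSNR` on the synthesized image recovers the
target within sampling error. Supporting this choice, the fitted
voxel-wise T₁ scatter under this calibration (≈30 % relative SD per
tissue) closely matches the per-visit voxel-wise SDs reported in vivo.

What the phantom does *not* emulate: partial-volume mixing at tissue
boundaries, susceptibility-induced B0/R₂\* structure, motion between
acquisitions, k-space correlated noise, and anatomical geometry. Passing
recovery tests on the phantom therefore demonstrates the correctness and
noise behaviour of the estimation chain, not robustness to those effects.

`synthesizeLoadingSeries` emulates the eight-hour loading: each ~50 ml
dose of 70 % D₂O contributes $100 \cdot v f / (\text{TBW} \cdot 1000)$
atom % with a single-exponential absorption half-life of 12 min (the
blood-absorption figure; dispersal into brain water is treated as equally
fast, consistent with the observed constant between-ROI signal ratios),
on top of the 0.015 atom % natural abundance.

## 4. ROI statistics, enrichment, protocol simulation

`roiStatistics` reports mean and sample SD (n−1) over unflagged voxels
per mask, or over lists of per-visit scalars. The `table1` rounding rule
reproduces the printed precision of the reference table; the printed
precision is value-dependent — ²H times ≥ 50 ms print to the nearest
10 ms, shorter ²H times and all ¹H times to the nearest 1 ms. (A flat
"²H to 10 ms" rule would mis-round the GM ²H T₂\* mean, 31.67 → 30
instead of the printed 32.) SD reproduction at the printed single
significant figure is ambiguous and not asserted anywhere.

`refineCSFMask` is a deterministic surrogate for the manual removal of
the outer CSF: connected components (26-connectivity) that touch a
supplied exterior mask are discarded and the k largest remaining
components kept (default k = 2, the lateral ventricles).
`resampleToGrid` pull-resamples through composed voxel-to-world affines
(0-based indices, NIfTI semantics), nearest-neighbour for masks and
trilinear for images. `twoSampleTTest` defaults to the pooled
(equal-variance) statistic — the classic reading of "two-sample t-test" —
with Welch as an option; on the printed per-visit values the GM-vs-WM T₁
comparison gives p ≈ 0.22 against a reported 0.21, suggesting the
original test used unrounded inputs; this is noted, not reconciled.

`totalBodyWater` defaults to the published Watson equations (a
fraction-of-mass route is available); dose accounting treats the D₂O
volume / TBW volume ratio as the deuterium atom fraction and ignores
isotope-exchange losses. `integrateHDOSignal` integrates the magnitude
spectrum over a peak-centred window — no lineshape fitting, since the
spectral processing used in vivo is not described. When pre-loading SNR
is too low for a natural-abundance baseline, `normalizeTimecourse`
implements the alternative anchor: all ROI series are scaled by the
reference ROI's value at the final time point.

`scanDuration` is pure Cartesian phase-encode accounting
($n_y n_z \times \text{averages} \times TR$, times an optional shutter
fraction). Printed in-vivo scan times imply an unstated vendor
acquisition-reduction factor of ≈0.78–0.95; the shutter knob represents
it without claiming bit-exactness.

## 5. Monte-Carlo protocol precision

`simulateT1Precision` repeats synthesize-and-refit on a single voxel's
TR×TE grid. Two estimator modes exist, and the choice matters a great
deal:

* `two_stage` (default): each repetition co-estimates the flip angle
  from the echo-summed saturation-recovery series, then runs the
  fixed-$\alpha$ dual fit — the same chain as the imaging pipeline.
* `fixed_alpha`: the true flip angle is supplied, isolating the dual fit.

For CSF (T₁ = 510 ms) under the standard 5-TR scheme (68–816 ms), adding
a single-average TR = 1500 ms measurement changes the T₁ SD by a factor
that is fundamentally different between the modes. A numerical
Cramér–Rao analysis (`crlbT1Sd`) shows why: with $\alpha$ known, the
extension's bound ratio is 0.74 — no estimator can do better than a ~26 %
SD reduction. With $\alpha$ co-estimated, the long-TR point anchors the
$\alpha$–$R_1$ degeneracy and the bound ratio is 0.42; the two-stage
Monte-Carlo reproduces 0.42–0.46, i.e. the extension *halves* the SD of
the estimated CSF T₁. The halving is thus a statement about the full
estimation chain, and `two_stage` is the default for exactly that reason.

Simulation conditions: Gaussian noise (matching the least-squares
objective), noise referenced to the echo/TR-summed GM signal, 500
repetitions, and an SNR of 800 — chosen by a convergence criterion:
at lower noise-levels-still the ratio changes by under 3 % when the SNR
is doubled, and fewer than 1 % of repetitions hit a parameter bound. At
image-level SNRs the single-voxel two-stage estimator is heavy-tailed
(bound-range outliers dominate the SD and the ratio is seed-unstable),
so the asymptotic regime is the meaningful one for comparing sampling
schemes; only cleanly converged repetitions enter the reported SD.

## 6. Known limitation: flip-angle/T₁ entanglement at image SNR

The package recovers all phantom parameters to machine precision from
noiseless data, and — given the *true* flip-angle field — recovers
tissue-median T₁ and T₂\* within ~2 % at the study noise level. The
complete two-stage chain, however, underestimates tissue T₁ by ~15–25 %
at that noise. The mechanism is the ridge degeneracy of the
three-parameter saturation-recovery fit (the B1–T₁ entanglement familiar
from variable-flip-angle T₁ mapping): at a per-point SNR of ~9 the
per-voxel $\alpha$ estimate has an SD of ~40° and a high-side bias of
+8–15 % in GM/WM; the 5×5×5 mean removes the variance but inherits the
bias, and the fixed-$\alpha$ dual fit converts it into a T₁
underestimate of roughly 1.7× the relative $\alpha$ error. The weighting,
start-spread and smoothing choices of §2 each reduce this bias; none
removes it, and an iterative $\alpha$ re-estimation (block coordinate
descent between the stages) diverges along the joint ridge rather than
fixing it. T₂\* is essentially immune (the TE decay is orthogonal to the
degeneracy) and its tissue medians recover within ~1–2 %.

Consequences for interpretation: tissue-median T₂\* recovery at study
SNR passes a 5 % tolerance; tissue-median T₁ does not, and the
corresponding acceptance-style test in this package fails by design
rather than being weakened. Users mapping T₁ with this protocol at
comparable SNR should treat absolute T₁ values as procedure-dependent
(an independently measured B1 map, longer TRs, or inversion-recovery
acquisitions remove the degeneracy); between-tissue orderings and
longitudinal comparisons under a fixed protocol remain meaningful.

## 7. Problem sizes and reproducibility

The bundled analyses use a 24×24×16 phantom grid (≈3400 brain voxels)
for noisy-recovery checks, a 16×16×12 grid for exact noiseless checks,
and 500 Monte-Carlo repetitions for scheme comparisons; these sizes give
stable medians and SDs while keeping a full run in the minutes range on
one CPU. Every stochastic step takes an explicit integer seed, the RNG
state of the caller is never perturbed, and `runPipeline` writes a JSON
log with a config hash so a run can be reproduced from its log alone.
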