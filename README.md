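# DeutRelax

Quantitative analysis of deuterium (²H) HDO signals in the human brain
during heavy-water (D₂O) loading. After oral D₂O intake raises body-water
deuterium from its 0.015 atom % natural abundance to ~1.5 %, the deuterons
of HDO become visible to ²H MRI; spoiled multi-echo gradient-echo (MEGE)
images acquired over a range of repetition times then let tissue relaxation
times be mapped voxel by voxel. DeutRelax is for imaging scientists who
want to plan, simulate, or analyse such acquisitions: it implements the
forward signal model, the two-stage flip-angle/R1/R2\* map fitting, tissue
ROI statistics, enrichment quantification from dose schedules and
spectroscopy amplitudes, and Monte-Carlo precision analysis of TR sampling
schemes — all exercisable end-to-end on a bundled synthetic digital brain
phantom, with no external data required.

## The model

The steady-state spoiled gradient-echo signal at repetition time TRᵢ and
echo time TEⱼ is

    S(TRᵢ, TEⱼ) = A · sin α · (1 − e^(−R₁·TRᵢ)) / (1 − cos α · e^(−R₁·TRᵢ)) · e^(−R₂*·TEⱼ)

with amplitude A, flip angle α, longitudinal rate R₁ = 1/T₁ and effective
transverse rate R₂\* = 1/T₂\*. Mapping proceeds in two stages, voxel-wise:

1. **Flip-angle map** — images are summed across echoes at each TR and the
   resulting saturation-recovery curve is fitted for (A′, α, R₁) by bounded
   nonlinear least squares; the α map is then smoothed by averaging over a
   5×5×5 voxel neighbourhood (the B1 field is spatially smooth).
2. **Dual relaxometry fit** — with α fixed, the full S(TRᵢ, TEⱼ) grid is
   fitted for (A, R₁, R₂\*) by minimising the sum of squared residuals.

Enrichment is quantified two ways: from the cumulative dose,
100 × Σ(volume × D₂O fraction) / total body water (Watson equations), and
from spectroscopy, natural abundance × signal/baseline-signal. Dose uptake
follows a single-exponential absorption with a ~12-minute half-life.

## Worked example

```r
library(DeutRelax)

# a 24x24x16 three-tissue brain phantom; noise calibrated so the
# echo-summed loading-protocol image shows SNR 16
gs    <- c(24, 24, 16)
truth <- buildPhantom(gridShape = gs, seed = 5, noiseModel = "gaussian")
truth@noiseSigma <- sigmaForSNR(truth, loadingProtocol(fov = gs * c(6, 6, 10)), 16)

proto <- relaxometryProtocol(fov = gs * c(6, 6, 10))  # TR 68..816 ms, 6 echoes
data  <- synthesizeMEGE(truth, proto, seed = 6)

b1    <- fitFlipAngleMap(data)
alpha <- smoothFlipAngleMap(b1@flipAngle, qcFlags(b1))
maps  <- fitRelaxationMaps(data, alpha, r1Init = b1@R1)
maps
#> QuantMaps: grid 24x24x16; 3370 fitted, 3524 skipped, 2294 bound-hit, 28 non-converged

tt <- ratesToTimes(maps)
mk <- phantomMasks(truth)
roiStatistics(tt$T1, mk[c("CSF", "GM", "WM")], qc = qcFlags(maps))
#>   roi     mean        sd    n
#> 1 CSF 399.0170 114.71320 1110
#> 2  GM 282.8815  88.19983 1248
#> 3  WM 250.7089  79.56600  522
```

The fitted voxel-wise scatter (~30 % relative SD) matches what is seen in
vivo at this SNR; the CSF > GM > WM ordering of T₁ reflects the programmed
tissue parameters (510/320/290 ms). The systematic shortfall of the T₁
means is a property of the two-stage procedure itself at this noise level —
the flip-angle/R₁ degeneracy of the saturation-recovery fit — and is
quantified and discussed in the methods vignette
(`vignettes/deuterium-relaxometry.Rmd`).

Reference per-visit tissue values, tissue comparisons, and the dose model:

```r
v <- visitRelaxationTimes()
roiStatistics(list(csf = v$csf_t1_2h), rounding = "table1")$mean  # 510
twoSampleTTest(v$csf_t1_2h, v$gm_t1_2h)$p                         # 0.00401

tbw <- totalBodyWater("male", 30, 175, 70)                        # 42.03 L
enrichmentFromDoses(standardDoseSchedule(nDoses = 18), tbw)       # 1.499 atom %
```

A thin command-line front end over the same functions lives at
`inst/cli/deutrelax.R` (subcommands `phantom`, `run-all`, `fit-b1`,
`fit-relax`, `loading`, `protocol`).

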