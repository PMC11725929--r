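# flimox

FLIM-FRET oxygen mapping for mitochondrial physiology, with the companion
qPCR and DRIP-seq quantification arithmetic.

## The problem

A mitochondria-targeted myoglobin–mCherry sensor converts local oxygen
partial pressure (pO2) into a fluorescence lifetime: oxygen binding to
myoglobin modulates FRET from mCherry, shortening the donor lifetime as
oxygen falls. Time-correlated single photon counting (TCSPC) microscopy
records a photon arrival-time histogram at every pixel (256 channels over a
12.5 ns window). Turning those histograms into per-mitochondrion oxygen
maps — and from there into high-/low-respiration subpopulation fractions
and redox readouts — requires a chain of estimators:

1. **Per-pixel decay fitting.** Each histogram is fit with a biexponential
   `N (a1 e^(−t/τ1) + (1−a1) e^(−t/τ2))` (channel-bin integrals, Poisson
   noise model, compiled Levenberg–Marquardt); the amplitude-weighted mean
   lifetime τ_mean = a1·τ1 + a2·τ2 and the amplitude fractions a1%/a2% are
   the pixel readouts.
2. **Calibration.** In a rotenone reference condition mitochondria cannot
   consume oxygen, so intracellular pO2 equals the imposed pO2. Lifetimes
   across an imposed-pO2 ladder are fit with the hyperbola

   τ(pO2) = (τ_max − 0.914) · pO2/(K + pO2) + 0.914

   with the 0.914 ns deoxygenated asymptote fixed.
3. **Backcalculation.** Inverting the fitted curve,
   pO2 = K(τ − 0.914)/(τ_max − τ), maps every pixel's τ_mean to mmHg
   (lifetimes ≥ τ_max are masked as saturated). Low pO2 marks high oxygen
   consumption (high OCR), so thresholding the map yields high-/low-OCR
   subpopulation fractions; Mann–Whitney and Welch t tests compare
   per-image summaries between conditions. The FLIM redox ratio
   FLIRR = bound-NAD(P)H % / bound-FAD % comes from the same fit machinery.

The package also implements the nucleic-acid quantification arithmetic used
alongside such imaging: DRIP-qPCR enrichment by the 2^ΔCt method with
dilution correction and RNaseH normalization, mtDNA copy number
(nd4/mTert), and binned RPKM coverage with circular sliding-window
smoothing for DRIP-seq signal on the mitochondrial genome.

Because no public instrument data accompany the method, a synthetic-data
generator with returned ground truth (`generateDecayImage()`,
`generateCalibrationSeries()`, `generateCtTable()`, `generateReads()`)
stands in for the microscope and the qPCR machine; every estimator is
validated against it.

## Worked example

```r
library(flimox)
report <- runDemo(outDir = "demo-run", seed = 1)
#> [flimox] simulate   40 condition images + 8 calibration levels
#> [flimox] fit        per-pixel biexponential fits done
#> [flimox] calibrate  K = 15.065 mmHg, tauMax = 2.5032 ns
#> [flimox] po2map     oxygen maps rendered
#> [flimox] summarize  subpopulation summary written
str(report$keyOutputs)
#> List of 4
#>  $ K              : num 15.1
#>  $ tauMax         : num 2.5
#>  $ highOCRFraction:List of 2
#>   ..$ WT: num 0.547
#>   ..$ KO: num 0.203
#>  $ mannWhitneyP   : num 1.92e-07
```

The demo simulates a wild-type-like condition (60% of mitochondria in the
high-OCR/low-pO2 state) and a knockout-like condition (20%), 20 images
each, plus an 8-level rotenone calibration ladder. The report shows the
calibration recovered the generator truth (K = 15 mmHg, τ_max = 2.5 ns),
the estimated high-OCR pixel fractions per condition (0.547 and 0.203
against nominal mixture weights 0.6 and 0.2), and a Mann–Whitney p-value
of 1.9e−07 for the difference in per-image median pO2 — the two simulated
genotypes are clearly separated. Pseudocolored pO2 maps (warm = low
pO2/high OCR), per-image subpopulation tables and a machine-readable
`report.json` land under `demo-run/`.

The same stages are scriptable (`runPipeline()` with a YAML config, or
`inst/scripts/flimox-pipeline.R` from a shell) and usable piecemeal:
`fitImage()`, `fitCalibration()`, `po2Map()`, `subpopulationFractions()`,
`flirrMap()`, `dripEnrichment()`, `binnedRPKM()`, `smoothSignal()`, …

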