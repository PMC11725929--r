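---
title: "Mapping mitochondrial oxygen from FLIM-FRET decays: models and methods"
author: "flimox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mitochondrial oxygen from FLIM-FRET decays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimox)
```

## The measurement and the model

A mitochondria-targeted myoglobin--mCherry fusion reports local oxygen: the
oxygenation state of myoglobin modulates FRET from mCherry, so the mCherry
fluorescence lifetime encodes the oxygen partial pressure (pO2) around the
probe. A two-photon microscope with time-correlated single photon counting
(TCSPC) records, for every pixel, a histogram of photon arrival times --
here 256 channels spanning a 12.5 ns window, the period of an 80 MHz pulsed
laser.

`flimox` turns those histograms into oxygen maps in three authored steps:

1. **Per-pixel decay fitting** (`fitImage()`, `fitPixelDecay()`). Each
   pixel's histogram is modelled as a biexponential,
   $N\,(a_1 e^{-t/\tau_1} + (1-a_1) e^{-t/\tau_2})$, integrated over each
   channel bin and truncated at the window. The amplitude-weighted mean
   lifetime $\tau_{mean} = a_1\tau_1 + a_2\tau_2$ and the amplitude
   fractions $a_1\%$, $a_2\%$ are the per-pixel readouts.
2. **Hyperbolic lifetime--oxygen calibration** (`fitCalibration()`). In a
   rotenone reference condition mitochondria cannot consume oxygen, so
   intracellular pO2 equals the media-imposed pO2. Full-image averaged
   lifetimes at a ladder of imposed levels are fit with
   $$\tau(pO_2) = (\tau_{max} - 0.914)\,\frac{pO_2}{K + pO_2} + 0.914,$$
   where $K$ (mmHg) reflects myoglobin's oxygen affinity, $\tau_{max}$ is
   the lifetime at saturating oxygen, and 0.914 ns is the deoxygenated
   asymptote, treated as a fixed constant (a config override exists but the
   default never re-estimates it).
3. **Backcalculation** (`backcalculatePO2()`, `po2Map()`). The fitted curve
   is inverted, $pO_2 = K(\tau - 0.914)/(\tau_{max} - \tau)$, and applied
   to every valid pixel's $\tau_{mean}$. Because the inverse diverges as
   $\tau \to \tau_{max}$, pixels at or above $\tau_{max}$ are *masked as
   saturated*, not assigned an arbitrary large value; lifetimes at or below
   the floor map to 0 mmHg.

Low local pO2 marks mitochondria that consume oxygen quickly (high OCR),
so the pixelwise oxygen map is an inverse activity map. Downstream readouts
are the lifetime histogram (`lifetimeHistogram()`), high-/low-OCR
subpopulation fractions (`subpopulationFractions()`), the FLIM-based redox
ratio FLIRR = bound-NAD(P)H % / bound-FAD % (`flirrMap()`), pseudocolor
rendering with warm colors at the high-OCR end (`renderPseudocolor()`), and
rank/t statistics between condition groups (`mannWhitney()`,
`unpairedTTests()`).

## What the synthetic generator emulates

No public microscope data accompany this pipeline, so `generateDecayImage()`
is a first-class forward model with a returned ground truth:

* **Scene**: non-overlapping disks stand in for mitochondria on a dark
  background. Shape realism (networks, tubules) is deliberately out of
  scope; the disk geometry only has to exercise masking and labelling.
* **Oxygen field**: each mitochondrion draws its pO2 from a two-component
  Gaussian mixture describing a high-OCR/low-pO2 and a low-OCR/high-pO2
  subpopulation. The bundled fixtures use a wild-type-like 60/40 split at
  10 +/- 3 and 60 +/- 10 mmHg and a knockout-like 20/80 split of the same
  components; these are fixture choices, not measured values.
* **Decay model**: oxygen sets the *amplitude-weighted mean lifetime*
  through the hyperbola above (truth K = 15 mmHg, tau_max = 2.5 ns by
  default), and the long component is solved from
  $\tau_{mean} = a_1\tau_1 + (1-a_1)\tau_2$ with the short component fixed
  (0.45 ns, amplitude 0.25). Anchoring the hyperbola on $\tau_{mean}$ --
  the quantity the calibration and the backcalculation actually consume --
  makes the generator and the estimator describe the same law, so
  calibration recovery and forward/inverse consistency are exact by
  construction. (Anchoring it on $\tau_2$ instead would shift the
  asymptote of the $\tau_{mean}$ response away from 0.914 ns and no
  floor-fixed fit could recover the truth parameters.)
* **Photon noise**: channel counts are independent Poisson draws with means
  proportional to the discretized decay -- exactly equivalent, jointly, to
  drawing a Poisson pixel total and spreading it multinomially across
  channels. Background pixels receive uniform Poisson noise. The instrument
  response is a delta function with an optional fixed time offset
  (default 0): the decays here are slow relative to a ~100 ps IRF, and no
  IRF is estimated anywhere in the pipeline. Incomplete-decay wraparound is
  off: at 12.5 ns more than 99% of a 2.5 ns decay has elapsed.
* **Rotenone series** (`generateCalibrationSeries()`): the mixture is
  replaced by a point mass at each imposed level.

The generator also emulates the quantification inputs of the nucleic-acid
assays: qPCR Ct tables with
$Ct = intercept - \log_E(\text{abundance}/\text{dilution})$ plus Gaussian
replicate noise (`generateCtTable()`), and read-interval tables on a
circular ~16.3 kb mitochondrial genome with rectangular enriched peaks
(`generateReads()`).

What passing tests on these fixtures do **not** show: robustness to
spectral bleed-through, photobleaching, detector afterpulsing, cell motion,
autofluorescence backgrounds, or non-disk mitochondrial geometry. They show
that the estimators are correct for the stated statistical model of the
measurement.

## Numerical choices in the decay fitter

The per-pixel fit is the computational core and is implemented in C++
(a damped Gauss--Newton/Levenberg--Marquardt loop with analytic Jacobian),
because a single image means thousands of 4-parameter fits.

* **Objective.** The default is the Poisson likelihood, maximised by
  iteratively reweighted least squares (Fisher scoring: weighted
  least-squares steps with weights $1/\max(m_k, \epsilon)$ refreshed from
  the current model $m_k$, step acceptance monitored on the Poisson
  deviance). The classic fixed observed-count weighting
  $1/\max(y_k, 1)$ remains available as `objective = "neyman"`. The choice
  matters: at 5,000 photons spread over 256 channels most tail channels
  hold 0--3 counts, and fixed observed-count weights over-trust downward
  fluctuations, biasing $\tau_{mean}$ by about $-8\%$ in simulation
  (model-based Pearson weights over-correct to about $+4\%$), while the
  likelihood solution is unbiased to ~0.1%. The recovery targets in the
  test suite (95% of pixels within 5%) are only attainable with the
  likelihood objective, which is why it is the default.
* **Initialisation.** $\tau_2$ from a log-linear fit of the tail (second
  half of the window), $\tau_1$ from the head (first ~10% of channels),
  $a_1$ from the first-channel amplitude ratio, $N$ from the photon sum;
  all clamped into bounds.
* **Bounds and ordering.** Lifetimes in [0.01 ns, window], $a_1 \in [0,1]$;
  components are swapped after convergence so $\tau_1 \le \tau_2$.
* **Degeneracy tie-break.** If the two lifetimes agree within 1% the pair
  is unidentifiable; the pixel is refit as a single exponential and
  reported with $a_1 = 1$.
* **Quality gates.** Pixels below `minPhotons` (default 100, a fixture
  choice -- vendor software thresholds are unpublished) are masked, not
  fitted; all-zero histograms are invalid, never an exception. The
  conventional observed-count-weighted reduced $\chi^2$ (denominator
  channels $-$ 4) is reported per pixel, and pixels above `chi2Gate`
  (default 5) are flagged but kept unless `excludeFlagged = TRUE`, since
  no exclusion rule is established for this probe.
* **Spatial binning.** `spatialBinning = k` pools photons over a k x k
  sliding neighborhood before fitting (k odd; partial windows at the image
  border), trading spatial resolution for variance, as FLIM packages
  commonly do.

## Calibration and map choices

* Calibration consumes **full-image averaged** lifetimes per imposed level
  (per-pixel pooling is possible by passing per-pixel rows, but averaged
  points are the default pathway the pipeline builds).
* Initialisation: $\tau_{max}$ from the largest observed lifetime, $K$
  from the level whose lifetime is nearest the response midpoint. The fit
  is bounded ($K > 0$, $\tau_{max} >$ floor); a solution driven to the
  boundary is flagged non-convergent rather than silently returned.
* Units are mmHg and ns throughout.
* **Subpopulation thresholds.** The low/high pO2 cuts are explicit mmHg
  arguments. A scale-free alternative -- quantiles of a pooled reference
  condition -- is provided by `referenceThresholds()`, but it is not the
  default route to *fractions*: by construction a 25th-percentile cut
  labels 25% of the reference as high-OCR regardless of the underlying
  structure, so it cannot estimate a mixture weight. The bundled analyses
  use 30 and 40 mmHg, chosen once as the midpoint region between the
  fixture mixture modes (10 and 60 mmHg).
* **Statistics aggregation.** Group tests compare per-image (per-cell)
  summaries -- the demo pipeline uses per-image median pO2 with 20 images
  per condition -- rather than pooled pixels, to avoid pseudoreplication.
  No multiplicity correction is applied by default; Holm is available via
  `unpairedTTests(adjust = "holm")`.

## qPCR and DRIP-seq arithmetic

Enrichment uses the $2^{\Delta Ct}$ convention with explicit dilution
correction: the undiluted quantity behind a record is
$\propto \text{dilution} \times 2^{-Ct}$, so
$\text{IP/input} = (d_{IP} 2^{-Ct_{IP}})/(d_{in} 2^{-Ct_{in}})$ (the
direction of the correction is documented and tested; enrichment is
invariant to any shared Ct shift). The optional input-fraction correction
(2% kept as input) is **off** by default because published ratios are not
stated to include it; `correctInputFraction = TRUE` enables it.
Amplification efficiency is fixed at 2.0 (pure doubling) and configurable
in (1, 2]. Copy number is $E^{Ct_{nuclear} - Ct_{mito}}$.

Coverage arithmetic bins reads by their 5'-most coordinate (strand-aware,
circular wrap) into 20 bp bins by default -- the prose bin size; the
quoted tool invocation used 15 bp, and `binSize` accepts either -- converts
to RPKM, and smooths with a 45 bp circular boxcar (window rounded up to an
odd bin count, mean-preserving on the circle). Track normalization is a
per-bin ratio against the input or RNaseH-treated control with a 0.1 RPKM
pseudocount on the reference.

## Problem sizes and reproducibility

The test-suite and demo problem sizes are deliberate package choices:
64 x 64 pixel scenes with ~10 disk mitochondria and 5,000 photons per
mitochondrial pixel for recovery checks, 40 x 40 scenes for the per-replicate
calibration ladders, 20 images per condition (matching the "at least 20
cells" design of the emulated experiment), and 50 meta-replicates for the
end-to-end detection-rate property. Full 256 x 256 scenes run with the same
code path (`sceneSpec()` defaults to 256 x 256).

Every generator is a pure function of its spec and seed; the pipeline
derives child seeds deterministically, records the resolved configuration,
seed and file digests in `report.json`, and regenerates byte-identical
artifacts on re-run.

```{r demo, eval = FALSE}
report <- runDemo(outDir = tempfile("flimox-demo-"), seed = 1)
report$keyOutputs
#> $K               15.06  mmHg   (truth 15)
#> $tauMax          2.503  ns     (truth 2.5)
#> $highOCRFraction WT 0.547, KO 0.203
#> $mannWhitneyP    1.9e-07
```

## Known limitations

* The biexponential model is assumed, not selected; triple-exponential
  decays or IRF estimation are out of scope.
* FLIRR assumes pre-registered NAD(P)H and FAD images; no alignment is
  implemented.
* Saturated pixels carry no pO2 estimate; experiments near the calibration
  ceiling will lose pixels rather than extrapolate.
* The DRIP module implements only the downstream arithmetic (binning,
  smoothing, normalization, enrichment); alignment, duplicate removal and
  mapping-quality filtering are upstream concerns.
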