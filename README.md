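# acrqc — automated ACR-phantom quality control for MRI systems

`acrqc` automates the image-quality portion of routine MRI quality control
performed with the American College of Radiology (ACR) accreditation
phantom: a 190 mm inside-diameter cylinder whose homogeneous slices (#6 and
#7 of the standard 11-slice axial T1 series) are used to measure ghosting,
uniformity and noise. Manual evaluation of these tests is slow and suffers
from intra- and inter-observer variability in where the regions of interest
(ROIs) are drawn; `acrqc` removes the human factor by locating the phantom
automatically and deriving every ROI from the detected geometry, and it
quantifies how much manual placement matters by re-running the ghosting
measurement over hundreds of randomly jittered ROI layouts.

It is aimed at medical physicists and MRI QA staff who run acceptance or
routine QC on clinical scanners, and at anyone who needs reproducible QC
numbers from ACR phantom DICOM series.

## What it computes

With the phantom center and radius \(R_0\) estimated by segmentation
(Otsu threshold → largest connected component → hole filling →
intensity-weighted centroid, radius from component area):

- **UFOV**: circular ROI concentric with the phantom, radius \(0.8 R_0\)
  (64 % of the phantom area); its mean is the phantom signal \(\bar S\).
- **Background bars**: four 10 cm² rectangles up/down/left/right of the
  phantom, 0.1 R₀ clear of both the phantom edge and the image border,
  long dimension \(H_q = \mathrm{round}(1000 / (w_q\, p_x p_y))\) pixels.
- **PSG** (percent signal ghosting):
  `PSG = 100 · |((S̄_R + S̄_L) − (S̄_U + S̄_D)) / (2 S̄)|`,
  judged against ≤ 2.5 % (ACR) or ≤ 1 % (AAPM/Greek protocol). A
  randomized mode perturbs bar widths, phantom distances and corner
  positions with zero-mean normal deviates (σ = 1 px for width and gap;
  1 px and 3 px for the corner along the long/short bar dimension) and
  summarizes the resulting PSG distribution (median, 99 % empirical CI).
- **PIU** (percentage image uniformity): the slice is convolved with a
  1 cm² disc mask; over all mask positions fully inside the UFOV,
  `PIU = 100 · [1 − (S̄max − S̄min)/(S̄max + S̄min)]`,
  judged against ≥ 87.5 % (ACR, < 3 T) or ≥ 90 % (AAPM/Greek).
- **SNR**, in every common variant: single-image
  `SNR = 0.655 · S̄ / σ_bkg` (Rayleigh-corrected background SD, any bar
  or bar pair), and two-image subtraction `SNR = 1.41 · S̄ / σ_diff`
  applied to slices #7/#6 of one acquisition and to slice #7 of two
  back-to-back acquisitions (series A/B, ≤ 5 min apart). Pass limit
  80 × T (field strength in Tesla); companion ratios must fall in
  [0.9, 1.1].
- **SNRU** (SNR uniformity): percent coefficient of variation of the SNR
  over five 1 cm-radius circles (center + four at R₀/2); 5 % achievable,
  10 % maximum acceptable; inter-slice SNRU ratios checked against
  [0.9, 1.1].

A built-in generator renders synthetic ACR-like slices with exact ground
truth — uniform disc, Rician magnitude noise from two Gaussian channels,
configurable N/2 ghost band and smooth non-uniformity — and a minimal
DICOM writer/reader lets the whole pipeline be exercised end to end
without scanner data.

## Worked example

```r
library(acrqc)

# two identical sequential acquisitions, 2.5 min apart (series A and B)
spec <- phantomSceneSpec(signalLevel = 1000, channelNoiseSd = 5,
                         nonuniformityAmplitude = 0.04, seed = 3L)
study <- pairSeries(renderSeries(spec, 2, acquisitionTime = 0),
                    renderSeries(spec, 1, sliceIndices = 7L,
                                 seriesLabel = "B", acquisitionTime = 150))
report <- runQc(study, list(protocol = "acr", nRuns = 500L, seed = 1L))
report
#> QCReport
#>   protocol: acr
#>   checks: 29 (29 pass, 0 fail)
#>   overall: PASS
```

The individual metrics (with `m <- reportMetrics(report)`):

```
PSG (slice 7, series A): 0.010%
PIU (slice 7, series A): 98.5%
SNR single-image (L,R bars): 202.8
SNR two-image (#7-#6):       198.7
SNR two-image (#7A-#7B):     198.6
SNRU single-image: 0.73%
randomized PSG: median 0.005%, 99% CI [0.000, 0.016]
```

The scene was rendered with signal 1000 and channel noise SD 5, so the
true SNR is 200: both the single-image estimate (Rayleigh-corrected
background) and the two subtraction estimates recover it to about 1 %.
PSG is at its noise floor on this ghost-free scene, and the 4 % intensity
gradient depresses PIU to 98.5 % — comfortably above the 87.5 % limit.
The randomized-PSG summary shows how far manual-like ROI placement could
move the ghosting value. `writeReport(report, "report.json")` serializes
everything (metrics, verdicts, randomization summary, provenance).

A command-line front end is included for shell use:

```sh
Rscript inst/cli/acrqc.R synth --out seriesA --noise 5 --seed 3 --slices 7
Rscript inst/cli/acrqc.R run --series-a seriesA --protocol acr \
    --randomize 500 --seed 2 --out report.json
```

Exit codes: 0 all checks pass, 1 any failure, 2 execution error.

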