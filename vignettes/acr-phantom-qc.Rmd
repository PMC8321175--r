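---
title: "Automated ACR-phantom QC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ACR-phantom QC: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrqc)
```

# The measurement problem

Routine MRI quality control with the ACR accreditation phantom reduces a
set of image-quality questions — how much signal leaks into phase-encode
ghosts, how uniform the image of a homogeneous object is, how much noise
the chain adds — to means and standard deviations of regions of interest
(ROIs) on two homogeneous slices (#6 and #7 of the standard 11-slice axial
T1 series). Done by hand, the answers depend on where the tester draws the
ROIs. `acrqc` makes the placement deterministic by anchoring every ROI to
the detected phantom geometry, and then quantifies the placement
sensitivity explicitly by re-measuring under randomized, manual-like ROI
jitter.

# Pipeline and models

## Phantom detection

The phantom is segmented by Otsu thresholding on min–max-normalized
intensity, keeping the largest connected component, filling holes, taking
the intensity-weighted centroid as a subpixel center, and setting
$R_0 = \sqrt{\text{area}/\pi}$. The method is parameter-free, invariant to
global intensity scaling, and recovers a rendered 190 mm disc on a 250 mm /
256-matrix grid to well under half a pixel (about 0.5 mm). A quality
diagnostic (fraction of component pixels inside the fitted circle, half a
pixel of slack) flags non-circular segmentations. Detection fails loudly
on constant images, on components covering less than 5 % of the image
(configurable), and when the fitted circle touches the image border, since
the background bars then cannot exist.

Assumptions: one bright quasi-circular object on a dark background; no
correction for phantom tilt about the scanner axis. These hold for the
homogeneous ACR slices this package analyzes.

## ROI construction

All geometry lives in 0-based row/column coordinates with pixel centers at
integers; a pixel belongs to a circular ROI iff its center is inside the
circle. The UFOV is concentric at $0.8R_0$ (64 % of the phantom area).
Each background bar fills the strip between $0.1R_0$ from the phantom edge
and $0.1R_0$ from the image border; its short dimension $w_q$ is the full
strip width and its long dimension is $H_q = \mathrm{round}(1000/(w_q p_x
p_y))$ pixels, giving a 10 cm² bar up to one pixel-row of rounding (the
tested invariant). Bars are centered on the phantom's row/column axis. If
a tight field of view cannot fit 10 cm², the long dimension is clipped to
the image with a warning rather than failing — the bar then simply reports
its actual pixel count.

The five SNR-uniformity circles have radius $\lceil 10\,\mathrm{mm}/p_x
\rceil$ pixels, one at the center and four at $\pm R_0/2$ along the two
axes — all safely inside the UFOV for any plausible ACR geometry.

## Randomized placement

Manual ROI drawing is emulated per run and per bar: the width and the
distance from the phantom each get a zero-mean normal perturbation with
SD 1 px; the long dimension is recomputed from the perturbed width so the
bar keeps its 10 cm² area; the corner is then displaced with SD 1 px along
the long dimension and 3 px along the short one. The wording that assigns
the two corner SDs to the two dimensions is ambiguous in the protocol
descriptions this follows; the literal reading (long: 1, short: 3) is
implemented and both values are configurable. Layouts that would overlap
the phantom or cross the image border are rejected and resampled (200
retries per bar; a rejection rate above 99 % is treated as a
misconfiguration). Runs are reproducible for a fixed seed, and with all
SDs at zero the machinery degenerates exactly to the deterministic layout.

## Metrics

* **PSG** $= 100\,|((\bar S_R+\bar S_L)-(\bar S_U+\bar S_D))/(2\bar S)|$,
  with $\bar S$ the UFOV mean. Limits: ≤ 2.5 % (ACR), ≤ 1 % (AAPM/Greek).
* **PIU**: the slice is convolved with a binary disc of area 1 cm²
  (radius $\lceil 10/(p_x\sqrt\pi)\rceil$ px, i.e. 6 px at typical
  spacings) and divided by the mask count; $\bar S_{max}, \bar S_{min}$
  are the extrema of this local mean over all centers whose full mask fits
  inside the UFOV, and $PIU = 100[1-(\bar S_{max}-\bar S_{min})/(\bar
  S_{max}+\bar S_{min})]$. Limits: ≥ 87.5 % (ACR < 3 T), ≥ 90 %
  (AAPM/Greek).
* **SNR**, single-image: $f\,\bar S/\sigma_{bkg}$ with $\sigma_{bkg}$ the
  mean SD of the chosen background bar(s); every pair from {U, D, L, R}
  and each single bar is reported, the L/R pair being the protocol
  default. Two-image: $1.41\,\bar S/\sigma_{diff}$ with $\sigma_{diff}$
  the SD of the signed difference image over the UFOV, with the numerator
  taken from the first image, the second, or their average; applied to
  #7 − #6 within one acquisition and to #7A − #7B across two sequential
  acquisitions. Limit 80 × T; companion ratios in [0.9, 1.1].
* **SNRU** $= 100\,\mathrm{sd}(SNR_{1..5})/\mathrm{mean}(SNR_{1..5})$ over
  the five circles, with per-circle SNR from the bar SDs (single-image
  form) or from per-circle difference-image SDs (two-image form);
  5 % achievable / 10 % maximum acceptable, inter-slice ratios in
  [0.9, 1.1].

# Numerical choices

* **Rayleigh factor.** The magnitude reconstruction of complex Gaussian
  noise makes a zero-signal background Rayleigh-distributed, with SD
  $\sqrt{2-\pi/2}\,\sigma \approx 0.655\,\sigma$ per channel-SD σ.
  Published protocol texts variously print 0.665, 0.655 and 0.65 for this
  correction; the package uses a single `rayleighFactor` parameter,
  default **0.655** (the value the Rayleigh argument actually gives),
  applied uniformly and recorded in the report provenance.
* **Subtraction factor.** Fixed at **1.41** ($\approx\sqrt2$),
  configurable to exact $\sqrt2$.
* **SD conventions.** Pixel-level statistics use the population SD
  (divide by $n$); the five-value SNRU spread uses the sample SD
  ($n-1$). The distinction is immaterial for ROIs of hundreds of pixels
  but matters for five values, and protocol texts do not specify it, so
  it is stated here and fixed in code.
* **Ties and determinism.** The PIU extremum search breaks ties by first
  occurrence in row-major order; difference images are computed in signed
  arithmetic; all randomization is seed-scoped and never disturbs the
  caller's RNG state. Reports with a pinned timestamp are byte-identical
  across reruns.
* **Convolution.** The local mean uses FFT convolution with zero padding;
  padding can only influence pixels within a mask radius of the border,
  and the extremum search never evaluates those (the UFOV is interior by
  construction). The search is verified against a brute-force disc-mean
  oracle on 16×16 toys.
* **Confidence intervals.** Randomized-run summaries report the empirical
  quantile interval ($(1-c)/2$, $1-(1-c)/2$; default 99 %), making no
  normality assumption; the method is recorded in the report.

# The synthetic generator

`phantomSceneSpec()` / `renderSlice()` emulate the acquisition the
metrics assume: a uniform disc (default 190 mm diameter, 250 mm FOV,
256×256 matrix — so a pixel is 0.977 mm and the true radius 97.28 px)
rasterized by the pixel-center rule (exact ground truth; an optional
one-pixel edge ramp adds realism at the cost of exactness), magnitude
noise $\sqrt{(S+n_1)^2+n_2^2}$ from two independent Gaussian channels (so
the background is Rayleigh and the in-disc noise Rician, Gaussian in the
high-SNR limit), an optional ghost as a wrapped copy of the disc support
shifted by half the matrix along the phase-encode axis at a configurable
fraction of the signal (the classic N/2 ghost; real ghost structure varies
and is not modeled — the protocols only measure it), and an optional
smooth non-uniformity, by default a planar gradient with peak-to-peak
fraction $a$ across the disc. The planar default was chosen because the
local mean of a linear field over a symmetric disc mask equals its center
value, which makes the PIU response analytically predictable; a radial
(parabolic) mode is available.

Defaults represent the standard protocol conditions; noise, ghost and
non-uniformity default to zero and are dials for constructing scenes on
either side of each pass limit. Series rendering derives per-slice seeds
deterministically and supports a per-slice fractional signal drift to
emulate scanner instability between acquisitions.

What passing tests on this generator do **not** show: behavior under real
coil shading patterns, structured ghosts, phantom tilt, susceptibility or
truncation artifacts, or vendor-specific intensity scaling. The generator
validates the estimators and the geometry contracts, not the full
physics of any scanner.

# Known limitations and conditioning

* The SNRU ratio check (inter-slice SNRU within [0.9, 1.1]) is
  ill-conditioned when the phantom is nearly perfectly uniform: both
  SNRUs then estimate pure noise CVs near zero and their ratio is
  essentially random. On real scanners SNRU has a deterministic spatial
  component and the check is meaningful; synthetic demonstrations use a
  mild (4 %) gradient for the same reason.
* The deterministic PSG is one member of the randomized-layout ensemble,
  not its expectation; its distance from the randomized median is
  naturally of the order of the ensemble SD (the package's tests bound it
  by three such SDs), so randomized summaries should be read as a
  sensitivity band around the deterministic value, not as a sharper
  estimate of it.
* With noise present, the Rayleigh background mean enters all four bars
  and partially cancels in the PSG numerator; an injected ghost of
  amplitude $g$ therefore measures slightly below $100\,g$ %. This is a
  property of the measurement definition, reproduced faithfully.
* DICOM support is deliberately minimal: classic single-frame
  explicit-VR little-endian MR images with 16-bit unsigned pixels —
  what the QC workflow encounters; enhanced multi-frame objects are out
  of scope. On export, intensities are rounded to integers exactly as
  scanners store them, and the read path applies RescaleSlope/Intercept.

# Problem sizes

The test suite runs the full pipeline on 256×256 scenes, uses 10⁶-pixel
fields for the noise-factor constants, 500-run randomization for
distribution checks (10⁴ runs for the jitter-SD calibration check), and
16×16 toys for the brute-force PIU oracle; the whole suite completes in
well under a minute on a single core. These sizes give Monte-Carlo
standard errors comfortably below the asserted tolerances (e.g. the
Rayleigh-ratio SE at 10⁶ pixels is about 0.0005 against a 0.005 band).
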