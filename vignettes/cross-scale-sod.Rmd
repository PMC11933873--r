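---
title: "Cross-scale correlation spectroscopy and transfer learning for leaf SOD activity"
author: "h2dcos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scale correlation spectroscopy and transfer learning for leaf SOD activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2dcos)
```

## The problem

Superoxide dismutase (SOD) is a frontline antioxidant enzyme: when a plant
is salt-stressed, reactive oxygen species accumulate and SOD activity rises
with both the stress level and the plant's developmental stage. Measuring
that activity biochemically (the NBT photoreduction assay) is destructive
and slow, so the attraction of hyperspectral imaging is obvious — but the
spectral fingerprint of an enzyme present at trace level is subtle, and it
looks different through a microscope-coupled hyperspectral camera (MHSI,
micrometre focus) than through a whole-leaf Vis–NIR imager. The questions
this package operationalizes are:

1. Which wavelengths of each instrument respond to the SOD-linked
   perturbation? (sensitive-band selection via heterogeneous 2D
   correlation spectroscopy)
2. Can a deep spectral regressor predict activity from one instrument's
   sensitive bands? (CNN-LSTM calibration)
3. Can that model be carried over to the *other* instrument using the
   paired sensitive bands, with only a few labelled target samples?
   (cross-scale transfer learning)

No public dataset accompanies this problem, so the package ships a seeded
synthetic generator that reproduces the statistical structure of the study
design; every claim the test suite makes is a claim about that structure.

## Two-dimensional correlation spectroscopy

For spectra $y(v, p_j)$ observed along an external perturbation sequence
$p_1 \le \dots \le p_N$ (here: samples ordered by SOD activity), the
dynamic spectrum is the deviation from a reference spectrum,
$\tilde y(v, p_j) = y(v, p_j) - \bar y(v)$. The synchronous and
asynchronous maps are

$$\Phi(v_1, v_2) = \frac{1}{N-1}\sum_{j=1}^{N}
  \tilde y(v_1, p_j)\,\tilde z(v_2, p_j), \qquad
\Psi(v_1, v_2) = \frac{1}{N-1}\sum_{j=1}^{N}
  \tilde y(v_1, p_j)\sum_{k=1}^{N} M_{jk}\,\tilde z(v_2, p_k),$$

with the Hilbert–Noda matrix $M_{jk} = 0$ if $j = k$ and
$1/(\pi(k-j))$ otherwise. When $\tilde z = \tilde y$ this is the ordinary
homogeneous analysis (symmetric $\Phi$ with band variances on the
diagonal, antisymmetric $\Psi$); when $\tilde z$ comes from the second
instrument it is the heterogeneous form (H2D-COS), whose cross-peaks link
wavelengths of the two instruments that co-vary under the same
perturbation. The implementation is the matrix form
$Y_1^\top Y_2/(N-1)$ and $Y_1^\top M Y_2/(N-1)$; the test suite holds it
against the explicit double-loop sums.

Numerical conventions worth stating:

- **Reference spectrum.** The arithmetic mean ($1/N$). A printed variant
  of the reference definition divides the sum by $N-1$ instead, which is
  not the mean; both are supported (`referenceDivisor = "n-1"`), the mean
  is the default because the centring property (`colMeans(Y) == 0`) is
  what the synchronous map's variance interpretation relies on.
- **Perturbation ordering.** Samples are ordered by measured SOD
  activity. Ordering by treatment code is possible by writing the code
  into `perturbation`; ties are broken stably by sample id and logged.
- **Map normalization** is $1/(N-1)$ exactly, in both maps.
- **Slice snapping.** Requested slice wavelengths snap to the nearest
  grid band; half-way ties snap downward. Out-of-range requests are
  errors, not snaps.

## Sensitive-peak selection

Peaks are local maxima of the slice magnitude. Two masking rules reflect
how such instruments behave: the `edgeBands = 5` bands at each spectrum
end are excluded (the ends are unstable during acquisition), and bands
above `maxWavelength = 750` nm are excluded because the long-wave region
of this system carries little information — *except* that a peak whose
magnitude reaches `retainStrong = 0.5` of the slice maximum is retained
anyway. That retention rule is how a genuinely strong long-wave feature
(an O–H overtone band near 950 nm) survives the cutoff, and it is the
package's explicit resolution of the tension between "cut everything
above 750" and "keep the 948 nm band": prominence wins. A
`minProminence = 0.05` floor drops incidental ripples, and `maxPeaks`
keeps the strongest *k* when a fixed-size band set is wanted.

**Discovery runs on detrended reflectance, not derivative spectra.** The
slice magnitude of reflectance maps peaks exactly at an absorption
feature's centre; the derivative of a Gaussian feature is zero at the
centre and extremal at $\pm\sigma$, so derivative-based maps displace the
apparent peak. Polynomial detrending (`baselineCorrect`) removes the
additive scatter component that otherwise competes with the planted
features, while leaving extremum positions untouched.

## The CNN-LSTM regressor

Spectra enter as $1 \times B$ data matrices. Three convolution blocks —
kernel $1 \times 2$, stride 2, ReLU, $1 \times 2$ max-pooling — produce
32, 64 and 128 feature maps; each block divides the band axis by four
(301 bands → 4 positions). The conv output is read by an LSTM as a
sequence over the reduced band axis with the filter dimension as
features; its final hidden state feeds a ReLU dense layer and a single
linear output. When the band axis cannot support three blocks (e.g. a
10-band sensitive-band model), depth auto-reduces and the realized
architecture is recorded in the model summary.

There is no deep-learning framework dependency: forward pass,
backpropagation (verified against numerical gradients in the tests) and
Adam are implemented in the package directly, in BLAS-friendly matrix
form.

Training choices, all exposed in `trainConfig()`:

- Adam, learning rate $10^{-3}$, batch 16, MSE loss; default 300 epochs
  (heavier test and acceptance runs use 30 epochs for full-spectrum
  models and 150 for 10-band models — at those budgets the loss curves
  on the default synthetic design have flattened, and the whole
  acceptance pipeline stays within about a minute).
- Inputs are centred per band but scaled by the *pooled* band standard
  deviation. Per-band z-scoring would blow noise-only bands (most bands
  of a derivative spectrum) up to unit variance and invite overfitting;
  pooled scaling preserves the relative intensity structure.
- Targets are z-scored; predictions are returned in U/mg.
- Everything is seeded. Determinism holds for a fixed seed under
  single-threaded BLAS; cross-platform bit-identity is not promised,
  metric tolerances are.

The calibration/prediction split is stratified by treatment × stage with
largest-remainder allocation (0.75 of 108 samples gives exactly 81/27),
falling back to a plain random split with a warning when a stratum has
fewer than two members.

## Transfer between instruments

`pairBands()` pairs the two instruments' sensitive wavelengths by rank
order when the lists have equal length — cross-instrument partners need
not be nearest neighbours in wavelength, so rank order is the honest
default — and greedily by nearest wavelength otherwise, dropping and
logging the unmatched surplus.

`transferModel()` carries a model trained on the source bands to the
target bands. The default strategy freezes the convolutional feature
extractor and fine-tunes the LSTM and dense layers on a small labelled
subset (25% of the target calibration set by default — the small-label
regime that motivates transfer in the first place). `full_finetune` and
`zero_shot` are available; zero-shot copies the model untouched and is
bitwise-identical on identical input, which the tests assert. For the
fine-tuning strategies the input standardization is re-anchored on the
(unlabelled) target calibration spectra, since the two instruments sit
on different reflectance scales; the activity scale is kept from the
source model.

**Band-subset models consume reflectance, not derivatives.** A derivative
needs neighbouring bands, which a 10-band subset does not have; and at a
planted feature's centre the derivative is exactly zero. So the
full-spectrum comparison uses the pretreatments, while sensitive-band
models (and hence transfer) use reflectance values at the selected
bands. The transfer direction default is micro → macro; the reverse
works identically by swapping arguments.

## The synthetic generator

`generatorConfig()` encodes the emulated study: 4 NaCl treatments (0, 1,
2, 3 g/L) × 3 stages (seedling, flowering, fruit-setting) × 27 plants =
324 paired spectra; micro grid 400–1000 nm at 2 nm; macro grid 400–1000
nm at 2.35 nm (deliberately incommensurate, so nothing downstream can
assume shared axes). Labels follow
$\mathrm{SOD} = 0.05 + 0.02\,c + 0.03\,s + \varepsilon$, truncated at 0,
with $c$ the concentration in g/L, $s$ the ordinal stage (0/1/2) and
$\varepsilon \sim N(0, 0.01)$ U/mg. The slopes put activities in the
0.05–0.17 U/mg range, the scale on which prediction errors of order 0.01
U/mg are meaningful for this assay.

Each spectrum is built from four layers:

1. a smooth modality baseline (micro: absorption peaks near 480/560 nm,
   valleys near 500/690 nm, low plateau past 700 nm; macro: green peak
   near 545 nm, red-edge plateau over 755–900 nm, small O–H valley near
   950 nm);
2. SOD-proportional Gaussian dips/bumps ($\sigma = 3$ nm, alternating
   sign, |effect| 0.6 reflectance per U/mg) at the planted sensitive
   bands — ten per modality by default, at the slice-peak wavelengths of
   the two instruments, snapped to the grid. The 3 nm width keeps
   neighbouring planted bands (down to ~5 nm apart on the macro list)
   resolvable as separate extrema;
3. per-sample baseline clutter: a dominant random offset/slope/curvature
   component (the classic additive scatter model that motivates
   polynomial baseline removal) plus weaker broad random Gaussians
   (60–120 nm wide) that only derivative pretreatment suppresses.
   Amplitude sd 0.05 makes clutter the largest variance component, as in
   real leaf reflectance where presentation effects dwarf constituent
   signals — and it is exactly this structure that gives the
   pretreatment comparison its expected ordering (derivative ≥ baseline
   removal ≥ raw/smoothing) for mechanistic rather than accidental
   reasons;
4. i.i.d. noise, sd 0.002.

Cubes are generated for a subset of samples spread evenly across the
design (so a figure set spans the treatment range, as a visualization
would), replicating the sample's spectrum per pixel and modulating it by
a planted ±15% column-wise activity gradient stored in
`metadata$sod_field`; the gradient is mean-zero, so the cube's pixel-mean
spectrum reproduces the sample spectrum.

What the generator does *not* emulate: radiative transfer, leaf anatomy,
instrument point-spread functions, wavelength miscalibration, or any
nonlinearity between activity and reflectance — the planted effect is
linear by design, the simplest structure a correlation-based peak search
assumes. Passing tests therefore demonstrate that the pipeline recovers
structure *of this kind*; they say nothing about chemical attribution in
real leaves.

## Degenerate inputs and edge behaviour

- Savitzky–Golay operators (window 7, order 2 by default) apply the
  centred filter on the interior and copy the nearest interior value
  into the `(window-1)/2` edge bands; peak selection masks spectrum ends
  anyway, which is why this cheap rule is acceptable.
- The first derivative is scaled by the mean band spacing
  (reflectance per nm).
- `calibrateCube()` refuses zero `white − dark` divisors naming the
  band, refuses double calibration, and broadcasts per-band reference
  vectors over pixels (whether references were captured as full frames
  or row averages is instrument-dependent; both are accepted).
- The assay formula is implemented as
  $((A_{S0}-A_S)\,V_t)/(A_{S0}\,W\,V_S\cdot 0.5\cdot 1000)$ — the
  grouping consistent with the 50%-inhibition unit definition. The fresh
  weight enters in grams by default; `weightUnit = "mg"` converts
  explicitly, never implicitly. Negative activities (sample absorbance
  above control) are returned as computed, with a warning.
- Zero-variance targets refuse to fit; zero-variance predictions report
  RMSE with `r = NA` and a flag; NaN loss aborts training naming the
  last finite epoch.

## Problem sizes used by the tests

Unit tests run on 24–48-sample configurations with reduced grids; the
acceptance-style tests and `scripts/acceptance.R` use the full default
design (324 samples, 301 + 256 bands), 30-epoch full-spectrum models,
150-epoch 10-band models, a 200-draw permutation null and one 32×32
cube — sizes at which every quantity the suite asserts has converged,
while a complete run stays in the low minutes on one CPU.

## Known limitations

- The CNN-LSTM engine is plain R; it is fast enough for spectra of this
  size but not for, say, pixel-level training on large cubes.
- Greedy nearest-wavelength pairing is not optimal matching; with
  grossly unequal peak lists an assignment solver would pair better.
- The ENVI reader covers the float32/float64 BSQ/BIL/BIP subset this
  workflow produces, not the whole ENVI zoo.
- Correlation maps are written as CSV + JSON sidecar rather than a
  hierarchical binary container.
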