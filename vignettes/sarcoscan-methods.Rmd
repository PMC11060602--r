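---
title: "Quantifying sarcomere structure: models, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcomere structure: models, pipeline, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sarcoscan measures the nanoscale geometry of striated muscle from
multi-channel fluorescence images: sarcomere length (the distance between
neighbouring Z-discs), Z-disc width, and the distances between titin
epitope bands (N2A, PEVK) used as intra-sarcomere landmarks. Because no
deposited image data exist for this kind of measurement, the package pairs
the analysis pipeline with a forward simulator, so that every stage can be
validated against known ground truth. This vignette explains the models,
the conventions, and the choices that were genuinely open.

## The forward model

**Structure.** A sarcomere lattice is one-dimensional along the fibre
axis: Z-disc band centres $c_i$ with per-sarcomere spacings $L_j \sim
\mathcal N(L, \sigma_L^2)$, truncated below so bands can never overlap
(`make_lattice()`). Resting mouse skeletal muscle motivates the defaults:
mean length $L = 2400$ nm (the midpoint of the commonly quoted
2.3–2.47 µm range) and a Z-disc width of 60 nm (reported widths span
roughly 30–140 nm across muscles and species). Titin epitopes are bands
at fixed offsets from each Z-disc centre: N2A at ±285 nm (so the two N2A
bands straddling a Z-disc are 570 nm apart) and PEVK at ±115 nm (so N2A
and PEVK on the same side are 170 nm apart), each 30 nm wide. All of
these are configurable; the defaults are the geometry the measurement
pipeline is expected to recover.

**Rendering.** Bands are top-hats of amplitude 1, constant along the
stripe direction (`render_ground_truth()`). A pixel's value is the mean
density over its footprint, so sub-pixel band edges render as fractional
coverage — computed analytically for axis-aligned lattices and by 5×5
supersampling for oblique orientations. Pixel $i$ spans $[ip, (i+1)p)$ nm
(0-based, half-open) with its centre at $(i+0.5)p$. Zero-width bands are
treated as indicators on the containing pixel.

**Optics.** The blur applied by `apply_optics()` is an isotropic Gaussian
whose SD combines the PSF and the antibody linkage error in quadrature:
$\sigma_{tot} = \sqrt{(\mathrm{FWHM}/2.3548)^2 + \epsilon^2}$, with
$2.3548 = 2\sqrt{2\ln 2}$. Linkage error — the physical displacement
between epitope and fluorophore introduced by the antibody stack — is
modelled as blur rather than per-molecule point scatter: at the labelling
densities of tissue sections, ensemble labelling is statistically
equivalent to convolving the density with the displacement distribution,
and it keeps the forward model analytic. The three presets
(`optics_preset()`) differ *only* in PSF FWHM and linkage error:

| preset         | PSF FWHM | linkage error |
|----------------|----------|---------------|
| `confocal_igg` | 280 nm   | 17.5 nm       |
| `sim_igg`      | 120 nm   | 17.5 nm       |
| `sim_nanobody` | 120 nm   | 2 nm          |

These are order-of-magnitude stand-ins (confocal ≈ diffraction limit at
high NA; structured illumination ≈ a two-fold improvement; IgG
primary+secondary stacks ≈ 15–20 nm RMS; single-domain nanobodies a few
nm). None is a calibrated instrument constant and all are exposed in the
API and config.

**Noise.** `add_noise()` draws
$\mathrm{Pois}(\alpha\,I + b)/\alpha + \mathcal N(0, \sigma_r^2)$,
clipped at zero: photon shot noise at scale $\alpha$ (`photons_per_unit`,
default 200 — a moderate-SNR exposure), a constant background $b$ (20
photons) added before the Poisson draw, and Gaussian read noise. Every
stochastic operation is a pure function of its parameters and an integer
seed.

The simulator emulates longitudinal sections with quasi-periodic, locally
parallel striations and spatially uniform labelling. It does **not**
emulate curved or branching myofibrils, intensity gradients,
out-of-focus haze, chromatic shifts between channels, or labelling
heterogeneity — so passing tests demonstrate correctness of the
*measurement machinery*, not robustness to every artefact of real tissue.

## The measurement pipeline

Per channel, three pre-processing steps (`preprocess_channel()`):

1. **Background subtraction** — the mean over a background rectangle
   (user-supplied, or the minimum-mean 64×64 tile) is subtracted
   globally and negatives are clipped; the subtracted value is logged.
2. **IsoData binarization** — the classical Ridler–Calvard iterative
   intermeans threshold on a 256-bin histogram: iterate
   $t \leftarrow (\mu_{\le t} + \mu_{> t})/2$ from the global mean. The
   iteration is run to the fixed point of the discrete split index (a
   rare two-cycle resolves to the split whose intermeans moves least);
   tests verify the result against an exhaustive 256-candidate scan.
   Pixels strictly above $t$ are foreground. The histogram variant was
   chosen over an exact-value iteration because it is the canonical
   published form and reproducible without reference to any particular
   software's internals; the bin count is exposed.
3. **Particle analysis** — connected components under 8-connected
   foreground / 4-connected background (the convention is recorded on
   the mask), an area filter (default ≥ 4 px, to suppress shot-noise
   specks; no upper bound), and per-particle *bare outlines*: foreground
   pixels with a 4-connected background neighbour, the image border
   counting as background. Labels are 1..K in raster order. Enclosed
   holes (background components not reaching the border) are filled in
   the scan mask, since a particle's reference points are its outer
   borders.

**Line scans.** Paths are straight lines in pixel coordinates sampled at
uniform arc length (default 0.25 px). Intensity images are sampled
bilinearly (a sample at a pixel centre equals the pixel value); binary
masks by nearest neighbour, so no sub-threshold values are invented —
sub-pixel precision comes from the fine sample step. A 0→1 transition
between consecutive samples places an `enter` event at the midpoint of
the two sample positions; 1→0 an `exit`; bands that touch a scan end are
flagged incomplete and excluded from all statistics. `auto_paths()`
estimates the stripe normal from the dominant 2D spectral peak (ties
broken toward the lower spatial frequency) and places parallel,
non-overlapping paths spanning the field.

Reading bands off a noisy mask needs two robustness rules, both of which
came out of failure analysis on simulated low-SNR confocal images:

* **Particle-aware runs with gap bridging.** The scan samples the
  particle *label* map; consecutive runs of the same particle separated
  by at most 1.5 px are bridged. This closes single-pixel noise notches
  that would otherwise split one band into two, while leaving genuinely
  distinct lobes of a noise-bridged particle (e.g. the two PEVK bands
  ~230 nm apart) separate.
* **Physiological minimum separation.** Z-disc band centres closer than
  1000 nm cannot be two real Z-discs — 1000 nm is the same lower bound
  that delimits the FFT period search band — so `merge_close_bands()`
  fuses them as fragments of one band before lengths are computed.

**Measurands.** Sarcomere lengths are consecutive centre-to-centre
differences of complete Z-disc bands; Z-disc widths are their
enter-to-exit extents; `epitope_distances()` pairs N2A bands straddling a
Z-disc centre (`flanking_pair`) and pairs N2A with its nearest PEVK
within half a sarcomere (`nearest_cross_channel`, exact ties broken
toward the lower position and flagged). The pairing rule for cross-channel
distances is a documented stand-in — no published convention exists.

**FFT comparator.** `fft_period()` estimates the dominant spatial period
of an intensity profile: detrend, Hann window, 4× zero-padding, magnitude
spectrum, peak within 1–5 µm, parabolic sub-bin interpolation. A peak is
only accepted if its power exceeds the extreme-value bound for pure noise
(periodogram bins are approximately exponential; the max of $m$ bins
concentrates near $\lambda \ln m$, and we require
$\lambda(\ln m + 8)$), otherwise the profile is declared aperiodic. The
canned comparison experiment deliberately runs the comparator with
`zero_pad = 1, refine = FALSE` — the raw peak-bin readout of the plain
FFT tools the line-scan method is meant to replace. This matters: with
sub-bin refinement the FFT estimate tracks the line-scan estimate almost
perfectly (both are dominated by the same realized lattice variability;
correlation ≈ 0.8 on simulation), whereas the raw bin readout quantizes
the period to ~100–150 nm steps, which is precisely the excess
variability the comparison is about.

## Nested statistics

Measurements are technical replicates nested in images nested in
biological replicates. `aggregate_measures()` implements two-stage
averaging: all technical measurements within a biological replicate are
averaged into one replicate mean, and group statistics are computed on
the *unweighted* replicate means. Sample SDs use the $n-1$ denominator;
CV is reported in percent. `compare_groups()` uses a Welch t-test on
replicate means plus a variance F-test (reported both on raw leaves — the
default for variability comparisons — and on replicate means) for two
groups, and for three or more a one-way ANOVA *on replicate means*, which
is exactly the between-group stratum of a nested one-way ANOVA for
balanced designs and conservative otherwise. Post-hoc comparisons are
Holm-adjusted pairwise Welch t-tests: a rank-based post hoc after a
parametric ANOVA is internally inconsistent, so we use the parametric
pairwise test with a standard family-wise correction and document the
substitution.

## Numerical choices

* Convolution is separable with reflective padding and a kernel truncated
  at $4\sigma$; a symmetric normalized kernel under reflection conserves
  total intensity exactly, which the tests check to 0.1%.
* Histograms use 256 bins over `[min, max]`; constant images are a
  degenerate-input error for thresholding.
* Band centres are `(enter + exit)/2`; crossing positions converge as the
  sample step shrinks (tested by refinement from 0.5 px to 0.05 px).
* All positions are nm; pixel size is never guessed — a missing pixel
  size is a hard error in the measurement command.
* Degenerate statistics (identical groups, zero variances) return null
  results (p = 1) rather than failing.

## Problem sizes used in validation

The test-suite simulations use fields of 9 Z-discs sampled at 40 nm/px
(64×620 px), 5 images × 5 scans for recovery checks; 3 replicates × 5
images × 5 scans per modality for the width-ordering experiment; 25
independent scans of 13-disc lattices for the FFT comparison; and 200
null simulations for test-size calibration. These sizes give comfortable
Monte-Carlo margins for every assertion while keeping a full validation
run in well under a minute; all of them are parameters, not constants.

## Known limitations

* Width estimates inherit pixel quantization: at 40 nm/px a 60 nm band
  measures 40–160 nm depending on blur and phase; the pipeline measures
  the *thresholded blurred* band, which is why validation compares
  against a 1-D thresholded-blurred-top-hat oracle rather than the bare
  truth, and why cross-modality comparisons are made on matched seeds.
* The IsoData threshold is global per channel; intensity gradients across
  the field would bias band widths (use smaller fields or flat-field
  first).
* `auto_paths()` assumes a single dominant striation orientation per
  field.
* The nearest-neighbour pairing for cross-channel epitope distances can
  be contaminated when two epitope lobes merge under low SNR; the
  flanking-pair mode is robust to this because it conditions on a
  straddled Z-disc centre.
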