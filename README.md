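# sarcoscan

Quantification of sarcomere structure from multi-channel fluorescence
microscopy, with a forward simulator for validation.

The sarcomere — the contractile unit of striated muscle, bounded by
protein-dense Z-discs — is about 2.3–2.5 µm long in resting mouse muscle,
while the Z-disc itself is only 30–140 nm wide and titin epitopes sit a
few hundred nm from it. Measuring this geometry from fluorescence images
requires objective, reproducible reference points instead of hand-picked
intensity peaks. sarcoscan implements that measurement pipeline:

1. **Pre-processing** per channel: mean background-ROI subtraction,
   automatic IsoData (Ridler–Calvard iterative intermeans) binarization,
   and connected-component particle analysis with bare-outline
   extraction,
   $t_{k+1} = \tfrac12\left(\mu_{\le t_k} + \mu_{> t_k}\right)$.
2. **Line scans** across the striations (placed automatically from the
   2-D spectral peak, or supplied explicitly), with sub-pixel band
   borders read off the particle mask at sample-midpoint crossings.
3. **Measurands**: sarcomere length (centre-to-centre distance of
   neighbouring Z-disc bands), Z-disc width (band extent), and titin
   inter-epitope distances (N2A–N2A across the Z-disc, N2A–PEVK), plus an
   FFT spatial-period comparator.
4. **Nested statistics**: two-stage averaging over technical → biological
   replicates (group statistics on unweighted replicate means, sample SD,
   CV%), Welch t-tests, variance F-tests, and one-way ANOVA on replicate
   means with Holm-adjusted pairwise comparisons.

Because no public image data exist for this assay, the package ships a
forward simulator: a ground-truth sarcomere lattice (jittered spacings,
configurable epitope layout) rendered with anti-aliased top-hat bands,
blurred by a Gaussian PSF combined in quadrature with antibody linkage
error, and degraded with Poisson shot noise and Gaussian read noise.
Three optics presets — `confocal_igg`, `sim_igg`, `sim_nanobody` — differ
only in PSF FWHM and linkage error. Everything downstream is validated
against this known truth; see `vignettes/sarcoscan-methods.Rmd` for the
models and design decisions.

## Worked example

Simulate one SIM + nanobody field of nine Z-discs with realistic jitter
and noise, then measure it end to end:

```r
library(sarcoscan)

img <- simulate_image(
  list(n_sarcomeres = 9, length_mean_nm = 2400, length_jitter_sd_nm = 60,
       zdisc_width_nm = 60, origin_nm = 700),
  optics_preset("sim_nanobody"), shape = c(64, 620), seed = 42)
img
#> <multichannel_image> 3 channel(s) [zdisc, N2A, PEVK], 64 x 620 px, 40 nm/px, with ground truth

sm <- measure_image(img, n_scans = 5, seed = 7)
sm
#> <scan_measures> 5 scan(s), 222 band(s), 264 measurement(s)
#> # A tibble: 5 × 4
#>   measure          pair          n mean_nm
#>   <chr>            <chr>     <int>   <dbl>
#> 1 epitope_distance N2A-N2A      45    568.
#> 2 epitope_distance N2A-PEVK     90    176.
#> 3 epitope_distance PEVK-PEVK    44    329.
#> 4 length           <NA>         40   2428.
#> 5 width            <NA>         45    148.
```

The recovered geometry matches the simulated truth: mean sarcomere length
2428 nm for a lattice drawn around 2400 nm, N2A–N2A 568 nm against a true
570 nm, N2A–PEVK 176 nm against 170 nm. The measured Z-disc width
(148 nm for a 60 nm band) is the width of the *thresholded, blurred* band
— the quantity the pipeline defines — and shrinks as optics improve,
which is the basis of the modality comparison below.

Measurements are tibbles throughout, so they pipe into the nested
aggregation and comparison layer (`aggregate_measures()`,
`compare_groups()`, with `tidy()`/`glance()`/`autoplot()` methods), and
two canned experiments reproduce the pipeline's qualitative claims
end-to-end:

```r
experiment_modality_ordering(seed = 1)
#> <experiment_result> modality_ordering
#>   mean widths 325 > 157 > 150 nm (confocal_igg, sim_igg, sim_nanobody)
#>   are strictly decreasing; ANOVA p = 2.09e-12: PASS

experiment_fft_vs_linescan(seed = 1)
#> <experiment_result> fft_vs_linescan
#>   FFT SD 67.0 nm > line-scan SD 23.7 nm (F = 7.96, p = 3e-06): PASS
```

## Command line

A thin entry point wraps the same functions:

```sh
Rscript inst/cli/sarcoscan simulate --preset sim_nanobody --n 3 --seed 7 --outdir fixtures
Rscript inst/cli/sarcoscan measure  --images fixtures/image_001.tif --outdir out
Rscript inst/cli/sarcoscan experiment --name modality_ordering --seeds 1..3 --outdir exp
```

`simulate` writes 16-bit multi-page TIFFs with JSON ground-truth sidecars
and a manifest; `measure` writes `bands.csv`, `scans.csv`, `summary.csv`,
`tests.csv` and a provenance log (all units nm; pixel size comes from a
flag or TIFF metadata and is never guessed); every run records its
effective configuration. Exit codes: 0 success, 1 user error, 2 internal
error.

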