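# mitodwell

Quantitative analysis of transcription-factor (TF) dynamics on mitotic and
interphase chromatin, for single-molecule imaging and CUT&Tag experiments on
live cells — the kind of data behind questions like *does this factor stay
bound through mitosis, and for how long?*

The package covers three measurements and the synthetic data to validate
them:

* **Residence times from slow-tracking movies.** Diffraction-limited spots
  are detected per frame with an MTT-style generalized-likelihood-ratio test
  (localization error 10^-6.25, PSF width fixed at the diffraction limit,
  3 deflation loops), linked into tracks with one-frame gap closing under a
  maximum-diffusion search radius (D_max = 0.5 um^2/s, <= 5 competitors),
  and converted to dwell times. The dwell-time survival curve is fitted
  with a two-exponential dissociation model

      S(t) = f exp(-k_fast (t - t0)) + (1 - f) exp(-k_slow (t - t0)),

  whose slow component is the apparent k_off. Subtracting the apparent
  k_off of an H2B-Halo control removes photobleaching, the inverse of the
  corrected rate is the residence time, and the fitted model also yields
  the time to 1% bound.
* **Chromatin enrichment of mitotic cells.** From two-channel (H2B +
  HaloTag-TF) stills: score = log2(chromatin mean / whole-cell mean) of the
  TF channel, with automated Otsu-based segmentation (or imported
  hand-drawn masks), replicate-averaged comparisons and two-tailed t-tests
  on replicate means.
* **Spike-in normalization of CUT&Tag counts.** Per-sample scalings =
  constant / fly-aligned reads, anchored so the asynchronous reference is
  exactly 1, applied to per-site read-count matrices (BED-interval sites).
* **Synthetic data with ground truth** for all of the above: mixture-
  exponential dwell times with bleaching and frame discretization, sparse
  single-molecule movies, two-channel mitotic cells with a designed
  enrichment, and binomial spike-in counts — so every stage is testable
  without raw microscopy or sequencing data.

## Worked example

Simulate a mitotic-like dwell-time experiment (5 Hz, fast non-specific
component, bleaching), fit it, and correct with a matched H2B control:

```r
library(mitodwell)

tf <- simulate_dwell_times(
  kinetic_config(frac_fast = 0.4, k_fast = 1.0, k_slow = 0.178,
                 k_bleach = 0.04),
  n = 5000, seed = 7, min_frames = 3)
h2b <- simulate_dwell_times(
  kinetic_config(frac_fast = 0.3, k_fast = 1.0, k_slow = 0.04),
  n = 5000, seed = 8, min_frames = 3)

fit <- fit_biexponential(build_survival(tf$dwell))
fit
#> Two-exponential survival fit
#>   n = 4058 dwells, t0 = 0.4 s, method = ls
#>   f(fast) = 0.3823, k_fast = 0.9727 1/s, k_slow = 0.1981 1/s
#>   apparent k_off (slow component) = 0.1981 1/s, rss = 0.000356

ctrl <- fit_biexponential(build_survival(h2b$dwell))
correct_photobleach(fit$k_slow, ctrl$k_slow)
#> corrected k_off = 0.1585 /s, residence time = 6.31 s
time_to_fraction(fit, 0.01)
#> time to 1% bound = 21.2 s
```

The true slow disappearance rate here is 0.178 + 0.04 = 0.218 /s; the fit
reads 0.198 /s apparent, and after subtracting the H2B rate the corrected
k_off (0.159 /s, residence ~6.3 s) recovers the programmed specific rate of
0.178 /s to within its sampling error. A survival curve with its fit
overlaid is one call: `plot(fit)`.

Spike-in scaling from a fly read-count table:

```r
counts <- data.frame(sample = c("async", "mitotic"),
                     condition = c("asynchronous", "mitotic"),
                     fly_reads = c(52341, 26170))
compute_scaling(counts, constant = 1e5, reference = "async")
#> spike-in scaling table (constant 100000, reference 'async')
#>   sample    condition fly_reads raw_scaling  scaling
#>    async asynchronous     52341    1.910548 1.000000
#>  mitotic      mitotic     26170    3.821169 2.000038
```

Whole movies go through `simulate_movie()` → `localize_stack()` →
`link_localizations()` → `extract_dwells()`, cell images through
`simulate_cell_image()` → `segment_masks()` → `enrichment_score()` →
`compare_constructs()`, and a YAML-configured multi-stage run through
`run_pipeline()` (with a thin command-line wrapper in `inst/cli/mitodwell.R`).
The methods vignette (`vignettes/mitodwell-methods.Rmd`) documents the
models, conventions and numerical choices.

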