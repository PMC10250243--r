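---
title: "Models and methods behind mitodwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitodwell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodwell)
```

mitodwell quantifies how transcription factors (TFs) interact with chromatin
through mitosis, from three kinds of measurement: single-molecule
slow-tracking movies (residence times), two-channel live-cell stills
(chromatin enrichment), and spike-in normalized CUT&Tag read counts
(site-specific binding). This vignette explains each model, its assumptions,
the tunable parameters, and the design choices made where more than one
reasonable implementation exists. Every number quoted here is computed by the
package's own tests or acceptance script; none is asserted from outside.

## The two-state dwell-time model

A chromatin-bound, fluorescently labeled TF molecule imaged at long exposure
(200 ms) appears as a stationary diffraction-limited spot until it unbinds,
its fluorophore bleaches, or the movie ends. Dwell times are modeled as a
two-component exponential mixture: a fast-dissociating population (transient,
non-specific interactions, rate $k_{fast}$) and a slow one (specific binding,
rate $k_{slow}$), observed through an independent single-step bleaching
process at rate $k_{bleach}$. The survival function of observed dwells is

$$S(t) = f\,e^{-(k_{fast}+k_{bleach})t} + (1-f)\,e^{-(k_{slow}+k_{bleach})t}.$$

The **apparent $k_{off}$** is the slow component of the fitted model: the
fast component absorbs transient binding, and the residence time the assay
is after belongs to the specific, long-lived interactions. Prior
single-particle-tracking work on which this analysis style is based makes
the same attribution. Bleaching is removed by subtracting the apparent
$k_{off}$ of an H2B-Halo control — histone H2B barely exchanges on the
imaging timescale, so its spot-disappearance rate estimates $k_{bleach}$ —
and the **residence time** is the inverse of the corrected rate:

$$k_{corr} = k_{off}^{TF} - k_{off}^{H2B}, \qquad \tau = 1/k_{corr}.$$

If $k_{corr} \le 0$ the correction is reported as an error, never clamped: a
TF that outlives the H2B control indicates a miscalibrated control, not a
negative rate. The **time to 1% bound**, the other headline statistic, is
the solution of $S(t) = 0.01$ under the fitted model (empirical curves
rarely reach 1%, so the fitted model is used; for a collapsed single
exponential the closed form $t_0 + \ln(100)/k$ applies, otherwise bisection
to a relative tolerance of $10^{-6}$).

### Fitting choices

`fit_biexponential()` fits $S(t)$ by unweighted least squares on the
empirical survival values (one point per distinct observed duration), the
convention in this literature; a maximum-likelihood mode on the raw dwells
(`method = "mle"`) is provided as a cross-check and agrees with the
least-squares slow rate to a few percent on simulated data. Numerical
details that matter:

* Parameters are transformed (logit fraction, log rates, with
  $k_{fast} \ge k_{slow}$ enforced by construction) so that every optimizer
  start is feasible; optimization is Nelder–Mead from a grid of log-spaced
  rate pairs around a crude single-rate estimate taken from where the curve
  crosses $e^{-1}$.
* If the best fit has $k_{fast}/k_{slow} < 1.5$ or $f$ outside
  $[0.01, 0.99]$ the two components are not identifiable; the model is refit
  as a single exponential and flagged `collapsed`, with `k_slow` carrying
  the single rate.
* Curves with more than 2000 distinct time points are thinned rank-uniformly
  before fitting — dense continuous-time curves carry no extra information
  at that resolution, and the thinning changes fitted rates by far less than
  their sampling error.
* The origin shift $t_0$ defaults to the shortest observed dwell: survival
  is conditional on a track being long enough to see at all.

### Dwell-time conventions

A track spanning frames $a..b$ has duration $(b-a)\,\Delta t$; gap-bridged
frames count as bound (the molecule is presumed bound throughout a bridged
gap). Tracks must span at least 3 frames by default (`min_frames`), a floor
on what detection can support; the threshold is configurable and stated here
because the underlying assay convention is not standardized. Tracks that
reach the movie's final frame are right-censored and excluded from survival
curves; with 1000-frame movies and residence times well under 200 s the
exclusion bias is negligible. Survival curves are pooled across cells within
a biological replicate, fitted per replicate, and summarized across
replicates — mean ± SEM over replicates, never over cells — with a two-tailed
t-test on replicate means for condition comparisons.

## The synthetic-data generator

Every stage is testable against ground truth because the generator draws
from the exact generative model above. Defaults mirror the imaging
conditions the pipeline targets: 5 Hz (0.2 s frame interval), 1000 frames,
200 ms exposure, 0.16 µm pixels, PSF sigma 1.2 px. Dwell times are
discretized to whole frame intervals by flooring, and a molecule must span
at least 2 consecutive frames to be observable. Movies render bound
molecules as immobile 2-D Gaussian spots over Gaussian camera background
(SNR = amplitude / background sd); localization error arises only at the
measurement stage, never in the rendering.

Free (unbound) molecules blur out at 200 ms exposure, so rather than
modeling motion blur explicitly each free molecule produces a detectable
spot with probability `p_detect_free` (default 0.05) per frame, at a
diffusive position anchored to its binding site (variance growing linearly
with frames from binding/unbinding, $D_{free} = 2\ \mu m^2/s$ by default).
The photophysics is single-step bleaching only — no blinking, no 3-D PSF,
no compartment model.

One measured consequence of this model is worth stating: a free-molecule
detection one or two frames before binding (or after unbinding) falls inside
the tracker's search radius often enough to extend roughly 10–15% of tracks
by about two frames. This is correct tracker behavior under the standard
search-radius settings, not a bug; tests of track-duration fidelity
therefore use movies with bound renderings only (`p_detect_free = 0`), which
isolate the linking contract, while free detections remain enabled wherever
detection itself is scored. Real movies carry the same ambiguity, so
measured dwell times inherit a small upward tail from this mechanism.

The labeled-molecule density per nucleus at the dye concentrations used in
this kind of experiment is not standardized; the default of 50 molecules per
movie (well separated at 128–256 px frame sizes) keeps nearest-neighbor
distances an order of magnitude above the PSF width, and the simulator warns
when the mean nearest-neighbor distance drops below $2\sigma_{PSF}$.

## Detection, localization and linking

Detection follows the multiple-target tracing (MTT) recipe. Each pixel is
tested with a generalized likelihood ratio for "Gaussian spot + flat
background" against "background only". With the per-frame background mean
and noise sd estimated robustly (median and MAD — robust because spots
occupy a small minority of pixels), the least-squares spot amplitude at a
pixel is a linear statistic of the image, and under the Gaussian null its
standardized value is standard normal; the detection threshold is the normal
quantile implied by `loc_error` (default $10^{-6.25}$) as a per-pixel
false-alarm probability. On a 128×128 frame that predicts ~0.01 false
positives per frame; the test suite observes at most one across 40 pure-noise
frames. Accepted local maxima are refined by least-squares Gaussian fits
(amplitude, background, sub-pixel center) on a 9×9 window with the PSF width
held fixed at 1.2 px — fixing the width at the diffraction limit is the MTT
convention and stabilizes fits at moderate SNR. Three deflation loops
(subtract fitted spots, re-test the residual) recover overlapping spots;
duplicates within one PSF sigma are merged, keeping the higher test
statistic. Because both the amplitude statistic and the MAD scale linearly
with intensity, detections and sub-pixel positions are exactly invariant to
global gain changes.

Linking minimizes total squared displacement per frame among candidate pairs
within the search radius

$$r = 3\sqrt{4 D_{max}\,\Delta t\,(1 + g)},$$

the 2-D mean-squared-displacement form with a 3× safety factor ($D_{max} =
0.5\ \mu m^2/s$, the standard slow-tracking cap; $g$ = frames the track end
has gone undetected, at most `max_gaps` = 1). Each target keeps its 5
nearest candidate sources (the competitor cap applied per target — the
per-source/per-target choice is not standardized, and per-target keeps the
matching well defined), and the per-frame assignment is solved exactly with
an $O(n^3)$ shortest-augmenting-path algorithm, verified in the tests
against exhaustive enumeration on small instances. Unmatched sources and
targets pair with dummy nodes at a cost above the maximal admissible pair
cost, so any in-radius link is preferred to track death plus birth. Ties are
broken deterministically (lower localization index).

## Chromatin enrichment of mitotic cells

The enrichment score of a cell is
$\log_2(\text{chromatin mean} / \text{whole-cell mean})$ of the TF channel:
0 when the TF is distributed like the cell average, ~1 for strong
chromosome coating, negative for exclusion. The score is invariant to global
multiplicative intensity changes and to any relabeling of pixels that
preserves the masks.

Masks come from automated segmentation standing in for hand-drawn regions: the
whole-cell mask is the largest connected component of an Otsu threshold on
the smoothed, log-transformed sum of channels; the log transform (applied
after normalizing the smoothed image to $[0,1]$, which keeps the mask
exactly gain- and offset-invariant) is what lets a single two-class
threshold separate cell from background when the H2B channel makes chromatin
an order of magnitude brighter than the rest of the cell. The chromatin mask
is an Otsu threshold of the smoothed H2B channel within the cell mask. Both
are hole-filled and speck-cleaned. On synthetic cells with 5–10% noise the
masks overlap truth with Jaccard ≥ 0.9; the residual boundary dilation
biases auto-mask scores by about +0.1 log2 units, which is why score
*accuracy* is validated on ground-truth masks while segmentation quality is
validated separately by overlap. Hand-drawn masks can be supplied through
`read_roi_masks()` and used verbatim.

Background subtraction defaults to none. An image-mode estimate
(`background = "mode"`) is available, but it is not the default because the
score of a uniform channel must be exactly 0 — the identity that anchors the
scale — and mode subtraction is undefined there (it would zero the means).

The synthetic cell is two nested ellipses (chromatin inside cell) with the
TF-channel level outside the chromatin chosen so the whole-cell mean is
exact, making the true score $\log_2$ of the configured ratio by
construction. It does not emulate out-of-focus light, intensity gradients,
neighboring cells, or mitotic-stage morphology; passing tests show the
estimator is correct and noise-stable, not that segmentation handles
arbitrary field-of-view clutter.

## Spike-in normalization of CUT&Tag counts

Each sample's raw scaling is an arbitrary constant (100 000 for a 10%
spike-in; 200 000 for 20%) divided by its count of reads aligned to the
*D. melanogaster* spike-in genome; scalings are then anchored so the
asynchronous reference sample is exactly 1, which cancels the constant.
Per-site read counts are multiplied by their sample's scaling and kept as
real numbers. When replicate pairs exist, each pair is normalized to its own
asynchronous sample — the only composition consistent with anchoring the
asynchronous sample to 1 per pair. The generator draws fly-read counts as
binomial thinning of the total read count at a configured spike-in fraction;
alignment itself (and peak calling, coverage tracks, heatmaps) is out of
scope — those go through the published tools.

## Problem sizes and the acceptance script

`scripts/acceptance.R` regenerates every reported quantity from scratch with
the package's own simulators: apparent-$k_{off}$ recovery at the rate
operating points of the studied constructs uses 5000 dwells per condition
with $k_{bleach} = 0.04\ s^{-1}$ (an H2B-scale bleaching rate at 5 Hz) and a
40% fast component at $1\ s^{-1}$; mixture-parameter recovery uses $10^5$
continuous dwells; the residence-time-ratio regimes use three replicate
pairs of 5000 dwells; detection/tracking is scored on a 128×128, 150-frame
movie with 15 well-separated bound molecules at SNR 12. These sizes were
chosen so each estimate's sampling error sits comfortably inside the
tolerance it is compared at; the same pipeline scales to full-length
(256×256, 1000-frame) movies unchanged.

## Known limitations

* The dwell model has exactly two kinetic components; heterogeneity beyond
  that (power-law tails, more states) collapses into the nearest
  two-exponential description.
* No drift correction, no 3-D localization, no EMCCD gain calibration.
* The tracker carries no motion model mixture; it is built for immobile
  bound molecules with occasional gaps, the slow-tracking regime.
* Enrichment works on single-plane images; z-stacks and mitotic-stage
  classification are out of scope.
* The headline numbers recomputed here are parameter-recovery results on
  simulations anchored at the reported rates, not reanalyses of raw
  microscopy data, which desk-scale reproduction cannot access.
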