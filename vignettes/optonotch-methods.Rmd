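---
title: "Methods: quantifying optogenetic Notch/Delta experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying optogenetic Notch/Delta experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optonotch)
```

This vignette is the package's own account of its methods: the models
implemented, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open. Every empirical
statement here is one the test suite or `scripts/acceptance.R` computes.

## The biological setting

Notch signalling specifies the *Drosophila* mesectoderm: two single-cell
rows flanking the mesoderm express the Notch target *sim* during the
roughly one-hour interphase of nuclear cycle 14. With an MS2-MCP live
reporter, each transcribing nucleus shows one bright diffraction-limited
spot; nuclei switch on stochastically some 30 minutes after cellularization
begins, and once on, a spot's intensity fluctuates around a stable mean —
"digital" activation at the single-nucleus level, graded activation timing
at the tissue level. Optogenetic Delta (a CRY2 fusion) adds the
perturbation arm: blue light clusters the ligand at the plasma membrane
within tens of seconds, blocks signal reception in the illuminated cells,
and biases cell-fate choices at mosaic clone borders in the pupal notum.

The package quantifies all of these readouts. Because the underlying
recordings are not publicly deposited, a synthetic-data module generates
every input modality with known ground truth; the analysis chain is
validated by recovering that truth.

## Spot calling

`detect_spots()` applies, per frame:

1. a 3 × 3 median filter to each z-slice (shot-noise removal);
2. subtraction of a 100 × 100 mean filter (slowly varying background);
3. maximum projection over z;
4. subtraction of the projection's 30 × 30 median filter (residual
   flattening);
5. Gaussian smoothing with σ = 3 px — the size of a diffraction-limited
   spot at 0.13 µm/px, so this acts as a matched filter;
6. segmentation of connected regions bounded by zero crossings of the
   Laplacian of the filtered image;
7. rejection of blobs by area and intensity.

Numerical conventions, stated because they are ambiguous in prose
descriptions of such chains:

* **Even windows** (100 × 100, 30 × 30) are anchored with the extra
  row/column toward larger indices: a window of size *w* covers offsets
  `-(w-1)%/%2 … w%/%2`.
* **Boundary handling** is symmetric reflection (the edge pixel is
  repeated) for every filter and for the Laplacian.
* **Zero-crossing convention:** a pixel belongs to a candidate blob when
  the Laplacian of the filtered image is negative there (bright-blob
  interior); blob boundaries therefore lie on the sign changes.
  Connectivity defaults to 8.
* **Negative intermediate values** produced by background subtraction are
  kept; intensities are only measured on the non-negative-clipped
  projection under the final mask, so weak spots are not biased by early
  clipping.

These primitives are implemented in C++ within the package because the
combination of reflect padding, even-window anchoring, and exact
even-count medians is part of the contract and is verified against
brute-force R oracles in the tests.

### Rejection thresholds

The original workflow curated segmentations by hand; here rejection is
automatic and configurable (`spot_call_config()`):

* `min_area_px`/`max_area_px` (default 10/2000) bound the blob area;
* `min_peak_snr` (default 5) requires the blob's peak on the *filtered*
  image to exceed that many robust noise units (`mad_sd`, a
  Gaussian-consistent MAD). Smooth noise produces spatially large
  negative-Laplacian regions whose integrated intensity can be sizeable,
  but their peaks stay within a few noise units, while the matched filter
  raises even dim spots far above the smoothed noise floor;
* `support_snr` (default 3) additionally requires candidate pixels to
  exceed 3 noise units, which stops weak noise pixels from bridging
  neighbouring negative-Laplacian regions into merged blobs that drag
  centroids off dim spots;
* `edge_margin_px` (default 2σ) discards blobs whose centroid sits at the
  frame border, where reflect padding doubles the noise correlation;
* `min_intensity` (or the `auto_snr` automatic variant) optionally bounds
  the integrated intensity, the classical "size and intensity" rejection.

SNR-based cuts never drop below 2% of the brightest filtered value: the
background mean/median subtractions leave ripples of roughly 1% of a
spot's peak around it, and on noise-free images (robust noise ~0) this
relative floor is what keeps those ripples out while leaving the core
segmentation the pure zero-crossing rule. On noisy frames the noise term
dominates and the floor is inert; the trade-off is that a second spot more
than ~50-fold dimmer than the brightest in the same noise-free frame would
be rejected. The defaults were calibrated on the synthetic SNR-5
regime; at that signal-to-noise the acceptance suite verifies precision
and recall of at least 0.95 against ground truth. The detection benchmark fixes each spot's amplitude at the
stated SNR (keeping the 20% temporal fluctuation); with the biological 75%
between-spot amplitude spread, some nuclei are intrinsically far dimmer
than the nominal SNR and detection of those is a property of the amplitude
draw, not of the detector.

`call_fish_spots()` runs the same chain on fixed material (single time
point) and assigns each spot the nucleus label under its centroid; nuclei
may carry two sister foci, and spots outside any nucleus are flagged.

## Activation kinetics

`build_activation_curve()` counts spots per frame and divides by the
measured tissue length (spots·µm⁻¹); times are shifted so the onset of
ventral furrow formation is *t* = 0. `fit_activation()` fits

$$N(t) = N_\max\,(1 - e^{-k (t - t_0)}), \qquad N(t) = 0 \text{ for } t < t_0,$$

with the plateau $N_\max$ held constant and only the rate $k$ and onset
delay $t_0$ adjusted. The formula is negative before $t_0$; clamping to
zero is the only sensible reading and is applied explicitly. $N_\max$ is a
required input (the nucleus census, from ground truth or the user) because
it is a constant of the tissue, not a free parameter. The onset-delay
statistic for condition comparisons is the fitted $t_0$, which is robust to
noise in the first nonzero frame.

The optimisation is deterministic: a coarse grid (25 log-spaced rates ×
~20 onset times spanning the curve) seeds Nelder-Mead from the three best
grid points, and the winner is polished by Levenberg-Marquardt
(`minpack.lm`), accepted only if it does not worsen the residual sum of
squares. On noiseless model-generated curves the fit recovers $(k, t_0)$
to 1 × 10⁻⁶ relative accuracy (20 random parameter draws in the
acceptance suite); an all-zero curve is flagged non-converged with the
rate reported as missing, never as zero.

`compare_conditions()` summarises per-embryo $(k, t_0)$ by condition
(mean ± s.e.m.) and compares each condition against the control with
Welch two-sample t-tests — the unequal-variance flavour, chosen because
the experimental description specifies only a two-sample t-test.
Single-embryo conditions are reported without a p-value.
`percent_of_control()` expresses densities as a percentage of the control
plateau (mean of the trailing control frames).

`spot_intensity_stability()` separates two coefficients of variation:
`cv_over_time`, the mean over spots of each spot's temporal CV, and
`cv_within_timepoint`, the mean over frames of the across-spot CV within a
frame. The per-spot reading of the temporal CV follows the biology being
described — each transcription site fluctuates around its own stable
mean — and is the definition under which the generator's inputs (20%
temporal, 75% between-spot) are recovered by the estimator; a
frame-mean-based temporal CV would shrink with the number of spots and
recover nothing.

### Rate conversions

Tissue-level activation is often quoted as spots·min⁻¹·µm⁻¹ while the
generator parameterises the per-nucleus rate $k$. Early in activation the
two are related by the linear nucleus density:
`nuclear_rate_from_tissue(rate, density)` = rate/density. The density is a
required user input — it is tissue-specific and not something the package
should guess.

## Membrane clustering

`segment_clusters()` thresholds a frame at the median plus `mad_mult`
(default 3) robust standard deviations of its positive pixels and removes
components below `min_size_px`. Both statistics scale with the image, so
segmentation and index are invariant under intensity scaling — an
important property when laser power varies between acquisitions.

`clustering_index()` implements
(number of clusters × mean cluster intensity) / total image intensity,
which reduces to the fraction of total intensity inside segmented
clusters: 0 with no clusters, 1 when clusters cover everything, and within
[0, 1] always on nonnegative images. `estimate_half_time()` fits
$P(1 - 2^{-t/t_{1/2}})$ by the same deterministic multi-start +
Levenberg-Marquardt scheme; a fitted half-time pinned far outside the
observation window (100× its span) is reported as non-converged rather
than as a number.

The synthetic clustering movie conserves total intensity exactly per frame
(when noise-free) while a fraction $f(t) = f_\max(1 - 2^{-t/t_{1/2}})$ of
it relocates into small cluster sites on the membrane lattice; the default
half-time is 40 s, the frame interval 2 s, and the duration 6 min, the
regime in which such clustering is typically acquired. The acceptance
suite checks that the measured index tracks the ground-truth clustered
fraction within 0.02 absolute and that the half-time is recovered within
10% under 5% noise.

## Membrane, interface, and colocalization measurements

* `project_sum()` provides sum-of-slices projections.
* `measure_interface()` averages intensity across a 7-px line width
  (bilinear interpolation at 1-px steps), finds the dominant peak of the
  σ = 1 px smoothed profile, and integrates the raw profile over a 0.78-µm
  window centred at the peak (trapezoidal rule; the window is clipped to
  the profile support with a flag). Profiles without an interior local
  maximum above the prominence floor are flagged and reported with
  integral 0 rather than dropped. Against the closed-form Gaussian-ridge
  integral $A\,\sigma_r\sqrt{2\pi}\,\mathrm{erf}(0.39/(\sqrt2\,\sigma_r))$
  the measured integral agrees within 0.5% at 0.05 µm/px, with the error
  decreasing under grid refinement.
* `normalize_to_reference()` divides measurements by the per-embryo median
  of a reference region (e.g. interface intensities normalised to the
  ectoderm median).
* `membrane_band_quant()` defines each cell's membrane band as the pixels
  within 0.3 µm (rounded to pixels) of the cell boundary — the cell minus
  its erosion by that radius — and the cytoplasm as the remaining
  interior; it reports both means and their cytoplasm-to-membrane ratio,
  flagging cells too small to retain an interior. The band radius is
  Euclidean, checked per pixel against all labels within the disc.
* `coloc_percent()` detects particles per channel with the single-frame
  spot caller and classifies each channel-A particle by a ≥ 1 pixel mask
  overlap with any channel-B particle, reporting the percentage. On
  noise-free synthetic fields the estimate equals the generator's realized
  overlap bookkeeping exactly, and over repeated fields the Wilson 95%
  interval for the overlap fraction covers the true value at near-nominal
  rates.

Coordinates follow one convention everywhere: 0-based pixel-centre
indices, x along columns, y along rows, physical distances via
`pixel_size_um`.

## Clone-border scoring

`score_border_sops()` operationalises "at the border" as a distance
criterion: SOPs within `border_band_px` of the clone boundary (default:
one proneural-cluster radius — the natural scale, since a
boundary-straddling cluster places its SOP within one radius of the
boundary). Sides are read off the clone mask at the SOP position.
`summarize_tallies()` reports per-pupa mean ± s.d. percentages, a pooled
exact binomial test against the 50% null (chosen because the null is a
per-SOP coin flip, making the pooled count the sufficient statistic), and
a two-sample t-test between conditions. `genotype_ratio_test()` is the
same exact binomial machinery for hatched-genotype counts; the one
quantity recomputable from printed data — 172 vs 169 hatchlings — yields
50% to the nearest integer with p ≈ 0.91.

The acceptance suite calibrates the null (rejection rate within
[0.03, 0.07] at α = 0.05 over 1,000 simulated tissues of 100 border SOPs;
exact binomial tests are conservative at n = 100, so the rate sits below
0.05) and recovers the generator's log-odds bias within 0.2 across
β ∈ {0, 1, 2, 3}.

## What the synthetic data emulate — and what they do not

The generators (`gen_spot_movie`, `gen_cluster_movie`,
`gen_interface_image`, `gen_vesicle_field`, `gen_clone_tissue`) fix the
study conditions:

* nuclei switch on **irreversibly** at $t_0 + \mathrm{Exp}(k)$ (no
  transcriptional bursting) with onset delay 30 min and rate 0.3 min⁻¹ by
  default, so nearly all nuclei are on within ~10 min of the first onsets;
* spot amplitudes are **lognormal** with 75% CV between nuclei and 20% CV
  over time — the magnitudes reported for this system; lognormality itself
  is this package's choice (only CV magnitudes are constrained);
* nuclei are **static**: the analysed interphase has no division or
  large-scale movement;
* membrane geometry is a **square lattice** with Gaussian-cross-section
  ridges (σ 0.15 µm), mesoderm ridge amplitude 0.3× the ectoderm
  (emulating ~70% depletion), and a small flat cytoplasm level;
* vesicle fields place partnered channel-B spots one radius from their A
  vesicle (guaranteed pixel overlap) and unpartnered ones far enough from
  every A vesicle that detected masks cannot touch;
* clone tissues use a straight boundary and resolve each border cluster's
  SOP inside the clone with probability $e^\beta/(1+e^\beta)$.

Seeded runs are bit-identical, and generators restore the caller's RNG
state. Not emulated: photobleaching, blinking, 3-D point-spread functions,
nuclear import dynamics, embryo curvature, cell movement, and irregular
clone shapes. Passing tests therefore demonstrate correctness of the
measurement chain under controlled conditions, not robustness to every
artefact of real microscopy; on real data the rejection thresholds and the
border band are the knobs a user should revisit.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each statistical claim is informative: a
60-nucleus, 40-frame movie for detection performance; 20 simulated embryos
of a whole-mesectoderm census (200 nuclei) for rate recovery — the
per-embryo rate CV is information-bounded at $1/\sqrt{n}$, so the census
is sized to make a 10% recovery tolerance a statement about the estimator
rather than about the draw; 181-frame clustering movies; 200 replicate
vesicle fields for interval coverage; 1,000 tissues for test calibration. The
`run_pipeline()` defaults are smaller still, sized for interactive use.

## Known limitations

* Spot tracking across frames is by nucleus position only (static nuclei);
  no motion model is provided.
* The spot caller's intensity thresholds assume the frame is dominated by
  background, as is true for sparse nuclear spots; dense fields would bias
  the robust noise estimate upward.
* `estimate_half_time()` assumes a monotone rise to plateau; reversible or
  overshooting kinetics need a different model.
* The clone generator's straight boundary makes the distance-to-boundary
  computation exact; convoluted real clone shapes may need a larger border
  band than one cluster radius.
* TIFF output stores 16-bit counts relative to a recorded scale (32-bit
  float optional) with calibration in a JSON sidecar; exotic TIFF metadata
  conventions are not parsed.
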