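# optonotch

Quantitative image analysis for optogenetic Notch/Delta signalling
experiments in R.

During *Drosophila* mesectoderm specification, Notch signalling drives
expression of the target gene *sim* in two single-cell rows flanking the
mesoderm. Live MS2-MCP reporters make nascent *sim* transcription visible as
diffraction-limited nuclear spots, and optogenetic Delta alleles (CRY2
fusions that oligomerize under blue light) let the signal be switched off at
defined times. Turning such experiments into numbers requires a chain of
image quantifications: calling transcription spots in noisy time-lapse
stacks, fitting activation kinetics, measuring light-induced membrane
clustering, quantifying membrane/interface intensities and vesicle
colocalization, and scoring cell-fate choices at mosaic clone borders. This
package implements that chain as tested, reusable R functions for
developmental biologists and image analysts, together with a synthetic-data
generator that emulates every input modality with recorded ground truth —
so the whole pipeline runs and validates itself without any external data.

## The models at the core

**Spot calling.** Each frame is median-filtered (3 × 3), background-corrected
by subtracting a 100 × 100 mean filter, maximum-projected over z, flattened
by subtracting its own 30 × 30 median filter, and Gaussian-filtered with
σ = 3 px (the size of a diffraction-limited spot). Spots are the connected
regions bounded by zero crossings of the Laplacian of the filtered image
(negative-Laplacian interiors), with blobs rejected by area and by peak
height in robust noise units.

**Activation kinetics.** Spot-density curves N(t) are fitted with the
saturating exponential

&nbsp;&nbsp;&nbsp;&nbsp;N(t) = N_max · (1 − exp(−k·(t − t₀))),&nbsp; N(t) = 0 for t < t₀,

where N_max (the number of nuclei that can activate) is held constant and
only the activation rate k and onset delay t₀ are fitted, by deterministic
multi-start least squares. Conditions are compared by Welch two-sample
t-tests on per-embryo estimates.

**Membrane clustering.** Per frame, clusters are segmented by a robust
(median + m·MAD) threshold and summarised by the clustering index
(number of clusters × mean cluster intensity) / total image intensity —
the fraction of signal locked into clusters, in [0, 1]. Its rise is fitted
with P·(1 − 2^(−t/t½)) to estimate the clustering half-time.

**Membrane and colocalization measurements.** Interface intensity profiles
(7-px-wide lines) are integrated over a 0.78-µm window centred at the
profile peak; per-cell membrane bands of 0.3 µm physical thickness separate
membrane from cytoplasm means; two-channel particles colocalize when their
segmented masks share at least one pixel.

**Clone-border statistics.** Sensory organ precursors within a border band
of a clone boundary are classified by side; the per-pupa percentages are
summarised as mean ± s.d., tested against the unbiased 50% null with an
exact binomial test, and compared between conditions with a t-test.

## Worked example

Simulate a transcription movie (two rows of nuclei switching on
irreversibly after a 30-min delay at 0.3 min⁻¹), call spots, and recover
the kinetics:

```r
library(optonotch)

params <- spot_movie_params(n_nuclei_per_row = 15, onset_rate_k = 0.3,
                            onset_delay_t0 = 30, movie_start = 25,
                            movie_end = 50, frame_interval = 0.5,
                            noise_scale = 50, seed = 4)
movie <- gen_spot_movie(params)
movie$stack
#> <calibrated_stack> 51 frame(s) x 1 slice(s) x 167 x 667 px [MCP-GFP]
#>   pixel 0.13 um, z-step 1 um, frame interval 0.5 min

spots <- detect_spots(movie$stack)
curve <- build_activation_curve(spots, movie$truth$region_length_um,
                                movie$truth$times)
fit <- fit_activation(curve,
                      nrow(movie$truth$nuclei) / movie$truth$region_length_um)
fit
#> <exp_fit> k = 0.3438 /min, t0 = 29.97 min (n_max = 0.4286, rss = 0.00918, n = 51)
```

The fitted activation rate (0.34 min⁻¹) and onset delay (29.97 min) recover
the generator's truth (0.3 min⁻¹, 30 min) from a single noisy embryo;
`autoplot(fit)` overlays the fitted curve on the data. The one
statistic recomputable from printed counts — the 50:50 genotype ratio among
341 hatched adults — comes out as:

```r
genotype_ratio_test(172, 169)
#> # A tibble: 1 × 5
#>   count_a count_b     n percent_a p_value
#>     <dbl>   <dbl> <dbl>     <dbl>   <dbl>
#> 1     172     169   341      50.4   0.914
```

i.e. 50% to the nearest integer, with no evidence against the Mendelian
ratio. `run_pipeline(pipeline_config(seed = 1))` executes every stage on
synthetic inputs and writes CSV tables, a JSON summary, and plots.

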