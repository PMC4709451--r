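# synstorm

Two-color single-molecule localization microscopy (dSTORM) analysis of the
nanoscale separation of synaptic protein populations, with a synthetic
ground-truth generator that makes the whole chain testable without raw
microscopy data.

## The problem

Pre- and postsynaptic proteins are layered a few tens to hundreds of
nanometers apart along the transsynaptic axis (the normal of the synaptic
cleft). dSTORM resolves this: a long two-color camera movie of blinking
fluorophores is turned into per-molecule localizations, and the separation
of two protein populations is the distance between the centers of mass
(COMs) of their localization distributions, measured through a 300 nm wide
line ROI across each synapse.

Because a 3D synapse is imaged in 2D, a randomly oriented separation `d`
appears as `d·sin θ` with `u = cos θ ~ U(0,1)`. The package's headline
statistic corrects this projection bias by keeping only the fraction
`q = 0.40` of synapses with the largest distances (those oriented edge-on)
and reporting their mean ± SEM. Under the uniform orientation prior the
expected estimator-to-truth ratio has the closed form

```
projection_factor(q) = (q·sqrt(1−q²) + asin(q)) / (2q)
```

which is 0.9727 at q = 0.40 (and π/4 at q = 1): the default cutoff recovers
97% of the true separation.

## What is implemented

| Stage | Functions |
|---|---|
| Synthetic synapses, labels, tables, movies | `synapse_config`, `make_synapse_population`, `sample_labels`, `emit_localization_table`, `render_movie` |
| Movie → localizations | `temporal_median_background` (101-frame running median), `detect_spots`, `localize_com`, `filter_localizations`, `localize_stack`, `localize_beads` |
| Two-channel registration | `fit_channel_transform` (affine / 2nd-order polynomial), `match_beads`, `apply_transform` |
| Drift correction | `estimate_drift_rcc` (redundant cross-correlation), `correct_drift` |
| Reconstruction | `render_sr_image` (10 nm raster, intensity weighted), `sr_gaussian_blur` (display only) |
| Distance statistics | `extract_line_profiles`, `com_1d`, `com_distance_1d`, `com_2d_distance`, `top_fraction_mean`, `cutoff_sweep`, `projection_factor` |
| Driver / I/O | `run_pipeline`, `pipeline_config`, `read_localizations`, `write_localizations`, JSON model/ROI serialization, `inst/cli/synapse-smlm` |

## Worked example

Simulate 40 synapses with a true 3D separation of 107 nm, uniformly random
orientations, localization noise, and run the full fast-path analysis:

```r
library(synstorm)
cfg <- pipeline_config(seed = 42, n_synapses = 40, separation_nm = 107,
                       field_size_nm = 40000)
res <- run_pipeline(cfg)
res$estimate
#> top-40% mean COM distance: 108.9 +/- 1.7 nm (SEM; n = 16 of 40)
res$sweep
#>     q mean_distance_nm   sem_nm n_used
#> 1 0.2        112.88089 2.695347      8
#> 2 0.4        108.86914 1.717207     16
#> 3 0.6        104.65080 1.722774     24
#> 4 0.8         99.91825 1.992508     32
#> 5 1.0         89.66341 3.820111     40
```

The top-40% estimate (108.9 nm) sits near the analytic expectation
`0.9727 × 107 ≈ 104` nm (selection on noisy distances adds a small upward
bias), while the uncorrected mean over all synapses (89.7 nm at `q = 1`)
is pulled down toward `107 × π/4 ≈ 84` nm by projection — the bias the
top-fraction estimator exists to remove. The mean decreases monotonically
in `q`, so orderings between protein pairs are robust to the cutoff.

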