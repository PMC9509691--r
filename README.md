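# oph — ratiometric optical pH sensing of dental biofilm

Dental caries begins with acid: after a sugar challenge, the microbial
biofilm on a tooth surface acidifies (the Stephan response), and the depth
of that pH drop tracks caries activity. `oph` is an R toolkit for a
non-contact optical way of measuring that acidity. Sodium fluorescein
applied to the biofilm partitions between two fluorescent protonation
states — the anion (emission peak near 550 nm) and the dianion (near
520 nm) — whose balance follows pH. A blue LED pulsed at a modulation
frequency `f_mod` excites the dye; four filtered photodiode channels record
the emission; the amplitude at `f_mod`, recovered by FFT, rejects ambient
light. The normalised channel contrast

```
ratio = (Ch1 - Ch2) / (Ch1 + Ch2)
pH    = slope * ratio + intercept        (defaults: 10.34, 3.42)
```

is insensitive to dye amount and probe distance and maps linearly to pH on
the 4–7.5 range typical of dental biofilm. The package is for instrument
developers and analysts who need the full computational chain without the
hardware: a forward simulator of the acquisition, the demodulation and
calibration algorithms, the clinical comparison statistics, and a
per-pixel pH-imaging extension.

## What's inside

| Layer | Functions |
|---|---|
| Forward model | `fluorescein_model()`, `instrument_config()`, `species_fractions()`, `emission_spectrum()`, `channel_signals()`, `simulate_acquisition()` |
| Demodulation | `lockin_amplitude()`, `lockin_square_gain()`, `demodulate()` |
| Calibration & QC | `calibration()`, `compute_ratio()`, `predict_ph()`, `fit_calibration()`, `qc_evaluate()`, `aggregate_replicates()`, `pooled_sd()` |
| Clinical analysis | `synth_cohort()`, `analyze_cohort()`, `welch_t_test()`, `permutation_test()`, `diff_ph()`, `normalize_by_saliva()` |
| Imaging | `synth_frames()`, `average_frames()`, `ph_map()`, `diff_map()`, `imaging_calibration()` |
| I/O & CLI | CSV recordings/cohorts, JSON calibrations, TIFF frame stacks, `oph_main()` and the `inst/cli/oph` script |

## Worked example

Simulate a measurement of a pH 6.2 biofilm spot, demodulate it, fit a
calibration from noiseless simulated buffers, and quality-gate the reading:

```r
library(oph)

acq  <- simulate_acquisition(6.2, seed = 42)
amps <- demodulate(acq)
round(unlist(amps), 4)
#>   f520   f550  af475   p632
#> 6.5791 1.9633 0.7159 0.2216

quiet <- instrument_config(noise_sd_v = 0, ambient_dc_v = 0, ambient_flicker = 0)
ratios <- sapply(c(4.5, 5.5, 6.5, 7.5), function(p) {
  a <- demodulate(simulate_acquisition(p, config = quiet))
  compute_ratio(a$f520, a$f550)
})
cal <- fit_calibration(ratios, c(4.5, 5.5, 6.5, 7.5))
cal
#> oph calibration: pH = 3.48 * ratio + 4.517
#>   accepted range [4.00, 7.50], AF threshold 4.55, min signal 0.909, r = 0.9829

qc_evaluate(amps, cal)
#> oph reading: pH 6.397 (ratio 0.5403), accepted
```

The four amplitudes are the lock-in estimates for the dianion (520 nm),
anion (550 nm), autofluorescence (475 nm) and porphyrin (632 nm) bands, in
channel-signal units. The autofluorescence amplitude sits below the
threshold and the predicted pH 6.40 lands within 0.2 pH of the simulated
truth — consistent with the mid-range accuracy of the linear calibration.

A synthetic clinical cohort (two cleaning groups, rest/drop pH in
triplicate) and the group comparison on diff pH (rest − drop):

```r
coh <- synth_cohort(seed = 1)
res <- analyze_cohort(coh, n_perm = 10000, seed = 1,
                      metrics = "diff", normalized = FALSE, comparisons = "group")
res[, c("metric", "group_a", "group_b", "n_a", "n_b",
        "mean_a", "mean_b", "welch_p", "perm_p", "significant")]
#>   metric group_a group_b n_a n_b mean_a mean_b  welch_p perm_p significant
#> 1   diff    post     pre  45  40  0.439  0.852 6.54e-07  1e-04        TRUE

rest <- coh$readings[coh$readings$phase == "rest", ]
round(pooled_sd(split(rest$ph, rest$surface_id)), 3)
#> [1] 0.234
```

The Pre-Cleaning group (heavier biofilm) shows the larger sugar-induced pH
drop, and the pooled SD of the replicate triplets reproduces the generator's
0.23 pH repeatability.

From a shell, the same chain is available as
`Rscript inst/cli/oph simulate --ph 6.5 --seed 1`, then
`... calibrate --out cal.json`, `... measure --input recording --cal cal.json`;
`synth`, `analyze` and `heatmap` cover the cohort and imaging paths.

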