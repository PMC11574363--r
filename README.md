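# sandgait

Human walking biomechanics on deformable sand substrates, as a tested,
reusable R pipeline.

When people walk on sand, the foot sinks and the substrate absorbs energy;
gait adapts in ways that depend on how deep the foot sinks. `sandgait`
quantifies those adaptations from synchronized motion capture (200 Hz
markers, lab frame, z = 0 at the hard floor) and surface EMG (1110 Hz):

* **Gait events** from marker coordinates: heel-strike = local maximum of
  the heel's position relative to the sacrum along the direction of
  progression, toe-off = local minimum of the hallux's relative position.
* **Spatiotemporal parameters** per stride: speed, stride length and width,
  cycle/stance/swing/double-support times, duty factor.
* **Foot sinkage**: substrate surface height minus the lowest calcaneus /
  hallux marker z per stride (cm), negative values flagged rather than
  clipped.
* **CoM pendular energetics** from a 13-segment anthropometric model:
  E_pot = m g z, E_kin = ½ m |v|², and per stride the recovery
  `R = 100 (W_v + W_f − W_ext) / (W_v + W_f)` (positive-increment work
  sums), relative amplitude `RA` (peak-to-peak E_pot / E_kin) and congruity
  `CO` (% of samples where both energies move in the same direction).
* **Joint kinematics**: sagittal hip/knee/ankle curves on the 101-node gait
  cycle; per-trial ROMs.
* **EMG**: 12 Hz second-order Butterworth high-pass (zero phase),
  rectification, normalisation to each participant's maximum (nEMG),
  trapezoidal per-stride integration (iEMG).
* **Statistics**: 1D statistical parametric mapping (paired t-fields,
  random-field-theory thresholds with a sign-flip permutation oracle,
  Bonferroni across substrate pairs), one-way ANOVA + Tukey HSD, Spearman
  correlograms ordered by the first principal component, and linear mixed
  models (REML, participant random intercepts, via lme4/lmerTest).
* **A synthetic study generator** (`simulate_study()`) with complete ground
  truth — scheduled events, drawn sinkage depths, prescribed
  potential/kinetic phase relation, joint-angle templates, EMG burst
  envelopes — so every stage has a parameter-recovery test.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects have
`tidy()` / `glance()` methods and `plot_*()` / `autoplot()` ggplot2
graphics. See the methods vignette (`vignettes/sandgait-methods.Rmd`) for
the models, conventions and design decisions.

## Worked example

Simulate a small study (4 participants, 2 trials per substrate), run the
kinematic pipeline, and compare substrates:

```r
library(sandgait)
library(dplyr)

cfg   <- gait_sim_config(n_participants = 4, trials_per_substrate = 2,
                         seed = 42)
study <- simulate_study(cfg, emg = FALSE)
proc  <- process_study(study$trials, emg = FALSE)

proc$stride_table |>
  group_by(substrate_id) |>
  summarise(n_strides = n(), speed = mean(speed),
            cycle_time = mean(cycle_time),
            heel_sink_cm = mean(heel_sink_depth, na.rm = TRUE))
#> # A tibble: 4 × 5
#>   substrate_id      n_strides speed cycle_time heel_sink_cm
#>   <chr>                 <int> <dbl>      <dbl>        <dbl>
#> 1 dry_building_sand        72  1.26       1.08        2.90
#> 2 hard_floor               72  1.53       1.02        0.263
#> 3 play_sand                72  1.25       1.13        4.22
#> 4 wet_building_sand        72  1.38       1.06        2.58
```

Per-stride speeds and cycle times track the configured substrate
conditions (slower, longer cycles on deeper sand); heel sinkage recovers
the configured depth means (2.68 and 4.09 cm for dry building and play
sand), and the 0.26 cm "depth" on the hard floor is the 1 mm marker-noise
floor — flagged by the pipeline, and exactly zero in the noise-free
ground truth.

```r
proc$exchange |>
  group_by(substrate_id) |>
  summarise(R = mean(r_pct), RA = mean(ra), CO = mean(co_pct))
#> # A tibble: 4 × 4
#>   substrate_id          R    RA    CO
#>   <chr>             <dbl> <dbl> <dbl>
#> 1 dry_building_sand  58.0  2.42  5.53
#> 2 hard_floor         65.9  2.00  5.46
#> 3 play_sand          57.7  2.43  5.53
#> 4 wet_building_sand  61.7  2.20  5.56
```

Pendular recovery sits near 60% — the magnitude observed in human walking —
because the generator's default kinetic-energy amplitude and phase (170°
against potential energy) were chosen to land in that regime.

```r
sands <- filter(proc$stride_table, substrate_id != "hard_floor")
res <- anova_tukey(sands, "heel_sink_depth", "substrate_id")
glance(res)
#> # A tibble: 1 × 4
#>       f df_between df_within  p_value
#>   <dbl>      <dbl>     <dbl>    <dbl>
#> 1  66.4          2       213 3.84e-23
tidy(res)
#> # A tibble: 3 × 5
#>   pair                                  diff    lwr     upr    p_adj
#>   <chr>                                <dbl>  <dbl>   <dbl>    <dbl>
#> 1 play_sand-dry_building_sand          1.31   0.959  1.67   4.23e-14
#> 2 wet_building_sand-dry_building_sand -0.321 -0.675  0.0340 8.55e- 2
#> 3 wet_building_sand-play_sand         -1.63  -1.99  -1.28   3.18e-14
```

The three sand substrates separate strongly overall; at this toy sample
size the closest pair (wet vs dry building sand, 0.6 cm apart) is not yet
significant — at the full study scale (21 participants, hundreds of strides
per substrate) all pairs separate at p < 0.001, which is what the
acceptance checks assert.

`run_stats(proc)` runs the whole battery (mixed models per variable, SPM
per joint per substrate pair, sinkage ANOVA, correlograms of trial means),
and `run_process(config)` orchestrates simulate → process with CSV outputs
and a JSON manifest. A thin CLI wrapper lives in `inst/cli/sandgait.R`.

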