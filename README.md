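# sckinetics

Kinetic analysis of synaptonemal complex (SC) assembly and disassembly
in live-cell 3D time-lapse fluorescence microscopy of budding-yeast
meiosis.

During meiotic prophase the SC — the zipper-like protein structure that
joins paired homologous chromosomes — elongates along each chromosome
and is later actively removed. With a Zip1-GFP reporter and a zip3
deletion that reduces synapsis to one or a few chromosomes per nucleus,
the growth and shortening of individual SCs become measurable in vivo.
This package provides the complete analysis chain for such experiments,
plus a synthetic-data generator so that every stage is testable without
microscope data:

* **Simulation** — piecewise-linear SC growth/shrink programs
  (`kinetic_model()`, cohort generators at the published population
  parameters), nuclear Zip1 expression profiles with genotype presets
  (`zip1_preset()`), 3D nucleus scenes and rendered multi-page image
  stacks with PSF and camera noise (`build_scene()`,
  `render_timelapse()`), and telomere-led motion tracks.
* **Imaging** — nucleus segmentation, SC voxel detection, geodesic
  ridge tracing with sub-voxel refinement and half-maximum endpoint
  location, identity linking over time (`measure_timecourse()`).
* **Kinetics** — the core model: continuous segmented regression.
* **Events** — classification of assembly, final disassembly and
  abortive disassembly in nuclear Zip1 context (`classify_event()`),
  profile alignment at Zip1 depletion, onset thresholds, accumulation
  rates and size-class histograms.
* **Statistics** — Poisson multiple-initiation model, binomial miss
  probability, two-proportion z test, Welch t, velocity clustering.

## The model at the core

SC length over time is fitted by a continuous piecewise-linear model
with k = 1–3 segments,

    l(t) = b0 + b1*t + sum_j c_j * (t - bp_j)+          (continuity built in)

with breakpoints located by exhaustive search over midpoints between
consecutive observations (>= 3 points per segment). Candidates are
scored by adjusted R² with p = 2k parameters and by the leave-one-out
PRESS statistic with a full breakpoint re-search per fold; the model
with the highest adjusted R² and lowest PRESS wins (lowest PRESS on
disagreement). A multi-segment winner is called biphasic only if its
rates differ at least 2-fold — the minimum slowdown predicted by
bidirectional growth losing one tip.

## Worked example

Simulate one biphasic assembly event (first phase 88 nm/min for
13.5 min, then 19 nm/min; 3-min sampling, 0.05 µm measurement noise)
and fit it:

```r
library(sckinetics)

traj <- simulate_trajectory(
  kinetic_model("chr4", phases = list(c(88, 13.5), c(19, 30))),
  sampling_interval = 3, noise_sd = 0.05, seed = 1)
fit <- fit_sc_kinetics(traj)
summary(fit)
#> Model selection (adjusted R2 + PRESS):
#>  n_segments     sse adj_r2   press press_fallbacks
#>           1 0.59532 0.8246 0.85827               0
#>           2 0.03367 0.9881 0.06911               0
#>           3 0.02866 0.9873 0.09913               0
#> Selected: 2-segment, biphasic
```

The one-segment line is a poor description (adj R² 0.82); adding a
breakpoint lifts adj R² to 0.988 and cuts the out-of-sample PRESS by
12-fold, while a third segment only adds parameters — so the trajectory
is classified biphasic, with `coef(fit)` giving both rates in nm/min
and the breakpoint in minutes. `plot(fit)` overlays the broken-line fit
on the data.

The closed-form statistics reproduce the published arithmetic:

```r
100 * multi_initiation_frequency(5 / 16)   # 3.98  -> "~4%" of chromosomes
miss_probability(0.04, 230)                # 8.36e-05 -> "0.01 percent"
two_proportion_z(90, 100, 70, 100)$z       # 3.54 (pooled two-proportion z)
```

A full synthetic experiment — cohorts simulated at the published
parameter values, fitted, selected and classified — runs with
`run_pipeline(pipeline_config(seed = 1))` and returns a summary table
plus per-trajectory fit tables.

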