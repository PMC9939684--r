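---
title: "Measuring synaptonemal complex assembly and disassembly kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring synaptonemal complex assembly and disassembly kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sckinetics)
```

## The biological problem

During meiotic prophase the synaptonemal complex (SC) — a zipper-like
protein structure — assembles along paired homologous chromosomes and is
later actively disassembled.  In budding yeast the transverse-filament
protein Zip1, imaged as a GFP fusion, reports both the diffuse
nucleoplasmic pool and the bright curvilinear SC stretches inside a
nucleus of roughly 2 µm diameter.  In a zip3 deletion background only a
few chromosomes synapse, each from a single (mostly centromeric)
initiation site, which makes the elongation and shortening of *single*
SCs measurable in live 3D time-lapse stacks.

This package implements the full quantitative chain for such data:

1. simulation of ground-truth kinetic programs, Zip1 expression
   profiles, nucleus scenes and rendered image stacks;
2. detection, tracing and length measurement of SC filaments in 3D;
3. segmented (continuous piecewise-linear) regression of
   length-versus-time trajectories with model selection by adjusted
   R² and the leave-one-out PRESS statistic;
4. classification of assembly, final-disassembly and
   abortive-disassembly events in the context of nuclear Zip1 levels;
5. the closed-form statistics of the analysis (Poisson
   multiple-initiation model, binomial miss probability, two-proportion
   z test, Welch t test, two-means velocity clustering).

## The kinetic model and its fitting

SC length over time is modelled as a continuous piecewise-linear
function with one to three segments.  For a k-segment model with
breakpoints $b_1 < \dots < b_{k-1}$ the fitted curve is

$$\ell(t) = \beta_0 + \beta_1 t + \sum_{j=1}^{k-1} \gamma_j\,(t-b_j)_+,$$

so continuity at the breakpoints is built into the basis and the
per-segment rates are the cumulative sums $\beta_1,\ \beta_1+\gamma_1,
\dots$  Fits are computed in µm/min and reported in nm/min.

**Breakpoint search.**  Candidate breakpoints are the midpoints between
consecutive observation times, with at least three observations on each
side; every admissible combination (for up to two breakpoints) is
scored by ordinary least squares and the global SSE minimiser is kept,
ties resolving toward the earliest breakpoints.  At the trajectory
sizes this data produces (≈10–60 points) the exhaustive search is exact
and cheap; internally each candidate's SSE is evaluated in constant
time from suffix-sum normal equations with a Schur-complement update,
and the winning candidate is refitted by QR for clean coefficients.

**Model selection.**  Each candidate segment count is scored by

* adjusted R² with parameter count $p = 2k$ (k slopes, one intercept,
  k−1 breakpoints all counted as estimated parameters), and
* the PRESS statistic: every point is held out in turn and the model —
  including the breakpoint search — is refitted on the remainder to
  predict it.  Re-searching breakpoints per fold is slower than
  fixing them from the full fit but is an honest estimate of
  prediction error; folds that fall below the per-segment minimum
  drop to the largest feasible segment count and are counted.

The winner is the candidate with the highest adjusted R² *and* the
lowest PRESS; when the two disagree, the lowest-PRESS model wins (a
prediction-oriented tie-break recorded in the fit object).  A
numerically perfect fit (SSE at machine zero) short-circuits to the
smallest segment count achieving it, since leave-one-out noise cannot
rank exact interpolants meaningfully.

**Monophasic versus biphasic.**  A multi-segment winner is still
kinetically monophasic if its rates are too similar to represent a real
phase change.  The package requires at least a 2-fold rate change
(`slope_tolerance = 0.5`) before calling a trajectory biphasic.  The
threshold is mechanistically motivated: the candidate explanation for
biphasic growth — bidirectional elongation from a single off-centre
initiation site in which one tip reaches its chromosome end — predicts
the total rate to halve, so any mechanism under consideration implies a
rate change of at least 2-fold, while Monte-Carlo calibration shows
that noise-driven splits of single-rate growth typically differ by only
25–35%.  With this rule, trajectories simulated monophasic (56 nm/min,
15 points, 0.1 µm noise) are classified monophasic in over 90% of
replicates.  For a 3-segment winner the initial and second rates are
the first- and last-segment slopes (the middle segment is the
fast-to-slow transition) and the phase boundary is the breakpoint with
the largest slope drop.

**Disassembly.**  Shortening trajectories sometimes begin with a slow
lead-in (a few nm/min) before rapid removal.  Following the convention
of not treating that lead-in as a kinetic phase, a leading segment
slower than 10 nm/min in magnitude is reported as lag, and the
disassembly rate is the duration-weighted mean slope of the remaining
segments — unbiased when noise splits a constant-rate decline, where
taking the steepest segment would systematically overstate the rate.

```{r fit-example}
traj <- simulate_trajectory(
  kinetic_model("example", phases = list(c(88, 13.5), c(19, 30))),
  sampling_interval = 3, noise_sd = 0.05, seed = 1)
fit <- fit_sc_kinetics(traj)
summary(fit)
```

## What the synthetic-data generator emulates

The generator reproduces the statistical structure the analysis
assumes, with defaults at the study's reported values:

* **Assembly cohorts** mix monophasic events (rates N(56, 23²) nm/min,
  truncated positive) and biphasic events (first phase N(88, 42²),
  second phase N(19, 12²), phase-1 length fraction N(0.59, 0.16²)) in a
  65/35 ratio; final SC lengths are uniform on 1.5–3 µm, reflecting the
  focus on nuclei where a single long chromosome synapses (the longest
  SCs observed are ≈3 µm, chromosome IV); sampling every 3 min with
  0.05 µm measurement noise, truncated at zero length.  Trajectories
  are capped at 50 samples: a second phase slower than a few nm/min
  would otherwise be followed for many hours, which no live-imaging
  experiment does.
* **Final-disassembly cohorts** shrink to zero at N(−66, 30²) nm/min.
  The acquisition interval is chosen per event from the experimentally
  used 3–10 min range — the widest of 10, 5 or 3 min that still yields
  at least five samples — so fast events are sampled faster instead of
  being silently dropped (strict 10-min sampling would censor roughly a
  third of the draws and bias the recovered mean toward slow rates).
* **Abortive-disassembly cohorts** shrink at ≈25 nm/min while the
  simulated nuclear Zip1 profile stays at plateau; after complete
  disassembly the tracker reports exactly zero length (there is nothing
  to detect), with two trailing zero frames as the linker would emit.
* **Zip1 expression profiles** rise linearly, plateau, and decline
  linearly to a depletion floor (the averaged published profiles show
  no finer structure to emulate).  Presets: wild type plateaus at
  740 IU for 1.5 h and declines within 1 h with synapsis onset at
  380 IU; the zip3-deletion preset plateaus at 424 IU (57% of wild
  type) for 6.3 h and declines over 3 h with onset at 310 IU.  The rise
  rates (42 and 15 IU/h) are set so the onset-to-depletion span matches
  the observed total synapsis durations of ≈11 h and ≈17 h.
* **Nucleus scenes** lay each SC down as a random chain of bounded
  curvature (minimum turning radius 0.3 µm) inside the 1 µm-radius
  nucleus, growing from its nucleation point in both directions
  according to an arm-fraction parameter; polyline arc length tracks
  the kinetic program exactly.  An SC longer than π·radius cannot fit
  and is rejected.
* **Rendering** deposits the line integral of filament brightness plus
  the diffuse pool onto a (0.2, 0.1, 0.1) µm voxel grid, convolves with
  an anisotropic Gaussian PSF (σ = 0.25 µm axial, 0.12 µm lateral), and
  applies Poisson shot noise plus Gaussian read noise — the standard
  camera model.  The xy pixel size is a typical 100×/1.45 NA value
  (only the 0.2 µm z-spacing is an experimental given).  Filament
  brightness is
  calibrated so the rendered peak is 5× the diffuse level; the true
  contrast ratio is not reported and is exposed as a parameter.
* **Motion tracks** draw per-frame speeds from a two-component mixture
  (defaults 0.3 and 0.8 µm/s, equal weight) and move the tracked SC end
  by billiard (specular) reflection inside the nucleus.  At 5-s frames
  the drawn path (up to 4 µm) exceeds the nuclear diameter, so net
  frame-to-frame displacement cannot equal speed × interval for fast
  steps; the track therefore stores each step's curvilinear path
  length, and `track_speeds()` uses it (net displacement is used for
  externally supplied tracks without path bookkeeping).

What the generator does **not** emulate: polycomplex aggregates,
photobleaching decay, uneven illumination, multi-nucleus fields,
chromosome-scale motion during the 3–10 min kinetic acquisitions beyond
optional small rigid re-placements, or optically overlapping SCs in
crowded nuclei.  Passing recovery tests on these synthetics therefore
demonstrates correctness of the measurement and fitting chain under the
stated noise model, not robustness to every artefact of real
microscopy.

## Image measurement

Nuclei are segmented from a 1-voxel Gaussian-smoothed volume by a
two-pass threshold: Otsu's method gives a first cut, then the boundary
is redrawn halfway between the outside background mode and the inside
diffuse median so that a bright SC cannot drag the boundary inward.
Total nuclear fluorescence is the background-subtracted sum over the
whole volume, which is conserved under the PSF; the mask is used for
volume only.  SC voxels are those above the diffuse level plus
`k_sigma` (default 3) diffuse standard deviations, estimated from the
histogram mode of the nucleus interior and the spread *below* it (the
bright minority cannot contaminate the lower half of the diffuse peak);
components under 3 voxels are sub-resolution foci, counted but excluded
from rate fitting.

Tracing works per connected component: the component is first trimmed
to its half-maximum core (the PSF smears a filament farthest along z,
and for short SCs that smear can exceed the true length, misdirecting
the search); the filament tips are the farthest-apart voxel pair under
physical, anisotropy-aware geodesic distance; the path between them
minimises distance divided by squared intensity so it follows the
bright centreline ridge instead of cutting bend interiors; the path is
refined by iterated local intensity centroids, smoothed by a 3-point
moving average, and finally cropped or extended to the half-maximum
crossings of the intensity profile along it — for a filament convolved
with a symmetric PSF the half-maximum sits at the true end.  On
noiseless phantoms (straight 0.5–3 µm, semicircle of radius 1 µm)
measured lengths are within a few percent of the analytic values.

Two resolution limits are inherent rather than algorithmic: objects
shorter than about half a micron are inflated toward the PSF width, and
bends at the PSF scale (the generator's 0.3 µm minimum turning radius
against a 0.25 µm axial σ) are genuinely shortcut by the imaged ridge.
Full time-course recovery tests therefore assert 15% RMS over
resolvable (≥0.5 µm) lengths, while gently curved phantoms trace to
within 1–4%.

Identities are propagated between frames by greedy minimum-cost
matching (centroid distance plus twice the absolute length change, in
µm); an SC is declared disappeared only after two consecutive unmatched
frames, tolerating single-frame detection dropouts.

## Event classification

Trajectories are interpreted in the context of the nucleus's total
Zip1 fluorescence.  Depletion time is where the profile first falls to
10% of its per-cell maximum (linearly interpolated); profiles are
aligned at depletion before averaging.  An SC that vanishes (length at
or below one xy pixel for two consecutive frames) while nuclear FI is
still at or above 75% of its running maximum is an *abortive*
disassembly; vanishing alongside FI decline below that fraction is
*final* disassembly; everything else is assembly.  The 10% and 75%
cutoffs are this package's operational definitions of depletion and of
persistently high Zip1 — the underlying biological observations are
qualitative — and both are exposed as parameters.  Size classes are half-open
intervals [0, 0.5), [0.5, 1.5) and [1.5, ∞) µm on the maximum attained
length, and the SC accumulation rate is the maximum simultaneous count
divided by the time from first SC to first attainment of that maximum
plus one acquisition interval (so single-step attainment is defined).

## Closed-form statistics

With five SCs per nucleus on average spread over 16 chromosomes, the
per-chromosome initiation count is modelled as Poisson with
λ = 5/16 — the reading under which the probability of two or more
initiations on one chromosome,
$f(\ge 2) = 1 - e^{-\lambda} - \lambda e^{-\lambda}$, is ≈4%.  The
chance of missing every such event in n = 230 independently observed
assemblies is $(1-p)^n$; with the rounded p = 0.04 this is ≈0.01%, and
the unrounded p = 0.0398 gives a slightly larger (still negligible)
value — both are reported.  Group comparisons use the pooled-variance
two-proportion z test (two-sided; sidedness is a package choice) and
Welch's unequal-variance t test via `stats::t.test()`.  Velocity
distributions are summarised by a deterministic one-dimensional
two-means clustering initialised by a median split — a fixed
initialisation keeps the summary reproducible where a randomly
initialised k-means would not be.

## Reproduction problem sizes

The cohort sizes used by the tests and the acceptance script are the
study's own: 34 assembly events per replicate (65/35
monophasic/biphasic) averaged over 20 replicate cohorts, 100 biphasic
trajectories for the phase-1 fraction, 50 final-disassembly events per
replicate over 10 replicates, and the 15 characterised medium/large
abortive events.  Phantom validation renders single nuclei at
(0.2, 0.1, 0.1) µm voxels, ≈19×38×38 grids.

## Known limitations

* Accuracy is only guaranteed for nuclei with one to a few
  well-separated SCs — the same regime the single-SC analysis is
  restricted to; overlapping filaments in crowded nuclei are not
  disambiguated.
* No gap detection inside shortening SCs (none were observed to look
  for), no polycomplex or photobleaching modelling.
* The λ = 5/16 initiation model is unconditional on synapsis
  competence; a conditional variant is a one-line change of λ.
* Lengths below ≈0.5 µm sit at the diffraction floor and are reported
  as measured, inflated toward the PSF width.
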