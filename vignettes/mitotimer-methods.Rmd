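---
title: "Modelling and measuring mitochondrial protein age with a fluorescent timer"
author: "mitotimeR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring mitochondrial protein age with a fluorescent timer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotimeR)
```

## The measurement problem

A matrix-targeted fluorescent timer (DsRed-E5 "Timer" fused to a
mitochondrial targeting sequence) is synthesized green and shifts
irreversibly to red fluorescence over roughly a day. Because new protein
enters mitochondria green and old protein is red, the red/green intensity
ratio of a mitochondrion is a proxy for the relative age of its matrix
protein. Three cell-biological processes shape the spatial pattern of this
ratio: turnover (import of new protein and autophagic degradation of old),
fusion/fission (content mixing between organelles), and transport (which
organelles get access to freshly imported protein).

`mitotimeR` implements this measurement chain end to end: a whole-cell
kinetic model of the probe, an agent-based simulator of an organelle
population, a synthetic two-channel confocal renderer with ground truth,
the ratiometric segmentation/measurement pipeline, and the derived
statistics (heterogeneity, age-versus-distance gradients, compartment
kinetics). Because no public dataset accompanies the original experiments,
the simulator and renderer double as the package's source of test data:
every claim the statistics make is validated against simulated ground
truth.

## The two-pool kinetic model

At whole-cell resolution the green pool $G$ and red pool $R$ (arbitrary
intensity units) obey

$$\frac{dG}{dt} = s\,\mathbf{1}[\text{import on}](t) - (k_{mat} + k_{deg})\,G,
\qquad
\frac{dR}{dt} = k_{mat}\,G - k_{deg}\,R .$$

* `k_mat` — first-order green-to-red maturation (per hour). The probe's
  color shift is reported only qualitatively ("within 24 h"), so the
  default is `log(2)/24`, i.e. a 24 h half-transition. Maturation is
  modelled as a single irreversible step; the true chromophore chemistry
  has intermediates that the ratio readout cannot resolve.
* `k_deg` — turnover acting equally on both colors (autophagy removes
  whole organelle content, not colors selectively).
* `s` — synthesis/import in intensity units per hour, gated by an on/off
  schedule (`import_windows`) that expresses doxycycline-style induction
  (continuous, pulse) and import blocks (depolarization). An optional
  `lag` shifts the schedule to model the delay between transcription and
  visible signal; the default is 0 because the delay is not identifiable
  from ratio data alone.

Two consequences of linearity anchor the test suite: with `s = 0` and
`k_deg = 0` the total $G+R$ is conserved exactly, and scaling `s` scales
both channels while leaving every ratio unchanged — the model analog of the
observation that the readout is independent of expression level. Under
continuous induction the ratio rises monotonically to $k_{mat}/k_{deg}$,
which is what `steady_state_ratio()` returns.

### Numerics

`simulate_pools()` advances the system with a fixed-step classical
4th-order Runge-Kutta scheme (step 0.01 h), splitting steps exactly at
schedule discontinuities. For a linear system one RK4 step is an affine
map; the implementation composes these maps (binary powering within each
constant-coefficient segment), which reproduces the stepper's trajectory
exactly at arbitrary output times in logarithmic cost. The test oracle is
an independent path: the piecewise matrix exponential of the augmented
system computed with `Matrix::expm()`. Agreement is required to 1e-6
relative error over randomized rates, schedules and grids.

`fit_kinetics()` estimates any subset of `(k_mat, k_deg, s)` by
Levenberg-Marquardt (`minpack.lm`) on the stacked residuals of both
channels. All-zero or constant trajectories are rejected as
unidentifiable.

## The population simulator

`run_simulation()` evolves a population of organelles, each with `size`
(volume proxy), `green`, `red` and a position on a cell geometry — either a
well-mixed field or a neuron (soma disk plus neurite polylines). Each step
of length `dt` applies, in a fixed order: pool kinetics, fusion, fission,
mitophagy, biogenesis, motility. Events are Bernoulli draws per step; the
constructor rejects any `rate * dt > 0.1`, keeping the discrete-time
approximation of the underlying Poisson processes accurate. One master
seed drives a single generator in a documented order, so runs are
bit-reproducible.

Key mechanisms and the reasoning behind them:

* **Import** is shared across organelles proportionally to `size` and, in
  neuron mode, to `exp(-d/λ)` where `d` is the path distance from the soma
  (`import_lambda`, default 20–25 µm). The decay expresses that delivery
  of newly synthesized protein is less available to distal organelles. In
  the default `"packet"` mode import arrives as discrete protein packets
  (Poisson counts of size `import_packet`); this is the stochastic source
  of age heterogeneity, and it naturally makes *small* organelles noisiest
  because they receive the fewest packets. The `"continuous"` mode is the
  deterministic mean-field limit used for closed-form cross-checks: with
  all spatial events off, population totals reproduce `simulate_pools()`
  to 1e-6.
* **Fusion** merges a pair into one organelle with summed size and pools —
  complete content mixing, conserving everything exactly. In the
  well-mixed cell every pair is a candidate; in a neuron only same-neurite
  neighbours within `capture_dist` (1 µm) and soma residents, whose
  per-pair probability is scaled by the encounter factor
  `(capture_dist/soma_radius)^2` so that fusion propensity reflects
  physical proximity rather than population size.
* **Fission** splits size and both pools by one uniform fraction in
  [0.3, 0.7]; both fragments inherit the parent ratio exactly
  (instantaneous intra-organelle mixing). Organelles below
  `min_size / 0.3` do not divide, which bounds fragmentation.
* **Mitophagy** removes whole organelles uniformly at random by default.
  An age-biased option exists but is off: the source experiments do not
  establish selectivity, only that turnover removes both colors.
* **Motility** is along-path diffusion (`motility_D`, reflecting at
  neurite tips) plus transport-run events (`shuttle_rate`) that relocate
  an organelle uniformly along its neurite — a deliberately coarse model
  of fast bidirectional microtubule transport whose equilibration limit is
  easy to reason about: as `shuttle_rate` grows, position decouples from
  import history and the age-versus-distance slope tends to zero.

### What fusion does to heterogeneity

The heterogeneity statistic is the sample SD of per-organelle red/green
ratios in one cell (`heterogeneity_sd()`). A fused organelle's ratio is
the green-weighted mean of its parents' ratios, so each fusion event
contracts the *green-weighted* variance of the ratio distribution — that
contraction is exact and is tested as such. The unweighted sample SD is
not monotone event by event (removing two mid-range values can raise the
SD of the survivors even though nothing moved apart), but it decreases in
expectation; the suite checks both facts. At population level, matched
simulations differing only in fusion rate show roughly twofold higher
heterogeneity SD without fusion, with the smallest size quartile deviating
most — the fragmentation phenotype.

## The synthetic microscope

`render_scene()` turns a simulator snapshot into a two-channel z-stack:
each organelle is an isotropic 2D Gaussian footprint (area proportional to
size, per-channel amplitude proportional to pool density `pool/size`)
distributed over six 0.7 µm z-slices with Gaussian axial weights, blurred
with a lateral Gaussian PSF (`EBImage::gblur`), then degraded with Poisson
shot noise, Gaussian read noise, constant background, and quantized to 16
bits. Defaults (0.2 µm pixels, PSF σ 0.25 µm, gain 2000 counts per
intensity unit, background 20, read noise 3) are plausible confocal
values, chosen so that the signal sits far above background, as it must
for a fractional threshold on the maximum to be meaningful. They are free
parameters, not measured ones.

Because blur and noise are channel-independent, noise-free rendering
preserves each object's red/green ratio exactly — the renderer-level analog
of expression-level independence, and the basis of the end-to-end
validation. Ground truth follows a "merge-truth" convention: organelles
whose footprints touch are merged into one truth object, since no
intensity-based pipeline can separate them. `evaluate_recovery()` scores a
segmentation by assigning each simulated organelle to the measured
component containing its center and comparing component ratios with pooled
truth ratios.

Not modelled: spectral bleed-through, photobleaching during time-lapse,
full 3D PSFs, and tubular (anisotropic) organelle shapes. Passing
end-to-end tests therefore demonstrates correctness of the measurement
chain on punctate, radially symmetric objects, not robustness to every
real-microscope artifact.

## The ratiometric pipeline

`segment_stack()` chains the classical per-organelle procedure:

1. `max_project()` — per-pixel maximum over z, so the whole organelle
   volume contributes to one 2D image.
2. `threshold_red()` — mask at ≥ 15% of the red image's maximum (boundary
   inclusive; the fraction is a parameter). The red channel defines
   mitochondrial areas; no upper threshold is applied, and
   `saturation_check()` verifies the data never reach the detector
   ceiling. An all-zero image yields an empty, flagged mask.
3. `remove_single_pixels()` — deletes 8-connected components of exactly
   one pixel (idempotent).
4. `label_objects()` — 8-connected components labeled in raster order.
   8-connectivity is a documented choice; the original software's
   convention is not recorded. The labeler is validated exhaustively
   against a flood-fill oracle on every 4×4 binary mask.
5. `measure_objects()` — per object: area (px and µm²), mean green, mean
   red, centroid, and the ratio **of mean intensities** (not the mean of
   pixelwise ratios), which is robust to dim pixels. Objects with zero
   mean green are retained with a flagged, undefined ratio. Background
   subtraction is off by default (the reference procedure describes none)
   and available as a constant-offset option for synthetic data with
   nonzero background.

`ratio_image()` produces pixelwise red/green (or green/red) images for
display only, with undefined pixels transparent in the pseudocolor PNG.

## Neurite age gradients and compartment kinetics

`path_distance()` measures geodesic arc length along a neurite polyline
from its soma-boundary root; soma points are 0 by convention, so "distance
from the nucleus" is re-anchored at the soma edge where the neurite
begins. Points farther than a 1 µm snap tolerance from any structure are
rejected. `neurite_traces()` builds one (distance, green/red) point per
organelle and fits OLS slopes; green/red is the default so that a
*negative* slope means older protein distally (the red/green direction
simply flips signs and is available). Slopes are reported raw, without
per-neuron normalization.

`compartment_kinetics()` reduces a time-lapse to per-compartment mean
intensities, each compartment's green peak time, and the post-peak decline
rate both absolute and as a fraction of the peak per hour. The fractional
rate is the right scale for comparing compartments whose absolute
intensities differ by an order of magnitude, as soma and neurites do.

## Study conditions and problem sizes

The named scenarios (`scenario_names()`) freeze the package's standard
conditions. The well-mixed pair (`fusion_off` / `fusion_on`) uses 120
organelles for 24 h at `dt = 0.1` h with import 60 units/h in 0.5-unit
packets; `fusion_on` corresponds to about one fusion event per organelle
per hour initially. The neuron pair (`neuron_control` /
`neuron_motility`) uses 300 organelles (a realistic count for a neuron's
arbor, and enough that compartment means are not dominated by event
noise), three neurites of 80–120 µm, import length scale 20 µm, low
fission (0.1 per hour — organelle dynamics are infrequent in neuronal
processes), and a population preloaded with partly matured probe
(`init_green = 5`, `init_red = 1` per unit size), representing a day of
prior expression. The preload sits between the soma's and the neurites'
import-determined steady states, so over a subsequent 12 h window soma
green still rises while neurite green falls — the compartment-kinetics
regime.

Monte-Carlo checks use 12–20 seeds, trajectory fits 100 replicates of 20
time points at 5% multiplicative noise, and the end-to-end scene 45
organelles in a 60 µm field (sparse enough that PSF-tail cross-talk
between distinct objects stays below the 1% noise-free tolerance). These
sizes keep the whole validation suite a few minutes of desk compute while
leaving each contrast far from its decision boundary.

## Known limitations

* All rate constants except the 24 h maturation half-time are conventions;
  none are fitted to published measurements, because the source
  experiments report none. Conclusions from the simulator are therefore
  qualitative contrasts between matched conditions, never absolute rates.
* Fluorescence is in arbitrary units; only ratios, and contrasts between
  matched conditions at the same time point, are comparable.
* The renderer's merge-truth convention means recovery is scored against
  what imaging can resolve, not against the underlying organelle count.
* Whether the 15% threshold should use the per-image or per-experiment
  maximum is ambiguous in the reference procedure; per-image is
  implemented.
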