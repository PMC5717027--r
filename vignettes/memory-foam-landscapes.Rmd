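---
title: "Memory-foam energy landscapes: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-foam energy landscapes: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memoryfoam)
```

## The model

`memoryfoam` implements a cognitive toy model in which behaviour is gradient
descent on an energy landscape, and *learning is deformation of that
landscape by the stimulus itself*. The state `x` (an `m`-dimensional point
in stimulus space) obeys

$$\frac{dx}{dt} = -\nabla V(x, t),$$

so the only attractors are fixed points at local minima of `V`. The
landscape is plastic. In the raw ("foam profile") form

$$\frac{\partial U}{\partial t} = -g(x - \eta(t)) - k\,U,$$

each stimulus sample `η(t)` presses a dent of shape `g` into the field and
the elasticity `k` (units 1/s) pulls the field back toward flat — the
forgetting mechanism. `U` acquires a linear downward trend, removed by the
change of variables `V = U/t`:

$$\frac{\partial V}{\partial t} = -\frac{1}{t}\left(V + g(x - \eta(t))\right) - k\,V.$$

The dent kernel is, per coordinate,

$$g(z) = \frac{1}{\sqrt{2\pi\sigma_z^2}} \exp\!\left(-\frac{z^2}{\sigma_z^2}\right),$$

and for vector stimuli the product of the per-coordinate kernels. Two
non-obvious conventions are kept deliberately:

* the exponent is $-z^2/\sigma_z^2$, **not** $-z^2/(2\sigma_z^2)$, so the
  kernel is narrower than a Gaussian density of the same $\sigma_z$ and its
  integral per axis is $1/\sqrt{2}$ rather than 1. Every convergence
  statement in the package is therefore phrased against the smoothed density
  $g * p$, which absorbs the normalisation;
* the multivariate kernel is the *product* of 1-D kernels with a product of
  1-D normalisers. A joint normaliser would only rescale depths; minima
  locations — the quantities of scientific interest — are unaffected.

With `k = 0` and an ergodic stationary stimulus of density `p`, the ergodic
average makes $V(x,t) \to -(g * p)(x)$: the landscape becomes the negative
smoothed stimulus density. Each well is a learned category; its minimum
(the smoothed-density mode) is the category prototype. Because the kernel
has finite width, the minima recover the *smoothed* density modes: a sharp,
asymmetric density peak is displaced by up to a fraction of $\sigma_z$
relative to the raw mode. Tests therefore compare learned minima against
the quadrature-computed minima of $-(g*p)$, and against raw density modes
only at kernel resolution ($\sigma_z/2$).

## Integrators

Stimuli arrive as uniformly sampled streams (`stimulus_series`) and are
treated as piecewise constant over each sampling interval `dt`. Three
integrators share this contract (`learn_landscape()` selects one):

* **Exact U form** (`step_u`, 1-D and 2-D grids). Over one holding interval
  the U equation is linear with constant forcing, so the integrating-factor
  update $U \leftarrow U e^{-k\,dt} - g\,(1-e^{-k\,dt})/k$ (and
  $U \leftarrow U - g\,dt$ at `k = 0`) is exact in time; the only error is
  the spatial grid.
* **Euler V form** (`step_v`). The de-trended equation is singular at
  `t = 0`; integration starts at $t_0 = dt$ with $V = -g(x - \eta_1)$
  scaled by $(1-e^{-k\,dt})/(k\,dt)$, which is exactly `U/t` after the first
  interval, so no ad-hoc regularisation is needed. The explicit Euler step
  carries an O(dt) truncation error against the exact U form; `substeps`
  subdivides each holding interval, and the test suite verifies the error
  halves when the step halves.
* **Mesh-free form** (`meshfree_absorb`/`meshfree_eval`, any dimension).
  For piecewise-constant stimuli the exact solution is a weighted dent sum
  $V(x) = -(1/t)\sum_i w_i\, g(x - \eta_i)$: absorption multiplies existing
  weights by $e^{-k\,dt}$ and appends the new center. This equals the grid
  U form at the nodes to machine precision (the suite checks 1e-10) and is
  the only representation used for 4-D phrase landscapes, since grid memory
  grows exponentially with dimension (grids are limited to m ≤ 2). Weights
  below `prune_tol` (default 1e-12) of the largest are dropped; with
  `k > 0` the total weight is bounded by `1/k`, so pruning bounds memory.

Grid bounds default to the observed stimulus range padded by $4\sigma_z$ per
side, and the kernel is always evaluated analytically, never truncated at a
boundary.

## Reading the landscape out

`descend()` integrates $dx/dt = -\nabla V$ on a frozen landscape by explicit
Euler with an adaptive step: a step that would raise `V` is halved
(backtracking), successful steps let the step grow again, a single move is
capped at $\sigma_z/4$ so the state cannot hop across a ridge into a
neighbouring basin, and a step that makes no representable progress in `V`
contracts the step (the iterate is straddling the minimum at machine
precision). The recorded `V` values are non-increasing *by construction*,
which the property tests assert per step. Convergence is declared at
gradient norm below `tol` (default 1e-8); hitting `max_iter` yields a
flagged non-converged trajectory, not an error.

On 1-D grids, `V` is interpolated with a natural cubic spline and the
gradient is the spline's exact derivative. The two must come from a single
interpolant: with linear interpolation of values and a separately
interpolated finite-difference gradient, the line search and the gradient
disagree near a node minimum and descent stalls. 2-D grids use bilinear
interpolation; mesh-free landscapes are evaluated exactly.

`find_minima()` runs seeded random restarts (uniform in a box defaulting to
the landscape extent), drops non-converged restarts, clusters endpoints by
single linkage at `merge_radius` and returns centroids with depths and
restart counts, deepest first. Three choices matter:

* `merge_radius` defaults to $\sigma_z/2$: dents closer than about
  $\sigma_z$ merge into a single minimum anyway, so nothing real is lost.
* a converged endpoint must also pass a **local-minimum probe** (axis
  probes at `merge_radius/2`): between far-apart dents the field and its
  gradient underflow to zero, and a restart landing there "converges"
  without being at a minimum. Probe-rejected restarts count as
  non-converged.
* `starts` may be an explicit matrix. In 4-D the default uniform box is
  essentially all dead volume (a basin of width a few $\sigma_z$ occupies
  ~1e-3 of the box), so the phrase pipeline restarts from the observed
  stimulus vectors themselves — the mean-shift convention for mode finding
  in kernel mixtures. The uniform box remains the default.
* `min_depth` optionally drops minima shallower than a floor. One stimulus
  sample can carve a dent of depth $g(0)\,dt/t$ at most; the audio and
  phrase pipelines use twice that, so a reported memory must have been
  reinforced by at least two samples. Pitch-track transition frames and
  jitter outliers otherwise show up as single-sample dust minima.

`recognize()` models recognition-by-reset: the state is set to the stimulus
value, descends the frozen landscape, and is labelled with the catalogued
minimum within `merge_radius` of the endpoint; no match is an *unknown
category* result (`NA`), distinct from an error. `run_online()` interleaves
absorption of every sample with recognition every `recognition_interval`
samples; recognition is read-only, so the final landscape is identical to
pure absorption of the same stream (asserted in the suite). Categories are
catalogued online in order of first appearance.

## Synthetic stimulus generators

The generators provide the three stimulus classes used throughout the tests,
with closed-form ground truth where possible.

* `gen_iid_bimodal()`: i.i.d. samples
  $\eta = A\tanh(\beta(\xi - \mu)) + c\,(\xi - \mu)$, $\xi$ standard normal.
  The saturation piles mass near $\pm A$ (two categories), $\mu$ makes the
  masses unequal, and the leak `c > 0` keeps the transform strictly
  monotone so the density follows in closed form by change of variables
  (`true_density_iid()`). Defaults `A = 1.5, β = 2, c = 0.1, μ = 0.3` give
  two modes of unequal mass (≈62% / 38%).
* `gen_langevin()`: correlated samples from an overdamped particle in a
  tilted quartic double well, Euler–Maruyama with step `h`. Defaults
  (`a4 = 1, a2 = 2.25, ε = 0.15, D = 0.4, h = 0.05`) put wells near
  $\pm 1.5$ — matching the bimodal generator's support — with a barrier low
  enough that a 10⁴-sample stream crosses wells many times. Its stationary
  density is the Boltzmann law $p \propto e^{-W/D}$
  (`true_density_langevin()`). Consecutive samples are strongly correlated
  (lag-1 ≈ 0.98 at the default step), which is the point: the same
  two-category structure arrives with and without serial correlation, and
  the correlated stream converges to its limit landscape measurably slower.
* `gen_melody()`: a pitch track emulating a three-note (G4/A4/B4,
  equal-temperament 392/440/493.88 Hz), 32-beat song played `reps = 6`
  times at beat τ = 0.75 s, emitted at 8 samples/s with i.i.d. Gaussian
  pitch jitter (default sd 2 Hz) standing in for performer and measurement
  variability. The default 32-beat arrangement is the standard three-note
  nursery song with held notes expanded into repeated beats; it is a
  configuration default, overridable along with the tuning map.

What the generators deliberately do **not** emulate: amplitude dynamics,
note transitions/portamento, reverberation or harmonics (the melody jitter
is white and purely in frequency), and any non-stationarity. Tests passing
on these streams show the landscape mechanics are correct; they do not by
themselves certify pitch tracking on real recordings, which is why the
audio front end is tested separately on synthesised waveforms and why the
recorded-performance check requires the actual recording.

## Audio front end

`read_wav()`/`write_wav()` handle plain PCM RIFF/WAVE (8/16/24/32-bit
integer and float32; multi-channel averaged to mono). `track_peak_frequency()`
slides a Hann-windowed Fourier transform (window 0.75 s ≈ one beat; hop
0.125 s, i.e. an 8 Hz track directly, equivalent to sliding finer and
resampling), restricts the peak search to 80–2000 Hz to reject DC and
harmonic artifacts, and refines the maximal bin by log-magnitude parabolic
interpolation — bringing a 1.33 Hz bin width down to well under 1 Hz on
steady tones. All-zero frames yield `NA` and are dropped, not interpolated.
`resample_track()` uses nearest-sample resampling under the convention that
`n` samples at rate `r` span `n/r` seconds. `delay_embed()` forms
$\eta(t) = (f(t), f(t+\tau), \ldots)$ at every track sample (sliding, not
beat-aligned: the embedded vector is defined for all `t`, and for
piecewise-constant notes every offset yields a valid 4-note phrase);
windows and rates are configurable.

`polygon_coords()` is the planar representation of a positive vector:
component `j` at radius `v[j]` on the half-axis at angle `2πj/m`, so a
4-beat phrase becomes a tetragon; `plot_polygons()` stacks phrase minima
deepest-on-top, and every plotting function returns its numeric data so no
result exists only as an image.

## Problem sizes and numerical tolerances

The test suite and the acceptance script are sized for a single CPU:
ergodic-limit checks use 10⁵ i.i.d. samples on a 401-node grid (sup-norm
within 5% of the dent depth `g(0)`); the convergence-speed comparison uses
10 seeds × 10⁴ samples per generator; melody runs use the default 1152
samples (6 × 32 × 0.75 × 8) and 200–400 restarts; the 4-D phrase landscape
holds ~1.1e3 dent centers. Mesh-free/grid agreement is asserted at 1e-10;
the Euler V form at its O(dt) order; the post-stimulus decay law
$V(t) = V(t_1)\,(t_1/t)\,e^{-k(t-t_1)}$ to 1e-12 relative through the exact
update and 1e-4 through the Euler form at small steps.

## Known limitations

* Grid landscapes stop at m = 2; higher dimensions are mesh-free only.
* The descent is first-order; it is robust and monotone but not the fastest
  way to polish minima to very high precision.
* `find_minima` guarantees nothing about minima whose basins the starts
  never intersect; in high dimension supply data-driven `starts`.
* The melody generator's white frequency jitter is a simplification; real
  performances drift and glide, which broadens and can split dents — the
  `min_depth` floor exists precisely because such artifacts appear in
  pitch-tracked audio.
* Recognition labels are stable only while the landscape's minima are;
  under strong forgetting (`k` large) categories can vanish between
  recognition events, which `run_online` reports as unknowns.
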