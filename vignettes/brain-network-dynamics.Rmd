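---
title: "Simulating and characterizing whole-brain network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and characterizing whole-brain network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bnmdyn` implements a complete simulate-and-compare workflow for whole-brain
resting-state activity: two delayed-coupling neural-mass models run on a
structural connectome, a hemodynamic forward model, the standard rs-fMRI
preprocessing chain, and five analysis methods that probe the data at
increasing levels of temporal structure. This vignette documents the models,
the assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## The two brain network models

Each of the `n` cortical regions (ROIs) carries one neural mass; masses
interact through a weight matrix `C` with pairwise conduction delays
`tau[n,p]` (fiber length / conduction velocity). Both systems are integrated
with the Euler-Maruyama method at `dt` (default 0.1 ms; the acceptance runs
use 0.2 ms), noise entering as `sigma * sqrt(dt) * N(0,1)` per step with
`sigma = 2`. The first 20 s are discarded as an initial-condition transient.

**Firing-rate model** — a linear network of leaky units:

    tau0 * dr[n]/dt = -r[n](t) + (k / c1) * sum_p C[n,p] r[p](t - tau[n,p]) + sigma n(t)

with relaxation constant `tau0 = 20` ms and `c1` the leading eigenvalue of
`C`, which makes the dynamics invariant to the overall weight scale. The
default global coupling `k = 0.9` places the network just below its linear
instability (the leading network mode relaxes ten times slower than an
isolated node), so slow, connectome-shaped fluctuations emerge from noise.
Sweep presets: 0.3 (low), 0.999 (high).

**Kuramoto model** — phase oscillators with delayed sinusoidal coupling:

    dtheta[n]/dt = omega[n] + k * sum_p C[n,p] sin(theta[p](t - tau[n,p]) - theta[n](t)) + sigma n(t)

with natural frequencies drawn once per run from Normal(60 Hz, 2 Hz)
(converted to rad/s) and initial phases uniform on [0, 2*pi). The observable
passed to the hemodynamic model is `sin(theta)`. Sweep presets: 3 (low),
13 (default), 60 (high).

### Coupling conventions

The stored connectome is normalized to unit spectral norm (largest singular
value), which is convenient for comparison with functional connectivity and
makes the firing-rate `c1` equal to 1. The Kuramoto equation, however, is not
scale-invariant: on *any* unit-spectral-norm non-negative matrix the mean row
sum is at most 1, so the coupling field (at most `k` rad/s, ~13) would be
negligible against `omega = 2*pi*60 = 377` rad/s and the 2-Hz frequency
spread, and the model would stay incoherent at every swept `k`. Two
observations fix the intended convention: the firing-rate equation divides by
a "calculated" `c1` (vacuous if the simulated weights had unit norm), and the
default `k = 13` is calibrated directly against the `k = 18` of the
oscillator-model lineage, whose weights are scaled to unit mean. The package
therefore couples the Kuramoto model through the weights rescaled to a fixed
mean nonzero entry (`coupling_norm = "mean"`), while `coupling_norm = "none"`
preserves the literal equation for small hand-built systems (this is what the
closed-form two-oscillator tests use).

One constant remains: where the coupling sweep lands relative to the
synchronization transition depends on the matrix. On the synthetic connectome
the metastable band sits at an effective coupling of roughly 28-36 (measured
by the slow variance of the Kuramoto order parameter), so the convention uses
`coupling_scale = 2.5`: with `k = 13` the model operates inside that band
(partial synchrony, slow cluster switching, delay-induced frequency
suppression), `k = 3` is incoherent, and `k = 60` locks globally at a
strongly suppressed frequency (~4 Hz). This mirrors the recalibration of `k`
that is needed whenever the structural matrix changes.

## The synthetic structural connectome

`generate_synthetic_connectome()` replaces tractography. ROI centroids sit on
two mirrored rings (one per hemisphere, default 33 + 33). Design features,
each mimicking a documented property of tractography-derived matrices:

- **Distance decay**: connection weight includes `exp(-d/60 mm)`.
- **Heavy-tailed weights**: log-normal magnitudes with `sdlog = 1.5`
  (~3 orders of magnitude, as in fiber-count matrices). The tail matters
  dynamically: strongly connected pairs phase-lock first, giving graded
  cluster formation instead of a discontinuous all-or-none transition.
- **Mirrored modules**: each hemisphere is split into 4 contiguous
  subnetworks (density 0.9, weight x3 within a module; modules are mirrored
  homotopically). Community structure is what makes functional subnetworks
  activate and deactivate as blocks.
- **Hemisphere dominance**: interhemispheric connection probability is low
  (0.04 versus 0.35 within), homotopic pairs are always connected, and all
  interhemispheric weights are multiplied by 4 before normalization
  (compensating tractography's insensitivity to long interhemispheric
  fibers). This keeps the second and third eigenvalues close to the first,
  which is what lets connectome structure survive global signal regression in
  the linear model.
- **Delay calibration**: fiber lengths are centroid distances times a
  log-normal tortuosity, rescaled so the mean delay over connected pairs is
  exactly 11 ms at 5.45 m/s.

The block densities and weight distribution are fixture choices, not
empirical claims; the delay calibration, the x4 interhemispheric scale, and
unit spectral norm are the stated study conditions.

## From neural activity to BOLD

`balloon_windkessel()` integrates the standard 4-state hemodynamic system per
ROI (vasodilatory signal, inflow, volume, deoxyhemoglobin) with the canonical
constant set kappa = 0.65/s, gamma = 0.41/s, tau = 0.98 s, alpha = 0.32,
E0 = 0.34, V0 = 0.02, k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2. Which published
variant of these constants a given study used is often ambiguous; this set is
recorded here and in the code, and `balloon_params()` makes every constant
configurable. The alternative "fast-inflow" variant (kappa = 1.25, gamma =
2.5, tau = 1, alpha = 0.2, E0 = 0.8) moves the hemodynamic resonance from
~0.10 Hz up to the band edge and flattens the in-band spectral slope of
simulated BOLD from ~1.8 to ~0.05; the slope is therefore almost entirely a
property of this choice, a point worth remembering when comparing fitted
exponents across studies.

`simulate_bold()` fuses the neural and hemodynamic integrations in one
streaming pass (a 15-minute run at dt = 0.1 ms would otherwise need ~3 GB to
materialize), records the smooth hemodynamic output at 10 ms resolution, and
then applies the guarded decimation to the scanner TR (0.72 s): a zero-phase
4th-order Butterworth at the TR Nyquist followed by sample picking. The
neural drive is scaled by `gain = 0.1` by default: heavy-tailed connectomes
give hub nodes sustained excursions strong enough to drive the inflow `f` to
zero (the integrator stops with a diagnostic rather than clamping silently),
while at gain 0.1 the system stays near its resting operating point.
Correlation- and spectrum-shape-based metrics are invariant to the gain in
this linear regime. The first 20 s of BOLD are dropped as the hemodynamic
onset transient.

## Preprocessing

One shared code path (`preprocess_pipeline()`) for simulated and
surrogate-empirical series, in this exact order: per-ROI z-score (population
SD convention), zero-phase 5th-order Butterworth band-pass 0.01-0.25 Hz,
global signal regression (least squares on the unweighted across-ROI mean,
with intercept), final z-score. The steps applied are recorded as flags on
the output. Spectral-slope analyses take the *unpreprocessed* BOLD.

## The five analysis methods

1. **Average FC and spectral slope** — pairwise Pearson correlation over the
   scan; Welch spectra (Hann window, 50% overlap, segment length the largest
   power of two below a quarter of the scan) averaged over ROIs and fit by a
   log-log line over 0.01-0.25 Hz, reported as the exponent of `(1/f)^n`.
2. **Point-process coactivation** — upward threshold crossings (thresholds 0
   and 1 on z-scored data; 1 is the headline), counting for each ROI pair the
   fraction of one ROI's crossings with a crossing of the other within +/-3
   TRs. The raw matrix is row-normalized and asymmetric; the symmetrized
   form `(M + t(M))/2` is used for comparison with FC.
3. **Quasiperiodic patterns** — iterative template matching with a 28-TR
   (20 s) window: sliding correlation, peak selection (threshold 0.1 for the
   first two iterations, 0.2 after; minimum separation half a window),
   averaging of peak windows, until successive templates correlate > 0.9999
   or 20 iterations; best of 10 random starting chunks by summed peak
   correlation. Templates are compared after circular-shift alignment.
4. **Sliding-window k-means states** — 60-TR windows advanced by 1 TR,
   correlations clipped to +/-(1 - 1e-6) and Fisher-z transformed, pooled
   across all runs under comparison, clustered with k = 7 Manhattan-distance
   k-means (componentwise-median centroid updates, best of 30 seeded
   restarts). Statistics per run: states visited, mean dwell (seconds),
   mean pairwise L2 distance among visited centroids; pooled transition
   matrix with zero diagonal and its occupancy ("sparsity") fraction.
5. **Recurrence quantification** — recurrence plot from Pearson correlations
   of spatial patterns across all TR pairs, thresholded at 0.3; recurrence
   rate over all entries including the line of identity (the formula's
   literal sum); diagonal-line statistics (mean length and entropy of the
   normalized length distribution, minimum length 2) excluding the line of
   identity, counting each symmetric diagonal once.

## The surrogate resting-state generator

`generate_surrogate_rest()` stands in for parcellated empirical scans. It
emulates exactly the features the five methods are sensitive to: a hidden
Markov chain over covariance regimes (default 3 states, geometric dwell with
mean 80 TRs ~ 1 minute, each regime a random rank-3 loading structure),
`(1/f)^0.9` spectral shaping applied identically to every ROI (0.9 matching
unfiltered empirical BOLD), and a periodically planted traveling motif
(28 TRs, staggered per-ROI peaks) for the QPP method. It does **not** emulate
head motion, physiological noise, spatial autocorrelation on the cortical
surface, scanner drift, or any relationship between its covariance regimes
and the synthetic connectome. Tests that pass against the surrogate therefore
validate the *machinery* (detection, clustering, template recovery), not
claims about real brains.

## Numerical choices and degenerate inputs

- Delays are rounded to integer multiples of `dt` (at dt = 0.1 ms and mean
  delay 11 ms the rounding error is below 0.5%); history before t = 0 is the
  initial state.
- Noise enters as `sigma*sqrt(dt)*N(0,1)`; all random draws go through R's
  RNG, so a single seed fixes connectome, initial conditions, frequencies,
  noise, k-means restarts and QPP starting chunks bit-for-bit.
- Correlations are clipped at 1 - 1e-6 before the Fisher transform.
- Constant time series, zero-variance windows, all-zero weight matrices and
  ragged TSV rows raise informative errors naming the offending ROI, TR,
  window or row; ROIs with no threshold crossings give `NA` coactivation rows
  (reported as missing, not zero).
- k-means ties and empty clusters: an empty cluster seizes the point farthest
  from its centroid; template alignment breaks ties by the smallest
  non-negative shift.
- A QPP iteration that finds no peaks returns the degenerate template flagged
  unconverged instead of failing (low-coupling runs are noise-like).

## Problem sizes

The package's own validation uses 66 ROIs with dt = 0.2 ms: five firing-rate
runs and three Kuramoto runs of 15 simulated minutes for the end-to-end
checks, three seeds per condition for directional comparisons (coupling
sweeps), and smaller systems (2-20 nodes) wherever a closed-form or
brute-force oracle exists. `preset = "desk"` in `experiment_config()` (dt =
1 ms, 180 s, 3 runs) exists for quick interactive runs.

## Known limitations

- The synthetic connectome reproduces the *kind* of structure tractography
  matrices have, not any specific cortical atlas; quantities that depend on
  the exact eigenstructure of the real matrix (the strength of
  coactivation-FC agreement, cross-model QPP template correlation, the
  in-band spectral exponent) land in plausible but not identical ranges.
- Homogeneous node parameters and hemodynamics; no subcortex; bidirectional
  connections only.
- The Kuramoto BOLD signal reaches the band of interest only through the
  slow modulation of synchrony (the 60-Hz carrier itself is filtered out),
  so its in-band signal-to-noise is intrinsically lower than the
  firing-rate model's.
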