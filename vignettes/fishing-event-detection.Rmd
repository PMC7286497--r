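---
title: "Detecting fishing events in artisanal-fleet GPS tracks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fishing events in artisanal-fleet GPS tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishHMM)
```

## The model and its assumptions

`fishHMM` segments GPS trips from small-scale fishing vessels into `fishing`
and `non_fishing` intervals. The behavioural premise is that fishing movement
is slow and sinuous while transit is fast and straight, and that per-gear
speed distributions are bimodal — which is why two states are the default
(`n_states` is general, but three- or four-state models, e.g. separating
setting from hauling for bottom gillnets, are untested beyond invariants).

Given a track regularized to a constant interval Δ, each interval yields a
step length (great-circle distance between consecutive positions, meters) and
each interior position a turning angle (signed bearing change, wrapped to
(−π, π], counterclockwise positive). The hidden state chain is first-order
Markov with transition matrix A and initial distribution π; conditional on
the state, the step is gamma (parameterized by mean and sd: shape = (μ/σ)²,
rate = μ/σ²) and the angle von Mises (mean direction, concentration κ), with
step and angle conditionally independent given the state. That conditional
independence is the standard convention of movement HMMs; it is an assumption,
not a theorem — strongly auto-correlated within-state speeds violate it
mildly, which mostly inflates κ estimates.

The likelihood sums over all state paths via the log-space forward recursion
(implemented in C++ since it sits inside the optimizer loop) and is maximized
directly — no EM, no priors. Decoding uses the Viterbi algorithm;
per-observation one-step-ahead pseudo-residuals (forecast CDF mapped through
the standard normal quantile) are the goodness-of-fit diagnostic and are
exactly N(0,1) under a correctly specified model.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `radius_km` | 3 | km | landing-site buffer: fishing is prohibited near ports and near-port movement is transit; "within 3 km" is read strictly (< 3 km removed), with an `inclusive` flag for the ≤ reading |
| `vmax_kmh` | 50 | km/h | speed filter ceiling, the realistic top speed of the 40 HP outboards these fleets use |
| `interval_s` | 5 | s | the loggers' native recording rate; all simulation is calibrated at this reference interval |
| `max_gap_s` | 10·Δ | s | recording gaps longer than this are not interpolated: grid points inside them are emitted as missing so dropouts cannot fabricate straight "transits" |
| `vmax_fishing_kmh` | 7 | km/h | the surrogate labeller's speed rule, the one explicit criterion the human experts used |
| `n_restarts` | 3 | — | jittered optimizer restarts (±20% on positive scalars, Dirichlet on simplex rows), seeded per restart index |
| `kappa_max` | 700 | — | κ cap keeping the Bessel normalizer finite; perfectly aligned angle samples hit this cap instead of diverging |

## Numerical choices

- **One sphere everywhere.** All geodesy (distances, speeds, interpolation,
  dead reckoning) is haversine on a sphere of radius 6,371,000 m — sub-0.5%
  error at fleet scale and a single convention the test oracles can share.
  Consequently the package's "equatorial half degree" is 55.597 km, not the
  WGS84-ellipsoid 55.66 km.
- **"Speed-based linear interpolation"** is implemented as constant-speed
  great-circle (slerp) interpolation within each original segment: position
  fraction = elapsed-time fraction. This makes `regularize(Δ)` then
  `decimate(k)` agree with `regularize(kΔ)` exactly on shared grid points.
- **Speed filter is a forward sweep** anchored on the first fix: a removed
  spike's neighbours are re-checked against the last retained fix, so one bad
  position does not poison two speeds.
- **Zero steps are missing, not data.** An exact zero step is invalid for the
  gamma density (and leaves the heading undefined), so the step emission is
  treated as missing there rather than bolting on a zero-inflation mixture;
  missing observations contribute likelihood factor 1 and still receive a
  decoded label through the transition structure.
- **Unconstrained reparameterization** for fitting: log for positive scalars,
  the pair (κ cos θ, κ sin θ) for the circular parameters (κ ≥ 0 by
  construction, no wrap-around), additive-logit rows (diagonal reference) for
  A and π. Working logits are clamped to ±30, so empirical initializers with
  structural zeros remain representable as ~1e-13 probabilities.
- **State identity.** After fitting, states are relabelled so that `fishing`
  has the smaller step mean. If the two fitted emission distributions are
  nearly identical the transition matrix is unidentifiable; the fit succeeds
  with an explicit warning rather than failing.
- **Viterbi ties** break toward the lower state index, making decodes
  reproducible; `pi` can be estimated freely (default) or tied to the
  stationary distribution of A (`stationary_pi = TRUE`) — the original
  analysis does not say which it used, so both are offered.
- **von Mises CDF** (for angle pseudo-residuals) uses the Bessel Fourier
  series with exponentially scaled terms; deep-tail values underflow to 0/1
  at ~1e-100, far below any diagnostic's resolution.

## The synthetic world

No field tracks are distributed, so the package carries a generator whose
defaults state, once, the world the tests run in. Anchored features (from the
study system): seven gear archetypes; handline fishing events as short as
600 s; trip durations spanning 2.3 h (purse seine) to 76.2 h (surface
drifting gillnet); fishing speed modes below the 7 km/h visual threshold and
transit modes below the 50 km/h filter; bimodal per-gear speed distributions;
a 99-trip default fleet composed SCG 10, SG 14, MCG 12, PS 32, HL 12, LL 8,
BG 11. Everything else — exact speed modes and spreads, angle concentrations,
transition diagonals, the remaining per-gear event-duration floors, the
near-equatorial coastal start box — is a stated calibration assumption,
versioned in `inst/extdata/gear_profiles.json` and never used as acceptance
truth.

Generation: the state chain is simulated as alternating geometric runs at the
5-s reference interval, with fishing runs drawn from the geometric law
conditioned on the minimum event length (the closed form of rejecting
too-short runs). This conditioning slightly lowers realized fishing-exit
rates relative to nominal A, so every simulated trip carries an audit of
realized transition frequencies and tests compare against those where it
matters. Coarser sampling intervals are always produced by decimating the
reference-interval simulation, so degradation experiments see internally
consistent dynamics. Positions are dead-reckoned from state-conditional steps
and turns; because start areas are near-equatorial (|lat| ≤ 1.5°) and trips
≤ ~165 km, equirectangular integration with cos(lat) fixed at the start
latitude deviates from exact spherical dead reckoning by < 0.01% of a step
and keeps the generator fully vectorized (a 99-trip fleet simulates in
seconds).

What the generator does **not** emulate: position noise (tracks are
noise-free unless `corrupt_track()` injects spikes/gaps), within-state speed
autocorrelation, tides/currents/bathymetry, port-adjacent behaviour, and the
shore itself (trips may cross the synthetic coastline). A green end-to-end
test therefore establishes that the estimation and decoding machinery is
correct *under the model's own assumptions* — it does not certify field
accuracy, where the original study saw median accuracies near 0.75–0.80
against expert labels.

## Design decisions taken where the source was open

- **Pooled-per-gear fitting** (all of a gear's trips share one model), the
  natural reading of fitting one model per gear type; per-trip fitting with
  aggregation is the alternative we did not take.
- **Expert visual interpretation is not reimplementable.** The surrogate
  labeller applies the experts' one stated rule (speed < 7 km/h) plus
  run-length smoothing (interior runs shorter than the minimum event are
  flipped) standing in for their "typical shape" judgment. Boundary runs are
  left alone — their true length is censored by the trip edges. Acceptance
  checks never treat the surrogate as equivalent to experts; synthetic truth
  is the reference.
- **Degradation sweeps refit at each interval** (initialised from reference
  labels decimated by majority vote, ties to the earliest covered interval)
  rather than rescaling 5-s parameters — matching the stated procedure of
  fitting to data regularized at each resolution.
- **Trip segmentation is upstream.** How multi-day deployment files were cut
  into individual trips is not specified; the package takes one trip per
  input track/group and concatenates GPX segments (power cycles) within a
  track.
- **JSON instead of YAML** for config, manifests and parameter files: no
  YAML parser is available in the deployment environment, and the structure
  is identical.

## Known limitations

Two-state decoding lumps searching, drifting and hauling into whichever state
they resemble; gears where the boat detaches from the gear (bottom gillnets,
drifting gillnets left briefly) are mislabelled by construction, as the GPS
records the boat, not the gear. Covariate-dependent transitions (bathymetry,
landing site) are out of scope. The optimizer is local: pathological
initializers can converge to a spurious optimum, which is why initialization
from labelled data plus jittered restarts is the supported route — and why
the fit object reports per-restart diagnostics.

```{r example, eval = FALSE}
# end-to-end on the synthetic world
cfg <- run_config("out",
                  simulate = list(n_trips_per_gear = list(PS = 2, HL = 2)),
                  interval_s = 60, seed = 1)
res <- run_pipeline(cfg)
res$metrics
```
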