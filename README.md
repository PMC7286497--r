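# fishHMM

Detecting fishing events in GPS tracks from small-scale fisheries with
two-state hidden Markov models.

## The problem

Small wooden fishing boats carry no VMS or AIS, so mapping where artisanal
fleets actually fish requires putting consumer GPS loggers on board and then
deciding, position by position, whether the vessel was fishing or not.
Experts can do this visually — fishing movement is slow and sinuous, transit
fast and straight — but visual interpretation does not scale. `fishHMM`
implements the scalable alternative: a hidden Markov model over track metrics
that decodes each interval of a trip into `fishing` / `non_fishing`, plus the
preprocessing, evaluation and simulation machinery needed to use and test it
end to end. It is aimed at fisheries scientists and managers working with
GPS-tracked artisanal fleets (seven gear types are covered: sardine and
mullet circling gillnets, surface drifting gillnets, purse seines, handlines,
longlines, bottom gillnets).

## The model

A trip is cleaned (positions within 3 km of a landing site removed, fixes
implying speeds above 50 km/h — beyond a 40 HP outboard — removed), then
regularized to a constant sampling interval by constant-speed great-circle
interpolation. From the regular track we derive, per interval *t*, the step
length `s_t` (m) and turning angle `φ_t` ∈ (−π, π]. The observation model is
a two-state HMM:

- hidden states `q_t ∈ {fishing, non_fishing}` with transition matrix
  `A = {a_ij}`, `a_ij = P(q_{t+1}=j | q_t=i)`, and initial distribution π;
- emissions, conditionally independent given the state:
  `s_t ~ Gamma(mean μ_j, sd σ_j)` and `φ_t ~ von Mises(mean θ_j, concentration κ_j)`.

The likelihood is computed with the (log-space) forward algorithm, maximized
directly by quasi-Newton optimization on an unconstrained reparameterization,
initialised from moment estimates on labelled data. The most probable state
path comes from the Viterbi algorithm; one-step-ahead pseudo-residuals check
model fit. Decoded states are scored against reference labels with confusion
matrices (fishing = positive class): accuracy, sensitivity, specificity,
fishing/non-fishing predictive values, aggregated across gears as median and
MAD. A degradation study refits the model at coarser sampling intervals
(10 s – 10 min) to find how sparse the GPS data may be before detection
breaks down; with 10-minute handline events and 3 positions needed per event,
the hard ceiling is `floor(600/3) = 200 s`.

Because no field data ship with the package, a calibrated synthetic fleet
generator (`simulate_fleet()`) produces labelled trips with the statistical
structure above for all seven gear archetypes; every numeric calibration
assumption lives in `inst/extdata/gear_profiles.json`.

## Worked example

```r
library(fishHMM)

profiles <- default_gear_profiles()
trips  <- lapply(1:3, function(i) simulate_trip(profiles$PS, seed = i))
series <- lapply(trips, steps_and_angles)
truth  <- lapply(trips, `[[`, "truth")

init <- initial_params_from_labels(series, truth)
fit  <- fit_hmm(series, init, seed = 1)
print(fit)
#> <fish_hmm_fit> loglik -35814.041 (init -35814.413), 8397 obs, converged: TRUE
#> <hmm_parameters> 2 states: fishing, non_fishing
#> pi: 0.3334 0.6666
#> A:
#>        [,1]   [,2]
#> [1,] 0.9993 0.0007
#> [2,] 0.0058 0.9942
#> fishing: step mean 5.60 m sd 4.48 m | angle mean 0.029 rad kappa 0.709
#> non_fishing: step mean 22.18 m sd 5.49 m | angle mean -0.009 rad kappa 12.066

decoded <- lapply(series, viterbi_decode, params = fit$params)
confusion(unlist(lapply(truth,   `[[`, "labels")),
          unlist(lapply(decoded, `[[`, "labels")))
#>    accuracy sensitivity specificity f_prediction nf_prediction
#> 1 0.9998809           1   0.9990503    0.9998639             1

max_interval_for_event(600, 3)   # 10-min handline events, 3-point rule
#> [1] 200
```

Reading: on three simulated purse-seine trips (8,397 five-second intervals),
the model refit from labelled moments decodes 99.99% of intervals correctly;
the fitted fishing state moves ~5.6 m per 5 s (≈ 4 km/h) with nearly uniform
turning angles (κ ≈ 0.7, sinuous), the transit state ~22 m (≈ 16 km/h) with
κ ≈ 12 (straight). Real tracks are harder than this clean synthetic world —
see the methods vignette for what these numbers do and do not establish.

The full pipeline (clean → fit → decode → score, with per-gear parameter
files, labelled tracks, metrics and a run manifest) is one call:

```r
cfg <- run_config("out", simulate = list(n_trips_per_gear = list(PS = 2, HL = 2)),
                  interval_s = 60, seed = 1)
run_pipeline(cfg)
```

or from the shell via `inst/cli/fishhmm.R` (`simulate`, `run`, `sweep`
subcommands, JSON config).

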