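# Synthetic fleet generator: labelled GPS trips with the statistical structure
# the detection pipeline assumes (two-state Markov switching between slow,
# sinuous fishing movement and fast, straight transit), calibrated to seven
# artisanal gear archetypes. The calibration file inst/extdata/
# gear_profiles.json states every numeric assumption.

#' Build a gear simulation profile
#'
#' @param gear Gear code (one of `GEAR_CODES`; `NA` allowed for ad-hoc
#'   profiles).
#' @param fishing,non_fishing [state_emission()] objects at the reference
#'   interval (5 s).
#' @param A 2x2 transition matrix at the reference interval
#'   (states ordered fishing, non-fishing).
#' @param trip_duration_range_h Length-2 numeric, hours.
#' @param min_fishing_event_s Shortest admissible fishing event, seconds
#'   (0 disables the constraint).
#' @param start_area List with `lat` and `lon` range vectors (degrees).
#' @param heading_persistence Transit heading concentration (kappa); by
#'   convention equals the non-fishing angle concentration.
#' @param reference_interval_s Interval the emissions and `A` refer to.
#' @return A `"gear_profile"` list.
#' @export
gear_profile <- function(gear, fishing, non_fishing, A,
                         trip_duration_range_h, min_fishing_event_s = 0,
                         start_area = list(lat = c(0.2, 1.0),
                                           lon = c(9.0, 9.5)),
                         heading_persistence = non_fishing$angle_concentration,
                         reference_interval_s = 5) {
  stopifnot(inherits(fishing, "state_emission"),
            inherits(non_fishing, "state_emission"),
            length(trip_duration_range_h) == 2,
            trip_duration_range_h[1] <= trip_duration_range_h[2],
            trip_duration_range_h[1] > 0, min_fishing_event_s >= 0)
  if (fishing$step_mean >= non_fishing$step_mean)
    stop("fishing state must have the smaller step mean")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8))
    stop("A must be row-stochastic")
  structure(list(gear = gear, fishing = fishing, non_fishing = non_fishing,
                 A = unname(as.matrix(A)),
                 trip_duration_range_h = trip_duration_range_h,
                 min_fishing_event_s = min_fishing_event_s,
                 start_area = start_area,
                 heading_persistence = heading_persistence,
                 reference_interval_s = reference_interval_s),
            class = "gear_profile")
}

#' Default profiles for the seven gear archetypes
#'
#' Reads the versioned calibration file shipped with the package. Anchored
#' features: the handline minimum fishing event is 600 s (handline operations
#' can last just 10 minutes); purse seine trips go down to 2.3 h; surface
#' drifting gillnet trips up to 76.2 h; each profile's fishing speed mode sits
#' below the 7 km/h visual-interpretation threshold and its transit mode below
#' the 50 km/h speed filter; per-gear speed distributions are bimodal.
#'
#' @param path Alternative calibration file (JSON, same schema).
#' @return Named list of seven [gear_profile()] objects.
#' @export
default_gear_profiles <- function(path = system.file("extdata",
                                                     "gear_profiles.json",
                                                     package = "fishHMM")) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- obj$reference_interval_s
  out <- lapply(obj$profiles, function(p) {
    mk_em <- function(e) {
      m <- e$speed_mode_kmh * iv / 3.6      # km/h -> m per interval
      state_emission(m, e$speed_cv * m, e$angle_mean, e$angle_concentration)
    }
    gear_profile(p$gear,
                 fishing = mk_em(p$fishing),
                 non_fishing = mk_em(p$non_fishing),
                 A = if (is.matrix(p$A)) p$A
                     else matrix(unlist(p$A), 2, 2, byrow = TRUE),
                 trip_duration_range_h = p$trip_duration_range_h,
                 min_fishing_event_s = p$min_fishing_event_s,
                 start_area = p$start_area,
                 heading_persistence = p$heading_persistence,
                 reference_interval_s = iv)
  })
  out[GEAR_CODES]
}

#' Fleet composition matching the study design
#'
#' @return Named integer vector of trips per gear (sums to 99).
#' @export
default_fleet_counts <- function() {
  c(SCG = 10L, SG = 14L, MCG = 12L, PS = 32L, HL = 12L, LL = 8L, BG = 11L)
}

# State chain as alternating geometric runs; fishing runs are drawn from the
# geometric distribution conditioned on >= min_run (memoryless shift), which
# is the closed form of resampling runs shorter than the minimum. If the
# remaining trip cannot hold a full fishing run, it is filled with transit so
# the minimum-event invariant also holds at the trip end.
simulate_state_chain <- function(n, A, min_run, initial_state = NULL) {
  p_exit <- c(A[1, 2], A[2, 1])      # 1 = fishing, 2 = non-fishing
  state <- if (!is.null(initial_state)) initial_state
           else sample.int(2, 1, prob = stationary_distribution(A))
  out <- integer(0)
  while (length(out) < n) {
    remaining <- n - length(out)
    if (state == 1L) {
      if (remaining < min_run && length(out) > 0) {
        out <- c(out, rep(2L, remaining))   # no room for a legal fishing run
        break
      }
      run <- if (p_exit[1] <= 0) remaining
             else min_run + rgeom(1, p_exit[1])
      run <- min(run, remaining)
      out <- c(out, rep(1L, run))
      state <- 2L
    } else {
      run <- if (p_exit[2] <= 0) remaining
             else 1 + rgeom(1, p_exit[2])
      run <- min(run, remaining)
      out <- c(out, rep(2L, run))
      state <- 1L
    }
  }
  out[seq_len(n)]
}

#' Simulate one labelled trip
#'
#' Draws the trip duration uniformly from the profile's range, simulates the
#' fishing/non-fishing chain at the 5-s reference interval (initial state from
#' the stationary distribution of `A`, fishing runs constrained to the
#' profile's minimum event duration), draws state-conditional steps (gamma)
#' and turning angles (von Mises), and integrates positions by dead reckoning
#' from a uniform start point in the profile's near-equatorial start area.
#' Coarser `interval_s` (a multiple of the reference) is produced by
#' decimating the reference-interval simulation, so decimation experiments see
#' internally consistent dynamics. Fully reproducible from `seed`.
#'
#' The returned trip carries per-fix labels; the per-interval truth is in
#' `$truth` and an `audit` attribute reports realized transition frequencies
#' (the minimum-event constraint makes realized exit rates slightly lower than
#' nominal `A`).
#'
#' @param profile A [gear_profile()].
#' @param seed Integer seed.
#' @param interval_s Output interval, multiple of the reference interval.
#' @param trip_id Identifier (default derived from gear and seed).
#' @param initial_state Force the starting state (1 = fishing,
#'   2 = non-fishing); default draws from the stationary distribution.
#' @return A `"fish_trip"` with extra element `truth` (a [state_sequence()]
#'   per observation interval), attributes `interval_s`, `seed`, `audit`.
#' @export
simulate_trip <- function(profile, seed, interval_s = 5, trip_id = NULL,
                          initial_state = NULL) {
  iv <- profile$reference_interval_s
  stopifnot(interval_s %% iv == 0)
  set.seed(seed)
  dur_h <- runif(1, profile$trip_duration_range_h[1],
                 profile$trip_duration_range_h[2])
  n <- round(dur_h * 3600 / iv)        # observation intervals at reference
  if (n < 10) stop("trip too short: ", n, " intervals (< 10)")
  min_run <- max(1L, ceiling(profile$min_fishing_event_s / iv))
  q <- simulate_state_chain(n, profile$A, min_run, initial_state)
  ems <- list(profile$fishing, profile$non_fishing)
  step <- numeric(n); turn <- numeric(n)
  for (j in 1:2) {
    idx <- which(q == j)
    if (length(idx) > 0) {
      step[idx] <- rgamma(length(idx), shape = gamma_shape(ems[[j]]),
                          rate = gamma_rate(ems[[j]]))
      turn[idx] <- rvonmises(length(idx), ems[[j]]$angle_mean,
                             ems[[j]]$angle_concentration)
    }
  }
  # headings: measured turning angle is bearing_in - bearing_out (left turn
  # positive), so each new heading subtracts the drawn turn
  h0 <- runif(1, -pi, pi)
  heading <- h0 - c(0, cumsum(turn[-1]))
  lat0 <- runif(1, profile$start_area$lat[1], profile$start_area$lat[2])
  lon0 <- runif(1, profile$start_area$lon[1], profile$start_area$lon[2])
  # equirectangular dead reckoning; start areas are near-equatorial and trips
  # short enough that the deviation from exact spherical integration is
  # negligible (see the methods vignette)
  coslat <- cos(deg2rad(lat0))
  lat <- lat0 + c(0, cumsum(step * cos(heading))) / EARTH_RADIUS_M * 180 / pi
  lon <- lon0 + c(0, cumsum(step * sin(heading))) / (EARTH_RADIUS_M * coslat) *
    180 / pi
  t0 <- as.POSIXct("2014-01-01 06:00:00", tz = "UTC") + (seed %% 10000) * 3600
  times <- t0 + seq(0, by = iv, length.out = n + 1)
  labels <- STATE_NAMES[q]
  if (is.null(trip_id))
    trip_id <- sprintf("%s_sim%06d", profile$gear %||% "XX", seed %% 1000000)
  trip <- new_trip(trip_id, times, lat, lon, gear = profile$gear,
                   fix_labels = c(labels, labels[n]), interval_s = iv)
  factor <- interval_s / iv
  if (factor > 1) {
    trip <- decimate(trip, factor)
    labels <- decimate_labels(labels, factor)
  }
  trip$truth <- state_sequence(trip_id, labels)
  tt <- table(factor(q[-n], 1:2), factor(q[-1], 1:2))
  attr(trip, "audit") <- list(
    realized_transition_freq = unname(as.matrix(tt / pmax(rowSums(tt), 1))),
    n_reference_intervals = n,
    duration_h = dur_h)
  attr(trip, "seed") <- seed
  attr(trip, "profile_gear") <- profile$gear
  trip
}

#' Aggregate per-base-interval labels to a coarser grid
#'
#' Coarse interval t spans base intervals `(t-1)*factor + 1 ... t*factor`; the
#' coarse label is the majority vote over those, ties going to the label of
#' the first covered base interval.
#'
#' @param labels Character vector of base-interval labels.
#' @param factor Integer decimation factor.
#' @return Character vector of coarse-interval labels.
#' @export
decimate_labels <- function(labels, factor) {
  if (factor == 1) return(labels)
  m <- length(labels) + 1L             # fixes at base interval
  n_coarse <- length(seq(1L, m, by = factor)) - 1L
  vapply(seq_len(n_coarse), function(t) {
    block <- labels[((t - 1) * factor + 1):(t * factor)]
    block <- block[!is.na(block)]
    if (length(block) == 0) return(NA_character_)
    tab <- table(block)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1) winners else block[block %in% winners][1]
  }, character(1))
}

#' Simulate a whole fleet
#'
#' Per-trip seeds are derived deterministically from `master_seed`, so the
#' same master seed always yields the identical fleet. Default composition
#' mirrors the 99-trip study design.
#'
#' @param profiles Named list of profiles (default [default_gear_profiles()]).
#' @param n_trips_per_gear Named counts (default [default_fleet_counts()]).
#' @param master_seed Integer master seed.
#' @param interval_s Output interval, seconds.
#' @return List of simulated trips (see [simulate_trip()]).
#' @export
simulate_fleet <- function(profiles = default_gear_profiles(),
                           n_trips_per_gear = default_fleet_counts(),
                           master_seed = 1, interval_s = 5) {
  stopifnot(all(n_trips_per_gear >= 1),
            all(names(n_trips_per_gear) %in% names(profiles)))
  trips <- list()
  k <- 0L
  for (g in names(n_trips_per_gear)) {
    for (i in seq_len(n_trips_per_gear[[g]])) {
      k <- k + 1L
      seed <- (master_seed * 7919L + k * 104729L) %% 2147483647L
      trips[[k]] <- simulate_trip(profiles[[g]], seed = seed,
                                  interval_s = interval_s,
                                  trip_id = sprintf("%s_%02d", g, i))
    }
  }
  trips
}

#' Inject GPS artifacts into a simulated trip
#'
#' Adds position spikes (displacements implying speeds far above the 50 km/h
#' filter) and recording gaps (deleted runs of fixes), the two artifact types
#' the cleaning rules target. Spike positions are never the first fix and
#' never adjacent to one another, so a single forward speed-filter sweep
#' removes exactly the spikes.
#'
#' @param trip A simulated (regular) trip.
#' @param spike_rate,gap_rate Rates in `[0, 1)`: expected fraction of fixes
#'   turned into spikes / removed inside gaps.
#' @param seed Integer seed.
#' @param gap_len_range Gap lengths in fixes (default 15–40, i.e. 75–200 s of
#'   dropout at the 5-s reference).
#' @return The corrupted trip (truth and labels dropped); attribute `audit`
#'   lists spike indices and gap windows.
#' @export
corrupt_track <- function(trip, spike_rate = 0, gap_rate = 0, seed = 1,
                          gap_len_range = c(15, 40)) {
  stopifnot(spike_rate >= 0, spike_rate < 1, gap_rate >= 0, gap_rate < 1)
  set.seed(seed)
  f <- trip$fixes
  n <- nrow(f)
  n_spikes <- floor(spike_rate * n)
  spike_idx <- integer(0)
  if (n_spikes > 0) {
    cand <- sample(2:n, min(n_spikes * 3, n - 1))
    for (i in cand) {
      if (length(spike_idx) >= n_spikes) break
      if (!any(abs(spike_idx - i) <= 1)) spike_idx <- c(spike_idx, i)
    }
    for (i in spike_idx) {
      b <- runif(1, -pi, pi)
      d <- runif(1, 500, 2000)        # >= 500 m in 5 s: >> 50 km/h
      p <- destination_point(f$lat[i], f$lon[i], b, d)
      f$lat[i] <- p$lat; f$lon[i] <- p$lon
    }
  }
  gaps <- list()
  keep <- rep(TRUE, n)
  n_gap_fixes <- floor(gap_rate * n)
  while (n_gap_fixes > 0) {
    len <- min(n_gap_fixes, sample(gap_len_range[1]:gap_len_range[2], 1))
    start <- sample(2:(n - len), 1)
    keep[start:(start + len - 1)] <- FALSE
    gaps[[length(gaps) + 1]] <- c(start = start, length = len)
    n_gap_fixes <- n_gap_fixes - len
  }
  out <- new_trip(trip$trip_id, f$time[keep], f$lat[keep], f$lon[keep],
                  gear = trip$gear, landing_site_id = trip$landing_site_id)
  attr(out, "audit") <- list(spike_idx = sort(spike_idx), gaps = gaps,
                             n_spikes = length(spike_idx),
                             n_removed_in_gaps = sum(!keep))
  out
}
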