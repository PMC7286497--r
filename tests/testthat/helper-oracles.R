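# Test helpers: independent brute-force oracles and small fixture builders.
# The oracles deliberately recompute everything from first principles
# (stats::dgamma, the von Mises formula, explicit path enumeration) so they
# share no code path with the implementation they check.

R_EARTH <- 6371000

# Build a step_series directly from raw observation vectors.
make_series <- function(step, angle = NULL, interval_s = 5, trip_id = "fix",
                        gear = NA_character_) {
  n <- length(step)
  if (is.null(angle)) angle <- rep(0, max(0, n - 1))
  stopifnot(length(angle) == n - 1)
  structure(list(trip_id = trip_id, gear = gear, interval_s = interval_s,
                 times = as.POSIXct(seq(0, by = interval_s,
                                        length.out = n + 1),
                                    tz = "UTC", origin = "1970-01-01"),
                 step = step, angle = angle),
            class = "step_series")
}

# A trip from explicit coordinates at given epoch seconds.
make_trip <- function(t_s, lat, lon, trip_id = "t", gear = NA_character_,
                      ...) {
  new_trip(trip_id, as.POSIXct(t_s, tz = "UTC", origin = "1970-01-01"),
           lat, lon, gear = gear, ...)
}

# Independent per-observation log-emission matrix (oracle side).
oracle_log_emissions <- function(params, series) {
  obs_step <- series$step
  obs_step[!is.na(obs_step) & obs_step <= 0] <- NA
  obs_angle <- c(NA, series$angle)
  Tn <- length(obs_step)
  N <- params$n_states
  le <- matrix(0, Tn, N)
  for (j in seq_len(N)) {
    e <- params$emissions[[j]]
    sh <- (e$step_mean / e$step_sd)^2
    ra <- e$step_mean / e$step_sd^2
    ok <- !is.na(obs_step)
    le[ok, j] <- le[ok, j] + stats::dgamma(obs_step[ok], shape = sh,
                                           rate = ra, log = TRUE)
    ok <- !is.na(obs_angle)
    k <- e$angle_concentration
    le[ok, j] <- le[ok, j] + k * cos(obs_angle[ok] - e$angle_mean) -
      log(2 * pi) - (log(besselI(k, 0, expon.scaled = TRUE)) + k)
  }
  le
}

# Exhaustive path enumeration: joint log-probability of every state path.
enum_path_logprobs <- function(params, series) {
  le <- oracle_log_emissions(params, series)
  Tn <- nrow(le)
  N <- params$n_states
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  apply(paths, 1, function(q) {
    lp <- log(params$pi[q[1]]) + le[1, q[1]]
    if (Tn >= 2)
      for (t in 2:Tn) lp <- lp + log(params$A[q[t - 1], q[t]]) + le[t, q[t]]
    lp
  }) -> lp
  list(paths = paths, logprobs = lp)
}

enum_forward <- function(params, series) {
  lp <- enum_path_logprobs(params, series)$logprobs
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

enum_viterbi <- function(params, series) {
  e <- enum_path_logprobs(params, series)
  best <- which.max(e$logprobs)   # expand.grid orders lower indices first,
                                  # matching the decoder's tie rule
  list(path = as.integer(e$paths[best, ]), log_joint = e$logprobs[best])
}

# Random two-state parameter set with well-behaved values.
random_params <- function() {
  A <- matrix(runif(4, 0.05, 0.95), 2)
  A <- A / rowSums(A)
  pi0 <- runif(2, 0.05, 0.95); pi0 <- pi0 / sum(pi0)
  ems <- list(
    state_emission(runif(1, 2, 20), runif(1, 1, 10),
                   runif(1, -pi, pi), runif(1, 0, 3)),
    state_emission(runif(1, 25, 80), runif(1, 5, 30),
                   runif(1, -pi, pi), runif(1, 0, 10)))
  hmm_parameters(pi0, A, ems)
}

# Random short observation series (positive steps, wrapped angles, a few
# missing values when allow_na).
random_series <- function(Tn = 8, allow_na = FALSE) {
  step <- exp(runif(Tn, 0, 4.5))
  angle <- runif(Tn - 1, -pi, pi)
  if (allow_na && Tn > 3) {
    step[sample(Tn, 1)] <- NA
    angle[sample(Tn - 1, 1)] <- NA
  }
  make_series(step, angle)
}

# Well-separated two-state profile used by recovery tests (step-mean ratio 10,
# diagonal transitions 0.95, no minimum-event constraint).
recovery_profile <- function(n_intervals = 1000) {
  gear_profile(NA_character_,
               fishing = state_emission(5, 3, 0, 1),
               non_fishing = state_emission(50, 25, 0, 8),
               A = matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE),
               trip_duration_range_h = rep(n_intervals * 5 / 3600, 2),
               min_fishing_event_s = 0)
}
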