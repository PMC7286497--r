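# Likelihood, fitting, decoding and diagnostics for the two-state (N-state
# capable) gamma / von Mises movement HMM.
#
# Observation model: at interval t the observation is the pair
# (step_t, angle_t); step and angle are conditionally independent given the
# state, so b_j(o_t) = f_gamma(step_t) * f_vonMises(angle_t). A missing
# component contributes likelihood factor 1. Exact zero steps are invalid for
# the gamma density and are flagged missing for the step emission (the angle
# there is already missing by construction).

# StepSeries -> T x 2 observation matrix (step, angle), NA = missing.
# Observation t pairs step t with the turning angle at the fix where that
# step starts (the first interval has no angle).
obs_matrix <- function(series) {
  step <- series$step
  step[!is.na(step) & step <= 0] <- NA_real_
  Tn <- length(step)
  angle <- rep(NA_real_, Tn)
  if (Tn >= 2 && length(series$angle) > 0)
    angle[seq_along(series$angle) + 1L] <- series$angle
  cbind(step = step, angle = angle)
}

# T x N log-emission matrix for an observation matrix.
log_emission_matrix <- function(params, obs) {
  Tn <- nrow(obs)
  le <- matrix(0, Tn, params$n_states)
  s_ok <- !is.na(obs[, 1])
  a_ok <- !is.na(obs[, 2])
  for (j in seq_len(params$n_states)) {
    em <- params$emissions[[j]]
    if (any(s_ok))
      le[s_ok, j] <- le[s_ok, j] +
        gamma_logpdf(obs[s_ok, 1], em$step_mean, em$step_sd)
    if (any(a_ok))
      le[a_ok, j] <- le[a_ok, j] +
        vonmises_logpdf(obs[a_ok, 2], em$angle_mean, em$angle_concentration)
  }
  le
}

as_series_list <- function(series) {
  if (inherits(series, "step_series")) list(series) else series
}

check_params_finite <- function(params) {
  vals <- c(params$pi, params$A,
            unlist(lapply(params$emissions, function(e)
              c(e$step_mean, e$step_sd, e$angle_mean, e$angle_concentration))))
  if (any(!is.finite(vals))) stop("non-finite HMM parameter")
  invisible(TRUE)
}

#' Forward log-likelihood
#'
#' Log probability of the observed step/angle series under the model, summed
#' over all state paths by the log-space forward recursion. Missing
#' observations (including exact zero steps) contribute likelihood factor 1,
#' so a series with every observation missing has log-likelihood 0.
#'
#' @param params [hmm_parameters()].
#' @param series A single [steps_and_angles()] series or a list of them
#'   (log-likelihoods add across series).
#' @return Scalar log-likelihood.
#' @export
forward_loglik <- function(params, series) {
  check_params_finite(params)
  logA <- log(params$A)
  logpi <- log(params$pi)
  sum(vapply(as_series_list(series), function(s) {
    obs <- obs_matrix(s)
    if (nrow(obs) == 0) return(0)
    forward_loglik_cpp(log_emission_matrix(params, obs), logA, logpi)
  }, numeric(1)))
}

#' Viterbi decoding
#'
#' Most probable state path given the parameters. Ties in the backtracking
#' are broken toward the lower state index, so decodes are reproducible.
#'
#' @param params [hmm_parameters()].
#' @param series One [steps_and_angles()] series.
#' @return A `"state_sequence"`: list with `trip_id`, `labels` (one per
#'   observation interval) and `log_joint`, the log probability of the
#'   decoded path.
#' @export
viterbi_decode <- function(params, series) {
  check_params_finite(params)
  obs <- obs_matrix(series)
  Tn <- nrow(obs)
  N <- params$n_states
  le <- log_emission_matrix(params, obs)
  logA <- log(params$A)
  delta <- log(params$pi) + le[1, ]
  psi <- matrix(0L, Tn, N)
  if (Tn >= 2) {
    for (t in 2:Tn) {
      cand <- delta + logA              # cand[i, j] = delta[i] + logA[i, j]
      best <- apply(cand, 2, which.max) # first max -> lower index on ties
      delta <- cand[cbind(best, seq_len(N))] + le[t, ]
      psi[t, ] <- best
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn >= 2)
    for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  state_sequence(series$trip_id, params$state_names[path],
                 log_joint = max(delta))
}

#' Construct a state sequence
#'
#' @param trip_id Trip identifier.
#' @param labels Character vector of per-interval state labels (NA allowed).
#' @param log_joint Optional Viterbi path log-probability.
#' @return A `"state_sequence"` list.
#' @export
state_sequence <- function(trip_id, labels, log_joint = NA_real_) {
  structure(list(trip_id = trip_id, labels = as.character(labels),
                 log_joint = log_joint),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  tab <- table(x$labels, useNA = "ifany")
  cat(sprintf("<state_sequence> %s  %d intervals (%s)\n", x$trip_id,
              length(x$labels),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

# --- moment estimators -------------------------------------------------------

# kappa from the mean resultant length (Best & Fisher approximation).
kappa_from_rbar <- function(r) {
  if (r >= 1) return(KAPPA_MAX)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  min(max(k, 0), KAPPA_MAX)
}

#' Initial parameters from labelled data
#'
#' Moment estimates from reference-labelled observations, the standard way to
#' seed the likelihood maximization: per-state step mean/sd are sample
#' moments of the labelled steps; the angle mean is the mean direction and
#' kappa is recovered from the mean resultant length; `A` holds the empirical
#' transition frequencies between consecutive labels; `pi` the empirical
#' frequencies of each series' first label.
#'
#' @param series A [steps_and_angles()] series or list of them.
#' @param labels Matching [state_sequence()] (or list), one label per
#'   observation interval.
#' @param state_names States to estimate; every state must have >= 2 labelled
#'   step observations.
#' @return [hmm_parameters()].
#' @export
initial_params_from_labels <- function(series, labels,
                                       state_names = STATE_NAMES) {
  series <- as_series_list(series)
  if (inherits(labels, "state_sequence")) labels <- list(labels)
  stopifnot(length(series) == length(labels))
  N <- length(state_names)
  steps <- setNames(vector("list", N), state_names)
  angs <- setNames(vector("list", N), state_names)
  trans <- matrix(0, N, N, dimnames = list(state_names, state_names))
  first <- setNames(numeric(N), state_names)
  for (k in seq_along(series)) {
    obs <- obs_matrix(series[[k]])
    lab <- labels[[k]]$labels
    if (length(lab) != nrow(obs))
      stop("trip '", series[[k]]$trip_id, "': labels (", length(lab),
           ") not aligned with observation intervals (", nrow(obs), ")")
    bad <- setdiff(unique(lab[!is.na(lab)]), state_names)
    if (length(bad) > 0) stop("unknown state label(s): ",
                              paste(bad, collapse = ", "))
    for (s in state_names) {
      steps[[s]] <- c(steps[[s]], obs[!is.na(lab) & lab == s, 1])
      angs[[s]] <- c(angs[[s]], obs[!is.na(lab) & lab == s, 2])
    }
    if (!is.na(lab[1])) first[lab[1]] <- first[lab[1]] + 1
    if (length(lab) >= 2) {
      from <- lab[-length(lab)]; to <- lab[-1]
      ok <- !is.na(from) & !is.na(to)
      if (any(ok)) {
        tt <- table(factor(from[ok], state_names), factor(to[ok], state_names))
        trans <- trans + as.matrix(tt)
      }
    }
  }
  ems <- lapply(state_names, function(s) {
    x <- steps[[s]][!is.na(steps[[s]])]
    if (length(x) < 2)
      stop("state '", s, "' has fewer than 2 labelled step observations")
    a <- angs[[s]][!is.na(angs[[s]])]
    if (length(a) >= 2) {
      C <- mean(cos(a)); S <- mean(sin(a))
      mu <- atan2(S, C)
      kap <- kappa_from_rbar(sqrt(C^2 + S^2))
    } else {
      mu <- 0; kap <- 0
    }
    state_emission(mean(x), sd(x), mu, kap)
  })
  rs <- rowSums(trans)
  A <- trans
  for (i in seq_len(N))
    A[i, ] <- if (rs[i] > 0) trans[i, ] / rs[i] else 1 / N
  pi0 <- if (sum(first) > 0) first / sum(first) else rep(1 / N, N)
  hmm_parameters(pi0, A, ems, state_names = state_names)
}

# --- unconstrained reparameterization ---------------------------------------

# Working vector layout: per state [log step_mean, log step_sd,
# kappa*cos(mu), kappa*sin(mu)], then row-wise off-diagonal logits of A
# (reference = diagonal), then (unless stationary pi) logits of pi
# (reference = state 1).
pack_params <- function(params, stationary_pi = FALSE) {
  N <- params$n_states
  w <- c()
  for (em in params$emissions)
    w <- c(w, log(em$step_mean), log(em$step_sd),
           em$angle_concentration * cos(em$angle_mean),
           em$angle_concentration * sin(em$angle_mean))
  clamp <- function(x) pmin(pmax(x, -30), 30)
  for (i in seq_len(N)) {
    ref <- max(params$A[i, i], 1e-300)
    w <- c(w, clamp(log(pmax(params$A[i, -i], 1e-300) / ref)))
  }
  if (!stationary_pi) {
    ref <- max(params$pi[1], 1e-300)
    w <- c(w, clamp(log(pmax(params$pi[-1], 1e-300) / ref)))
  }
  w
}

unpack_params <- function(w, N, state_names, stationary_pi = FALSE) {
  ems <- vector("list", N)
  idx <- 1
  for (j in seq_len(N)) {
    x <- w[idx + 2]; y <- w[idx + 3]
    kap <- min(sqrt(x^2 + y^2), KAPPA_MAX)
    mu <- if (kap > 0) atan2(y, x) else 0
    ems[[j]] <- state_emission(exp(w[idx]), exp(w[idx + 1]), mu, kap)
    idx <- idx + 4
  }
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    eta <- w[idx:(idx + N - 2)]
    idx <- idx + N - 1
    e <- exp(pmin(eta, 300))
    row <- numeric(N)
    row[i] <- 1 / (1 + sum(e))
    row[-i] <- e / (1 + sum(e))
    A[i, ] <- row
  }
  if (stationary_pi) {
    pi0 <- stationary_distribution(A)
  } else {
    eta <- w[idx:(idx + N - 2)]
    e <- exp(pmin(eta, 300))
    pi0 <- c(1, e) / (1 + sum(e))
  }
  hmm_parameters(pi0, A, ems, state_names = state_names)
}

jitter_working <- function(w, N, stationary_pi) {
  # +/-20% multiplicative jitter on positive scalars (additive on the log
  # scale), Dirichlet resampling of the simplex blocks.
  n_em <- 4 * N
  w2 <- w
  w2[seq_len(n_em)] <- w[seq_len(n_em)] + log(1 + runif(n_em, -0.2, 0.2))
  idx <- n_em + 1
  for (i in seq_len(N)) {
    eta <- w[idx:(idx + N - 2)]
    p <- exp(c(0, eta)); p <- p / sum(p)           # (diag, offdiag...) order
    g <- rgamma(N, shape = 50 * p + 0.2)
    p2 <- g / sum(g)
    w2[idx:(idx + N - 2)] <- log(pmax(p2[-1], 1e-12) / pmax(p2[1], 1e-12))
    idx <- idx + N - 1
  }
  if (!stationary_pi) {
    eta <- w[idx:(idx + N - 2)]
    p <- exp(c(0, eta)); p <- p / sum(p)
    g <- rgamma(N, shape = 10 * p + 0.2)
    p2 <- g / sum(g)
    w2[idx:(idx + N - 2)] <- log(pmax(p2[-1], 1e-12) / pmax(p2[1], 1e-12))
  }
  w2
}

#' Fit the HMM by direct likelihood maximization
#'
#' Maximizes the summed forward log-likelihood over the pooled series (one
#' model per gear is the intended use) with quasi-Newton optimization on an
#' unconstrained reparameterization: log for positive scalars, the pair
#' `(kappa cos mu, kappa sin mu)` for the angle parameters, and additive-logit
#' rows for `A` and `pi`. `n_restarts` jittered restarts guard against local
#' optima; the first start is the unjittered initializer, so the returned
#' log-likelihood never falls below the initializer's. After fitting, states
#' are relabelled so that the first state name (by convention `"fishing"`)
#' belongs to the smallest step mean — fishing movement is slow and sinuous.
#'
#' @param series A [steps_and_angles()] series or list of them.
#' @param init Initial [hmm_parameters()], typically from
#'   [initial_params_from_labels()].
#' @param n_restarts Number of starts (default 3): start 1 is `init`, later
#'   starts are jittered.
#' @param stationary_pi Tie `pi` to the stationary distribution of `A` instead
#'   of estimating it freely (default `FALSE`).
#' @param seed Seed for the restart jitter (restart k uses `seed + k`).
#' @param maxit,reltol Passed to [stats::optim()] (BFGS).
#' @return A `"fish_hmm_fit"` list: `params`, `loglik`, `init_loglik`,
#'   `converged`, `restarts` (per-start diagnostics), `n_obs`.
#' @export
fit_hmm <- function(series, init, n_restarts = 3, stationary_pi = FALSE,
                    seed = 1, maxit = 300, reltol = 1e-9) {
  series <- as_series_list(series)
  N <- init$n_states
  state_names <- init$state_names
  obs_list <- lapply(series, obs_matrix)
  obs_list <- obs_list[vapply(obs_list, nrow, integer(1)) > 0]
  if (length(obs_list) == 0) stop("no observations to fit")
  negll <- function(w) {
    p <- try(unpack_params(w, N, state_names, stationary_pi), silent = TRUE)
    if (inherits(p, "try-error")) return(1e100)
    logA <- log(p$A); logpi <- log(p$pi)
    # exploration steps may propose emission params where dgamma warns (NaN);
    # those points are rejected via the 1e100 barrier
    ll <- suppressWarnings(sum(vapply(obs_list, function(obs)
      forward_loglik_cpp(log_emission_matrix(p, obs), logA, logpi),
      numeric(1))))
    if (!is.finite(ll)) 1e100 else -ll
  }
  w0 <- pack_params(init, stationary_pi)
  init_ll <- -negll(w0)
  best <- NULL
  restarts <- list()
  for (k in seq_len(n_restarts)) {
    wk <- if (k == 1) w0 else {
      set.seed(seed + k)
      jitter_working(w0, N, stationary_pi)
    }
    res <- try(optim(wk, negll, method = "BFGS",
                     control = list(maxit = maxit, reltol = reltol)),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      restarts[[k]] <- list(value = NA_real_, convergence = NA_integer_,
                            error = attr(res, "condition")$message)
      next
    }
    restarts[[k]] <- list(value = -res$value, convergence = res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("optimizer failed on all restarts; initial loglik was ", init_ll)
  fitted <- unpack_params(best$par, N, state_names, stationary_pi)
  # relabel: order states by step mean so state_names[1] is the slow state
  means <- vapply(fitted$emissions, function(e) e$step_mean, numeric(1))
  o <- order(means)
  fitted <- hmm_parameters(fitted$pi[o], fitted$A[o, o, drop = FALSE],
                           fitted$emissions[o], state_names = state_names)
  # identifiability: near-identical emissions leave A essentially flat
  if (N == 2) {
    e1 <- fitted$emissions[[1]]; e2 <- fitted$emissions[[2]]
    rel <- abs(e1$step_mean - e2$step_mean) /
      max(e1$step_mean, e2$step_mean)
    if (rel < 1e-3)
      warning("state emission distributions are nearly identical; ",
              "the likelihood is flat in the transition matrix ",
              "(unidentifiable states)")
  }
  structure(list(params = fitted, loglik = -best$value, init_loglik = init_ll,
                 converged = best$convergence == 0,
                 restarts = restarts,
                 n_obs = sum(vapply(obs_list, nrow, integer(1)))),
            class = "fish_hmm_fit")
}

#' @export
print.fish_hmm_fit <- function(x, ...) {
  cat(sprintf("<fish_hmm_fit> loglik %.3f (init %.3f), %d obs, converged: %s\n",
              x$loglik, x$init_loglik, x$n_obs, x$converged))
  print(x$params)
  invisible(x)
}

#' One-step-ahead pseudo-residuals
#'
#' Each observation is pushed through its one-step-ahead forecast CDF under
#' the model (state weights `P(q_t | o_{1:t-1})` from the normalized forward
#' recursion) and then through the standard normal quantile. Under a correctly
#' specified model the residuals are standard normal. Returned separately for
#' steps and angles; missing observations yield missing residuals.
#'
#' @param params [hmm_parameters()].
#' @param series One [steps_and_angles()] series.
#' @return List with numeric vectors `step` and `angle` (length = number of
#'   observation intervals).
#' @export
pseudo_residuals <- function(params, series) {
  check_params_finite(params)
  obs <- obs_matrix(series)
  Tn <- nrow(obs)
  N <- params$n_states
  le <- log_emission_matrix(params, obs)
  shapes <- vapply(params$emissions, gamma_shape, numeric(1))
  rates <- vapply(params$emissions, gamma_rate, numeric(1))
  r_step <- r_angle <- rep(NA_real_, Tn)
  phi <- params$pi                     # filtered P(q_{t-1} | o_{1:t-1})
  for (t in seq_len(Tn)) {
    w <- if (t == 1) params$pi else as.numeric(phi %*% params$A)
    if (!is.na(obs[t, 1])) {
      u <- sum(w * pgamma(obs[t, 1], shape = shapes, rate = rates))
      r_step[t] <- qnorm(min(max(u, 1e-15), 1 - 1e-15))
    }
    if (!is.na(obs[t, 2])) {
      u <- sum(w * vapply(seq_len(N), function(j)
        vonmises_cdf(obs[t, 2], params$emissions[[j]]$angle_mean,
                     params$emissions[[j]]$angle_concentration),
        numeric(1)))
      r_angle[t] <- qnorm(min(max(u, 1e-15), 1 - 1e-15))
    }
    a <- log(w) + le[t, ]
    m <- max(a)
    phi <- if (is.finite(m)) exp(a - m) / sum(exp(a - m)) else rep(1 / N, N)
  }
  list(step = r_step, angle = r_angle)
}

#' Simulate an observation series directly from HMM parameters
#'
#' Draws a state chain from `pi` and `A` and state-conditional steps (gamma)
#' and angles (von Mises). Intended for model checking and tests; for
#' position-level simulation of whole trips see [simulate_trip()].
#'
#' @param params [hmm_parameters()].
#' @param n_intervals Number of observation intervals.
#' @param interval_s Nominal interval, seconds (metadata only).
#' @param seed Optional seed.
#' @param trip_id Identifier for the resulting series.
#' @return List with `series` (a `"step_series"`) and `states` (a
#'   [state_sequence()] of the true states).
#' @export
simulate_series <- function(params, n_intervals, interval_s = 5, seed = NULL,
                            trip_id = "sim") {
  if (!is.null(seed)) set.seed(seed)
  N <- params$n_states
  q <- integer(n_intervals)
  q[1] <- sample.int(N, 1, prob = params$pi)
  for (t in seq_len(n_intervals - 1))
    q[t + 1] <- sample.int(N, 1, prob = params$A[q[t], ])
  shapes <- vapply(params$emissions, gamma_shape, numeric(1))
  rates <- vapply(params$emissions, gamma_rate, numeric(1))
  step <- rgamma(n_intervals, shape = shapes[q], rate = rates[q])
  angle <- vapply(q, function(j)
    rvonmises_1(params$emissions[[j]]$angle_mean,
                params$emissions[[j]]$angle_concentration), numeric(1))
  series <- structure(
    list(trip_id = trip_id, gear = NA_character_, interval_s = interval_s,
         times = as.POSIXct(seq(0, by = interval_s, length.out = n_intervals + 1),
                            tz = "UTC", origin = "1970-01-01"),
         step = step, angle = angle[-1]),
    class = "step_series")
  list(series = series,
       states = state_sequence(trip_id, params$state_names[q]))
}

# Single von Mises draw (Best & Fisher rejection sampler).
rvonmises_1 <- function(mu, kappa) {
  if (kappa < 1e-8) return(runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- sign(u[3] - 0.5) * acos(f)
      return(wrap_angle(mu + theta))
    }
  }
}

# Vectorized von Mises sampling by state (used by the trip simulator).
rvonmises <- function(n, mu, kappa) {
  vapply(seq_len(n), function(i) rvonmises_1(mu, kappa), numeric(1))
}
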