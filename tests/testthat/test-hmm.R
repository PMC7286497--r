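# Emission densities, forward/Viterbi against enumeration oracles, moment
# initialization, fitting, pseudo-residuals, stationary distribution.

test_that("gamma_logpdf: exponential reduction, normalization, mode", {
  # mean = sd -> shape 1 (exponential with rate 1/mean); at x = mean the
  # log-density is log(rate) - 1
  m <- 120
  expect_equal(gamma_logpdf(m, m, m), log(1 / m) - 1, tolerance = 1e-12)

  # quadrature oracle: density integrates to 1
  q <- integrate(function(x) exp(gamma_logpdf(x, 300, 150)), 0, 200 * 300,
                 rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)

  # closed-form mode (shape-1)/rate vs grid argmax for shape > 1
  mean <- 300; sd <- 150
  shape <- (mean / sd)^2; rate <- mean / sd^2
  grid <- seq(1, 1200, by = 0.25)
  expect_equal(grid[which.max(gamma_logpdf(grid, mean, sd))],
               (shape - 1) / rate, tolerance = 1e-3)
})

test_that("vonmises_logpdf: uniform limit, symmetry, normalization", {
  th <- seq(-pi, pi, length.out = 7)
  expect_equal(vonmises_logpdf(th, 0.3, 0), rep(log(1 / (2 * pi)), 7))
  mu <- 0.7; d <- 1.1
  expect_equal(vonmises_logpdf(mu + d, mu, 3), vonmises_logpdf(mu - d, mu, 3))
  q <- integrate(function(x) exp(vonmises_logpdf(x, 0.5, 2)), -pi, pi,
                 rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
  # large kappa stays finite
  expect_true(is.finite(vonmises_logpdf(0.01, 0, 700)))
})

test_that("vonmises_cdf matches a quadrature oracle", {
  cases <- list(c(mu = 0.5, kappa = 2), c(mu = -2.5, kappa = 5),
                c(mu = 3.0, kappa = 0.3), c(mu = 0, kappa = 120))
  for (cs in cases) {
    for (th in c(-3, -1.2, 0, 0.4, 2.9)) {
      oracle <- integrate(function(x) exp(vonmises_logpdf(x, cs["mu"],
                                                          cs["kappa"])),
                          -pi, th, rel.tol = 1e-10)$value
      # absolute comparison: deep tails underflow to 0 in the series form
      expect_lt(abs(vonmises_cdf(th, cs[["mu"]], cs[["kappa"]]) - oracle),
                1e-7,
                label = sprintf("cdf(mu=%g,k=%g,th=%g)",
                                cs[["mu"]], cs[["kappa"]], th))
    }
  }
  expect_equal(vonmises_cdf(pi, 1.2, 4), 1)
  expect_equal(vonmises_cdf(-pi, 1.2, 4), 0)
})

test_that("forward_loglik: closed form at T=1, enumeration at T=8, missing contract", {
  set.seed(41)
  p <- random_params()
  s1 <- random_series(1)
  le <- oracle_log_emissions(p, s1)
  expect_equal(forward_loglik(p, s1),
               log(sum(p$pi * exp(le[1, ]))), tolerance = 1e-12)

  for (i in 1:5) {
    p <- random_params()
    s <- random_series(8, allow_na = TRUE)
    expect_equal(forward_loglik(p, s), enum_forward(p, s),
                 tolerance = 1e-10)
  }

  # all observations missing -> loglik 0 (every path has emission likelihood 1)
  s_na <- make_series(rep(NA_real_, 6), rep(NA_real_, 5))
  expect_equal(forward_loglik(random_params(), s_na), 0)

  # zero steps are treated as missing, not -Inf
  s0 <- make_series(c(0, 10, 0), c(NA, NA))
  expect_true(is.finite(forward_loglik(random_params(), s0)))

  # non-finite parameter rejected
  p_bad <- random_params()
  p_bad$emissions[[1]]$step_mean <- Inf
  expect_error(forward_loglik(p_bad, random_series(4)), "non-finite")
})

test_that("viterbi_decode matches the enumeration argmax and its score", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_params()
    s <- random_series(8, allow_na = TRUE)
    v <- viterbi_decode(p, s)
    o <- enum_viterbi(p, s)
    expect_equal(v$labels, p$state_names[o$path])
    expect_equal(v$log_joint, o$log_joint, tolerance = 1e-10)
    # the single-path score can never exceed the total likelihood
    expect_lte(v$log_joint, forward_loglik(p, s) + 1e-12)
  }
})

test_that("an absorbing chain decodes to its start state regardless of data", {
  p <- hmm_parameters(c(1, 0), diag(2),
                      list(state_emission(5, 3), state_emission(50, 20)))
  s <- make_series(c(60, 55, 40), c(0.1, -0.2))   # data favour state 2
  v <- viterbi_decode(p, s)
  expect_equal(v$labels, rep("fishing", 3))
})

test_that("likelihood and decoding are invariant under state permutation", {
  set.seed(43)
  for (i in 1:3) {
    p <- random_params()
    s <- random_series(10)
    perm <- c(2, 1)
    p2 <- hmm_parameters(p$pi[perm], p$A[perm, perm], p$emissions[perm],
                         state_names = p$state_names[perm])
    expect_equal(forward_loglik(p, s), forward_loglik(p2, s),
                 tolerance = 1e-12)
    expect_equal(viterbi_decode(p, s)$labels, viterbi_decode(p2, s)$labels)
  }
})

test_that("initial_params_from_labels recovers generator moments", {
  prof <- recovery_profile(10000)
  tr <- simulate_trip(prof, seed = 44)
  s <- steps_and_angles(tr)
  init <- initial_params_from_labels(s, tr$truth)
  truth_em <- list(prof$fishing, prof$non_fishing)
  for (j in 1:2) {
    n_j <- sum(tr$truth$labels == init$state_names[j])
    se <- truth_em[[j]]$step_sd / sqrt(n_j)
    expect_lt(abs(init$emissions[[j]]$step_mean - truth_em[[j]]$step_mean),
              3 * se)
  }
  # transition frequencies close to the (undistorted) generator matrix
  expect_lt(max(abs(init$A - prof$A)), 0.02)

  # all-one-state labels are rejected
  lab1 <- state_sequence(tr$trip_id, rep("fishing", length(s$step)))
  expect_error(initial_params_from_labels(s, lab1), "non_fishing")

  # perfectly aligned angles -> kappa capped, not infinite
  s2 <- make_series(c(10, 60, 12, 55, 9, 70), rep(0.2, 5))
  lab2 <- state_sequence("x", rep(c("fishing", "non_fishing"), 3))
  init2 <- initial_params_from_labels(list(s2), list(lab2))
  expect_lte(init2$emissions[[1]]$angle_concentration, 700)
  expect_gte(init2$emissions[[1]]$angle_concentration, 600)
})

test_that("fit_hmm improves on its initializer and flags degenerate states", {
  prof <- recovery_profile(800)
  trips <- lapply(1:2, function(i) simulate_trip(prof, seed = 50 + i))
  series <- lapply(trips, steps_and_angles)
  refs <- lapply(trips, `[[`, "truth")
  init <- initial_params_from_labels(series, refs)
  fit <- fit_hmm(series, init, n_restarts = 2)
  expect_gte(fit$loglik, fit$init_loglik - 1e-8)
  expect_true(fit$converged)
  # state identity convention: "fishing" has the smaller step mean
  expect_lt(fit$params$emissions[[1]]$step_mean,
            fit$params$emissions[[2]]$step_mean)

  # truth-initialised fit can only do better than the truth's own likelihood
  truth_params <- hmm_parameters(
    stationary_distribution(prof$A), prof$A,
    list(prof$fishing, prof$non_fishing))
  fit2 <- fit_hmm(series, truth_params, n_restarts = 1)
  expect_gte(fit2$loglik, forward_loglik(truth_params, series) - 1e-8)

  # identical emissions: unidentifiable A -> warning, not an error
  em <- state_emission(20, 10, 0, 2)
  p_flat <- hmm_parameters(c(0.5, 0.5),
                           matrix(c(0.6, 0.4, 0.4, 0.6), 2),
                           list(em, em))
  sim <- simulate_series(p_flat, 300, seed = 7)
  expect_warning(fit_hmm(list(sim$series), p_flat, n_restarts = 1,
                         maxit = 50),
                 "nearly identical")
})

test_that("stationary_distribution: symmetry, fixed point, reducibility", {
  expect_equal(stationary_distribution(matrix(c(0.9, 0.1, 0.1, 0.9), 2)),
               c(0.5, 0.5))
  expect_error(stationary_distribution(diag(2)), "reducible")
  set.seed(45)
  for (i in 1:5) {
    A <- matrix(runif(4, 0.05, 0.95), 2); A <- A / rowSums(A)
    d <- stationary_distribution(A)
    expect_equal(as.numeric(d %*% A), d, tolerance = 1e-12)
    expect_equal(sum(d), 1, tolerance = 1e-12)
  }
})

test_that("pseudo-residuals are calibrated under the true model", {
  em <- list(state_emission(5, 3, 0.2, 1), state_emission(50, 20, -0.1, 8))
  p <- hmm_parameters(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.2, 0.8), 2,
                                          byrow = TRUE), em)
  pass_step <- pass_angle <- 0
  n_rep <- 60
  for (i in 1:n_rep) {
    sim <- simulate_series(p, 200, seed = 1000 + i)
    r <- pseudo_residuals(p, sim$series)
    if (stats::shapiro.test(r$step)$p.value > 0.01) pass_step <- pass_step + 1
    if (stats::shapiro.test(r$angle[!is.na(r$angle)])$p.value > 0.01)
      pass_angle <- pass_angle + 1
  }
  expect_gte(pass_step / n_rep, 0.95)
  expect_gte(pass_angle / n_rep, 0.95)
})

test_that("pseudo-residuals flag tail observations and use pi at t = 1", {
  em <- list(state_emission(5, 3, 0, 1), state_emission(50, 20, 0, 8))
  p <- hmm_parameters(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.2, 0.8), 2,
                                          byrow = TRUE), em)
  # constant step far in the right tail of both emissions
  s <- make_series(rep(500, 5), rep(0, 4))
  r <- pseudo_residuals(p, s)
  expect_true(all(abs(r$step) > 3))

  # t = 1 residual comes from the pi-weighted forecast CDF
  s1 <- make_series(30)
  r1 <- pseudo_residuals(p, s1)
  u <- sum(p$pi * c(pgamma(30, shape = (5 / 3)^2, rate = 5 / 9),
                    pgamma(30, shape = (50 / 20)^2, rate = 50 / 400)))
  expect_equal(r1$step[1], qnorm(u), tolerance = 1e-10)

  # missing observations give missing residuals
  s2 <- make_series(c(10, NA, 12), c(0.1, NA))
  r2 <- pseudo_residuals(p, s2)
  expect_true(is.na(r2$step[2]))
})

test_that("parameter files round-trip at full double precision", {
  set.seed(46)
  p <- random_params()
  f <- tempfile(fileext = ".json")
  write_hmm_parameters(p, f, interval_s = 5)
  p2 <- read_hmm_parameters(f)
  expect_equal(p$pi, p2$pi, tolerance = 1e-12)
  expect_equal(p$A, p2$A, tolerance = 1e-12)
  expect_equal(p$emissions[[1]]$step_mean, p2$emissions[[1]]$step_mean,
               tolerance = 1e-12)
  expect_equal(p$emissions[[2]]$angle_concentration,
               p2$emissions[[2]]$angle_concentration, tolerance = 1e-12)
  expect_equal(attr(p2, "interval_s"), 5, ignore_attr = TRUE)
})
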