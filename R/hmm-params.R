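# Parameter containers for the gamma / von Mises hidden Markov model.

KAPPA_MAX <- 700  # keeps besselI(kappa, 0) finite in double precision

#' Per-state emission parameters
#'
#' Step lengths are gamma with the (mean, sd) parameterization used throughout
#' movement HMMs: shape = (mean/sd)^2, rate = mean/sd^2. Turning angles are
#' von Mises with mean direction `angle_mean` and concentration
#' `angle_concentration` (kappa, capped at 700).
#'
#' @param step_mean,step_sd Gamma mean and sd of step length, meters (> 0).
#' @param angle_mean Mean turning angle, radians in `(-pi, pi]`.
#' @param angle_concentration von Mises kappa, >= 0.
#' @return A `"state_emission"` list.
#' @export
state_emission <- function(step_mean, step_sd, angle_mean = 0,
                           angle_concentration = 1) {
  stopifnot(step_mean > 0, step_sd > 0, angle_concentration >= 0,
            is.finite(step_mean), is.finite(step_sd))
  structure(list(step_mean = step_mean, step_sd = step_sd,
                 angle_mean = wrap_angle(angle_mean),
                 angle_concentration = min(angle_concentration, KAPPA_MAX)),
            class = "state_emission")
}

gamma_shape <- function(em) (em$step_mean / em$step_sd)^2
gamma_rate <- function(em) em$step_mean / em$step_sd^2

#' HMM parameter set
#'
#' @param pi Initial state distribution (length-N simplex).
#' @param A N x N row-stochastic transition matrix.
#' @param emissions List of N [state_emission()] objects.
#' @param state_names Character vector of N state names; by convention the
#'   fishing state (slow, sinuous) comes first.
#' @return An `"hmm_parameters"` list with elements `n_states`, `state_names`,
#'   `pi`, `A`, `emissions`.
#' @export
hmm_parameters <- function(pi, A, emissions, state_names = STATE_NAMES) {
  N <- length(pi)
  stopifnot(N >= 2, nrow(A) == N, ncol(A) == N, length(emissions) == N,
            length(state_names) == N)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-10)
    stop("pi must be a probability simplex")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-10))
    stop("A must be row-stochastic")
  for (em in emissions)
    if (!inherits(em, "state_emission")) stop("emissions must be state_emission")
  structure(list(n_states = N, state_names = as.character(state_names),
                 pi = as.numeric(pi), A = unname(as.matrix(A)),
                 emissions = emissions),
            class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, ...) {
  cat("<hmm_parameters>", x$n_states, "states:",
      paste(x$state_names, collapse = ", "), "\n")
  cat("pi:", paste(sprintf("%.4f", x$pi), collapse = " "), "\n")
  cat("A:\n"); print(round(x$A, 4))
  for (j in seq_len(x$n_states)) {
    em <- x$emissions[[j]]
    cat(sprintf("%s: step mean %.2f m sd %.2f m | angle mean %.3f rad kappa %.3f\n",
                x$state_names[j], em$step_mean, em$step_sd, em$angle_mean,
                em$angle_concentration))
  }
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `delta A = delta`, `sum(delta) = 1` for an irreducible row-stochastic
#' matrix.
#'
#' @param A Row-stochastic matrix.
#' @return Length-N probability vector.
#' @export
stationary_distribution <- function(A) {
  N <- nrow(A)
  stopifnot(ncol(A) == N, all(A >= 0), all(abs(rowSums(A) - 1) < 1e-8))
  reach <- diag(N) + A
  reach <- Reduce(`%*%`, rep(list(reach), max(1, N - 1)))
  if (any(reach == 0))
    stop("transition matrix is reducible; no unique stationary distribution")
  M <- rbind(t(diag(N) - A), rep(1, N))
  delta <- qr.solve(M, c(rep(0, N), 1))
  delta <- pmax(delta, 0)
  delta / sum(delta)
}

#' Serialize fitted parameters to JSON
#'
#' Writes pi, A, per-state emissions, state names and the data interval so a
#' later decode run can reload them at full double precision.
#'
#' @param params [hmm_parameters()].
#' @param path Output file.
#' @param interval_s Optional observation interval the model was fitted at.
#' @return `path`, invisibly.
#' @export
write_hmm_parameters <- function(params, path, interval_s = NULL) {
  obj <- list(state_names = params$state_names, pi = params$pi,
              A = params$A,
              emissions = lapply(params$emissions, unclass))
  if (!is.null(interval_s)) obj$interval_s <- interval_s
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read parameters written by [write_hmm_parameters()]
#'
#' @param path JSON parameter file.
#' @return [hmm_parameters()]; the stored `interval_s`, if any, is attached as
#'   an attribute.
#' @export
read_hmm_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ems <- lapply(seq_len(nrow(obj$emissions)), function(j)
    state_emission(obj$emissions$step_mean[j], obj$emissions$step_sd[j],
                   obj$emissions$angle_mean[j],
                   obj$emissions$angle_concentration[j]))
  out <- hmm_parameters(obj$pi, obj$A, ems, state_names = obj$state_names)
  if (!is.null(obj$interval_s)) attr(out, "interval_s") <- obj$interval_s
  out
}
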