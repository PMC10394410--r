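#' Construct a lattice state for the mean-field exclusion process
#'
#' Bundles the expected site occupancies with the hop and boundary rates of
#' an asymmetric simple exclusion process (ASEP) on an open 1-D lattice of
#' `N` sites. A particle at site `i` hops right at rate `p[i]` (left at
#' `q[i]`) when the target is free; particles enter the first site at rate
#' `p0` and the last at rate `qN1`, and leave through the boundaries at the
#' exit rates. By the paper-standard indexing the left exit rate is `q[1]`
#' and the right exit rate is `p[N]`; both can be overridden.
#'
#' @param phi numeric vector of expected occupancies in `[0, 1]`, length
#'   `N >= 3`.
#' @param p forward hop rates, length `N` (per unit time), non-negative.
#' @param q backward hop rates, length `N` (recycled from a scalar).
#' @param p0 injection rate into site 1.
#' @param qN1 injection rate into site `N`.
#' @param q1_exit exit rate from site 1 through the left boundary;
#'   defaults to `q[1]`.
#' @param pN_exit exit rate from site `N` through the right boundary;
#'   defaults to `p[N]`.
#' @return An object of class `lattice_state` (a list).
#' @export
lattice_state <- function(phi, p, q = 0, p0 = 0, qN1 = 0,
                          q1_exit = NULL, pN_exit = NULL) {
  n <- length(phi)
  if (n < 3) stop("lattice needs at least 3 sites", call. = FALSE)
  if (length(p) == 1L) p <- rep(p, n)
  if (length(q) == 1L) q <- rep(q, n)
  if (length(p) != n || length(q) != n) {
    stop("`p` and `q` must have the same length as `phi`", call. = FALSE)
  }
  if (!all(is.finite(phi)) || !all(is.finite(p)) || !all(is.finite(q)) ||
      !is.finite(p0) || !is.finite(qN1)) {
    stop("non-finite occupancies or rates", call. = FALSE)
  }
  if (any(p < 0) || any(q < 0) || p0 < 0 || qN1 < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  tol <- 1e-9
  if (any(phi < -tol) || any(phi > 1 + tol)) {
    stop("occupancies outside [0, 1] beyond tolerance 1e-9", call. = FALSE)
  }
  phi <- pmin(1, pmax(0, phi))
  if (is.null(q1_exit)) q1_exit <- q[1]
  if (is.null(pN_exit)) pN_exit <- p[n]
  structure(
    list(phi = phi, p = p, q = q, p0 = p0, qN1 = qN1,
         q1_exit = q1_exit, pN_exit = pN_exit),
    class = "lattice_state"
  )
}

#' Mean-field time derivative of the site occupancies
#'
#' Evaluates the closed ODE system obtained from the exclusion-process
#' master equation by factorizing neighbour correlations: for a bulk site,
#' `dphi_i/dt = p_{i-1} phi_{i-1} (1 - phi_i) - p_i phi_i (1 - phi_{i+1}) +
#' q_{i+1} phi_{i+1} (1 - phi_i) - q_i phi_i (1 - phi_{i-1})`, with the
#' boundary sites exchanging particles with external reservoirs through the
#' injection and exit rates of the state.
#'
#' @param state a [lattice_state()].
#' @return Numeric vector `dphi/dt` of length `N`.
#' @export
meanfield_rhs <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  phi <- state$phi; p <- state$p; q <- state$q
  n <- length(phi)
  d <- numeric(n)
  i <- 2:(n - 1)
  d[i] <- p[i - 1] * phi[i - 1] * (1 - phi[i]) -
    p[i] * phi[i] * (1 - phi[i + 1]) +
    q[i + 1] * phi[i + 1] * (1 - phi[i]) -
    q[i] * phi[i] * (1 - phi[i - 1])
  d[1] <- state$p0 * (1 - phi[1]) - p[1] * phi[1] * (1 - phi[2]) +
    q[2] * phi[2] * (1 - phi[1]) - state$q1_exit * phi[1]
  d[n] <- p[n - 1] * phi[n - 1] * (1 - phi[n]) - state$pN_exit * phi[n] +
    state$qN1 * (1 - phi[n]) - q[n] * phi[n] * (1 - phi[n - 1])
  d
}

# shared driver around the compiled integrator; returns the raw matrix
mf_integrate_core <- function(phi, p, q, p0, q1_exit, pN_exit, qN1, times,
                              rtol, atol, clip_tol) {
  res <- .mf_integrate_cpp(phi, p, q, p0, q1_exit, pN_exit, qN1,
                           as.numeric(times), rtol, atol, clip_tol)
  if (res$status != 0L) {
    msg <- if (res$status == 1L) {
      sprintf("occupancy excursion beyond clip tolerance %g at t = %g",
              clip_tol, res$t_reached)
    } else {
      sprintf("step size underflow at t = %g (tolerance not attainable)",
              res$t_reached)
    }
    stop(structure(
      class = c("polrate_integration_error", "error", "condition"),
      list(message = msg, call = sys.call(-1), t_reached = res$t_reached)
    ))
  }
  res$rho
}

#' Integrate the mean-field exclusion process
#'
#' Advances the factorized occupancy ODEs from `t = 0` with an adaptive
#' embedded Runge-Kutta (Cash-Karp 4(5)) scheme and returns the occupancy
#' at the requested output times in long (tidy) format.
#'
#' @param state a [lattice_state()] holding the initial occupancies and rates.
#' @param times increasing output times starting at 0.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param clip_tol occupancies within `clip_tol` of `[0, 1]` are clamped;
#'   larger excursions raise an integration error. The default scales with
#'   `atol` (local truncation error near an empty or full site is of that
#'   order), with a floor of `1e-9`, so that round-off is distinguished
#'   from genuine solver failure at any operating tolerance.
#' @return A tibble with columns `time`, `site`, `phi`; also carries the
#'   occupancy matrix (times by sites) in attribute `"matrix"`.
#' @export
integrate_meanfield <- function(state, times, rtol = 1e-6, atol = 1e-8,
                                clip_tol = max(1e-9, 10 * atol)) {
  stopifnot(inherits(state, "lattice_state"))
  times <- as.numeric(times)
  if (times[1] != 0) stop("`times` must start at 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  m <- mf_integrate_core(state$phi, state$p, state$q, state$p0,
                         state$q1_exit, state$pN_exit, state$qN1,
                         times, rtol, atol, clip_tol)
  n <- length(state$phi)
  out <- tibble::tibble(
    time = rep(times, times = rep(n, length(times))),
    site = rep(seq_len(n), times = length(times)),
    phi = as.numeric(t(m))
  )
  attr(out, "matrix") <- m
  out
}

#' Stochastic exclusion-process simulator
#'
#' Simulates exact trajectories of the ASEP with the given rates by the
#' Gillespie algorithm and averages site occupancies over replicas. Serves
#' as a validation oracle for the mean-field factorization, which is an
#' approximation for small systems.
#'
#' @param state a [lattice_state()]; initial occupancies are rounded to
#'   \{0, 1\} per replica (values must already be 0 or 1).
#' @param n_replicas number of independent replicas to average over.
#' @param times output times (non-decreasing, may start anywhere >= 0).
#' @param seed optional integer seed (`set.seed`).
#' @return A tibble with columns `time`, `site`, `phi` (mean occupancy);
#'   matrix in attribute `"matrix"`.
#' @export
gillespie_asep <- function(state, n_replicas, times, seed = NULL) {
  stopifnot(inherits(state, "lattice_state"), n_replicas >= 1)
  if (!all(state$phi %in% c(0, 1))) {
    stop("gillespie_asep needs a deterministic 0/1 initial configuration",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- .gillespie_cpp(as.integer(state$phi), state$p, state$q, state$p0,
                      state$q1_exit, state$pN_exit, state$qN1,
                      as.numeric(times), as.integer(n_replicas))
  n <- length(state$phi)
  out <- tibble::tibble(
    time = rep(as.numeric(times), times = rep(n, length(times))),
    site = rep(seq_len(n), times = length(times)),
    phi = as.numeric(t(m))
  )
  attr(out, "matrix") <- m
  out
}
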