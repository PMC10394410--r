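# Independent oracles used across the suite.

# Exact stationary occupancies of a small open ASEP by enumerating the
# 2^N-state master equation (no mean-field factorization).
master_equation_stationary <- function(p, q, p0, q1_exit, pN_exit, qN1) {
  n <- length(p)
  states <- t(vapply(0:(2^n - 1),
                     function(k) as.integer(intToBits(k)[1:n]),
                     integer(n)))
  ns <- nrow(states)
  key <- function(s) sum(s * 2^(0:(n - 1))) + 1
  Q <- matrix(0, ns, ns)
  add <- function(from, to, rate) {
    i <- key(from); j <- key(to)
    Q[i, j] <<- Q[i, j] + rate
    Q[i, i] <<- Q[i, i] - rate
  }
  for (si in seq_len(ns)) {
    s <- states[si, ]
    if (s[1] == 0 && p0 > 0) add(s, replace(s, 1, 1), p0)
    if (s[n] == 0 && qN1 > 0) add(s, replace(s, n, 1), qN1)
    if (s[1] == 1 && q1_exit > 0) add(s, replace(s, 1, 0), q1_exit)
    if (s[n] == 1 && pN_exit > 0) add(s, replace(s, n, 0), pN_exit)
    for (i in seq_len(n - 1)) {
      if (s[i] == 1 && s[i + 1] == 0 && p[i] > 0) {
        add(s, replace(replace(s, i, 0), i + 1, 1), p[i])
      }
      if (s[i + 1] == 1 && s[i] == 0 && q[i + 1] > 0) {
        add(s, replace(replace(s, i + 1, 0), i, 1), q[i + 1])
      }
    }
  }
  # stationary distribution: left null vector of Q, normalized
  A <- rbind(t(Q), rep(1, ns))
  pi_hat <- qr.solve(A, c(rep(0, ns), 1))
  as.numeric(t(states) %*% pi_hat)
}

# mean-field rhs coded independently (plain loops, no vectorization) for
# the dual-coding continuity check
meanfield_rhs_loop <- function(phi, p, q, p0, q1_exit, pN_exit, qN1) {
  n <- length(phi)
  d <- numeric(n)
  for (i in seq_len(n)) {
    jin_left <- if (i == 1) p0 * (1 - phi[1]) else p[i - 1] * phi[i - 1] * (1 - phi[i])
    jout_right <- if (i == n) pN_exit * phi[n] else p[i] * phi[i] * (1 - phi[i + 1])
    jin_right <- if (i == n) qN1 * (1 - phi[n]) else q[i + 1] * phi[i + 1] * (1 - phi[i])
    jout_left <- if (i == 1) q1_exit * phi[1] else q[i] * phi[i] * (1 - phi[i - 1])
    d[i] <- jin_left - jout_right + jin_right - jout_left
  }
  d
}

# resample-then-mean metagene oracle: straightforward reimplementation
metagene_oracle_body <- function(profiles, lengths, n_points, end_window) {
  u <- seq(0, 1, length.out = n_points)
  rows <- lapply(seq_along(profiles), function(i) {
    at <- end_window + u * (lengths[i] - 2 * end_window)
    stats::approx(profiles[[i]]$pos, profiles[[i]]$rate, xout = at, rule = 2)$y
  })
  colMeans(do.call(rbind, rows))
}

# study + reduced-size fit shared by the recovery-style tests; computed
# once per test run and cached
fit_cache <- new.env(parent = emptyenv())

replicate_fit <- function(i, n_total = 2000, n_burn = 500) {
  nm <- sprintf("rep%d_%d_%d", i, n_total, n_burn)
  if (!is.null(fit_cache[[nm]])) return(fit_cache[[nm]])
  study <- generate_study(simulation_study_config(seed = i))
  fit <- run_mcmc(study$obs, n_total = n_total, n_burn = n_burn,
                  seed = 1000 + i)
  out <- list(study = study, fit = fit)
  fit_cache[[nm]] <- out
  out
}
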