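#' Time-course observation set for a gene
#'
#' Holds the binned read-scale profiles observed at a set of run-on times
#' after initiation was blocked, together with the unperturbed
#' (pre-treatment) profile `y_star` that anchors the initial condition of
#' the forward model. Observations relate to the occupancy density by
#' `kappa * y_ij = rho(x_i, t_j) + eps`, `eps ~ N(0, sigma_eps)`, where
#' `kappa` is the inverse amplification factor of the assay.
#'
#' @param x observation positions (lattice units; one unit per bin).
#' @param times strictly increasing run-on times (minutes).
#' @param y non-negative matrix of observations, `length(x)` rows by
#'   `length(times)` columns.
#' @param y_star unperturbed profile at the same positions.
#' @param bin_width nucleotides per bin (metadata; default 1 for
#'   dimensionless synthetic data).
#' @param gene_id label.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(x, times, y, y_star, bin_width = 1,
                            gene_id = "gene") {
  y <- as.matrix(y)
  if (nrow(y) != length(x) || ncol(y) != length(times)) {
    stop("`y` must be length(x) by length(times)", call. = FALSE)
  }
  if (length(y_star) != length(x)) {
    stop("`y_star` must match `x`", call. = FALSE)
  }
  if (any(y < 0) || any(y_star < 0)) {
    stop("observations must be non-negative", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(list(x = as.numeric(x), times = as.numeric(times), y = y,
                 y_star = as.numeric(y_star), bin_width = bin_width,
                 gene_id = gene_id),
            class = "observation_set")
}

#' @method as_tibble observation_set
#' @export
as_tibble.observation_set <- function(x, ...) {
  obs <- unclass(x)
  tibble::tibble(
    x = rep(obs$x, times = length(obs$times)),
    time = rep(obs$times, each = length(obs$x)),
    y = as.numeric(obs$y)
  )
}

# forward solve for the likelihood: initial condition kappa * y_star
# (interpolated to the grid, clipped into [0,1]), zero-influx boundaries,
# densities returned at the observation positions/times. NULL on failure.
forward_density <- function(obs, p_tilde, kappa, grid, b,
                            rtol, atol, clip_tol) {
  y0 <- stats::approx(obs$x, obs$y_star, xout = grid$x, rule = 2)$y
  rho0 <- pmin(1, pmax(kappa * y0, 0))
  # direct solver call: the tidy container is skipped on this hot path
  r <- hydro_rates(p_tilde, grid$a, b, boundary_zero_influx())
  res <- .mf_integrate_cpp(rho0, r$p, r$q, r$p0, r$q1_exit, r$pN_exit,
                           r$qN1, c(0, obs$times), rtol, atol, clip_tol)
  if (res$status != 0L) return(NULL)
  m <- res$rho[-1, , drop = FALSE]             # drop t = 0
  if (identical(grid$x, obs$x)) return(t(m))
  # interpolate each time slice onto the observation positions
  vapply(seq_along(obs$times), function(j) {
    stats::approx(grid$x, m[j, ], xout = obs$x, rule = 2)$y
  }, numeric(length(obs$x)))
}

#' Gaussian log-likelihood of a time-course observation set
#'
#' Runs the forward model for the rate profile implied by the latent field
#' `f` and evaluates the Gaussian log-density of the residuals
#' `kappa * y_ij - rho(x_i, t_j)` with standard deviation `sigma_eps`,
#' normalized over all `n * t` observations.
#'
#' @param obs an [observation_set()].
#' @param f latent field on the solver grid.
#' @param theta named 5-vector `(m, sigma_eps, kappa, sigma_f, l)`; only
#'   `sigma_eps` and `kappa` enter the likelihood.
#' @param p_max upper rate bound of the sigmoid link.
#' @param grid solver grid ([spatial_grid()]); defaults to unit spacing
#'   over the observation positions.
#' @param b backward-hop fraction.
#' @param rtol,atol,clip_tol forward-solver controls; the likelihood path
#'   defaults to looser tolerances than the standalone solver since it is
#'   called inside MCMC.
#' @return Scalar log-likelihood; `-Inf` when the forward solve fails
#'   (treated as a rejected state by the sampler).
#' @export
log_likelihood <- function(obs, f, theta, p_max, grid = NULL, b = 0,
                           rtol = 1e-5, atol = 1e-7, clip_tol = 1e-6) {
  stopifnot(inherits(obs, "observation_set"))
  if (is.null(grid)) grid <- spatial_grid(length(obs$x), 1)
  sigma_eps <- theta[["sigma_eps"]]
  kappa <- theta[["kappa"]]
  if (!is.finite(sigma_eps) || sigma_eps <= 0) return(-Inf)
  rho <- forward_density(obs, link_rates(f, p_max), kappa, grid, b,
                         rtol, atol, clip_tol)
  if (is.null(rho)) return(-Inf)
  r <- kappa * obs$y - rho
  nt <- length(r)
  -sum(r^2) / (2 * sigma_eps^2) - (nt / 2) * log(2 * pi * sigma_eps^2)
}

#' One elliptical slice sampling update
#'
#' Updates a vector with a standard multivariate normal prior (whitened
#' coordinates) against an arbitrary log-likelihood. The move is
#' rejection-free: an ellipse through the current state and a fresh prior
#' draw is shrunk until a point above the slice level is found.
#'
#' @param x current state (standard-normal prior in these coordinates).
#' @param loglik_fn function of `x` returning a scalar log-likelihood.
#' @param ll_cur log-likelihood at `x` (recomputed when `NULL`).
#' @param max_shrink maximal number of bracket shrinkages before failing
#'   (a failure indicates a broken likelihood).
#' @return List with the new `x`, its log-likelihood `ll`, and the number
#'   of likelihood evaluations `n_evals`.
#' @export
elliptical_slice_step <- function(x, loglik_fn, ll_cur = NULL,
                                  max_shrink = 100) {
  if (is.null(ll_cur)) ll_cur <- loglik_fn(x)
  nu <- stats::rnorm(length(x))
  logy <- ll_cur + log(stats::runif(1))
  ang <- stats::runif(1, 0, 2 * pi)
  lo <- ang - 2 * pi
  hi <- ang
  for (k in seq_len(max_shrink)) {
    xp <- x * cos(ang) + nu * sin(ang)
    llp <- loglik_fn(xp)
    if (llp > logy) {
      return(list(x = xp, ll = llp, n_evals = k))
    }
    if (ang < 0) lo <- ang else hi <- ang
    ang <- stats::runif(1, lo, hi)
  }
  stop("elliptical slice bracket failed to accept within ", max_shrink,
       " shrinkages (likelihood is likely broken)", call. = FALSE)
}

#' Fit the rate profile by elliptical slice sampling within block Gibbs
#'
#' Samples the joint posterior of the latent rate field and the five
#' hierarchical parameters `theta = (m, sigma_eps, kappa, sigma_f, l)`
#' given time-course observations. Each Gibbs sweep performs two
#' elliptical slice updates in whitened coordinates: (i) the latent
#' residual `eta` with `f = m + chol(K(sigma_f, l)) eta`, and (ii) the
#' hyperparameter vector `zeta` with `xi = mu_xi + sigma_xi zeta` mapped
#' to `theta` through the scaled sigmoid. Whitening keeps the slice
#' sampler valid when the covariance hyperparameters move.
#'
#' @param obs an [observation_set()].
#' @param spec a [hyperprior_spec()]; defaults to the simulation-study
#'   bounds of [default_hyperprior()].
#' @param p_max upper rate bound.
#' @param n_total total number of sweeps.
#' @param n_burn sweeps discarded as burn-in.
#' @param seed optional integer seed.
#' @param a grid spacing (lattice units per observation bin).
#' @param b backward-hop fraction.
#' @param rtol,atol,clip_tol forward-solver controls for likelihood
#'   evaluations.
#' @param block_updates number of consecutive slice updates applied to
#'   each block within one sweep. One sweep always alternates the two
#'   blocks in the stated order; values above 1 repeat each block's
#'   update to improve mixing of the covariance hyperparameters at the
#'   cost of proportionally more forward solves.
#' @param progress print a line every 500 sweeps.
#' @return An object of class `polrate_fit` with elements `f_draws`
#'   (kept draws of the latent field, rows are draws), `theta_draws`
#'   (kept draws of the hierarchical parameters), `loglik` (trace), plus
#'   the grid, observations and settings needed to reuse the forward
#'   model.
#' @export
run_mcmc <- function(obs, spec = default_hyperprior(), p_max = 3,
                     n_total = 10000, n_burn = 2000, seed = NULL,
                     a = 1, b = 0, rtol = 1e-5, atol = 1e-7,
                     clip_tol = 1e-6, block_updates = 1,
                     progress = FALSE) {
  stopifnot(inherits(obs, "observation_set"), inherits(spec, "hyperprior_spec"))
  if (n_burn < 0 || n_total <= n_burn) {
    stop("need n_total > n_burn >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(obs$x)
  grid <- spatial_grid(n, a)

  ll_of <- function(f, theta) {
    log_likelihood(obs, f, theta, p_max, grid, b, rtol, atol, clip_tol)
  }
  state <- new.env(parent = emptyenv())
  refresh_chol <- function(theta) {
    K <- se_kernel_matrix(grid$x, sigma_f = theta[["sigma_f"]],
                          l = theta[["l"]])
    chol_lower_jitter(K, theta[["sigma_f"]])
  }

  eta <- numeric(n)
  zeta <- numeric(5)
  theta <- theta_from_xi(spec$mu_xi + spec$sigma_xi * zeta, spec)
  Lc <- refresh_chol(theta)
  f <- theta[["m"]] + as.numeric(Lc %*% eta)
  ll_cur <- ll_of(f, theta)
  if (!is.finite(ll_cur)) {
    stop("initial state has invalid likelihood; check the observations",
         call. = FALSE)
  }

  n_kept <- n_total - n_burn
  f_draws <- matrix(NA_real_, n_kept, n)
  theta_draws <- matrix(NA_real_, n_kept, 5,
                        dimnames = list(NULL, theta_names))
  ll_trace <- numeric(n_total)
  n_evals <- 0L
  fail_window <- 0L
  eval_window <- 0L

  for (s in seq_len(n_total)) {
    # block 1: latent field in whitened coordinates
    for (r in seq_len(block_updates)) {
      step1 <- elliptical_slice_step(eta, function(e) {
        ll <- ll_of(theta[["m"]] + as.numeric(Lc %*% e), theta)
        eval_window <<- eval_window + 1L
        if (!is.finite(ll)) fail_window <<- fail_window + 1L
        ll
      }, ll_cur = ll_cur)
      eta <- step1$x
      ll_cur <- step1$ll
      n_evals <- n_evals + step1$n_evals
    }

    # block 2: hyperparameters in whitened coordinates
    for (r in seq_len(block_updates)) {
      step2 <- elliptical_slice_step(zeta, function(z) {
        th <- theta_from_xi(spec$mu_xi + spec$sigma_xi * z, spec)
        Lz <- refresh_chol(th)
        ll <- ll_of(th[["m"]] + as.numeric(Lz %*% eta), th)
        eval_window <<- eval_window + 1L
        if (!is.finite(ll)) fail_window <<- fail_window + 1L
        ll
      }, ll_cur = ll_cur)
      zeta <- step2$x
      ll_cur <- step2$ll
      n_evals <- n_evals + step2$n_evals
    }
    theta <- theta_from_xi(spec$mu_xi + spec$sigma_xi * zeta, spec)
    Lc <- refresh_chol(theta)
    f <- theta[["m"]] + as.numeric(Lc %*% eta)

    ll_trace[s] <- ll_cur
    if (s > n_burn) {
      f_draws[s - n_burn, ] <- f
      theta_draws[s - n_burn, ] <- theta
    }
    if (s %% 500L == 0L) {
      if (eval_window > 0L && fail_window / eval_window > 0.5) {
        stop(sprintf(
          "aborting: %d of %d forward solves failed in the last 500 sweeps",
          fail_window, eval_window), call. = FALSE)
      }
      fail_window <- 0L
      eval_window <- 0L
      if (progress) {
        message(sprintf("sweep %d / %d  loglik %.2f  sigma_eps %.4g",
                        s, n_total, ll_cur, theta[["sigma_eps"]]))
      }
    }
  }

  structure(
    list(f_draws = f_draws, theta_draws = theta_draws, loglik = ll_trace,
         grid = grid, obs = obs, p_max = p_max, spec = spec, a = a, b = b,
         rtol = rtol, atol = atol, clip_tol = clip_tol,
         seed = seed, n_total = n_total, n_burn = n_burn,
         n_evals = n_evals),
    class = "polrate_fit"
  )
}

# kept rate draws as a draws-by-positions matrix
rate_draws <- function(fit) link_rates(fit$f_draws, fit$p_max)

#' Posterior predictive density profiles
#'
#' For a subset of kept posterior draws, reruns the forward model and adds
#' observation noise, yielding predictive densities `rho + eps` on the
#' density scale at the observation positions and times. Also summarizes
#' the rate-profile draws with (by default) 99% credible bands.
#'
#' @param fit a `polrate_fit`.
#' @param n_draws number of posterior draws to push through the forward
#'   model (evenly spaced over the kept draws).
#' @param level credible level for the density bands.
#' @param rate_level credible level for the rate-profile bands.
#' @param noise add observation noise to the forward solutions.
#' @param seed optional integer seed for the noise draws.
#' @return A list of class `polrate_predictive` with tibbles `density`
#'   (`x`, `time`, `median`, `lo`, `hi`) and `rate`
#'   (`x`, `median`, `lo`, `hi`), and the array of predictive draws.
#' @export
posterior_predictive <- function(fit, n_draws = 200, level = 0.95,
                                 rate_level = 0.99, noise = TRUE,
                                 seed = NULL) {
  stopifnot(inherits(fit, "polrate_fit"))
  if (!is.null(seed)) set.seed(seed)
  n_kept <- nrow(fit$f_draws)
  if (n_kept < 1) stop("no kept draws", call. = FALSE)
  idx <- unique(round(seq(1, n_kept, length.out = min(n_draws, n_kept))))
  obs <- fit$obs
  nx <- length(obs$x)
  nt <- length(obs$times)
  draws <- array(NA_real_, c(length(idx), nx, nt))
  for (k in seq_along(idx)) {
    i <- idx[k]
    th <- fit$theta_draws[i, ]
    rho <- forward_density(obs, link_rates(fit$f_draws[i, ], fit$p_max),
                           th[["kappa"]], fit$grid, fit$b,
                           fit$rtol, fit$atol, fit$clip_tol)
    if (is.null(rho)) next
    if (noise) rho <- rho + stats::rnorm(length(rho), 0, th[["sigma_eps"]])
    draws[k, , ] <- rho
  }
  alpha <- (1 - level) / 2
  qs <- apply(draws, c(2, 3), stats::quantile,
              probs = c(alpha, 0.5, 1 - alpha), na.rm = TRUE)
  density <- tibble::tibble(
    x = rep(obs$x, times = nt),
    time = rep(obs$times, each = nx),
    lo = as.numeric(qs[1, , ]),
    median = as.numeric(qs[2, , ]),
    hi = as.numeric(qs[3, , ])
  )
  ra <- (1 - rate_level) / 2
  pd <- rate_draws(fit)
  rate <- tibble::tibble(
    x = fit$grid$x,
    median = unname(apply(pd, 2, stats::median)),
    lo = unname(apply(pd, 2, stats::quantile, probs = ra)),
    hi = unname(apply(pd, 2, stats::quantile, probs = 1 - ra))
  )
  structure(list(density = density, rate = rate, draws = draws,
                 level = level, rate_level = rate_level),
            class = "polrate_predictive")
}

#' Posterior summaries of a fit
#'
#' Equal-tailed quantile summaries: per-position posterior median of the
#' rate profile with a 99% credible interval, and per-hyperparameter
#' median with a 95% credible interval (linear-interpolation quantiles,
#' the R default).
#'
#' @param fit a `polrate_fit`.
#' @param rate_level,theta_level credible levels.
#' @return List with tibbles `rate` (`x`, `median`, `lo`, `hi`) and
#'   `theta` (`parameter`, `median`, `lo`, `hi`, `truth`-free).
#' @export
fit_summary <- function(fit, rate_level = 0.99, theta_level = 0.95) {
  list(rate = tidy(fit, "rate", level = rate_level),
       theta = tidy(fit, "theta", level = theta_level))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries
#'
#' @param x a `polrate_fit`.
#' @param what `"rate"` for the per-position rate profile (99% CI by
#'   default), `"theta"` for the five hierarchical parameters (95% CI by
#'   default).
#' @param level credible level override.
#' @param ... unused.
#' @method tidy polrate_fit
#' @export
tidy.polrate_fit <- function(x, what = c("rate", "theta"), level = NULL, ...) {
  what <- match.arg(what)
  if (what == "rate") {
    if (is.null(level)) level <- 0.99
    alpha <- (1 - level) / 2
    pd <- rate_draws(x)
    tibble::tibble(
      x = x$grid$x,
      median = unname(apply(pd, 2, stats::median)),
      lo = unname(apply(pd, 2, stats::quantile, probs = alpha)),
      hi = unname(apply(pd, 2, stats::quantile, probs = 1 - alpha))
    )
  } else {
    if (is.null(level)) level <- 0.95
    alpha <- (1 - level) / 2
    tibble::tibble(
      parameter = colnames(x$theta_draws),
      median = unname(apply(x$theta_draws, 2, stats::median)),
      lo = unname(apply(x$theta_draws, 2, stats::quantile, probs = alpha)),
      hi = unname(apply(x$theta_draws, 2, stats::quantile, probs = 1 - alpha))
    )
  }
}

#' @method glance polrate_fit
#' @export
glance.polrate_fit <- function(x, ...) {
  med_rate <- apply(rate_draws(x), 2, stats::median)
  tibble::tibble(
    n_total = x$n_total,
    n_burn = x$n_burn,
    n_kept = nrow(x$f_draws),
    n_loglik_evals = x$n_evals,
    loglik_final = x$loglik[x$n_total],
    rate_min_x = x$grid$x[which.min(med_rate)]
  )
}

#' @export
print.polrate_fit <- function(x, ...) {
  cat("<polrate_fit>\n")
  cat(sprintf("  gene: %s | grid: %d points (a = %g) | times: %s\n",
              x$obs$gene_id, x$grid$n, x$grid$a,
              paste(x$obs$times, collapse = ", ")))
  cat(sprintf("  sweeps: %d (burn-in %d), %d likelihood evaluations\n",
              x$n_total, x$n_burn, x$n_evals))
  th <- tidy(x, "theta")
  cat("  posterior medians (95% CI):\n")
  for (i in seq_len(nrow(th))) {
    cat(sprintf("    %-9s %8.4g  (%.4g, %.4g)\n",
                th$parameter[i], th$median[i], th$lo[i], th$hi[i]))
  }
  invisible(x)
}
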