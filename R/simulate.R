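#' Configuration of the synthetic simulation study
#'
#' Defaults reproduce the reference simulation setting: a gene body of
#' `L = 100` lattice units, a GP-drawn rate profile with
#' `(l, sigma_f, m, p_max) = (7.32, 0.67, 0.29, 3)`, a stationary state
#' held at boundary density 0.5 on both ends, depletion profiles observed
#' at `t = 30, 60, 300`, no added observation noise (profiles are
#' extracted from the integrated dynamics) and a true inverse
#' amplification factor of 1 (inside its prior bounds 0.8-1.2).
#'
#' @param L domain length (number of sites at `a = 1`).
#' @param gp a [gp_hyper()] for the generative GP.
#' @param p_max upper rate bound of the sigmoid link.
#' @param ness_boundary_density reservoir density at both ends for the
#'   stationary state.
#' @param obs_times observation (run-on) times.
#' @param noise_sigma additive observation noise standard deviation on
#'   the density scale (0 = noise-free extraction).
#' @param kappa_true true inverse amplification factor.
#' @param seed integer seed controlling the GP draw and the noise.
#' @param a grid spacing; `b` backward-hop fraction.
#' @param b backward-hop fraction.
#' @return A list of class `sim_config`.
#' @export
simulation_study_config <- function(L = 100,
                                    gp = gp_hyper(m = 0.29, sigma_f = 0.67,
                                                  l = 7.32),
                                    p_max = 3,
                                    ness_boundary_density = 0.5,
                                    obs_times = c(30, 60, 300),
                                    noise_sigma = 0,
                                    kappa_true = 1,
                                    seed = 1,
                                    a = 1, b = 0) {
  stopifnot(inherits(gp, "gp_hyper"), p_max > 0, noise_sigma >= 0,
            kappa_true > 0)
  structure(list(L = L, gp = gp, p_max = p_max,
                 ness_boundary_density = ness_boundary_density,
                 obs_times = obs_times, noise_sigma = noise_sigma,
                 kappa_true = kappa_true, seed = seed, a = a, b = b),
            class = "sim_config")
}

#' Generate a complete synthetic study
#'
#' Draws a rate profile from the GP prior, computes the stationary state
#' under fixed boundary densities, integrates the depletion transient with
#' zero influx, and converts the extracted density profiles into read-scale
#' observations `y = (rho + eps) / kappa_true` together with the
#' pre-treatment profile `y_star = rho* / kappa_true`. Fully reproducible
#' for a fixed seed.
#'
#' @param config a [simulation_study_config()].
#' @return A list with elements `truth` (list: `rate_profile`, `ness`,
#'   `depletion` density field, `config`) and `obs` (an
#'   [observation_set()]).
#' @export
generate_study <- function(config = simulation_study_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- spatial_grid(round(config$L / config$a), config$a)
  rp <- sample_rate_profile(grid, config$gp, config$p_max)
  ness <- find_ness(rp$p_tilde, grid, config$b,
                    boundary_fixed(config$ness_boundary_density),
                    rho_init = config$ness_boundary_density)
  dep <- run_depletion(ness, rp$p_tilde, grid, config$b,
                       obs_times = config$obs_times)
  rho <- t(field_matrix(dep))                      # positions x times
  eps <- if (config$noise_sigma > 0) {
    matrix(stats::rnorm(length(rho), 0, config$noise_sigma), nrow(rho))
  } else 0
  y <- pmax((rho + eps) / config$kappa_true, 0)
  obs <- observation_set(grid$x, config$obs_times, y,
                         y_star = ness$rho / config$kappa_true,
                         bin_width = 1, gene_id = "synthetic")
  list(truth = list(rate_profile = rp, ness = ness, depletion = dep,
                    config = config),
       obs = obs)
}

#' Default hyperprior of the simulation study
#'
#' Bounds `theta_min = (0, 0, 0.8, 0, 0)`,
#' `theta_max = (2, 10, 1.2, 1, 10)` for
#' `(m, sigma_eps, kappa, sigma_f, l)`, with `(mu_xi, sigma_xi) = (0, 1)`.
#'
#' @return A [hyperprior_spec()].
#' @export
default_hyperprior <- function() {
  hyperprior_spec(theta_min = c(0, 0, 0.8, 0, 0),
                  theta_max = c(2, 10, 1.2, 1, 10),
                  mu_xi = 0, sigma_xi = 1)
}

#' Hyperprior bounds for real coverage data
#'
#' For genomic fits the upper rate bound is quoted in nucleotides per
#' minute (default 6e3, a safe cap on reported elongation speeds) and the
#' bounds on the inverse amplification factor are derived from the total
#' read count `Y` of the unperturbed profile via literature estimates of
#' total bound polymerase per cell: `kappa_min = P_min / Y`,
#' `kappa_max = P_max / Y` with `P` between 11e5 and 18e5.
#'
#' @param total_reads total read count `Y` of the unperturbed profile.
#' @param P_min,P_max bounds on the number of bound polymerases per cell.
#' @return A [hyperprior_spec()] with the kappa bounds replaced.
#' @export
realdata_hyperprior <- function(total_reads, P_min = 11e5, P_max = 18e5) {
  if (total_reads <= 0) stop("total_reads must be positive", call. = FALSE)
  def <- default_hyperprior()
  tmin <- def$theta_min
  tmax <- def$theta_max
  tmin[["kappa"]] <- P_min / total_reads
  tmax[["kappa"]] <- P_max / total_reads
  hyperprior_spec(tmin, tmax, def$mu_xi, def$sigma_xi)
}
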