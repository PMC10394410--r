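#' Uniform spatial grid over a gene body
#'
#' The continuum description lives on a uniform grid with spacing `a` (the
#' lattice constant). Site `i` sits at `x_i = (i - 1) a`, and the domain
#' length is `L = n a`. Internally one grid point corresponds to one
#' lattice site; for genomic data one site is one coverage bin, and rates
#' quoted in nucleotides per minute are divided by the bin width on input.
#'
#' @param n number of grid points (`>= 3`).
#' @param a grid spacing (lattice constant), `> 0`.
#' @return An object of class `spatial_grid` with fields `x`, `n`, `a`, `L`.
#' @export
spatial_grid <- function(n, a = 1) {
  n <- as.integer(n)
  if (n < 3 || a <= 0) stop("need n >= 3 and a > 0", call. = FALSE)
  structure(list(x = (seq_len(n) - 1) * a, n = n, a = a, L = n * a),
            class = "spatial_grid")
}

#' Boundary specification for the density equation
#'
#' Either end of the domain can be held at a fixed reservoir density
#' (`"fixed-density"`) or closed to incoming particles (`"zero-influx"`,
#' the analogue of blocking initiation: injection rates are zero while
#' exits through the boundary remain free).
#'
#' @param kind_left,kind_right one of `"fixed-density"`, `"zero-influx"`.
#' @param value_left,value_right reservoir densities in `[0, 1]`
#'   (required for fixed-density ends).
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(kind_left = "zero-influx", kind_right = "zero-influx",
                          value_left = NA_real_, value_right = NA_real_) {
  kinds <- c("fixed-density", "zero-influx")
  kind_left <- match.arg(kind_left, kinds)
  kind_right <- match.arg(kind_right, kinds)
  chk <- function(kind, value, side) {
    if (kind == "fixed-density") {
      if (!is.finite(value) || value < 0 || value > 1) {
        stop(sprintf("%s fixed-density boundary needs a value in [0, 1]", side),
             call. = FALSE)
      }
    }
  }
  chk(kind_left, value_left, "left")
  chk(kind_right, value_right, "right")
  structure(list(kind_left = kind_left, kind_right = kind_right,
                 value_left = value_left, value_right = value_right),
            class = "boundary_spec")
}

#' @rdname boundary_spec
#' @param left,right reservoir densities for the two ends.
#' @export
boundary_fixed <- function(left, right = left) {
  boundary_spec("fixed-density", "fixed-density", left, right)
}

#' @rdname boundary_spec
#' @export
boundary_zero_influx <- function() boundary_spec()

#' Transport coefficients of the hydrodynamic limit
#'
#' From the forward rate profile `p_tilde` and the backward-to-forward
#' ratio `b` (`q_tilde = b p_tilde`), the density equation
#' `d rho/dt = -d/dx ( lambda rho (1 - rho) - nu d rho/dx )` uses the
#' drift coefficient `lambda(x) = p_tilde(x) (1 - b)` and the diffusion
#' coefficient `nu(x) = (a/2) p_tilde(x) (1 + b)`. Their ratio
#' `nu/lambda = (a/2) (1 + b) / (1 - b)` is constant in `x` and equals
#' `a/2` in the totally asymmetric case `b = 0`.
#'
#' @param p_tilde non-negative forward rate values on the grid.
#' @param a grid spacing.
#' @param b backward-hop fraction in `[0, 1)`.
#' @return A tibble with columns `lam` and `nu`; `b` and `a` are carried
#'   as attributes.
#' @export
transport_coefficients <- function(p_tilde, a = 1, b = 0) {
  if (b < 0 || b >= 1) stop("`b` must lie in [0, 1)", call. = FALSE)
  if (any(p_tilde < 0)) stop("`p_tilde` must be non-negative", call. = FALSE)
  out <- tibble::tibble(lam = p_tilde * (1 - b),
                        nu = (a / 2) * p_tilde * (1 + b))
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

#' Taylor-expanded flux at cell interfaces
#'
#' Evaluates `J = lambda rho (1 - rho) - nu d rho/dx` at the `n - 1`
#' interior interfaces, with densities and coefficients averaged onto the
#' interface and the gradient discretized there. This is the first-order
#' continuum flux; the time integrator itself uses the discrete product
#' form, which agrees to second order in the spacing.
#'
#' @param rho density values on the grid at one time, in `[0, 1]`.
#' @param coeffs output of [transport_coefficients()].
#' @param grid a [spatial_grid()].
#' @return Numeric vector of length `n - 1` (interface fluxes).
#' @export
flux_profile <- function(rho, coeffs, grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  n <- grid$n
  if (length(rho) != n) stop("`rho` must match the grid", call. = FALSE)
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]", call. = FALSE)
  lam <- coeffs$lam; nu <- coeffs$nu
  rmid <- (rho[-n] + rho[-1]) / 2
  lmid <- (lam[-n] + lam[-1]) / 2
  nmid <- (nu[-n] + nu[-1]) / 2
  grad <- diff(rho) / grid$a
  lmid * rmid * (1 - rmid) - nmid * grad
}

# translate a rate profile + boundary spec into core lattice rates
hydro_rates <- function(p_tilde, a, b, boundary) {
  p <- p_tilde / a
  q <- b * p_tilde / a
  n <- length(p)
  if (boundary$kind_left == "fixed-density") {
    rl <- boundary$value_left
    p0 <- p[1] * rl
    q1_exit <- q[1] * (1 - rl)
  } else {
    p0 <- 0
    q1_exit <- q[1]
  }
  if (boundary$kind_right == "fixed-density") {
    rr <- boundary$value_right
    pN_exit <- p[n] * (1 - rr)
    qN1 <- q[n] * rr
  } else {
    pN_exit <- p[n]
    qN1 <- 0
  }
  list(p = p, q = q, p0 = p0, q1_exit = q1_exit, pN_exit = pN_exit, qN1 = qN1)
}

# assemble the tidy density-field container from a times-by-grid matrix
density_field <- function(grid, times, m, boundary = NULL) {
  out <- tibble::tibble(
    time = rep(as.numeric(times), times = rep(grid$n, length(times))),
    x = rep(grid$x, times = length(times)),
    rho = as.numeric(t(m))
  )
  attr(out, "matrix") <- m
  attr(out, "grid") <- grid
  attr(out, "boundary") <- boundary
  class(out) <- c("density_field", class(out))
  out
}

#' Extract the values matrix from a tidy field
#'
#' @param field a tibble returned by [integrate_density()],
#'   [integrate_meanfield()] or [run_depletion()].
#' @return The times-by-positions numeric matrix stored alongside the
#'   tidy representation.
#' @export
field_matrix <- function(field) {
  m <- attr(field, "matrix")
  if (is.null(m)) stop("no matrix attribute on this field", call. = FALSE)
  m
}

#' Integrate the hydrodynamic density equation
#'
#' Conservative method-of-lines integration of the nonlinear density
#' equation with open boundaries. The spatial discretization is the
#' discrete product-form flux of the exclusion process (advection
#' `lambda rho (1 - rho)` plus diffusion `nu`), so that with spacing
#' `a = 1` the scheme coincides exactly with the discrete mean-field
#' system. Time stepping is adaptive embedded Runge-Kutta with a
#' CFL-limited initial step.
#'
#' @param rho0 initial density on the grid, values in `[0, 1]`.
#' @param p_tilde forward rate profile on the grid (continuum units:
#'   length per time).
#' @param grid a [spatial_grid()]; defaults to unit spacing over `rho0`.
#' @param b backward-hop fraction in `[0, 1)`.
#' @param boundary a [boundary_spec()].
#' @param times increasing output times starting at 0.
#' @param rtol,atol solver tolerances.
#' @param clip_tol occupancy clamping tolerance (see
#'   [integrate_meanfield()]).
#' @return A `density_field` tibble with columns `time`, `x`, `rho`.
#' @export
integrate_density <- function(rho0, p_tilde, grid = NULL, b = 0,
                              boundary = boundary_zero_influx(),
                              times = c(0, 1), rtol = 1e-8, atol = 1e-10,
                              clip_tol = max(1e-9, 10 * atol)) {
  if (is.null(grid)) grid <- spatial_grid(length(rho0), 1)
  stopifnot(inherits(grid, "spatial_grid"), inherits(boundary, "boundary_spec"))
  if (length(rho0) != grid$n || length(p_tilde) != grid$n) {
    stop("`rho0` and `p_tilde` must match the grid", call. = FALSE)
  }
  if (any(rho0 < -1e-9 | rho0 > 1 + 1e-9)) {
    stop("`rho0` must lie in [0, 1]", call. = FALSE)
  }
  rho0 <- pmin(1, pmax(0, rho0))
  times <- as.numeric(times)
  if (times[1] != 0) stop("`times` must start at 0", call. = FALSE)
  r <- hydro_rates(p_tilde, grid$a, b, boundary)
  m <- mf_integrate_core(rho0, r$p, r$q, r$p0, r$q1_exit, r$pN_exit, r$qN1,
                         times, rtol, atol, clip_tol)
  density_field(grid, times, m, boundary)
}

# discrete product-form flux (continuum units), including boundary fluxes;
# this is the flux the integrator conserves, so it is the one reported for
# stationary states. Length n + 1.
product_flux <- function(rho, p_tilde, grid, b, boundary) {
  r <- hydro_rates(p_tilde, grid$a, b, boundary)
  n <- grid$n
  p <- r$p; q <- r$q
  inner <- p[-n] * rho[-n] * (1 - rho[-1]) - q[-1] * rho[-1] * (1 - rho[-n])
  left <- r$p0 * (1 - rho[1]) - r$q1_exit * rho[1]
  right <- r$pN_exit * rho[n] - r$qN1 * (1 - rho[n])
  grid$a * c(left, inner, right)
}

#' Non-equilibrium stationary state (NESS)
#'
#' Computes the time-invariant density profile `rho*(x)` carried by a
#' constant non-zero particle flux, by long-horizon integration with
#' stationarity detection: the integration stops once the maximal local
#' time derivative stays below `tol` at three consecutive checkpoints.
#'
#' @inheritParams integrate_density
#' @param boundary must be fixed-density on both ends.
#' @param rho_init initial density (scalar or vector on the grid).
#' @param tol stationarity tolerance on `max |d rho/dt|` (per unit time).
#' @param check_dt time between stationarity checkpoints.
#' @param max_t maximal integration horizon before giving up.
#' @return A list of class `polrate_ness`: `rho` (the profile), `flux`
#'   (discrete flux at the `n + 1` interfaces, constant in `x` at
#'   convergence), `residual`, `t`, `grid`, and the residual trajectory.
#' @export
find_ness <- function(p_tilde, grid = NULL, b = 0,
                      boundary = boundary_fixed(0.5),
                      rho_init = 0.5, tol = 1e-10, check_dt = 50,
                      max_t = 1e5, rtol = 1e-12, atol = 1e-14) {
  if (is.null(grid)) grid <- spatial_grid(length(p_tilde), 1)
  if (boundary$kind_left != "fixed-density" ||
      boundary$kind_right != "fixed-density") {
    stop("NESS computation requires fixed-density boundaries on both ends",
         call. = FALSE)
  }
  if (length(rho_init) == 1L) rho_init <- rep(rho_init, grid$n)
  r <- hydro_rates(p_tilde, grid$a, b, boundary)
  rho <- pmin(1, pmax(0, rho_init))
  t_now <- 0
  ok_streak <- 0L
  res_path <- numeric(0)
  resid <- Inf
  while (t_now < max_t) {
    m <- mf_integrate_core(rho, r$p, r$q, r$p0, r$q1_exit, r$pN_exit, r$qN1,
                           c(0, check_dt), rtol, atol, 1e-9)
    rho <- m[2, ]
    t_now <- t_now + check_dt
    resid <- max(abs(.mf_rhs_cpp(rho, r$p, r$q, r$p0, r$q1_exit,
                                 r$pN_exit, r$qN1)))
    res_path <- c(res_path, resid)
    ok_streak <- if (resid < tol) ok_streak + 1L else 0L
    if (ok_streak >= 3L) break
  }
  if (ok_streak < 3L) {
    stop(structure(
      class = c("polrate_ness_error", "error", "condition"),
      list(message = sprintf(
        "NESS not reached within t = %g (last residual %.3g); residual trajectory attached",
        max_t, resid), call = sys.call(), residuals = res_path)
    ))
  }
  structure(
    list(rho = rho, flux = product_flux(rho, p_tilde, grid, b, boundary),
         residual = resid, t = t_now, grid = grid, boundary = boundary,
         residual_path = res_path),
    class = "polrate_ness"
  )
}

#' Depletion transient after blocking initiation
#'
#' Starting from a stationary profile, integrates the density equation
#' with zero-influx boundaries (no injection at either end, free exit),
#' mimicking the decay of the polymerase profile after triptolide blocks
#' initiation: the gene body empties from the TSS side as the standing
#' particles run off through the TES.
#'
#' @param rho_star stationary density profile (vector, or a
#'   `polrate_ness` object).
#' @inheritParams integrate_density
#' @param obs_times positive observation times.
#' @param include_initial prepend the `t = 0` profile to the output.
#' @return A `density_field` tibble at the observation times.
#' @export
run_depletion <- function(rho_star, p_tilde, grid = NULL, b = 0,
                          obs_times = c(30, 60, 300),
                          include_initial = FALSE,
                          rtol = 1e-8, atol = 1e-10,
                          clip_tol = max(1e-9, 10 * atol)) {
  if (inherits(rho_star, "polrate_ness")) {
    if (is.null(grid)) grid <- rho_star$grid
    rho_star <- rho_star$rho
  }
  if (is.null(grid)) grid <- spatial_grid(length(rho_star), 1)
  if (any(obs_times <= 0)) stop("`obs_times` must be positive", call. = FALSE)
  times <- c(0, as.numeric(obs_times))
  fld <- integrate_density(rho_star, p_tilde, grid, b,
                           boundary_zero_influx(), times,
                           rtol = rtol, atol = atol, clip_tol = clip_tol)
  if (!include_initial) {
    m <- field_matrix(fld)[-1, , drop = FALSE]
    fld <- density_field(grid, obs_times, m, boundary_zero_influx())
  }
  fld
}

#' Total particle mass of a density field
#'
#' @param field a `density_field` tibble.
#' @return Tibble with columns `time` and `mass` (`sum(rho) * a`).
#' @export
total_mass <- function(field) {
  grid <- attr(field, "grid")
  a <- if (is.null(grid)) 1 else grid$a
  dplyr::summarise(dplyr::group_by(field, .data$time),
                   mass = sum(.data$rho) * a, .groups = "drop")
}
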