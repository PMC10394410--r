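#' Gaussian-process hyperparameters for the latent rate field
#'
#' @param m GP mean on the latent scale.
#' @param sigma_f kernel amplitude (marginal standard deviation), `> 0`.
#' @param l kernel length-scale in lattice units, `> 0`.
#' @return An object of class `gp_hyper`.
#' @export
gp_hyper <- function(m, sigma_f, l) {
  if (sigma_f <= 0 || l <= 0) stop("sigma_f and l must be positive", call. = FALSE)
  structure(list(m = m, sigma_f = sigma_f, l = l), class = "gp_hyper")
}

#' Squared-exponential covariance matrix
#'
#' `k(x, x') = sigma_f^2 exp(-(x - x')^2 / (2 l^2))`.
#'
#' @param x grid positions (or a [spatial_grid()]).
#' @param hyper a [gp_hyper()], or `sigma_f`/`l` supplied directly.
#' @param sigma_f,l kernel amplitude and length-scale (ignored when
#'   `hyper` is given).
#' @return Symmetric positive semi-definite matrix with `sigma_f^2` on the
#'   diagonal. No jitter is added here; the Cholesky path adds adaptive
#'   diagonal jitter from `1e-10 sigma_f^2` up to at most `1e-6 sigma_f^2`.
#' @export
se_kernel_matrix <- function(x, hyper = NULL, sigma_f = NULL, l = NULL) {
  if (inherits(x, "spatial_grid")) x <- x$x
  if (!is.null(hyper)) {
    sigma_f <- hyper$sigma_f
    l <- hyper$l
  }
  if (sigma_f <= 0 || l <= 0) stop("sigma_f and l must be positive", call. = FALSE)
  d <- outer(x, x, "-")
  sigma_f^2 * exp(-d^2 / (2 * l^2))
}

# lower-triangular Cholesky factor with adaptive diagonal jitter
chol_lower_jitter <- function(K, sigma_f) {
  jit <- 1e-10 * sigma_f^2
  max_jit <- 1e-6 * sigma_f^2
  R <- tryCatch(chol(K), error = function(e) NULL)
  while (is.null(R) && jit <= max_jit) {
    R <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    jit <- jit * 2
  }
  if (is.null(R)) {
    stop("Cholesky factorization failed even with maximal jitter", call. = FALSE)
  }
  t(R)
}

#' Sigmoid link from latent field to hop rates
#'
#' `p_tilde = p_max / (1 + exp(-f))`: strictly increasing in `f`, with
#' range `(0, p_max)`, so rates are smooth, positive and bounded.
#'
#' @param f latent values.
#' @param p_max upper rate bound, `> 0`.
#' @return Rate values, same length as `f`.
#' @export
link_rates <- function(f, p_max) {
  if (p_max <= 0) stop("p_max must be positive", call. = FALSE)
  p_max * stats::plogis(f)
}

#' Draw a rate profile from the GP prior
#'
#' Samples the latent field `f ~ N(m, K)` on the grid and maps it through
#' the sigmoid link.
#'
#' @param grid a [spatial_grid()].
#' @param hyper a [gp_hyper()].
#' @param p_max upper rate bound.
#' @param seed optional integer seed.
#' @return A tibble of class `rate_profile` with columns `x`, `f`,
#'   `p_tilde`; `grid`, `hyper` and `p_max` are carried as attributes.
#' @export
sample_rate_profile <- function(grid, hyper, p_max, seed = NULL) {
  stopifnot(inherits(grid, "spatial_grid"), inherits(hyper, "gp_hyper"))
  if (!is.null(seed)) set.seed(seed)
  K <- se_kernel_matrix(grid$x, hyper)
  Lc <- chol_lower_jitter(K, hyper$sigma_f)
  f <- hyper$m + as.numeric(Lc %*% stats::rnorm(grid$n))
  out <- tibble::tibble(x = grid$x, f = f, p_tilde = link_rates(f, p_max))
  attr(out, "grid") <- grid
  attr(out, "hyper") <- hyper
  attr(out, "p_max") <- p_max
  class(out) <- c("rate_profile", class(out))
  out
}

theta_names <- c("m", "sigma_eps", "kappa", "sigma_f", "l")

#' Bounds and hyperparameters of the scaled-sigmoid prior
#'
#' The five hierarchical parameters `theta = (m, sigma_eps, kappa,
#' sigma_f, l)` carry a scaled sigmoid Gaussian prior:
#' `theta = theta_min + (theta_max - theta_min) / (1 + exp(-xi))` with
#' `xi ~ N(mu_xi, sigma_xi^2)` componentwise, which constrains every
#' parameter to its stated interval.
#'
#' @param theta_min,theta_max numeric 5-vectors of lower/upper bounds, in
#'   the order `m, sigma_eps, kappa, sigma_f, l`.
#' @param mu_xi,sigma_xi location and standard deviation of `xi`.
#' @return An object of class `hyperprior_spec`.
#' @export
hyperprior_spec <- function(theta_min, theta_max, mu_xi = 0, sigma_xi = 1) {
  theta_min <- as.numeric(theta_min)
  theta_max <- as.numeric(theta_max)
  if (length(theta_min) != 5 || length(theta_max) != 5) {
    stop("bounds must be 5-vectors (m, sigma_eps, kappa, sigma_f, l)",
         call. = FALSE)
  }
  if (any(theta_min >= theta_max)) {
    stop("theta_min must be strictly below theta_max componentwise",
         call. = FALSE)
  }
  if (sigma_xi <= 0) stop("sigma_xi must be positive", call. = FALSE)
  names(theta_min) <- names(theta_max) <- theta_names
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 mu_xi = mu_xi, sigma_xi = sigma_xi),
            class = "hyperprior_spec")
}

#' Map unconstrained `xi` to bounded `theta` (and back)
#'
#' `theta = theta_min + (theta_max - theta_min) / (1 + exp(-xi))`,
#' componentwise and strictly monotone; `xi_from_theta` is the exact
#' inverse (logit of the rescaled parameter) and requires `theta` strictly
#' inside its bounds.
#'
#' @param xi unconstrained 5-vector.
#' @param spec a [hyperprior_spec()].
#' @return Named numeric 5-vector.
#' @export
theta_from_xi <- function(xi, spec) {
  stopifnot(inherits(spec, "hyperprior_spec"), length(xi) == 5)
  th <- spec$theta_min + (spec$theta_max - spec$theta_min) * stats::plogis(xi)
  names(th) <- theta_names
  th
}

#' @rdname theta_from_xi
#' @param theta bounded 5-vector strictly inside `(theta_min, theta_max)`.
#' @export
xi_from_theta <- function(theta, spec) {
  stopifnot(inherits(spec, "hyperprior_spec"), length(theta) == 5)
  u <- (theta - spec$theta_min) / (spec$theta_max - spec$theta_min)
  if (any(u <= 0) || any(u >= 1)) {
    stop("theta must lie strictly inside (theta_min, theta_max)", call. = FALSE)
  }
  xi <- stats::qlogis(u)
  names(xi) <- theta_names
  xi
}

#' Read a hyperprior specification from a key = value text file
#'
#' Recognized keys: `theta_min`, `theta_max` (comma-separated 5-vectors),
#' `mu_xi`, `sigma_xi`. Missing keys fall back to [default_hyperprior()].
#'
#' @param path file path.
#' @return A [hyperprior_spec()].
#' @export
read_hyperprior <- function(path) {
  kv <- read_keyvalue(path)
  def <- default_hyperprior()
  parse_vec <- function(s) as.numeric(strsplit(s, ",")[[1]])
  hyperprior_spec(
    theta_min = if (!is.null(kv$theta_min)) parse_vec(kv$theta_min) else def$theta_min,
    theta_max = if (!is.null(kv$theta_max)) parse_vec(kv$theta_max) else def$theta_max,
    mu_xi = if (!is.null(kv$mu_xi)) as.numeric(kv$mu_xi) else def$mu_xi,
    sigma_xi = if (!is.null(kv$sigma_xi)) as.numeric(kv$sigma_xi) else def$sigma_xi
  )
}

# minimal key = value reader used for plain-text configs
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    out[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  out
}
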