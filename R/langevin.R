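#' Configuration for the overdamped Langevin generator
#'
#' @param n_steps number of integration steps.
#' @param dt time step (dimensionless simulation units).
#' @param diffusion diffusion coefficient D (units^2 per time unit); a
#'   scalar, or one value per dimension for anisotropic coordinates (the
#'   activation order parameters span very different length scales, so the
#'   default three-basin world uses per-axis D proportional to the squared
#'   axis scale).
#' @param kT thermal energy in kcal/mol; default 0.596 (300 K).
#' @param x0 initial point; default the first basin centre / domain midpoint.
#' @param seed RNG seed; a fixed seed gives byte-identical trajectories.
#' @param thin keep every `thin`-th frame (frame 0 always kept).
#' @return a `langevin_config`.
#' @export
langevin_config <- function(n_steps, dt = 0.01, diffusion = 1, kT = 0.596,
                            x0 = NULL, seed = 1L, thin = 1L) {
  stopifnot(n_steps >= 1, dt > 0, all(diffusion >= 0), kT > 0, thin >= 1)
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 diffusion = as.numeric(diffusion), kT = kT, x0 = x0,
                 seed = as.integer(seed), thin = as.integer(thin)),
            class = "langevin_config")
}

#' Simulate overdamped Langevin (Brownian) dynamics on a potential surface
#'
#' Euler-Maruyama update
#' \deqn{x_{t+1} = x_t - \nabla V(x_t)\,\Delta t\, D / kT + \sqrt{2 D \Delta t}\,\xi_t,}
#' with reflecting domain boundaries. The long-run empirical distribution
#' converges to the Boltzmann distribution \eqn{\propto e^{-V/kT}} on the
#' domain (up to O(dt) discretization bias). This is the synthetic stand-in
#' for molecular-dynamics sampling of the order-parameter landscape.
#'
#' Gaussian-mixture and harmonic surfaces run in compiled code; arbitrary
#' closures fall back to an R loop.
#'
#' @param surface a `potential_surface`.
#' @param config a [langevin_config()]; `x0` must lie inside the domain.
#' @return a [feature_trajectory()] with one row per kept frame; attribute
#'   `"n_reflect"` counts boundary reflections (also reported via a message
#'   when positive).
#' @export
simulate_langevin <- function(surface, config) {
  stopifnot(inherits(surface, "potential_surface"),
            inherits(config, "langevin_config"))
  d <- length(surface$lower)
  x0 <- config$x0
  if (is.null(x0)) {
    x0 <- if (surface$kind == "gaussian_mixture")
      surface$params$centers[1L, ] else (surface$lower + surface$upper) / 2
  }
  x0 <- as.numeric(x0)
  if (length(x0) != d) stop("`x0` has wrong dimension")
  if (any(x0 < surface$lower | x0 > surface$upper))
    stop("initial point outside the domain")
  set.seed(config$seed)
  D <- rep(config$diffusion, length.out = d)
  if (all(D == 0)) {
    # zero-temperature quench: deterministic steepest descent with unit
    # diffusion mobility (D enters drift and noise together, so D = 0 is
    # interpreted as "no thermal noise", not "frozen")
    res <- .sim_langevin_quench(surface, x0, config)
  } else if (surface$kind == "gaussian_mixture") {
    p <- surface$params
    res <- .sim_langevin_gaussmix(p$centers, p$depths, p$widths,
                                  p$confinement, p$mid, p$half,
                                  surface$lower, surface$upper, x0,
                                  config$dt, D, config$kT,
                                  config$n_steps, config$thin)
  } else if (surface$kind == "harmonic") {
    res <- .sim_langevin_harmonic(surface$params$k, surface$lower,
                                  surface$upper, x0, config$dt,
                                  D, config$kT,
                                  config$n_steps, config$thin)
  } else {
    res <- .sim_langevin_r(surface, x0, config)
  }
  if (res$n_reflect > 0)
    message(sprintf("simulate_langevin: %d boundary reflection(s)",
                    res$n_reflect))
  labels <- if (d == 2L) c("distance", "angle") else paste0("x", seq_len(d))
  traj <- feature_trajectory(res$traj, labels = labels,
                             dt = config$dt * config$thin)
  attr(traj, "n_reflect") <- res$n_reflect
  traj
}

.sim_langevin_quench <- function(surface, x0, config) {
  d <- length(x0)
  nout <- config$n_steps %/% config$thin + 1L
  out <- matrix(NA_real_, nout, d)
  out[1L, ] <- x <- x0
  drift <- config$dt / config$kT
  row <- 1L
  for (t in seq_len(config$n_steps)) {
    x <- x - surface$gradient(x) * drift
    x <- pmin(pmax(x, surface$lower), surface$upper)
    if (t %% config$thin == 0L) {
      row <- row + 1L
      out[row, ] <- x
    }
  }
  list(traj = out, n_reflect = 0L)
}

# Reference R integrator for arbitrary energy/gradient closures.
.sim_langevin_r <- function(surface, x0, config) {
  d <- length(x0)
  nout <- config$n_steps %/% config$thin + 1L
  out <- matrix(NA_real_, nout, d)
  out[1L, ] <- x <- x0
  D <- rep(config$diffusion, length.out = d)
  drift <- config$dt * D / config$kT
  noise <- sqrt(2 * D * config$dt)
  nref <- 0L
  row <- 1L
  for (t in seq_len(config$n_steps)) {
    g <- surface$gradient(x)
    if (any(!is.finite(g))) stop("non-finite gradient during integration")
    x <- x - g * drift + noise * stats::rnorm(d)
    while (any(x < surface$lower | x > surface$upper)) {
      x <- ifelse(x < surface$lower, 2 * surface$lower - x, x)
      x <- ifelse(x > surface$upper, 2 * surface$upper - x, x)
      nref <- nref + 1L
    }
    if (t %% config$thin == 0L) {
      row <- row + 1L
      out[row, ] <- x
    }
  }
  list(traj = out, n_reflect = nref)
}
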