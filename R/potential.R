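#' Model potential surfaces
#'
#' A `potential_surface` bundles an energy evaluator \eqn{V(x)} (kcal/mol), its
#' analytic gradient, and rectangular domain bounds. Surfaces drive the
#' overdamped Langevin generator ([simulate_langevin()]) and the nudged elastic
#' band optimizer ([anneal_band()]); their Boltzmann weights are the oracle for
#' Markov-state-model population recovery ([boltzmann_populations()]).
#'
#' @name potential_surface
#' @keywords internal
NULL

new_potential_surface <- function(energy, gradient, lower, upper,
                                  kind = "closure", params = NULL) {
  stopifnot(is.function(energy), is.function(gradient),
            length(lower) == length(upper), all(upper > lower))
  structure(
    list(energy = energy, gradient = gradient,
         lower = as.numeric(lower), upper = as.numeric(upper),
         kind = kind, params = params),
    class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("<potential_surface> kind=%s, dim=%d\n", x$kind, length(x$lower)))
  cat("  domain:", paste(sprintf("[%.3g, %.3g]", x$lower, x$upper),
                         collapse = " x "), "\n")
  invisible(x)
}

#' Evaluate a potential surface
#'
#' @param surface a `potential_surface`.
#' @param x a point (numeric vector) or a matrix of points (one per row).
#' @return `surface_energy()`: numeric vector of energies (kcal/mol);
#'   `surface_gradient()`: gradient vector, or matrix of gradients for matrix
#'   input.
#' @export
surface_energy <- function(surface, x) {
  if (!is.matrix(x)) return(surface$energy(x))
  if (!is.null(surface$energy_batch)) return(surface$energy_batch(x))
  apply(x, 1L, surface$energy)
}

#' @rdname surface_energy
#' @export
surface_gradient <- function(surface, x) {
  if (!is.matrix(x)) return(surface$gradient(x))
  if (!is.null(surface$gradient_batch)) return(surface$gradient_batch(x))
  t(apply(x, 1L, surface$gradient))
}

#' Three-basin model potential in activation order-parameter space
#'
#' Builds a smooth two-dimensional surface with exactly three local minima,
#' emulating the inactive / intermediate / active basins of a class A GPCR
#' activation landscape in (TM5-TM7 Calpha distance, TM6 opening angle) space.
#' The surface is a sum of inverted anisotropic Gaussians plus a weak
#' confining quadratic centred on the domain:
#' \deqn{V(x) = \sum_b -A_b \exp\left(-\tfrac12 \sum_k \frac{(x_k - c_{bk})^2}{\sigma_{bk}^2}\right) + \kappa \sum_k \left(\frac{x_k - m_k}{s_k}\right)^2}
#'
#' Default basin centres sit at the inactive (21.3 Å, 38.0°), intermediate
#' (18.0 Å, 48.5°) and active (17.4 Å, 69.4°) regions of the landscape. Depths
#' and widths are fixed package defaults chosen so that (i) the
#' inactive-intermediate saddle is low and the intermediate-active saddle is
#' the highest barrier on the path (the rate-limiting step of activation), and
#' (ii) barrier heights are a few kT at kT = 0.596 kcal/mol so that an
#' affordable trajectory crosses all basins many times.
#'
#' @param centers 3x2 matrix of basin centres, rows = (distance Å, angle deg).
#' @param depths length-3 well depths A_b in kcal/mol.
#' @param widths 3x2 matrix of Gaussian sigma per basin and dimension.
#' @param confinement quadratic coefficient kappa (kcal/mol at the domain
#'   half-width); keeps trajectories on the domain without affecting minima.
#' @param lower,upper domain bounds, (distance, angle).
#' @return a `potential_surface`.
#' @export
make_three_basin_potential <- function(centers = default_basin_centers(),
                                       depths = c(2.60, 1.60, 1.85),
                                       widths = rbind(c(1.00, 3.2),
                                                      c(0.80, 3.0),
                                                      c(0.85, 4.2)),
                                       confinement = 0.6,
                                       lower = c(14, 25), upper = c(26, 85)) {
  centers <- as.matrix(centers)
  widths <- as.matrix(widths)
  if (nrow(centers) != 3L || ncol(centers) != 2L)
    stop("`centers` must be a 3x2 matrix")
  if (any(dist(centers) < 1e-8))
    stop("basin centers must be distinct")
  if (!all(dim(widths) == c(3L, 2L)) || any(widths <= 0))
    stop("`widths` must be a positive 3x2 matrix")
  if (length(depths) != 3L || any(depths <= 0))
    stop("`depths` must be 3 positive well depths")
  # place the minima on the requested centres exactly: the confinement and
  # neighbouring wells tilt each well, so shift the internal Gaussian
  # centres by fixed-point iteration until the total gradient vanishes at
  # the requested centres
  internal <- centers
  for (it in 1:50) {
    s <- make_gaussian_mixture_potential(internal, depths, widths,
                                         confinement, lower, upper)
    g <- surface_gradient(s, centers)
    if (max(abs(g)) < 1e-10) break
    internal <- internal + g * widths^2 / depths
  }
  s <- make_gaussian_mixture_potential(internal, depths, widths,
                                       confinement, lower, upper)
  # the requested basin centres (the Gaussian centres are shifted slightly
  # so that the surface minima land exactly on these)
  s$params$basins <- centers
  s
}

#' Default basin centres of the activation landscape
#'
#' Inactive, intermediate and active basin centres in
#' (distance Å, angle deg) order-parameter space.
#' @return named 3x2 matrix.
#' @export
default_basin_centers <- function() {
  rbind(inactive     = c(21.3, 38.0),
        intermediate = c(18.0, 48.5),
        active       = c(17.4, 69.4))
}

#' General inverted-Gaussian-mixture surface
#'
#' Sum of inverted anisotropic Gaussian wells plus a quadratic confinement;
#' any number of wells, any dimension. Carries its parameters so the
#' compiled Langevin fast path applies.
#'
#' @param centers n_wells x d matrix of well centres.
#' @param depths well depths (kcal/mol).
#' @param widths n_wells x d matrix of Gaussian sigmas.
#' @param confinement quadratic coefficient (kcal/mol at the domain
#'   half-width).
#' @param lower,upper domain bounds.
#' @return a `potential_surface`.
#' @export
make_gaussian_mixture_potential <- function(centers, depths, widths,
                                            confinement, lower, upper) {
  centers <- as.matrix(centers); widths <- as.matrix(widths)
  d <- ncol(centers)
  mid <- (lower + upper) / 2
  half <- (upper - lower) / 2
  energy <- function(x) {
    dx <- sweep(centers, 2L, x)           # rows: center - x
    z2 <- rowSums((dx / widths)^2)
    sum(-depths * exp(-0.5 * z2)) + confinement * sum(((x - mid) / half)^2)
  }
  gradient <- function(x) {
    dx <- sweep(centers, 2L, x, FUN = function(c, x) x - c)  # x - center
    z2 <- rowSums((dx / widths)^2)
    g <- colSums(depths * exp(-0.5 * z2) * dx / widths^2)
    g + 2 * confinement * (x - mid) / half^2
  }
  # vectorized batch evaluators (n points at once); used by the NEB
  # optimizer and the dense-grid routines, where per-point closures are slow
  energy_batch <- function(X) {
    out <- confinement * as.numeric(sweep(X, 2L, mid)^2 %*% (1 / half^2))
    for (b in seq_len(nrow(centers))) {
      z2 <- rowSums(sweep(sweep(X, 2L, centers[b, ]), 2L, widths[b, ],
                          "/")^2)
      out <- out - depths[b] * exp(-0.5 * z2)
    }
    out
  }
  gradient_batch <- function(X) {
    G <- 2 * confinement * sweep(sweep(X, 2L, mid), 2L, half^2, "/")
    for (b in seq_len(nrow(centers))) {
      dx <- sweep(X, 2L, centers[b, ])
      z2 <- rowSums(sweep(dx, 2L, widths[b, ], "/")^2)
      G <- G + depths[b] * exp(-0.5 * z2) * sweep(dx, 2L, widths[b, ]^2,
                                                  "/")
    }
    G
  }
  out <- new_potential_surface(
    energy, gradient, lower, upper, kind = "gaussian_mixture",
    params = list(centers = centers, depths = as.numeric(depths),
                  widths = widths, confinement = confinement,
                  mid = mid, half = half))
  out$energy_batch <- energy_batch
  out$gradient_batch <- gradient_batch
  out
}

#' Harmonic (quadratic) test potential
#'
#' \eqn{V(x) = \tfrac12 \sum_k k_k x_k^2}. The Gibbs distribution is Gaussian
#' with variance kT / k_k per axis, giving closed-form checks for the Langevin
#' sampler.
#'
#' @param k spring constants per dimension (kcal/mol per unit^2).
#' @param lower,upper domain bounds (default +/- 8 sd at kT = 1).
#' @return a `potential_surface`.
#' @export
make_harmonic_potential <- function(k, lower = -8 / sqrt(k), upper = 8 / sqrt(k)) {
  k <- as.numeric(k)
  stopifnot(all(k > 0))
  new_potential_surface(
    energy = function(x) 0.5 * sum(k * x^2),
    gradient = function(x) k * x,
    lower = lower, upper = upper,
    kind = "harmonic", params = list(k = k))
}

#' Locate the local minima of a 2-D surface by dense grid descent
#'
#' Discrete steepest-descent watershed: every grid cell points to its lowest
#' 8-neighbour; cells that are their own lowest neighbour are local minima and
#' label the basins. Used both to enumerate minima and as the basin partition
#' behind [boltzmann_populations()].
#'
#' @param surface a 2-D `potential_surface`.
#' @param resolution grid points per dimension.
#' @return list with `minima` (matrix of minima coordinates), `assignment`
#'   (integer matrix of basin labels), `energy` (grid energies), and the grid
#'   axes `x`, `y`.
#' @export
grid_basins <- function(surface, resolution = 500L) {
  stopifnot(length(surface$lower) == 2L)
  nx <- ny <- as.integer(resolution)
  x <- seq(surface$lower[1], surface$upper[1], length.out = nx)
  y <- seq(surface$lower[2], surface$upper[2], length.out = ny)
  if (surface$kind == "gaussian_mixture") {
    # vectorized evaluation (a scalar-closure double loop is too slow at 500x500)
    p <- surface$params
    xx <- rep(x, times = ny); yy <- rep(y, each = nx)
    acc <- numeric(nx * ny)
    for (b in seq_len(nrow(p$centers))) {
      z2 <- ((xx - p$centers[b, 1]) / p$widths[b, 1])^2 +
            ((yy - p$centers[b, 2]) / p$widths[b, 2])^2
      acc <- acc - p$depths[b] * exp(-0.5 * z2)
    }
    acc <- acc + p$confinement * (((xx - p$mid[1]) / p$half[1])^2 +
                                  ((yy - p$mid[2]) / p$half[2])^2)
    V <- matrix(acc, nx, ny)
  } else {
    V <- outer(seq_len(nx), seq_len(ny),
               Vectorize(function(i, j) surface$energy(c(x[i], y[j]))))
  }
  # index of lowest 8-neighbour (or self) for every cell
  n <- nx * ny
  idx <- matrix(seq_len(n), nx, ny)
  best <- idx
  bestV <- V
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is <- seq_len(nx); js <- seq_len(ny)
    si <- is + di; sj <- js + dj
    ok_i <- si >= 1 & si <= nx; ok_j <- sj >= 1 & sj <= ny
    ii <- is[ok_i]; jj <- js[ok_j]
    nb <- idx[ii + di, jj + dj, drop = FALSE]
    nbV <- V[ii + di, jj + dj, drop = FALSE]
    cur <- bestV[ii, jj, drop = FALSE]
    take <- nbV < cur
    sub_best <- best[ii, jj, drop = FALSE]
    sub_best[take] <- nb[take]
    best[ii, jj] <- sub_best
    cur[take] <- nbV[take]
    bestV[ii, jj] <- cur
  }
  # pointer-jump until every cell reaches its sink
  ptr <- as.integer(best)
  repeat {
    nxt <- ptr[ptr]
    if (identical(nxt, ptr)) break
    ptr <- nxt
  }
  sinks <- sort(unique(ptr))
  lab <- match(ptr, sinks)
  si <- (sinks - 1L) %% nx + 1L
  sj <- (sinks - 1L) %/% nx + 1L
  minima <- cbind(x[si], y[sj])
  colnames(minima) <- c("x", "y")
  list(minima = minima,
       assignment = matrix(lab, nx, ny),
       energy = V, x = x, y = y)
}

#' Boltzmann basin populations by grid integration
#'
#' Integrates \eqn{e^{-V/kT}} over each basin of the watershed partition of a
#' dense grid ([grid_basins()]). This is the independent equilibrium oracle
#' against which MSM stationary distributions and PCCA+ macrostate populations
#' are validated.
#'
#' @param surface a 2-D `potential_surface`.
#' @param kT thermal energy in kcal/mol (default 0.596, i.e. 300 K).
#' @param resolution grid points per dimension.
#' @return named numeric vector of basin probabilities (sums to 1); names are
#'   basin indices, attribute `"minima"` carries the minima coordinates. When
#'   the surface was built by [make_three_basin_potential()] the basins are
#'   matched to the requested centres and named accordingly.
#' @export
boltzmann_populations <- function(surface, kT = 0.596, resolution = 500L) {
  gb <- grid_basins(surface, resolution)
  w <- exp(-(gb$energy - min(gb$energy)) / kT)
  tot <- sum(w)
  p <- vapply(seq_len(nrow(gb$minima)), function(b)
    sum(w[gb$assignment == b]), numeric(1)) / tot
  names(p) <- as.character(seq_along(p))
  basins <- surface$params$basins %||% surface$params$centers
  if (surface$kind == "gaussian_mixture" &&
      nrow(basins) == nrow(gb$minima)) {
    ctr <- basins
    # match each requested centre to the nearest grid minimum
    m <- apply(ctr, 1L, function(cc)
      which.min(colSums((t(gb$minima) - cc)^2)))
    if (!anyDuplicated(m)) {
      p <- p[m]
      names(p) <- rownames(ctr) %||% as.character(seq_along(p))
    }
  }
  stopifnot(abs(sum(p) - 1) < 1e-9)
  attr(p, "minima") <- gb$minima
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
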