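#' Initialize a nudged-elastic-band between two endpoints
#'
#' Replicas are linearly interpolated (evenly spaced) between `start` and
#' `end`. With `superpose = TRUE` and 3-column coordinate matrices as
#' endpoints, the rigid-body difference is first removed by centering both
#' structures and rotating `end` onto `start` ([kabsch_superpose()]), so the
#' band only spans internal deformation.
#'
#' @param start,end endpoint configurations: numeric vectors (order-parameter
#'   space) or n x 3 coordinate matrices (superposable).
#' @param n_replicas total number of replicas including the two endpoints
#'   (>= 3; 20 is a typical choice for receptor activation paths).
#' @param k spring constant (kcal mol^-1 per unit^2); 10 during heating, 50
#'   afterwards in the reference protocol.
#' @param superpose remove rigid-body difference first (matrices only).
#' @return a `neb_band`: list with `replicas` (n_replicas x d matrix, one
#'   replica per row), `k`, `fixed` (endpoint flags), `shape` (original
#'   endpoint dim).
#' @export
init_band <- function(start, end, n_replicas = 20L, k = 10, superpose = FALSE) {
  if (n_replicas < 3L) stop("need at least 3 replicas")
  shape <- if (is.matrix(start)) dim(start) else length(start)
  if (is.matrix(start)) {
    if (!all(dim(start) == dim(end))) stop("endpoint dimension mismatch")
    if (superpose) {
      start <- sweep(start, 2L, colMeans(start))
      end <- sweep(end, 2L, colMeans(end))
      end <- end %*% kabsch_superpose(end, start)$rotation
    }
    start <- as.numeric(start); end <- as.numeric(end)
  } else {
    start <- as.numeric(start); end <- as.numeric(end)
    if (length(start) != length(end)) stop("endpoint dimension mismatch")
  }
  w <- seq(0, 1, length.out = n_replicas)
  replicas <- outer(1 - w, start) + outer(w, end)
  structure(list(replicas = replicas, k = k,
                 fixed = c(TRUE, rep(FALSE, n_replicas - 2L), TRUE),
                 shape = shape),
            class = "neb_band")
}

#' @export
print.neb_band <- function(x, ...) {
  cat(sprintf("<neb_band> %d replicas, dim %d, k = %g\n",
              nrow(x$replicas), ncol(x$replicas), x$k))
  invisible(x)
}

#' NEB tangent at an interior replica
#'
#' Upwind tangent with energy-weighted switching at extrema: along the
#' ascending/descending segment when the energies are monotone through
#' replica i, and the |dV|-weighted mix of both segments at local extrema
#' (weights DVmax on the uphill side of a maximum, swapped at a minimum).
#' The returned tangent is normalized to unit length.
#'
#' @param band a `neb_band`.
#' @param i interior replica index (2 .. n-1, 1-based).
#' @param energies energies of all replicas (or at least i-1, i, i+1).
#' @return unit tangent vector.
#' @export
neb_tangent <- function(band, i, energies) {
  n <- nrow(band$replicas)
  if (i <= 1L || i >= n)
    stop("tangent undefined at fixed endpoint replicas")
  Vm <- energies[i - 1L]; V0 <- energies[i]; Vp <- energies[i + 1L]
  fwd <- band$replicas[i + 1L, ] - band$replicas[i, ]
  bwd <- band$replicas[i, ] - band$replicas[i - 1L, ]
  tau <-
    if (Vp > V0 && V0 > Vm) fwd
    else if (Vp < V0 && V0 < Vm) bwd
    else {
      dVmax <- max(abs(Vp - V0), abs(Vm - V0))
      dVmin <- min(abs(Vp - V0), abs(Vm - V0))
      if (Vp >= Vm) fwd * dVmax + bwd * dVmin
      else          fwd * dVmin + bwd * dVmax
    }
  nt <- sqrt(sum(tau^2))
  if (nt == 0) {
    # degenerate (coincident replicas): fall back to the chord
    tau <- band$replicas[i + 1L, ] - band$replicas[i - 1L, ]
    nt <- sqrt(sum(tau^2))
    if (nt == 0) return(tau)
  }
  tau / nt
}

#' NEB force decomposition
#'
#' For every interior replica: the potential force acts only perpendicular to
#' the path, \eqn{F^\perp = -\nabla V + (\nabla V \cdot \tau)\tau}, and the
#' spring force only parallel,
#' \eqn{F^\parallel = k(|R_{i+1}-R_i| - |R_i-R_{i-1}|)\,\tau}. Endpoint rows
#' are zero (endpoints are fixed).
#'
#' @param band a `neb_band`.
#' @param surface a `potential_surface`.
#' @return list with matrices `tangent`, `f_perp`, `f_par`, `f_total`
#'   (rows = replicas) and vector `energies`.
#' @export
neb_forces <- function(band, surface) {
  R <- band$replicas
  n <- nrow(R)
  V <- surface_energy(surface, R)
  G <- surface_gradient(surface, R)
  if (any(!is.finite(G))) stop("non-finite gradient along the band")
  tangent <- f_perp <- f_par <- matrix(0, n, ncol(R))
  for (i in 2:(n - 1L)) {
    tau <- neb_tangent(band, i, V)
    g <- G[i, ]
    fp <- -g + sum(g * tau) * tau
    fs <- band$k * (sqrt(sum((R[i + 1L, ] - R[i, ])^2)) -
                    sqrt(sum((R[i, ] - R[i - 1L, ])^2)))
    tangent[i, ] <- tau
    f_perp[i, ] <- fp
    f_par[i, ] <- fs * tau
  }
  list(tangent = tangent, f_perp = f_perp, f_par = f_par,
       f_total = f_perp + f_par, energies = V)
}

#' Default annealing schedule for band optimization
#'
#' Mirrors the heat / equilibrate / anneal / cool protocol: heating with a
#' soft spring (k = 10), equilibration and a top-temperature-to-zero
#' annealing ladder with a stiff spring (k = 50), then a zero-temperature
#' quench. The default base temperature is scaled far below the sampling
#' temperature: on a smooth 2-D model surface the band only needs enough
#' noise to hop out of kinks, and replica chains tangle (adjacent replicas
#' swap order) when the thermal spread approaches the replica spacing.
#'
#' @param kT base thermal energy of the ladder (kcal/mol).
#' @param steps_per_phase integration steps per phase.
#' @return data.frame with columns `kT`, `steps`, `k`.
#' @export
neb_default_schedule <- function(kT = 0.05, steps_per_phase = 400L) {
  ladder <- c(500, 400, 300, 200, 100, 50, 20, 5, 0) / 300
  data.frame(
    kT = c(seq(0, 1, length.out = 4L), 1, ladder * 1, 0) * kT,
    steps = steps_per_phase,
    k = c(rep(10, 4L), rep(50, length(ladder) + 1L), 50))
}

#' Anneal a band to a minimum-energy path
#'
#' Overdamped Langevin dynamics on the interior replicas driven by the NEB
#' total force, run through a temperature schedule and finished with a
#' zero-temperature relaxation until the largest interior perpendicular force
#' falls below `tol` (a warning reports the residual otherwise; the band is
#' returned regardless). Endpoints never move.
#'
#' @param band a `neb_band` from [init_band()].
#' @param surface a `potential_surface`.
#' @param schedule data.frame of phases (`kT`, `steps`, `k`), default
#'   [neb_default_schedule()].
#' @param seed RNG seed for the thermal noise.
#' @param dt integration step for replica motion.
#' @param tol convergence threshold on max interior |F_perp| (kcal/mol per
#'   unit coordinate).
#' @param max_relax_steps cap on the final relaxation.
#' @return the optimized `neb_band`, with attributes `residual` (final max
#'   |F_perp|), `converged`, and `energies`.
#' @export
anneal_band <- function(band, surface, schedule = neb_default_schedule(),
                        seed = 1L, dt = 2e-3, tol = 1e-3,
                        max_relax_steps = 200000L) {
  stopifnot(inherits(band, "neb_band"), inherits(surface, "potential_surface"))
  set.seed(seed)
  R <- band$replicas
  n <- nrow(R); d <- ncol(R)
  interior <- which(!band$fixed)
  for (ph in seq_len(nrow(schedule))) {
    band$k <- schedule$k[ph]
    kT_ph <- schedule$kT[ph]
    noise <- sqrt(2 * kT_ph * dt)
    for (s in seq_len(schedule$steps[ph])) {
      f <- neb_forces(band, surface)
      step <- f$f_total[interior, , drop = FALSE] * dt
      if (kT_ph > 0)
        step <- step + noise * matrix(stats::rnorm(length(interior) * d),
                                      length(interior), d)
      newR <- band$replicas[interior, , drop = FALSE] + step
      # keep replicas on the surface domain during hot phases
      lo <- matrix(surface$lower, length(interior), d, byrow = TRUE)
      hi <- matrix(surface$upper, length(interior), d, byrow = TRUE)
      band$replicas[interior, ] <- pmin(pmax(newR, lo), hi)
    }
  }
  # zero-temperature relaxation to the stated force tolerance using the
  # FIRE scheme (fast inertial relaxation engine), the standard choice for
  # band optimization: plain fixed-step descent chatters because the upwind
  # tangent switches discretely near saddles
  residual <- Inf
  steps <- 0L
  v <- matrix(0, length(interior), d)
  dt_f <- dt
  dt_max <- 10 * dt
  alpha <- 0.1
  n_pos <- 0L
  while (steps < max_relax_steps) {
    f <- neb_forces(band, surface)
    Fi <- f$f_total[interior, , drop = FALSE]
    residual <- max(sqrt(rowSums(f$f_perp[interior, , drop = FALSE]^2)))
    if (residual < tol) break
    P <- sum(Fi * v)
    if (P > 0) {
      n_pos <- n_pos + 1L
      nf <- sqrt(sum(Fi^2)); nv <- sqrt(sum(v^2))
      if (nf > 0) v <- (1 - alpha) * v + alpha * nv * Fi / nf
      if (n_pos > 5L) {
        dt_f <- min(dt_f * 1.1, dt_max)
        alpha <- alpha * 0.99
      }
    } else {
      v[] <- 0
      dt_f <- dt_f * 0.5
      alpha <- 0.1
      n_pos <- 0L
    }
    v <- v + Fi * dt_f
    band$replicas[interior, ] <- band$replicas[interior, ] + v * dt_f
    steps <- steps + 1L
  }
  if (residual >= tol)
    warning(sprintf("band not converged: max |F_perp| = %.3g after %d steps",
                    residual, steps))
  attr(band, "residual") <- residual
  attr(band, "converged") <- residual < tol
  attr(band, "energies") <- surface_energy(surface, band$replicas)
  band
}

#' Apex (barrier) energy of a band
#'
#' Maximum energy along the band; with `interpolate = TRUE` (default) a
#' parabola through the apex replica and its neighbours refines the estimate,
#' which removes most of the replica-spacing discretization error at a
#' saddle.
#'
#' @param band an annealed `neb_band`.
#' @param surface a `potential_surface`.
#' @return apex energy (kcal/mol).
#' @export
band_apex <- function(band, surface, interpolate = TRUE) {
  V <- surface_energy(surface, band$replicas)
  i <- which.max(V)
  if (!interpolate || i == 1L || i == nrow(band$replicas)) return(V[i])
  # parabola through (-1, 0, 1) x (V[i-1], V[i], V[i+1]) in arclength
  s0 <- sqrt(sum((band$replicas[i, ] - band$replicas[i - 1L, ])^2))
  s1 <- sqrt(sum((band$replicas[i + 1L, ] - band$replicas[i, ])^2))
  x <- c(-s0, 0, s1); y <- V[(i - 1L):(i + 1L)]
  co <- tryCatch(solve(cbind(1, x, x^2), y), error = function(e) NULL)
  if (is.null(co) || co[3] >= 0) return(V[i])
  max(V[i], co[1] - co[2]^2 / (4 * co[3]))
}

#' Sub-select the most mutually distinct replicas
#'
#' Greedy thinning by adjacent-distance: repeatedly drop the interior replica
#' whose summed distance (RMSD for coordinate bands) to its two current
#' neighbours is smallest, until `n_select` remain. Endpoints are always
#' kept, so the selection spans the full path.
#'
#' @param band a `neb_band`.
#' @param n_select number of replicas to keep (>= 2).
#' @return list with `indices` (kept replica indices, ascending) and
#'   `replicas`.
#' @export
select_replicas <- function(band, n_select) {
  n <- nrow(band$replicas)
  if (n_select > n) stop("n_select exceeds band size")
  if (n_select < 2L) stop("must keep at least the two endpoints")
  keep <- seq_len(n)
  while (length(keep) > n_select) {
    interior <- keep[-c(1L, length(keep))]
    if (length(interior) == 0L) break
    score <- vapply(seq_along(interior), function(j) {
      pos <- which(keep == interior[j])
      prev <- band$replicas[keep[pos - 1L], ]
      nxt <- band$replicas[keep[pos + 1L], ]
      cur <- band$replicas[interior[j], ]
      sqrt(sum((cur - prev)^2)) + sqrt(sum((cur - nxt)^2))
    }, numeric(1))
    keep <- setdiff(keep, interior[which.min(score)])
  }
  list(indices = keep, replicas = band$replicas[keep, , drop = FALSE])
}
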