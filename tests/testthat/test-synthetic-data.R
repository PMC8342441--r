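test_that("three-basin surface places minima at the requested centers", {
  s <- make_three_basin_potential()
  ctr <- s$params$basins
  for (b in 1:3) {
    g <- surface_gradient(s, ctr[b, ])
    expect_lt(sqrt(sum(g^2)), 0.05)
  }
  # closed form at far-apart centers with equal depths/widths: energy at each
  # center is -depth + confinement (cross-Gaussian terms negligible)
  far <- rbind(c(16, 30), c(20, 55), c(24, 80))
  s2 <- make_three_basin_potential(centers = far, depths = rep(2, 3),
                                   widths = matrix(0.5, 3, 2))
  p <- s2$params
  for (b in 1:3) {
    conf <- p$confinement * sum(((far[b, ] - p$mid) / p$half)^2)
    # the internal centres are shifted to put the minima exactly on the
    # requested centres, which perturbs the centre energy at O(shift^2)
    expect_equal(surface_energy(s2, far[b, ]), -2 + conf, tolerance = 1e-2)
  }
  expect_error(make_three_basin_potential(
    centers = rbind(c(1, 1), c(1, 1), c(2, 2))), "distinct")
})

test_that("gradient matches central differences at random interior points", {
  set.seed(11)
  s <- make_three_basin_potential()
  h <- 1e-5
  for (r in 1:25) {
    x <- runif(2, s$lower + 1, s$upper - 1)
    g <- surface_gradient(s, x)
    gn <- vapply(1:2, function(k) {
      e <- c(0, 0); e[k] <- h
      (surface_energy(s, x + e) - surface_energy(s, x - e)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gn)) / max(abs(gn), 1e-8), 1e-4)
    expect_true(all(is.finite(c(g, surface_energy(s, x)))))
  }
})

test_that("dense grid search finds exactly three local minima", {
  gb <- grid_basins(make_three_basin_potential(), resolution = 500L)
  expect_identical(nrow(gb$minima), 3L)
  # minima close to the requested centers
  ctr <- default_basin_centers()
  d <- as.matrix(dist(rbind(ctr, gb$minima)))[1:3, 4:6]
  expect_lt(max(apply(d, 1, min)), 0.5)
})

test_that("harmonic Gibbs variance and Boltzmann marginal are recovered", {
  k <- 2.5; kT <- 1.3
  s <- make_harmonic_potential(k)
  traj <- simulate_langevin(
    s, langevin_config(n_steps = 6e6, dt = 0.005, diffusion = 1, kT = kT,
                       x0 = 0, seed = 5, thin = 600L))
  x <- as.numeric(traj)
  expect_equal(var(x), kT / k, tolerance = 0.05)
  # KS agreement with the Boltzmann (Gaussian) marginal on thinned samples
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", 0, sqrt(kT / k)))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero diffusion gives monotone energy descent to a minimum", {
  s <- make_three_basin_potential()
  traj <- simulate_langevin(
    s, langevin_config(n_steps = 4000, dt = 0.01, diffusion = 0, kT = 0.596,
                       x0 = c(20.0, 44), seed = 1))
  V <- surface_energy(s, as.matrix(traj))
  expect_true(all(diff(V) <= 1e-12))
  final <- as.matrix(traj)[nrow(traj), ]
  g <- surface_gradient(s, final)
  expect_lt(sqrt(sum(g^2)), 1e-3)
})

test_that("seeded trajectories are byte-identical; domain is respected", {
  s <- make_three_basin_potential()
  cfg <- langevin_config(n_steps = 5000, dt = 0.02, seed = 99)
  t1 <- suppressMessages(simulate_langevin(s, cfg))
  t2 <- suppressMessages(simulate_langevin(s, cfg))
  expect_identical(unclass(t1), unclass(t2))
  X <- as.matrix(t1)
  expect_true(all(X[, 1] >= s$lower[1] & X[, 1] <= s$upper[1]))
  expect_true(all(X[, 2] >= s$lower[2] & X[, 2] <= s$upper[2]))
})

test_that("long run visits all basins with near-Boltzmann occupancies", {
  s <- make_three_basin_potential()
  p0 <- boltzmann_populations(s)
  minima <- attr(p0, "minima")
  # kT such that the lowest escape barrier out of the intermediate is ~3 kT
  sad <- grid_saddle_level(s, minima[2, ], minima[3, ], resolution = 100L)
  barrier <- sad$level - surface_energy(s, minima[2, ])
  kT <- barrier / 3
  traj <- suppressMessages(simulate_langevin(
    s, langevin_config(n_steps = 1e6, dt = 0.02, diffusion = c(1.5, 8),
                       kT = kT, seed = 1)))
  # Voronoi partition (axis-scaled) used consistently for both sides
  scale <- apply(minima, 2, function(v) diff(range(v)) / 2)
  Z <- sweep(as.matrix(traj), 2, scale, "/")
  Cz <- sweep(minima, 2, scale, "/")
  lab <- conformpath:::.assign_nearest(Z, Cz)
  occ <- tabulate(lab, 3) / length(lab)
  # Boltzmann weights on the same Voronoi partition
  nx <- 300
  gx <- seq(s$lower[1], s$upper[1], length.out = nx)
  gy <- seq(s$lower[2], s$upper[2], length.out = nx)
  G <- cbind(rep(gx, times = nx), rep(gy, each = nx))
  w <- exp(-(surface_energy(s, G) - min(surface_energy(s, minima))) / kT)
  glab <- conformpath:::.assign_nearest(sweep(G, 2, scale, "/"), Cz)
  pv <- vapply(1:3, function(b) sum(w[glab == b]), numeric(1)) / sum(w)
  expect_true(all(occ > 0.02))           # all three basins visited
  expect_lt(max(abs(occ - pv)), 0.10)
})

test_that("boltzmann_populations: symmetry, offset ratio, grid refinement", {
  # symmetric double well in 2-D -> 50/50. Wells deep relative to kT so
  # that essentially all probability mass lies inside the wells: the
  # discrete watershed splits near-flat plateau regions only approximately
  # (8-neighbour drainage quantization), which is irrelevant exactly when
  # the plateau carries no weight.
  sym <- make_gaussian_mixture_potential(
    centers = rbind(c(-1.5, 0), c(1.5, 0)), depths = c(4, 4),
    widths = matrix(0.35, 2, 2), confinement = 0.2,
    lower = c(-4, -4), upper = c(4, 4))
  p <- boltzmann_populations(sym, kT = 0.25, resolution = 401L)
  expect_equal(as.numeric(p), c(0.5, 0.5), tolerance = 1e-5)
  expect_lt(abs(sum(p) - 1), 1e-9)

  # wells offset by dV (same deep-well regime). Independent oracle: the
  # separatrix between far-apart wells on the x axis is the x = 0 plane,
  # so the population ratio equals the half-plane quadrature of e^(-V/kT).
  # Gaussian wells of equal sigma stiffen as they deepen, so the
  # idealized identical-shape ratio e^(-dV/kT) carries a Laplace
  # curvature correction (A1/A2); both are checked.
  dV <- 0.7; kT <- 0.35
  off <- make_gaussian_mixture_potential(
    centers = rbind(c(-1.5, 0), c(1.5, 0)), depths = c(4 + dV, 4),
    widths = matrix(0.35, 2, 2), confinement = 0.0001,
    lower = c(-4, -4), upper = c(4, 4))
  p2 <- boltzmann_populations(off, kT = kT, resolution = 501L)
  gx <- seq(-4, 4, length.out = 801L)
  G <- as.matrix(expand.grid(x = gx, y = gx))
  w <- exp(-surface_energy(off, G) / kT)
  ratio_quad <- sum(w[G[, 1] > 0]) / sum(w[G[, 1] < 0])
  expect_equal(unname(p2[2] / p2[1]), ratio_quad, tolerance = 0.005)
  expect_equal(unname(p2[2] / p2[1]), (4.7 / 4) * exp(-dV / kT),
               tolerance = 0.03)

  # grid-refinement self-consistency on the default surface
  s <- make_three_basin_potential()
  pa <- boltzmann_populations(s, resolution = 500L)
  pb <- boltzmann_populations(s, resolution = 1000L)
  expect_lt(max(abs(pa - pb)), 1e-3)
})

test_that("dose-response generator: zero noise, EC50 limit, determinism", {
  tr0 <- dose_response_truth(basal = 5, Emax = 95, n = 1.2, LogKA = -7.5,
                             LogR = 8, noise_sd = 0, n_replicates = 2,
                             seed = 3)
  d0 <- generate_dose_response(tr0)
  mu <- operational_forward(list(basal = 5, Emax = 95, n = 1.2,
                                 LogKA = -7.5, LogR = 8),
                            log10(d0$concentration_M), role = "test")
  expect_equal(d0$response, mu, tolerance = 1e-12)

  # high-KA limit: EC50 = 10^-LogR, so A = 1e-8 with LogR = 8 gives 50
  tr1 <- dose_response_truth(basal = 0, Emax = 100, n = 1, LogKA = Inf,
                             LogR = 8, concentrations = 1e-8, noise_sd = 0,
                             n_replicates = 1)
  expect_equal(generate_dose_response(tr1)$response, 50, tolerance = 1e-6)

  tr <- dose_response_truth(seed = 42)
  expect_identical(generate_dose_response(tr), generate_dose_response(tr))
  expect_error(dose_response_truth(Emax = 10, basal = 20))
  expect_error(dose_response_truth(concentrations = c(1e-9, -1e-8)))
})
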