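# symmetric 2-D double well with an analytic saddle:
# V = (x^2 - 1)^2 + y^2; minima (+-1, 0) at V = 0, saddle (0,0) at V = 1
double_well <- function() {
  new_surface <- conformpath:::new_potential_surface
  new_surface(
    energy = function(p) (p[1]^2 - 1)^2 + p[2]^2,
    gradient = function(p) c(4 * p[1] * (p[1]^2 - 1), 2 * p[2]),
    lower = c(-2.5, -2.5), upper = c(2.5, 2.5))
}

test_that("init_band interpolates linearly and removes rigid motion", {
  b <- init_band(c(0, 0), c(1, 0), n_replicas = 5L)
  expect_equal(b$replicas[, 1], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(b$replicas[, 2], rep(0, 5))
  expect_true(b$fixed[1] && b$fixed[5])

  b2 <- init_band(c(2, 3), c(2, 3), n_replicas = 4L)
  expect_true(all(apply(b2$replicas, 1, identical, c(2, 3))))

  set.seed(41)
  X <- matrix(rnorm(24), 8, 3)
  Y <- X %*% rotation_z(53) + matrix(c(1, -4, 2), 8, 3, byrow = TRUE)
  b3 <- init_band(X, Y, n_replicas = 6L, superpose = TRUE)
  spread <- apply(b3$replicas, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-9)
  expect_error(init_band(c(0, 0), c(1, 1), n_replicas = 2L), "3 replicas")
})

test_that("neb_tangent implements the four energy-ordered cases", {
  b <- init_band(c(0, 0), c(2, 2), n_replicas = 3L)
  b$replicas <- rbind(c(0, 0), c(1, 0.5), c(2, 0))
  fwd <- c(1, -0.5); bwd <- c(1, 0.5)
  unit <- function(v) v / sqrt(sum(v^2))
  expect_equal(neb_tangent(b, 2, c(1, 2, 3)), unit(fwd))
  expect_equal(neb_tangent(b, 2, c(3, 2, 1)), unit(bwd))
  # local max, V = (1, 3, 2): dV -> fwd weight max(|2-3|,|1-3|) = 2, bwd 1
  expect_equal(neb_tangent(b, 2, c(1, 3, 2)), unit(2 * fwd + 1 * bwd))
  # local max, V = (2, 3, 1): V_{i-1} > V_{i+1} -> weights swapped
  expect_equal(neb_tangent(b, 2, c(2, 3, 1)), unit(1 * fwd + 2 * bwd))
  expect_error(neb_tangent(b, 1, c(1, 2, 3)), "endpoint")
  expect_error(neb_tangent(b, 3, c(1, 2, 3)), "endpoint")
})

test_that("neb_forces: orthogonality, flat band, projection oracle", {
  dw <- double_well()
  # gradient parallel to tangent -> F_perp = 0: straight band along x on
  # a 1-D-in-x slice (y = 0 line, gradient has no y component off-minimum)
  b <- init_band(c(-1, 0), c(1, 0), n_replicas = 9L)
  f <- neb_forces(b, dw)
  for (i in 2:8) {
    expect_lt(abs(sum(f$f_perp[i, ] * f$tangent[i, ])),
              1e-8 * max(1, sqrt(sum(f$f_total[i, ]^2))))
    expect_lt(sqrt(sum(f$f_perp[i, ]^2)), 1e-10)  # grad parallel to path
  }
  # evenly spaced straight band on a flat surface -> all forces zero
  flat <- conformpath:::new_potential_surface(
    energy = function(p) 0, gradient = function(p) c(0, 0),
    lower = c(-5, -5), upper = c(5, 5))
  f0 <- neb_forces(init_band(c(-1, -1), c(2, 2), n_replicas = 7L), flat)
  expect_equal(max(abs(f0$f_total)), 0)
  # endpoints never carry force
  expect_equal(f$f_total[c(1, 9), ], matrix(0, 2, 2))
})

test_that("F_perp equals an independent orthogonal-projection oracle", {
  set.seed(43)
  quad <- conformpath:::new_potential_surface(
    energy = function(p) 1.3 * p[1]^2 + 0.4 * p[2]^2 + 0.3 * p[1] * p[2],
    gradient = function(p) c(2.6 * p[1] + 0.3 * p[2],
                             0.8 * p[2] + 0.3 * p[1]),
    lower = c(-5, -5), upper = c(5, 5))
  b <- init_band(c(-2, 1), c(2, -1), n_replicas = 8L)
  b$replicas[2:7, ] <- b$replicas[2:7, ] + matrix(rnorm(12, sd = 0.3), 6, 2)
  f <- neb_forces(b, quad)
  V <- surface_energy(quad, b$replicas)
  for (i in 2:7) {
    tau <- neb_tangent(b, i, V)
    g <- surface_gradient(quad, b$replicas[i, ])
    P <- diag(2) - tau %*% t(tau)   # projector onto tangent-orthogonal space
    expect_equal_tol(f$f_perp[i, ], as.numeric(P %*% (-g)), 1e-8)
  }
})

test_that("annealed band finds the double-well saddle", {
  dw <- double_well()
  b <- init_band(c(-1, 0.4), c(1, -0.2), n_replicas = 15L)
  # endpoints slightly off the minima: relax them onto the minima first
  b$replicas[1, ] <- c(-1, 0); b$replicas[15, ] <- c(1, 0)
  ann <- anneal_band(b, dw, schedule = neb_default_schedule(kT = 0.05),
                     seed = 7, dt = 5e-3, tol = 1e-3)
  expect_true(attr(ann, "converged"))
  interior <- 2:14
  f <- neb_forces(ann, dw)
  expect_lt(max(sqrt(rowSums(f$f_perp[interior, ]^2))), 1e-3)
  expect_equal(band_apex(ann, dw), 1, tolerance = 1e-3)
  # single interior maximum along the path
  V <- surface_energy(dw, ann$replicas)
  peaks <- sum(diff(sign(diff(V))) == -2)
  expect_identical(peaks, 1L)
  # endpoints untouched
  expect_equal(ann$replicas[c(1, 15), ], b$replicas[c(1, 15), ])
})

test_that("band from a minimum to itself collapses to the point", {
  dw <- double_well()
  b <- init_band(c(1, 0), c(1, 0), n_replicas = 8L)
  ann <- anneal_band(b, dw, schedule = neb_default_schedule(kT = 0.02,
                                                           steps_per_phase = 150L),
                     seed = 2, dt = 5e-3)
  expect_lt(max(abs(sweep(ann$replicas, 2, c(1, 0)))), 0.05)
})

test_that("three-basin path passes through the intermediate basin", {
  s <- make_three_basin_potential()
  ctr <- attr(boltzmann_populations(s, resolution = 300L), "minima")
  b <- init_band(ctr[1, ], ctr[3, ], n_replicas = 21L)
  ann <- anneal_band(b, s, seed = 3, dt = 2e-3, tol = 1e-3)
  # oracle: at the connecting energy level, the inactive-active component
  # must contain the intermediate minimum (the MEP runs through its basin)
  sad <- grid_saddle_level(s, ctr[1, ], ctr[3, ], p_via = ctr[2, ],
                           resolution = 120L)
  expect_true(sad$via_connected)
  # the annealed band passes within one grid cell of the intermediate minimum
  d <- sqrt(colSums((t(ann$replicas) - ctr[2, ])^2 /
                    c(sad$grid_dx, sad$grid_dy)^2))
  expect_lt(min(d), sqrt(2))
  # apex within 2% of the grid saddle level (brute-force oracle)
  apex <- band_apex(ann, s)
  expect_lt(abs(apex - sad$level), 0.02 * max(abs(sad$level), 1))
})

test_that("select_replicas keeps endpoints and drops near-duplicates first", {
  b <- init_band(c(0, 0), c(1, 0), n_replicas = 9L)
  all9 <- select_replicas(b, 9L)
  expect_identical(all9$indices, 1:9)
  # collinear evenly spaced band, keep 3 -> endpoints + middle
  sel3 <- select_replicas(b, 3L)
  expect_identical(sel3$indices, c(1L, 5L, 9L))
  # a duplicated replica is removed first
  b2 <- b
  b2$replicas[4, ] <- b2$replicas[5, ]
  keep <- select_replicas(b2, 8L)$indices
  expect_true(!(4L %in% keep) || !(5L %in% keep))
  expect_true(all(c(1L, 9L) %in% keep))
  expect_error(select_replicas(b, 1L), "endpoints")
  expect_error(select_replicas(b, 10L), "exceeds")
})
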