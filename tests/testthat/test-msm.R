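test_that("k-means recovers separated clouds; k=1 gives the global mean", {
  set.seed(51)
  X <- rbind(matrix(rnorm(400, 0, 0.1), ncol = 2),
             matrix(rnorm(400, 5, 0.1), ncol = 2))
  m <- cluster_microstates(X, k = 2, seed = 1, standardize = FALSE)
  got <- m$centers[order(m$centers[, 1]), ]
  want <- rbind(colMeans(X[1:200, ]), colMeans(X[201:400, ]))
  expect_lt(max(abs(got - want)), 0.05)

  m1 <- cluster_microstates(X, k = 1, standardize = FALSE)
  expect_equal(as.numeric(m1$centers), colMeans(X), tolerance = 1e-12)

  # fixed seed -> identical assignments
  ma <- cluster_microstates(X, k = 5, seed = 42)
  mb <- cluster_microstates(X, k = 5, seed = 42)
  expect_identical(ma$dtraj, mb$dtraj)
  expect_error(cluster_microstates(X[1:3, ], k = 10), "distinct")
  # assign_microstates maps the training data identically
  expect_identical(assign_microstates(ma, X), ma$dtraj)
})

test_that("count_transitions matches hand enumeration", {
  C <- count_transitions(c(0, 0, 1, 1, 0) + 1L, lag = 1)
  expect_equal(C, matrix(c(1, 1, 1, 1), 2, 2))
  expect_warning(C0 <- count_transitions(c(1L, 2L), lag = 5), "shorter")
  expect_equal(sum(C0), 0)
  # separate trajectories have no cross-boundary counts
  t1 <- c(1L, 1L, 2L); t2 <- c(2L, 1L)
  Csep <- count_transitions(list(t1, t2), lag = 1)
  expect_equal(Csep, matrix(c(1, 1, 1, 0), 2, 2))
  Ccat <- count_transitions(c(t1, t2), lag = 1)
  expect_equal(sum(Ccat) - sum(Csep), 1)  # one extra boundary count
})

test_that("estimate_T: analytic stationary solve and reversibility", {
  C <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE)
  tm <- estimate_T(C)
  expect_equal(tm$T, matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE))
  expect_equal(tm$pi, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(rowSums(tm$T), c(1, 1), tolerance = 1e-12)
  expect_equal(as.numeric(tm$pi %*% tm$T), tm$pi, tolerance = 1e-8)

  # symmetric counts: reversible and nonreversible estimates coincide
  Cs <- matrix(c(5, 2, 3, 2, 6, 1, 3, 1, 4), 3, 3, byrow = TRUE)
  Cs <- (Cs + t(Cs))
  expect_equal(estimate_T(Cs, "reversible")$T, estimate_T(Cs)$T,
               tolerance = 1e-9)

  # detailed balance residual on a random count matrix
  set.seed(52)
  Cr <- matrix(rpois(25, 8) + 1, 5, 5)
  tr <- estimate_T(Cr, "reversible")
  db <- outer(tr$pi, rep(1, 5)) * tr$T
  expect_lt(max(abs(db - t(db))), 1e-8)
})

test_that("SCC restriction drops unreachable states with a message", {
  C <- matrix(0, 3, 3)
  C[1, 2] <- 5; C[2, 1] <- 4; C[1, 1] <- 3
  C[3, 1] <- 2  # state 3 has inflow=0, only outflow: not in the SCC
  expect_message(tm <- estimate_T(C), "strongly connected")
  expect_identical(tm$states, 1:2)
})

test_that("implied timescales: closed form, Markovian flatness, sentinels", {
  TT <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  # direct-from-T closed form to 1e-12
  expect_equal(timescales_from_T(TT, 1, 1L), -1 / log(0.7),
               tolerance = 1e-12)
  # sampled chain: lag 1 and lag 2 agree with -tau/ln lambda within error
  set.seed(53)
  chain <- simulate_chain(TT, 2e5)
  its <- implied_timescales(chain, lags = c(1L, 2L), n_its = 1L)
  expect_equal(its[1, 1], -1 / log(0.7), tolerance = 0.05)
  expect_equal(its[2, 1], its[1, 1], tolerance = 0.08)
  # non-positive eigenvalue -> NA sentinel
  flip <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2, byrow = TRUE)
  expect_true(is.na(timescales_from_T(flip, 1, 1L)))
})

test_that("PCCA+ recovers block structure; m = k is the identity limit", {
  eps <- 1e-6
  blockT <- rbind(c(0.7 - eps, 0.3, eps, 0),
                  c(0.4, 0.6 - eps, 0, eps),
                  c(eps, 0, 0.5 - eps, 0.5),
                  c(0, eps, 0.2, 0.8 - eps))
  blockT <- blockT / rowSums(blockT)
  tm <- estimate_T(blockT * 1e7)  # counts proportional to T
  mac <- pcca(tm, 2)
  expect_identical(mac$crisp[1], mac$crisp[2])
  expect_identical(mac$crisp[3], mac$crisp[4])
  expect_false(mac$crisp[1] == mac$crisp[3])
  expect_equal(sum(mac$macro_pi), 1, tolerance = 1e-9)
  expect_true(all(mac$chi >= 0 & mac$chi <= 1))

  mk <- pcca(tm, 4)
  expect_identical(sort(mk$crisp), 1:4)  # every microstate its own macrostate
})

test_that("CK test: exact 3-state chain passes, memory chain fails", {
  TT <- rbind(c(0.95, 0.04, 0.01),
              c(0.03, 0.94, 0.03),
              c(0.01, 0.05, 0.94))
  set.seed(54)
  chain <- simulate_chain(TT, 3e5)
  macro <- structure(list(crisp = 1:3, states = 1:3, m = 3L,
                          chi = diag(3), macro_pi = rep(1 / 3, 3)),
                     class = "macrostate_model")
  ck <- ck_test(chain, lag = 1L, macro, factors = 2:5)
  expect_true(all(abs(ck$predicted - ck$estimated) < 4 * ck$se + 1e-3))
  # f = 1 is the identity check
  ck1 <- ck_test(chain, lag = 1L, macro, factors = 1L)
  expect_equal(ck1$predicted, ck1$estimated, tolerance = 1e-12)

  # hidden two-step memory: s_t flips only after two identical hidden steps
  set.seed(55)
  hidden <- simulate_chain(rbind(c(0.9, 0.1, 0, 0),
                                 c(0, 0, 0.2, 0.8),
                                 c(0.8, 0.2, 0, 0),
                                 c(0, 0, 0.1, 0.9)), 3e5)
  obs <- ifelse(hidden <= 2, 1L, 2L)
  macro2 <- structure(list(crisp = 1:2, states = 1:2, m = 2L,
                           chi = diag(2), macro_pi = c(0.5, 0.5)),
                      class = "macrostate_model")
  ck2 <- ck_test(obs, lag = 1L, macro2, factors = 2:5)
  expect_gt(max(abs(ck2$predicted - ck2$estimated) / pmax(ck2$se, 1e-12)), 6)
})

test_that("similarity scores follow S = exp(-d/d_scale) with sd scale", {
  # pool of identical frames -> all scores 1, tie resolved to index 1
  rc0 <- representative_conformation(matrix(1, 4, 2))
  expect_identical(rc0$index, 1L)
  expect_true(all(rc0$S == 1))

  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 4; d[2, 3] <- d[3, 2] <- 4
  ds <- sd(c(1, 4, 4))
  sm <- similarity_matrix(d)
  expect_equal(sm$d_scale, ds)
  expect_equal(sm$S, exp(-d / ds), tolerance = 1e-12)
  # a pair separated by exactly d_scale scores e^-1: distances {a, 1, 5}
  # with a chosen so that a = sd({a, 1, 5})
  a <- uniroot(function(a) a - sd(c(a, 1, 5)), c(1.5, 3))$root
  dd <- matrix(0, 3, 3)
  dd[1, 2] <- dd[2, 1] <- a; dd[1, 3] <- dd[3, 1] <- 1
  dd[2, 3] <- dd[3, 2] <- 5
  expect_equal(similarity_matrix(dd)$S[1, 2], exp(-1), tolerance = 1e-6)

  # hand-evaluated 3-frame pool: frames 1 and 2 tie, rule picks frame 1
  rc <- representative_conformation(d = d)
  s12 <- exp(-1 / ds); s13 <- exp(-4 / ds)
  expect_equal(rc$scores, c((s12 + s13) / 2, (s12 + s13) / 2, s13),
               tolerance = 1e-12)
  expect_identical(rc$index, 1L)
})
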