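#' Cluster trajectory features into microstates (seeded k-means++)
#'
#' k-means++ seeding under a fixed RNG seed followed by Lloyd iterations
#' (capped at `max_iter`, 200 in the reference protocol). Features are
#' z-scored per axis by default so that Å and degree axes contribute
#' comparably; the scaling is stored and reapplied when assigning new frames.
#'
#' @param features a [feature_trajectory()] or numeric matrix.
#' @param k number of microstates (200 in the reference protocol).
#' @param max_iter maximum Lloyd iterations.
#' @param seed RNG seed for the k-means++ initialization.
#' @param standardize z-score each feature column first (default TRUE).
#' @param fit_sample optional cap on the number of frames used to fit the
#'   centers (frames are subsampled evenly; all frames are still assigned).
#'   Keeps k-means affordable on very long trajectories.
#' @return a `microstate_model`: list with `centers` (k x d, original units),
#'   `dtraj` (1-based assignments of all input frames), `k`, `seed`,
#'   `center`/`scale` (standardization), `inertia`.
#' @export
cluster_microstates <- function(features, k, max_iter = 200L, seed = 42L,
                                standardize = TRUE, fit_sample = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (k < 1L) stop("k must be positive")
  ndistinct <- nrow(unique(X))
  if (k > ndistinct) stop("k exceeds the number of distinct frames")
  ctr <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (standardize) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  fit_idx <- seq_len(nrow(Z))
  if (!is.null(fit_sample) && nrow(Z) > fit_sample)
    fit_idx <- round(seq(1L, nrow(Z), length.out = fit_sample))
  Zf <- Z[fit_idx, , drop = FALSE]
  set.seed(seed)
  init <- kmeanspp_init(Zf, k)
  km <- if (k == 1L) {
    list(centers = matrix(colMeans(Zf), 1L), tot.withinss =
           sum(sweep(Zf, 2L, colMeans(Zf))^2))
  } else {
    suppressWarnings(stats::kmeans(Zf, centers = init, iter.max = max_iter,
                                   algorithm = "Lloyd"))
  }
  centers_z <- km$centers
  dtraj <- .assign_nearest(Z, centers_z)
  centers <- sweep(sweep(centers_z, 2L, scl, "*"), 2L, ctr, "+")
  colnames(centers) <- colnames(X)
  structure(list(centers = centers, centers_z = centers_z, dtraj = dtraj,
                 k = as.integer(k), seed = as.integer(seed),
                 center = ctr, scale = scl,
                 inertia = km$tot.withinss),
            class = "microstate_model")
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, then each
# next centre sampled with probability proportional to squared distance to
# the nearest chosen centre.
kmeanspp_init <- function(Z, k) {
  n <- nrow(Z)
  ids <- integer(k)
  ids[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(Z, 2L, Z[ids[1L], ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) {
      ids[j] <- sample.int(n, 1L)
    } else {
      ids[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(Z, 2L, Z[ids[j], ])^2))
  }
  Z[ids, , drop = FALSE]
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d, %d frames assigned\n",
              x$k, length(x$dtraj)))
  invisible(x)
}

#' Assign frames to the nearest microstate centre
#'
#' @param model a `microstate_model`.
#' @param features frames to assign (same feature columns as the fit).
#' @return integer vector of 1-based microstate labels.
#' @export
assign_microstates <- function(model, features) {
  X <- as.matrix(features)
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  .assign_nearest(Z, model$centers_z)
}

#' Sliding-window transition counts
#'
#' \eqn{C_{ij} = \#\{t : s_t = i, s_{t+\mathrm{lag}} = j\}}, counted within
#' each trajectory independently (no counts across trajectory boundaries).
#'
#' @param dtrajs integer vector of microstate labels, or a list of such
#'   vectors (one per trajectory).
#' @param lag lag time in frames (>= 1).
#' @param n_states number of states (default: largest label seen).
#' @return n x n count matrix. All-zero (with a warning) when every
#'   trajectory is shorter than `lag + 1`.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1 frame")
  n <- n_states %||% max(vapply(dtrajs, max, numeric(1)))
  C <- matrix(0, n, n)
  usable <- FALSE
  for (s in dtrajs) {
    s <- as.integer(s)
    if (length(s) <= lag) next
    usable <- TRUE
    from <- s[seq_len(length(s) - lag)]
    to <- s[seq_len(length(s) - lag) + lag]
    tab <- table(factor(from, levels = seq_len(n)),
                 factor(to, levels = seq_len(n)))
    C <- C + as.numeric(tab)
  }
  if (!usable) warning("all trajectories shorter than lag; zero counts")
  C
}

#' Estimate a transition matrix from counts
#'
#' Restricts to the largest strongly connected component of the count graph
#' (dropped states are reported via a message), then estimates either the
#' nonreversible maximum-likelihood matrix (row-normalized counts) or the
#' reversible (detailed-balance) maximum-likelihood matrix by the standard
#' self-consistent iteration, converged when no element changes by more than
#' 1e-10. The stationary distribution is the dominant left eigenvector.
#'
#' @param counts square count matrix.
#' @param mode `"nonreversible"` (default) or `"reversible"`.
#' @param lag lag time in frames (metadata, used by timescale/MFPT units).
#' @param dt_frame physical time per frame (metadata).
#' @return a `transition_matrix`: list with `T` (row-stochastic), `C`,
#'   `states` (original state labels kept), `pi`, `lag`, `dt_frame`,
#'   `reversible`.
#' @export
estimate_T <- function(counts, mode = c("nonreversible", "reversible"),
                       lag = 1L, dt_frame = 1) {
  mode <- match.arg(mode)
  C <- as.matrix(counts)
  stopifnot(nrow(C) == ncol(C), all(C >= 0))
  keep <- largest_scc(C)
  if (length(keep) == 0L) stop("empty connected component")
  if (length(keep) < nrow(C))
    message(sprintf("estimate_T: restricting to largest strongly connected component (%d of %d states)",
                    length(keep), nrow(C)))
  C <- C[keep, keep, drop = FALSE]
  if (any(rowSums(C) == 0)) stop("state with zero outgoing counts inside SCC")
  if (mode == "nonreversible") {
    TT <- C / rowSums(C)
  } else {
    TT <- reversible_mle(C)
  }
  pi <- stationary_distribution(TT)
  structure(list(T = TT, C = C, states = keep, pi = pi,
                 lag = as.integer(lag), dt_frame = dt_frame,
                 reversible = mode == "reversible"),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d states, lag %d frame(s)%s\n",
              nrow(x$T), x$lag, if (x$reversible) ", reversible" else ""))
  invisible(x)
}

largest_scc <- function(C) {
  A <- (C > 0) * 1
  diag(A) <- pmax(diag(A), 1)  # self-connectivity never splits a component
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  # largest component; ties broken by total counts
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    tot <- vapply(best, function(b) {
      m <- comp$membership == b
      sum(C[m, m])
    }, numeric(1))
    best <- best[which.max(tot)]
  }
  which(comp$membership == best)
}

# Reversible MLE by the self-consistent update on the symmetric flow matrix
# x_ij: x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j).
reversible_mle <- function(C, tol = 1e-10, max_iter = 10000L) {
  csum <- rowSums(C)
  X <- (C + t(C)) / 2
  X <- X / sum(X)
  Told <- X / rowSums(X)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(csum / xi, csum / xi, "+")
    X <- (C + t(C)) / denom
    X <- X / sum(X)
    Tnew <- X / rowSums(X)
    if (max(abs(Tnew - Told)) < tol) return(Tnew)
    Told <- Tnew
  }
  warning("reversible estimator: not fully converged")
  Told
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Dominant left eigenvector, normalized to a probability vector.
#'
#' @param TT row-stochastic matrix.
#' @return numeric vector `pi` with `pi %*% TT = pi`.
#' @export
stationary_distribution <- function(TT) {
  e <- eigen(t(TT))
  i <- which.max(Re(e$values) - 1e6 * abs(Im(e$values)))
  v <- Re(e$vectors[, i])
  v <- v * sign(sum(v))
  pi <- v / sum(v)
  if (any(pi < -1e-10)) stop("stationary distribution not nonnegative")
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Implied relaxation timescales
#'
#' \eqn{t_i(\tau) = -\tau / \ln |\lambda_i(\tau)|} for the largest nontrivial
#' eigenvalues of the transition matrix estimated at each lag.
#' Lag-independence ("flat" curves) indicates Markovian dynamics at that lag.
#' Non-positive (or unit-modulus) eigenvalues yield `NA` timescales.
#'
#' @param dtrajs discrete trajectories (vector or list).
#' @param lags ascending vector of lag times (frames).
#' @param n_its number of timescales.
#' @param dt_frame physical time per frame; timescales are returned in these
#'   units.
#' @param mode estimator passed to [estimate_T()].
#' @return matrix (length(lags) x n_its) of timescales; rownames are lags.
#' @export
implied_timescales <- function(dtrajs, lags, n_its = 2L, dt_frame = 1,
                               mode = "nonreversible") {
  if (is.unsorted(lags)) stop("lags must be ascending")
  out <- matrix(NA_real_, length(lags), n_its,
                dimnames = list(lags, paste0("t", seq_len(n_its))))
  for (i in seq_along(lags)) {
    C <- count_transitions(dtrajs, lags[i])
    tm <- estimate_T(C, mode = mode, lag = lags[i], dt_frame = dt_frame)
    out[i, ] <- timescales_from_T(tm$T, lags[i] * dt_frame, n_its)
  }
  out
}

#' @rdname implied_timescales
#' @param TT row-stochastic matrix.
#' @param lag_physical physical lag time corresponding to `TT`.
#' @export
timescales_from_T <- function(TT, lag_physical = 1, n_its = 2L) {
  ev <- eigen(TT, only.values = TRUE)$values
  lam <- Mod(ev)[order(Mod(ev), decreasing = TRUE)]
  re <- Re(ev)[order(Mod(ev), decreasing = TRUE)]
  lam <- lam[-1L]  # drop the stationary eigenvalue
  re <- re[-1L]
  n_av <- min(n_its, length(lam))
  ts <- rep(NA_real_, n_its)
  for (j in seq_len(n_av)) {
    # undefined for non-positive (real part) or non-decaying eigenvalues
    if (re[j] > 0 && lam[j] < 1) ts[j] <- -lag_physical / log(lam[j])
  }
  ts
}

#' PCCA+ spectral coarse-graining into metastable macrostates
#'
#' Robust Perron Cluster Cluster Analysis: the `m` dominant right
#' eigenvectors of the transition matrix span an m-simplex whose vertices
#' correspond to maximally metastable sets; the inner-simplex algorithm picks
#' the vertex microstates and the linear transform onto barycentric
#' coordinates gives fuzzy memberships chi (clipped to [0,1] and
#' row-renormalized). For a nonreversible estimate the matrix is first
#' symmetrized with respect to its stationary distribution (which preserves
#' pi and the metastable structure) so the spectrum is real.
#'
#' @param tm a `transition_matrix`.
#' @param m number of macrostates.
#' @return a `macrostate_model`: `chi` (k x m memberships), `crisp` (argmax
#'   assignment per microstate), `macro_pi` (stationary macrostate
#'   probabilities), `m`, plus the microstate `states` labels.
#' @export
pcca <- function(tm, m) {
  TT <- tm$T
  k <- nrow(TT)
  if (m < 2L) stop("need m >= 2 macrostates")
  if (m > k) stop("more macrostates than microstates")
  pi <- tm$pi
  # pi-symmetrized (reversibilized) operator: real spectrum, same pi
  Tsym <- (TT + t(pi * TT) / pi) / 2
  S <- sqrt(pi) * t(t(Tsym) / sqrt(pi))  # D^1/2 Tsym D^-1/2, symmetric
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (m < k && abs(e$values[m] - e$values[m + 1L]) < 1e-10)
    stop("degenerate eigenvalue gap at m = ", m,
         "; choose a different number of macrostates")
  X <- e$vectors[, seq_len(m), drop = FALSE] / sqrt(pi)
  X[, 1L] <- 1  # exact constant first eigenvector
  verts <- inner_simplex_vertices(X)
  A <- tryCatch(solve(X[verts, , drop = FALSE]),
                error = function(e) stop("PCCA+ vertex matrix is singular"))
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  macro_pi <- as.numeric(t(chi) %*% pi)
  macro_pi <- macro_pi / sum(macro_pi)
  structure(list(chi = chi, crisp = crisp, macro_pi = macro_pi,
                 m = as.integer(m), states = tm$states,
                 eigenvalues = e$values[seq_len(m)]),
            class = "macrostate_model")
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat(sprintf("<macrostate_model> %d macrostates; populations: %s\n",
              x$m, paste(sprintf("%.3f", x$macro_pi), collapse = " ")))
  invisible(x)
}

# Inner-simplex vertex search (Deuflhard/Weber ISA): first vertex is the row
# of the eigenvector matrix furthest from the origin; subsequent vertices
# maximize distance after projecting out the directions already chosen.
inner_simplex_vertices <- function(X) {
  m <- ncol(X)
  ind <- integer(m)
  ind[1L] <- which.max(rowSums(X^2))
  Y <- sweep(X, 2L, X[ind[1L], ])
  for (j in seq_len(m - 1L) + 1L) {
    ind[j] <- which.max(rowSums(Y^2))
    v <- Y[ind[j], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-14) stop("degenerate simplex in PCCA+ (coincident vertices)")
    v <- v / nv
    Y <- Y - (Y %*% v) %*% t(v)
  }
  ind
}

#' Empirical macrostate populations (fraction of frames)
#'
#' The fraction of trajectory snapshots whose microstate belongs to each
#' crisp macrostate -- the "proportion of the ensemble" reading of state
#' populations. Unlike the stationary-distribution populations
#' (`macro_pi`), this estimate does not depend on the MSM lag.
#'
#' @param macro a `macrostate_model`.
#' @param dtrajs discrete microstate trajectories (vector or list).
#' @return numeric vector of length m summing to 1.
#' @export
empirical_populations <- function(macro, dtrajs) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  all_s <- unlist(dtrajs, use.names = FALSE)
  lut <- rep(NA_integer_, max(all_s))
  lut[macro$states] <- macro$crisp
  m <- lut[all_s]
  p <- tabulate(m[!is.na(m)], macro$m)
  p / sum(p)
}

#' Label macrostates by landscape position
#'
#' Matches each macrostate's population-weighted mean order parameters to the
#' nearest configured basin centre (inactive / intermediate / active by
#' default), mirroring the spatial reading of the landscape.
#'
#' @param macro a `macrostate_model`.
#' @param micro a `microstate_model` (for centre coordinates).
#' @param basin_centers named matrix of reference centres
#'   (default [default_basin_centers()]).
#' @param pi microstate stationary weights (default: uniform over
#'   microstates).
#' @return character vector of labels, one per macrostate.
#' @export
label_macrostates <- function(macro, micro,
                              basin_centers = default_basin_centers(),
                              pi = NULL) {
  ctr <- micro$centers[macro$states, , drop = FALSE]
  w <- pi %||% rep(1, nrow(ctr))
  means <- t(vapply(seq_len(macro$m), function(j) {
    ww <- macro$chi[, j] * w
    colSums(ctr * ww) / sum(ww)
  }, numeric(ncol(ctr))))
  lab <- rownames(basin_centers)
  # scale axes by the spread of the reference centres before matching
  scl <- apply(basin_centers, 2L, function(cc) max(diff(range(cc)), 1e-12))
  assign <- apply(means, 1L, function(mm)
    which.min(colSums(((t(basin_centers) - mm) / scl)^2)))
  lab[assign]
}

#' Chapman-Kolmogorov test on macrostates
#'
#' Compares, for each macrostate, the self-transition probability predicted
#' by powering the macrostate transition matrix estimated at lag tau
#' (`T(tau)^f`) with the one estimated directly at lag f*tau, for each
#' factor f. Crisp PCCA+ sets coarse-grain the discrete trajectories.
#' Error bars are the multinomial standard errors of the estimated
#' probabilities.
#'
#' @param dtrajs discrete microstate trajectories (vector or list).
#' @param lag base lag (frames).
#' @param macro a `macrostate_model` (crisp sets used).
#' @param factors integer factors f (default 2:5; f = 1 is the identity).
#' @return data.frame with columns `factor`, `macrostate`, `predicted`,
#'   `estimated`, `se` (multinomial error of the estimate, computed from the
#'   number of non-overlapping transition windows, since sliding-window
#'   counts are serially dependent).
#' @export
ck_test <- function(dtrajs, lag, macro, factors = 2:5) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  # map microstate labels to macrostates (frames outside the SCC are dropped)
  lut <- rep(NA_integer_, max(vapply(dtrajs, max, numeric(1))))
  lut[macro$states] <- macro$crisp
  mtrajs <- lapply(dtrajs, function(s) {
    m <- lut[s]
    m[!is.na(m)]
  })
  est_macro_T <- function(l) {
    C <- count_transitions(mtrajs, l, n_states = macro$m)
    list(T = C / pmax(rowSums(C), 1), n = rowSums(C))
  }
  base <- est_macro_T(lag)
  out <- list()
  for (f in factors) {
    pred <- matpow(base$T, f)
    est <- est_macro_T(lag * f)
    for (s in seq_len(macro$m)) {
      p <- est$T[s, s]
      n_eff <- est$n[s] / (lag * f)
      se_est <- sqrt(p * (1 - p) / max(n_eff, 1))
      # the prediction T(tau)^f carries the base-lag estimation error too;
      # delta method on the dominant self-transition term
      p0 <- base$T[s, s]
      n0_eff <- base$n[s] / lag
      se_pred <- f * p0^(f - 1) * sqrt(p0 * (1 - p0) / max(n0_eff, 1))
      out[[length(out) + 1L]] <- data.frame(
        factor = f, macrostate = s,
        predicted = pred[s, s], estimated = p,
        se = sqrt(se_est^2 + se_pred^2))
    }
  }
  do.call(rbind, out)
}

matpow <- function(M, p) {
  out <- diag(nrow(M))
  for (i in seq_len(p)) out <- out %*% M
  out
}

#' Pairwise similarity scores from a distance matrix
#'
#' \eqn{S_{ij} = e^{-d_{ij}/d_{scale}}} with `d_scale` the standard deviation
#' of the pairwise distances (each unordered pair counted once). When all
#' distances are zero the scores are all 1.
#'
#' @param d symmetric distance (RMSD) matrix with zero diagonal.
#' @return list with `S` (similarity matrix) and `d_scale`.
#' @export
similarity_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 candidate frames")
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  d_scale <- stats::sd(d[upper.tri(d)])
  if (!is.finite(d_scale) || d_scale == 0) {
    if (any(d[upper.tri(d)] != 0)) stop("degenerate distance scale")
    return(list(S = matrix(1, nrow(d), ncol(d)), d_scale = 0))
  }
  list(S = exp(-d / d_scale), d_scale = d_scale)
}

#' Most representative conformation of a pool of frames
#'
#' Scores every candidate frame by its mean similarity
#' \eqn{S_{ij} = e^{-d_{ij}/d_{scale}}} to all other frames in the pool and
#' returns the argmax (ties broken by the lowest index). The pool is
#' typically the frames closest to the microstate cluster centres of one
#' macrostate.
#'
#' @param frames list of coordinate matrices (pairwise RMSD with optimal
#'   superposition), or a matrix of feature-space frames (plain Euclidean
#'   distance), or `NULL` when `d` is given.
#' @param d optional precomputed symmetric distance matrix.
#' @param superpose superpose coordinate frames before the RMSD.
#' @return list with `index` (winner), `scores`, `S`, `d_scale`.
#' @export
representative_conformation <- function(frames = NULL, d = NULL,
                                        superpose = TRUE) {
  if (is.null(d)) {
    if (is.matrix(frames))
      d <- as.matrix(stats::dist(frames))
    else
      d <- pairwise_rmsd(frames, superpose = superpose)
  }
  sm <- similarity_matrix(d)
  n <- nrow(sm$S)
  scores <- (rowSums(sm$S) - diag(sm$S)) / (n - 1)
  list(index = which.max(scores), scores = scores, S = sm$S,
       d_scale = sm$d_scale)
}
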