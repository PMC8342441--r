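#' Forward committor probabilities
#'
#' Probability, per microstate, of reaching target set B before source set A.
#' Solves the discrete committor linear system
#' \eqn{(I - T)\,q = 0} on the intermediate states with boundary conditions
#' q = 0 on A and q = 1 on B.
#'
#' @param tm a `transition_matrix` (or plain row-stochastic matrix).
#' @param A,B disjoint, nonempty sets of state indices (1-based, in the
#'   row/column order of the matrix).
#' @return numeric committor vector q+ of length nrow(T), in [0, 1].
#' @export
committor <- function(tm, A, B) {
  TT <- if (inherits(tm, "transition_matrix")) tm$T else as.matrix(tm)
  n <- nrow(TT)
  A <- as.integer(A); B <- as.integer(B)
  if (length(A) == 0L || length(B) == 0L) stop("A and B must be nonempty")
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  q <- numeric(n)
  q[B] <- 1
  C <- setdiff(seq_len(n), union(A, B))
  if (length(C) == 0L) {
    message("committor: A and B cover all states; boundary values returned")
    return(q)
  }
  M <- diag(length(C)) - TT[C, C, drop = FALSE]
  rhs <- rowSums(TT[C, B, drop = FALSE])
  q[C] <- solve(M, rhs)
  pmin(pmax(q, 0), 1)
}

#' Mean first passage time between state sets
#'
#' Per-state first-passage times to the target set solve
#' \eqn{(I - T_{\neg target})\,t = \mathrm{lag}\cdot 1}; the set-level MFPT
#' is the stationary-weighted average over the source states (stationary
#' distribution restricted to the source set and renormalized).
#'
#' @param tm a `transition_matrix` (uses its `pi`, `lag`, `dt_frame`), or a
#'   plain row-stochastic matrix (then supply `pi`/`lag_physical`).
#' @param source,target disjoint sets of state indices.
#' @param lag_physical physical time per matrix application; default
#'   `lag * dt_frame` from the `transition_matrix`, else 1.
#' @param pi stationary weights for the source average; default from the
#'   object (or computed).
#' @return MFPT in physical units (0 when source is a subset of target;
#'   `Inf` with a warning when the target is unreachable).
#' @export
mfpt <- function(tm, source, target, lag_physical = NULL, pi = NULL) {
  if (inherits(tm, "transition_matrix")) {
    TT <- tm$T
    lag_physical <- lag_physical %||% (tm$lag * tm$dt_frame)
    pi <- pi %||% tm$pi
  } else {
    TT <- as.matrix(tm)
    lag_physical <- lag_physical %||% 1
    pi <- pi %||% stationary_distribution(TT)
  }
  n <- nrow(TT)
  source <- as.integer(source); target <- as.integer(target)
  if (all(source %in% target)) return(0)
  notT <- setdiff(seq_len(n), target)
  M <- diag(length(notT)) - TT[notT, notT, drop = FALSE]
  t_not <- tryCatch(solve(M, rep(lag_physical, length(notT))),
                    error = function(e) NULL)
  if (is.null(t_not) || any(t_not < 0)) {
    warning("target unreachable from part of the state space")
    return(Inf)
  }
  tvec <- numeric(n)
  tvec[notT] <- t_not
  src <- setdiff(source, target)
  w <- pi[src]
  if (sum(w) <= 0) w <- rep(1, length(src))
  sum(tvec[src] * w) / sum(w)
}

#' MFPT table between macrostates
#'
#' All pairwise mean first passage times between the crisp PCCA+ macrostate
#' sets of a microstate transition matrix.
#'
#' @param tm a `transition_matrix`.
#' @param macro a `macrostate_model` built from `tm`.
#' @param labels optional macrostate names for the dimnames.
#' @return m x m matrix, entry (a, b) = MFPT from macrostate a to b (0 on the
#'   diagonal), in physical units.
#' @export
mfpt_matrix <- function(tm, macro, labels = NULL) {
  m <- macro$m
  sets <- lapply(seq_len(m), function(j) which(macro$crisp == j))
  out <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a != b) out[a, b] <- mfpt(tm, sets[[a]], sets[[b]])
  }
  dimnames(out) <- list(labels %||% paste0("macro", seq_len(m)),
                        labels %||% paste0("macro", seq_len(m)))
  out
}

#' Net reactive flux (transition-path theory)
#'
#' Effective flux \eqn{f_{ij} = \pi_i q^-_i T_{ij} q^+_j} (with
#' \eqn{q^- = 1 - q^+} for reversible dynamics) and its net part
#' \eqn{\max(f_{ij} - f_{ji}, 0)}.
#'
#' @param tm a `transition_matrix`.
#' @param A,B source and target sets.
#' @return list with `flux`, `net_flux`, `committor`, `total_flux` (reactive
#'   flux out of A), `rate` (flux / stationary reactant probability-time).
#' @export
reactive_flux <- function(tm, A, B) {
  qf <- committor(tm, A, B)
  qb <- 1 - qf
  TT <- tm$T
  f <- (tm$pi * qb) * TT * rep(qf, each = nrow(TT))
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  total <- sum(f[A, , drop = FALSE])
  list(flux = f, net_flux = net, committor = qf, total_flux = total,
       rate = total / (sum(tm$pi * qb) * tm$lag * tm$dt_frame))
}
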