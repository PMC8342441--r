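#' Time-lagged independent component analysis
#'
#' Finds linear combinations of features that decorrelate most slowly:
#' solves the generalized eigenproblem
#' \eqn{C_\tau v = \lambda (C_0 + \epsilon I) v}
#' with \eqn{C_0} the instantaneous covariance (averaged over both ends of
#' the lagged pairs) and \eqn{C_\tau} the symmetrized time-lagged covariance
#' \eqn{(C_\tau + C_\tau^\top)/2}. Eigenvalues are lag-\eqn{\tau}
#' autocorrelations of the components; the implied timescale of component i
#' is \eqn{-\tau/\ln|\lambda_i|}.
#'
#' @param features a [feature_trajectory()] or numeric matrix (T x d), or a
#'   list of them (multiple trajectories).
#' @param lag lag time in frames (>= 1, < T).
#' @param n_components number of components kept.
#' @param eps ridge regularization added to C0; default
#'   `1e-6 * mean(diag(C0))`. Use 0 to require full-rank features (an error
#'   advises regularization if C0 is singular).
#' @param kinetic_map scale components by their eigenvalues (off by
#'   default).
#' @return a `tica_model`: list with `mean`, `components` (d x n, C0-
#'   orthonormal columns), `eigenvalues`, `lag`, `eps`, `timescales`,
#'   `labels`.
#' @export
fit_tica <- function(features, lag, n_components = 2L, eps = NULL,
                     kinetic_map = FALSE) {
  trajs <- if (is.list(features) && !is.data.frame(features))
    lapply(features, as.matrix) else list(as.matrix(features))
  d <- ncol(trajs[[1L]])
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  if (all(vapply(trajs, nrow, 1L) <= lag))
    stop("need at least one trajectory longer than the lag")
  if (n_components > d) stop("more components than features")
  ntot <- sum(vapply(trajs, nrow, 1L))
  mu <- colSums(do.call(rbind, lapply(trajs, function(X)
    colSums(X)))) / ntot
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d); npairs <- 0
  for (X in trajs) {
    Tn <- nrow(X)
    if (Tn <= lag) next
    X0 <- sweep(X[seq_len(Tn - lag), , drop = FALSE], 2L, mu)
    Xt <- sweep(X[seq_len(Tn - lag) + lag, , drop = FALSE], 2L, mu)
    C0 <- C0 + (crossprod(X0) + crossprod(Xt)) / 2
    Ct <- Ct + crossprod(X0, Xt)
    npairs <- npairs + (Tn - lag)
  }
  C0 <- C0 / (npairs - 1)
  Ct <- Ct / (npairs - 1)
  Ct <- (Ct + t(Ct)) / 2
  if (is.null(eps)) eps <- 1e-6 * mean(diag(C0))
  C0r <- C0 + diag(eps, d)
  U <- tryCatch(chol(C0r), error = function(e)
    stop("instantaneous covariance is rank-deficient; ",
         "set eps > 0 to regularize"))
  Ui <- backsolve(U, diag(d))
  M <- t(Ui) %*% Ct %*% Ui
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  keep <- seq_len(n_components)
  V <- Ui %*% e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  if (kinetic_map) V <- sweep(V, 2L, lam, "*")
  ts <- rep(NA_real_, length(lam))
  ok <- lam > 0 & lam < 1
  ts[ok] <- -lag / log(lam[ok])
  structure(list(mean = mu, components = V, eigenvalues = lam,
                 C0 = C0, Ct = Ct, lag = lag, eps = eps,
                 timescales = ts, kinetic_map = kinetic_map,
                 labels = colnames(trajs[[1L]])),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> lag %d, %d component(s); eigenvalues: %s\n",
              x$lag, ncol(x$components),
              paste(sprintf("%.4f", x$eigenvalues), collapse = " ")))
  invisible(x)
}

#' Project features onto tICA components
#'
#' \eqn{y = (x - \bar x) V} for the fitted components.
#'
#' @param model a `tica_model`.
#' @param features frames with the same feature columns as the fit.
#' @return a [feature_trajectory()] of projections (columns `tic1`,
#'   `tic2`, ...).
#' @export
tica_transform <- function(model, features) {
  X <- as.matrix(features)
  if (!is.null(model$labels) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$labels))
    stop("feature labels do not match the tICA training features")
  Y <- sweep(X, 2L, model$mean) %*% model$components
  feature_trajectory(Y, labels = paste0("tic", seq_len(ncol(Y))),
                     dt = attr(features, "dt") %||% 1)
}
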