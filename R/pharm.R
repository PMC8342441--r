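#' Operational-model forward response
#'
#' Black-Leff operational model as parameterized in GraphPad-style explicit
#' form, with A = 10^X the agonist concentration (M), LogR = log10(tau/K_A)
#' the transduction coefficient and LogKA = log10 K_A:
#' \preformatted{
#'   operate1 = ((1 + A) / (10^LogR * A))^n            # reference branch
#'   operate2 = ((1 + A/10^LogKA) / (10^LogR * A))^n   # full branch
#'   Y = basal + (Emax - basal) / (1 + operate)
#' }
#' The `role` selects the branch: curves of the reference (wild-type)
#' receptor use `operate1`, all other curves `operate2`.
#'
#' @param params list (or `operational_fit`) with `basal`, `Emax`, `n`,
#'   `LogR`, and `LogKA` (test branch only).
#' @param X log10 agonist concentration (M); concentrations must be
#'   positive (finite X).
#' @param role `"reference"` (operate1) or `"test"` (operate2).
#' @return mean response vector.
#' @export
operational_forward <- function(params, X, role = c("test", "reference")) {
  role <- match.arg(role)
  if (any(!is.finite(X))) stop("non-positive concentration (X must be finite)")
  A <- 10^X
  R <- 10^params$LogR
  num <- if (role == "reference") 1 + A else 1 + A / 10^params$LogKA
  operate <- (num / (R * A))^params$n
  params$basal + (params$Emax - params$basal) / (1 + operate)
}

#' Fit the operational model to dose-response curves
#'
#' Nonlinear least squares over (basal, Emax, n, LogR[, LogKA]) from
#' multi-start initial guesses: asymptotes from the curve extremes, n = 1,
#' LogKA at the mid concentration, and a grid of LogR start values
#' (-2 ... 10 shifted to the concentration scale). Standard errors come from
#' the Gauss-Newton covariance \eqn{\hat\sigma^2 (J^\top J)^{-1}} at the
#' optimum.
#'
#' Curves with no concentration dependence are flagged `identifiable =
#' FALSE` (LogR is unbounded below for a flat curve) rather than returning a
#' silent number.
#'
#' @param data data.frame with columns `concentration_M` and `response`
#'   (replicates as extra rows); >= 5 distinct concentrations required.
#' @param role model branch, see [operational_forward()].
#' @param fix_n optional fixed transducer slope (e.g. shared across
#'   receptors); NULL fits n freely.
#' @return an `operational_fit`: estimates, `sem` per parameter, `sigma`,
#'   `ssr`, `identifiable`, `converged`, `role`, `n_obs`.
#' @export
fit_operational <- function(data, role = c("test", "reference"),
                            fix_n = NULL) {
  role <- match.arg(role)
  stopifnot(all(c("concentration_M", "response") %in% names(data)))
  conc <- data$concentration_M
  if (any(conc <= 0)) stop("concentrations must be positive")
  X <- log10(conc)
  y <- data$response
  if (length(unique(conc)) < 5L)
    stop("need at least 5 distinct concentrations")
  ord <- order(X)
  ylo <- mean(y[X <= stats::quantile(X, 0.2)])
  yhi <- mean(y[X >= stats::quantile(X, 0.8)])
  basal0 <- min(ylo, yhi)
  emax0 <- max(ylo, yhi, max(y))
  span <- max(emax0 - basal0, 1e-8)
  # flat-curve guard: response range indistinguishable from noise
  res_sd <- stats::sd(y - stats::ave(y, X))
  flat <- (max(stats::ave(y, X)) - min(stats::ave(y, X))) <
    2 * max(res_sd, 1e-12) ||
    abs(yhi - ylo) < 0.05 * max(abs(y), 1)
  midX <- stats::median(X)
  free <- c("basal", "Emax", if (is.null(fix_n)) "n", "LogR",
            if (role == "test") "LogKA")
  make_theta <- function(LogR0) {
    th <- c(basal = basal0, Emax = emax0, n = 1, LogR = LogR0,
            LogKA = midX)
    th[free]
  }
  predict_fun <- function(th) {
    p <- as.list(th)
    if (!is.null(fix_n)) p$n <- fix_n
    if (role == "reference") p$LogKA <- Inf
    operational_forward(p, X, role = role)
  }
  obj <- function(th) {
    mu <- predict_fun(th)
    if (any(!is.finite(mu))) return(1e12)
    sum((y - mu)^2)
  }
  starts <- lapply(seq(-2, 10, by = 2), make_theta)
  starts <- c(starts, list(make_theta(-midX)))  # EC50 at the mid concentration
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(stats::optim(th0, obj, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("operational-model fit failed from all starts")
  # polish with Nelder-Mead, then a final BFGS from the polished point
  pol <- stats::optim(best$par, obj,
                      control = list(maxit = 2000, reltol = 1e-14))
  if (pol$value < best$value) best <- pol
  fin <- tryCatch(stats::optim(best$par, obj, method = "BFGS",
                               control = list(maxit = 500,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
  if (!is.null(fin) && fin$value <= best$value) best <- fin
  th <- best$par
  mu <- predict_fun(th)
  ssr <- best$value
  dof <- max(length(y) - length(th), 1L)
  sigma <- sqrt(ssr / dof)
  J <- numeric_jacobian(predict_fun, th)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * sigma^2, error = function(e)
    matrix(NA_real_, length(th), length(th)))
  sem <- sqrt(pmax(diag(cov), 0))
  names(sem) <- names(th)
  pars <- as.list(th)
  if (!is.null(fix_n)) pars$n <- fix_n
  if (role == "reference") pars$LogKA <- Inf
  identifiable <- !flat && all(is.finite(sem)) &&
    (pars$Emax - pars$basal) > 2 * sigma
  structure(list(basal = pars$basal, Emax = pars$Emax, n = pars$n,
                 LogKA = pars$LogKA, LogR = pars$LogR,
                 sem = sem, sigma = sigma, ssr = ssr,
                 cov = cov, identifiable = identifiable,
                 converged = best$convergence == 0, role = role,
                 n_obs = length(y)),
            class = "operational_fit")
}

numeric_jacobian <- function(f, th, h = 1e-6) {
  f0 <- f(th)
  J <- matrix(NA_real_, length(f0), length(th))
  for (j in seq_along(th)) {
    hp <- h * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + hp
    tmm <- th; tmm[j] <- tmm[j] - hp
    J[, j] <- (f(tp) - f(tmm)) / (2 * hp)
  }
  J
}

#' @export
print.operational_fit <- function(x, ...) {
  cat(sprintf("<operational_fit> (%s branch)%s\n", x$role,
              if (!x$identifiable) " [NOT IDENTIFIABLE]" else ""))
  cat(sprintf("  basal=%.3g Emax=%.3g n=%.3g LogKA=%.3g LogR=%.4g (SEM %.3g)\n",
              x$basal, x$Emax, x$n, x$LogKA, x$LogR,
              if ("LogR" %in% names(x$sem)) x$sem[["LogR"]] else NA))
  invisible(x)
}

#' Relative activity of a mutant vs the reference receptor
#'
#' \eqn{\Delta\log(\tau/K_A) = \log(\tau/K_A)_{mut} - \log(\tau/K_A)_{WT}},
#' with the SEM propagated as
#' \eqn{\sqrt{SEM_{mut}^2 + SEM_{WT}^2}}.
#'
#' @param fit_mut,fit_wt `operational_fit` objects for the same pathway.
#' @param pathway_mut,pathway_wt optional pathway labels; a mismatch is an
#'   error.
#' @return list with `delta`, `sem`, and the inputs' LogR values.
#' @export
delta_log_tau_ka <- function(fit_mut, fit_wt, pathway_mut = NULL,
                             pathway_wt = NULL) {
  if (!is.null(pathway_mut) && !is.null(pathway_wt) &&
      !identical(pathway_mut, pathway_wt))
    stop("pathway mismatch: ", pathway_mut, " vs ", pathway_wt)
  if (!isTRUE(fit_mut$converged) || !isTRUE(fit_wt$converged))
    stop("both fits must have converged")
  s1 <- fit_mut$sem[["LogR"]]; s2 <- fit_wt$sem[["LogR"]]
  list(delta = fit_mut$LogR - fit_wt$LogR,
       sem = sqrt(s1^2 + s2^2),
       LogR_mut = fit_mut$LogR, LogR_wt = fit_wt$LogR)
}

#' Bias heat-map matrix from relative activities
#'
#' Arranges delta-log(tau/K_A) entries into a mutants x pathways matrix with
#' symmetric colour-scale bounds (+/- max |delta|). Missing combinations
#' must be marked explicitly with NA entries.
#'
#' @param entries data.frame with columns `receptor`, `pathway`, `delta`
#'   (and optionally `sem`).
#' @return list with `matrix` (mutants x pathways), `sem` matrix (or NULL),
#'   `bounds` = c(-max|delta|, +max|delta|).
#' @export
bias_heatmap <- function(entries) {
  stopifnot(all(c("receptor", "pathway", "delta") %in% names(entries)))
  receptors <- unique(entries$receptor)
  pathways <- unique(entries$pathway)
  M <- matrix(NA_real_, length(receptors), length(pathways),
              dimnames = list(receptors, pathways))
  S <- if ("sem" %in% names(entries)) M else NULL
  for (i in seq_len(nrow(entries))) {
    M[entries$receptor[i], entries$pathway[i]] <- entries$delta[i]
    if (!is.null(S)) S[entries$receptor[i], entries$pathway[i]] <-
        entries$sem[i]
  }
  b <- max(abs(M), na.rm = TRUE)
  list(matrix = M, sem = S, bounds = c(-b, b))
}
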