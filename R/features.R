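#' Time-ordered feature trajectory
#'
#' A thin matrix wrapper: T x d numeric matrix of feature values with column
#' labels and a frame spacing (time units per row). All downstream stages
#' (landscape, MSM, tICA) consume this container.
#'
#' @param x numeric matrix (or vector for d = 1), one row per frame.
#' @param labels feature labels; defaults to existing column names.
#' @param dt frame spacing in time units.
#' @return a `feature_trajectory` (matrix subclass).
#' @export
feature_trajectory <- function(x, labels = colnames(x), dt = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stop("feature values must be finite")
  if (is.null(labels)) labels <- paste0("f", seq_len(ncol(x)))
  stopifnot(length(labels) == ncol(x), dt > 0)
  colnames(x) <- labels
  structure(x, dt = dt, class = c("feature_trajectory", class(x)))
}

#' @export
print.feature_trajectory <- function(x, ...) {
  cat(sprintf("<feature_trajectory> %d frames x %d features (dt = %g)\n",
              nrow(x), ncol(x), attr(x, "dt")))
  cat("  features:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write feature trajectories as CSV
#'
#' CSV layout: `frame` column (0-based) followed by one column per feature;
#' frame spacing stored in a `# dt:` header comment.
#'
#' @param traj a `feature_trajectory`.
#' @param path file path.
#' @return `read_features()`: a `feature_trajectory`.
#' @export
write_features <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt: %.17g", attr(traj, "dt")), con)
  df <- data.frame(frame = seq_len(nrow(traj)) - 1L, unclass(traj),
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  first <- readLines(path, n = 1L)
  dt <- 1
  if (startsWith(first, "# dt:"))
    dt <- as.numeric(sub("# dt:", "", first, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  feature_trajectory(as.matrix(df[, setdiff(names(df), "frame"), drop = FALSE]),
                     dt = dt)
}

#' Ground-truth parameters for synthetic dose-response data
#'
#' Operational-model (Black-Leff) truth for one receptor/pathway:
#' concentration-response curves are generated from the model mean plus i.i.d.
#' Gaussian noise. `LogR` is the transduction coefficient log10(tau/K_A);
#' `LogKA` the log10 agonist dissociation constant (molar).
#'
#' @param basal,Emax response asymptotes (% of reference Emax).
#' @param n transducer slope.
#' @param LogKA log10 K_A (M); `Inf` selects the reference-receptor branch of
#'   the model (operate1), finite values the full branch (operate2).
#' @param LogR log10(tau/K_A).
#' @param concentrations agonist concentration grid (M), strictly positive.
#' @param noise_sd Gaussian noise sd (response units).
#' @param n_replicates replicates per concentration.
#' @param seed RNG seed.
#' @return a `dose_response_truth`.
#' @export
dose_response_truth <- function(basal = 0, Emax = 100, n = 1,
                                LogKA = -7, LogR = 8.5,
                                concentrations = 10^seq(-11, -6, by = 0.5),
                                noise_sd = 5, n_replicates = 3, seed = 1L) {
  stopifnot(Emax >= basal, n > 0, all(concentrations > 0),
            noise_sd >= 0, n_replicates >= 1)
  structure(list(basal = basal, Emax = Emax, n = n, LogKA = LogKA,
                 LogR = LogR, concentrations = as.numeric(concentrations),
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "dose_response_truth")
}

#' Generate synthetic dose-response curves from operational-model truth
#'
#' Forward model via [operational_forward()] (shared with the fitting code's
#' dual-route tests), plus seeded Gaussian noise.
#'
#' @param truth a [dose_response_truth()].
#' @param receptor,pathway labels attached to the output rows.
#' @return data.frame with columns `receptor`, `pathway`, `replicate`,
#'   `concentration_M`, `response`.
#' @export
generate_dose_response <- function(truth, receptor = "WT", pathway = "Gq") {
  stopifnot(inherits(truth, "dose_response_truth"))
  X <- log10(truth$concentrations)
  mu <- operational_forward(
    list(basal = truth$basal, Emax = truth$Emax, n = truth$n,
         LogKA = truth$LogKA, LogR = truth$LogR),
    X, role = if (is.infinite(truth$LogKA)) "reference" else "test")
  set.seed(truth$seed)
  reps <- seq_len(truth$n_replicates)
  out <- expand.grid(replicate = reps, i = seq_along(X))
  out <- data.frame(
    receptor = receptor, pathway = pathway,
    replicate = out$replicate,
    concentration_M = truth$concentrations[out$i],
    response = mu[out$i] + stats::rnorm(nrow(out), 0, truth$noise_sd))
  out[order(out$replicate, out$concentration_M), , drop = FALSE]
}
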