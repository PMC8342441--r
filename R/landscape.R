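#' Estimate a 2-D free-energy landscape by Boltzmann inversion
#'
#' Histograms two feature columns and converts bin probabilities to free
#' energies \eqn{F = -kT \ln(p / p_{max})}, shifted so the most populated bin
#' has F = 0. Empty bins carry `Inf` (never 0, which would fake basins).
#'
#' @param features a [feature_trajectory()] (first two columns used unless
#'   `select` names others).
#' @param bins bins per dimension (default 100 x 100).
#' @param kT thermal energy (kcal/mol).
#' @param range list of two length-2 vectors of axis limits; default the
#'   data range padded by half a bin.
#' @param select indices or names of the two feature columns.
#' @param smooth_sd optional Gaussian bin smoothing (in bins, 0 = off).
#' @return a `free_energy_landscape`: list with `edges` (per axis), `mids`,
#'   `p` (bin probability matrix), `F` (free-energy matrix, kcal/mol), `kT`,
#'   `labels`.
#' @export
estimate_landscape <- function(features, bins = c(100L, 100L), kT = 0.596,
                               range = NULL, select = 1:2, smooth_sd = 0) {
  X <- as.matrix(features)[, select, drop = FALSE]
  if (nrow(X) == 0L) stop("empty trajectory")
  if (ncol(X) != 2L) stop("need exactly 2 feature columns")
  bins <- rep(as.integer(bins), length.out = 2L)
  if (any(bins < 10L)) stop("need at least 10 bins per dimension")
  if (is.null(range)) {
    range <- lapply(1:2, function(k) {
      r <- base::range(X[, k])
      pad <- diff(r) / (2 * bins[k]) + 1e-9
      c(r[1] - pad, r[2] + pad)
    })
  }
  edges <- lapply(1:2, function(k)
    seq(range[[k]][1], range[[k]][2], length.out = bins[k] + 1L))
  ix <- findInterval(X[, 1], edges[[1]], rightmost.closed = TRUE)
  iy <- findInterval(X[, 2], edges[[2]], rightmost.closed = TRUE)
  ok <- ix >= 1L & ix <= bins[1] & iy >= 1L & iy <= bins[2]
  counts <- matrix(0, bins[1], bins[2])
  tab <- table(factor(ix[ok], levels = seq_len(bins[1])),
               factor(iy[ok], levels = seq_len(bins[2])))
  counts[] <- as.numeric(tab)
  if (smooth_sd > 0) counts <- gaussian_blur(counts, smooth_sd)
  p <- counts / sum(counts)
  FE <- matrix(Inf, bins[1], bins[2])
  occ <- p > 0
  FE[occ] <- -kT * log(p[occ] / max(p))
  structure(list(edges = edges,
                 mids = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
                 p = p, F = FE, kT = kT,
                 labels = colnames(X) %||% c("x", "y")),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("<free_energy_landscape> %dx%d bins, kT = %g kcal/mol, %d occupied\n",
              nrow(x$p), ncol(x$p), x$kT, sum(x$p > 0)))
  invisible(x)
}

gaussian_blur <- function(m, sd) {
  r <- ceiling(3 * sd)
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  blur1 <- function(mm) {
    out <- mm * k[r + 1L]
    for (s in seq_len(r)) {
      n <- nrow(mm)
      out[(s + 1L):n, ] <- out[(s + 1L):n, ] + k[r + 1L + s] * mm[1:(n - s), ]
      out[1:(n - s), ] <- out[1:(n - s), ] + k[r + 1L - s] * mm[(s + 1L):n, ]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Bin index of points on a landscape
#'
#' @param landscape a `free_energy_landscape`.
#' @param points matrix with columns matching the landscape axes.
#' @return data.frame with bin indices (`NA` when out of range), `in_range`
#'   flag, and the bin free energy.
#' @export
landscape_bin <- function(landscape, points) {
  points <- as.matrix(points)
  e1 <- landscape$edges[[1]]; e2 <- landscape$edges[[2]]
  i <- findInterval(points[, 1], e1, rightmost.closed = TRUE)
  j <- findInterval(points[, 2], e2, rightmost.closed = TRUE)
  inr <- i >= 1L & i <= length(e1) - 1L & j >= 1L & j <= length(e2) - 1L
  i[!inr] <- NA_integer_; j[!inr] <- NA_integer_
  FE <- rep(NA_real_, nrow(points))
  FE[inr] <- landscape$F[cbind(i[inr], j[inr])]
  data.frame(bin1 = i, bin2 = j, in_range = inr, F = FE)
}

#' Project experimental structures onto a landscape
#'
#' Computes the activation order parameters of each structure and locates
#' them on the free-energy landscape (the Fig.-2B-style projection of
#' crystal/cryo-EM structures onto a simulated landscape). Out-of-range
#' points are flagged, not dropped.
#'
#' @param structures list of `pdb_structure` objects.
#' @param bw_maps a single `bw_map` shared by all structures, or a list, one
#'   per structure.
#' @param landscape a `free_energy_landscape` whose axes are
#'   (distance, angle).
#' @return data.frame with `distance`, `angle`, bin indices, `in_range`, `F`.
#' @export
project_structures <- function(structures, bw_maps, landscape) {
  if (inherits(bw_maps, "bw_map"))
    bw_maps <- rep(list(bw_maps), length(structures))
  op <- t(mapply(function(s, bw) order_params(s, bw), structures, bw_maps))
  cbind(data.frame(distance = op[, 1], angle = op[, 2]),
        landscape_bin(landscape, op))
}

#' Landscape self-consistency across data splits
#'
#' Splits the trajectory (contiguous halves by time, or round-robin by
#' simulation round), estimates a landscape per split on a common grid, and
#' returns the RMS free-energy difference over bins occupied in every split
#' with F <= `fmax` in all of them. Small values indicate a converged
#' landscape.
#'
#' @param features a [feature_trajectory()].
#' @param split `"time"` (contiguous blocks) or `"round"` (interleaved).
#' @param n_splits number of splits (>= 2).
#' @param fmax free-energy cap (kcal/mol) for the comparison.
#' @param ... passed to [estimate_landscape()] (`bins`, `kT`, ...).
#' @return RMS divergence (kcal/mol), with attribute `"n_bins"` compared.
#' @export
landscape_convergence <- function(features, split = c("time", "round"),
                                  n_splits = 2L, fmax = 5, ...) {
  split <- match.arg(split)
  X <- as.matrix(features)
  if (n_splits < 2L) stop("need at least 2 splits")
  idx <- if (split == "time")
    base::split(seq_len(nrow(X)),
                cut(seq_len(nrow(X)), n_splits, labels = FALSE))
  else base::split(seq_len(nrow(X)), rep_len(seq_len(n_splits), nrow(X)))
  rng <- lapply(1:2, function(k) base::range(X[, k]))
  ls <- lapply(idx, function(ii)
    estimate_landscape(feature_trajectory(X[ii, , drop = FALSE],
                                          dt = attr(features, "dt") %||% 1),
                       range = rng, ...))
  Fs <- lapply(ls, `[[`, "F")
  ok <- Reduce(`&`, lapply(Fs, function(f) is.finite(f) & f <= fmax))
  if (!any(ok)) stop("no commonly occupied bins below fmax")
  pairs <- utils::combn(length(Fs), 2L)
  ss <- mean(apply(pairs, 2L, function(pr)
    mean((Fs[[pr[1]]][ok] - Fs[[pr[2]]][ok])^2)))
  out <- sqrt(ss)
  attr(out, "n_bins") <- sum(ok)
  out
}
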