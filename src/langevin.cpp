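#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (Brownian) Euler-Maruyama integrator with reflecting bounds:
//   x <- x - grad(V) * dt * D / kT + sqrt(2 D dt) * xi
// Two parametric fast paths (inverted-Gaussian mixture + quadratic
// confinement; diagonal harmonic well); arbitrary surfaces use the R loop.
// Uses R's RNG so set.seed() gives byte-identical trajectories.

static inline void reflect(double* x, const double* lo, const double* hi,
                           int d, int* nref) {
  for (int k = 0; k < d; ++k) {
    // fold until inside (steps are small; usually one fold)
    while (x[k] < lo[k] || x[k] > hi[k]) {
      if (x[k] < lo[k]) x[k] = 2.0 * lo[k] - x[k];
      if (x[k] > hi[k]) x[k] = 2.0 * hi[k] - x[k];
      ++(*nref);
    }
  }
}

// [[Rcpp::export(name = ".sim_langevin_gaussmix")]]
List sim_langevin_gaussmix(NumericMatrix centers, NumericVector depths,
                           NumericMatrix widths, double confinement,
                           NumericVector mid, NumericVector half,
                           NumericVector lower, NumericVector upper,
                           NumericVector x0, double dt, NumericVector D,
                           double kT, int nsteps, int thin) {
  const int d = x0.size(), nb = centers.nrow();
  const int nout = nsteps / thin + 1;
  NumericMatrix out(nout, d);
  std::vector<double> x(x0.begin(), x0.end()), g(d), drift(d), noise(d);
  for (int k = 0; k < d; ++k) {
    drift[k] = dt * D[k] / kT;
    noise[k] = std::sqrt(2.0 * D[k] * dt);
  }
  int nref = 0, row = 0;
  for (int k = 0; k < d; ++k) out(0, k) = x[k];
  RNGScope scope;
  for (int t = 1; t <= nsteps; ++t) {
    // gradient of the Gaussian mixture + confinement
    for (int k = 0; k < d; ++k)
      g[k] = 2.0 * confinement * (x[k] - mid[k]) / (half[k] * half[k]);
    for (int b = 0; b < nb; ++b) {
      double z2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double z = (x[k] - centers(b, k)) / widths(b, k);
        z2 += z * z;
      }
      const double e = depths[b] * std::exp(-0.5 * z2);
      for (int k = 0; k < d; ++k)
        g[k] += e * (x[k] - centers(b, k)) / (widths(b, k) * widths(b, k));
    }
    for (int k = 0; k < d; ++k)
      x[k] += -g[k] * drift[k] + noise[k] * norm_rand();
    reflect(x.data(), lower.begin(), upper.begin(), d, &nref);
    if (t % thin == 0) {
      ++row;
      for (int k = 0; k < d; ++k) out(row, k) = x[k];
    }
  }
  return List::create(_["traj"] = out, _["n_reflect"] = nref);
}

// [[Rcpp::export(name = ".sim_langevin_harmonic")]]
List sim_langevin_harmonic(NumericVector kspring, NumericVector lower,
                           NumericVector upper, NumericVector x0, double dt,
                           NumericVector D, double kT, int nsteps, int thin) {
  const int d = x0.size();
  const int nout = nsteps / thin + 1;
  NumericMatrix out(nout, d);
  std::vector<double> x(x0.begin(), x0.end()), drift(d), noise(d);
  for (int k = 0; k < d; ++k) {
    drift[k] = dt * D[k] / kT;
    noise[k] = std::sqrt(2.0 * D[k] * dt);
  }
  int nref = 0, row = 0;
  for (int k = 0; k < d; ++k) out(0, k) = x[k];
  RNGScope scope;
  for (int t = 1; t <= nsteps; ++t) {
    for (int k = 0; k < d; ++k)
      x[k] += -kspring[k] * x[k] * drift[k] + noise[k] * norm_rand();
    reflect(x.data(), lower.begin(), upper.begin(), d, &nref);
    if (t % thin == 0) {
      ++row;
      for (int k = 0; k < d; ++k) out(row, k) = x[k];
    }
  }
  return List::create(_["traj"] = out, _["n_reflect"] = nref);
}

// Nearest-centre assignment (Euclidean), 1-based labels.
// [[Rcpp::export(name = ".assign_nearest")]]
IntegerVector assign_nearest(NumericMatrix X, NumericMatrix centers) {
  const int n = X.nrow(), k = centers.nrow(), d = X.ncol();
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = X(i, c) - centers(j, c);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    lab[i] = bj + 1;
  }
  return lab;
}
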