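#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Roessler flow, fixed-step RK4. Output sampled every `dt` time units after a
// transient of `transient` units; returns n_out x 3 matrix (x, y, z).
static inline void rossler_rhs(double a, double b, double c,
                               double x, double y, double z,
                               double &dx, double &dy, double &dz) {
  dx = -y - z;
  dy = x + a * y;
  dz = b + z * (x - c);
}

static inline void rk4_step(double a, double b, double c, double h,
                            double &x, double &y, double &z) {
  double k1x, k1y, k1z, k2x, k2y, k2z, k3x, k3y, k3z, k4x, k4y, k4z;
  rossler_rhs(a, b, c, x, y, z, k1x, k1y, k1z);
  rossler_rhs(a, b, c, x + 0.5 * h * k1x, y + 0.5 * h * k1y, z + 0.5 * h * k1z,
              k2x, k2y, k2z);
  rossler_rhs(a, b, c, x + 0.5 * h * k2x, y + 0.5 * h * k2y, z + 0.5 * h * k2z,
              k3x, k3y, k3z);
  rossler_rhs(a, b, c, x + h * k3x, y + h * k3y, z + h * k3z, k4x, k4y, k4z);
  x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
  y += h / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);
  z += h / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
}

// [[Rcpp::export]]
NumericMatrix rossler_orbit_cpp(int n_out, double dt, int substeps,
                                double a, double b, double c,
                                double x0, double y0, double z0,
                                double transient) {
  if (n_out < 1) stop("n_out must be >= 1");
  if (dt <= 0.0 || substeps < 1) stop("invalid step configuration");
  double h = dt / substeps;
  double x = x0, y = y0, z = z0;
  // burn in the transient at the same step size
  int burn = (int)std::ceil(transient / h);
  for (int i = 0; i < burn; ++i) rk4_step(a, b, c, h, x, y, z);
  NumericMatrix out(n_out, 3);
  for (int i = 0; i < n_out; ++i) {
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
    for (int s = 0; s < substeps; ++s) rk4_step(a, b, c, h, x, y, z);
    if (!std::isfinite(x)) stop("orbit diverged (non-finite state)");
  }
  return out;
}

// Mean log nearest-neighbour divergence curve (Rosenstein). `emb` is the full
// embedded trajectory (rows = delay vectors); references `ref_idx` (0-based)
// are matched to their nearest neighbour outside the Theiler window among
// candidates on a stride grid, then both trajectories are followed k = 0..kmax
// steps. Returns kmax+1 mean log distances (NA where no pair contributed).
// [[Rcpp::export]]
List rosenstein_divergence_cpp(NumericMatrix emb, IntegerVector ref_idx,
                               int theiler, int kmax, int cand_stride) {
  int n = emb.nrow(), m = emb.ncol();
  int last = n - 1 - kmax;  // both i and j must be followable for kmax steps
  if (last < 1) stop("trajectory too short for requested kmax");
  NumericVector acc(kmax + 1, 0.0);
  IntegerVector cnt(kmax + 1, 0);
  int used = 0;
  for (int r = 0; r < ref_idx.size(); ++r) {
    int i = ref_idx[r];
    if (i < 0 || i > last) continue;
    double best = R_PosInf;
    int jbest = -1;
    for (int j = 0; j <= last; j += cand_stride) {
      int lag = j - i; if (lag < 0) lag = -lag;
      if (lag <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = emb(i, k) - emb(j, k);
        d2 += diff * diff;
      }
      if (d2 < best) { best = d2; jbest = j; }
    }
    if (jbest < 0 || best <= 0.0) continue;
    ++used;
    for (int k = 0; k <= kmax; ++k) {
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = emb(i + k, c) - emb(jbest + k, c);
        d2 += diff * diff;
      }
      if (d2 > 0.0) {
        acc[k] += 0.5 * std::log(d2);
        cnt[k] += 1;
      }
    }
  }
  NumericVector curve(kmax + 1);
  for (int k = 0; k <= kmax; ++k)
    curve[k] = cnt[k] > 0 ? acc[k] / cnt[k] : NA_REAL;
  return List::create(_["curve"] = curve, _["n_pairs"] = used);
}

// Correlation sums for the Grassberger-Procaccia estimator. `idx` carries the
// original time index of each row of `emb` so the Theiler exclusion works on
// subsampled point sets. `radii` must be sorted ascending. Returns, for each
// radius, the number of admissible pairs with distance < r, plus the total
// number of admissible pairs.
// [[Rcpp::export]]
List correlation_counts_cpp(NumericMatrix emb, IntegerVector idx,
                            NumericVector radii, int theiler) {
  int n = emb.nrow(), m = emb.ncol(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  std::vector<double> hist(nr, 0.0);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int lag = idx[j] - idx[i]; if (lag < 0) lag = -lag;
      if (lag <= theiler) continue;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = emb(i, c) - emb(j, c);
        d2 += diff * diff;
        if (d2 >= r2[nr - 1]) break;
      }
      total += 1.0;
      if (d2 >= r2[nr - 1]) continue;
      // first radius with d < r (binary search over sorted radii)
      int lo = 0, hi = nr - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (d2 < r2[mid]) hi = mid; else lo = mid + 1;
      }
      hist[lo] += 1.0;
    }
  }
  NumericVector counts(nr);
  double cum = 0.0;
  for (int k = 0; k < nr; ++k) { cum += hist[k]; counts[k] = cum; }
  return List::create(_["counts"] = counts, _["n_pairs"] = total);
}

// Close returns: all (i, p) with ||x_i - x_{i+p}|| < eps, min_p <= p <= max_p.
// [[Rcpp::export]]
DataFrame close_returns_cpp(NumericMatrix emb, double eps,
                            int min_p, int max_p) {
  int n = emb.nrow(), m = emb.ncol();
  std::vector<int> is, ps;
  std::vector<double> ds;
  double e2 = eps * eps;
  for (int i = 0; i < n; ++i) {
    int pmax = std::min(max_p, n - 1 - i);
    for (int p = min_p; p <= pmax; ++p) {
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = emb(i, c) - emb(i + p, c);
        d2 += diff * diff;
        if (d2 >= e2) break;
      }
      if (d2 < e2) {
        is.push_back(i + 1);  // 1-based for R
        ps.push_back(p);
        ds.push_back(std::sqrt(d2));
      }
    }
  }
  return DataFrame::create(_["index"] = is, _["period"] = ps,
                           _["return_distance"] = ds);
}
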