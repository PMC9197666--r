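// Single-pass kernel-regression hole filling.
//
// Every empty voxel is estimated from the PRE-pass filled mask only, so
// the result is independent of visit order and of any parallel
// partition of the empty set. The math mirrors the R reference engine
// exactly: Gaussian weights exp(-||d/M||^2/2) of voxel-center offsets,
// local-linear (or order-0) weighted least squares, estimate = fitted
// intercept.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// per-axis cube offsets for side k (floor-centred for even k)
void cube_offsets(int k, std::vector<int>& off) {
  off.clear();
  int lo = (k % 2 == 1) ? -(k - 1) / 2 : -k / 2;
  int hi = (k % 2 == 1) ? (k - 1) / 2 : k / 2 - 1;
  for (int o = lo; o <= hi; ++o) off.push_back(o);
}

struct LocalSystem {
  arma::mat X;   // n x 4 design (1, d1, d2, d3) in mm
  arma::vec w;   // Gaussian weights
  arma::vec z;   // neighbour intensities
};

// gather filled neighbours in the ksize^3 cube around (c1,c2,c3),
// excluding the center, lexicographic in (d1,d2,d3)
void gather(const NumericVector& intensity, const LogicalVector& filled,
            const IntegerVector& dims, const NumericVector& spacing,
            const arma::vec& bw, int ksize,
            int c1, int c2, int c3, LocalSystem& sys) {
  std::vector<int> off;
  cube_offsets(ksize, off);
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<double> xs, ws, zs;
  for (int a : off) {
    int i = c1 + a;
    if (i < 0 || i >= d1) continue;
    for (int b : off) {
      int j = c2 + b;
      if (j < 0 || j >= d2) continue;
      for (int c : off) {
        if (a == 0 && b == 0 && c == 0) continue;
        int k = c3 + c;
        if (k < 0 || k >= d3) continue;
        R_xlen_t lin = (R_xlen_t)i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (!filled[lin]) continue;
        double e1 = a * spacing[0], e2 = b * spacing[1], e3 = c * spacing[2];
        double u1 = e1 / bw[0], u2 = e2 / bw[1], u3 = e3 / bw[2];
        xs.push_back(e1); xs.push_back(e2); xs.push_back(e3);
        ws.push_back(std::exp(-(u1 * u1 + u2 * u2 + u3 * u3) / 2.0));
        zs.push_back(intensity[lin]);
      }
    }
  }
  const arma::uword n = ws.size();
  sys.X.set_size(n, 4);
  sys.w.set_size(n);
  sys.z.set_size(n);
  for (arma::uword l = 0; l < n; ++l) {
    sys.X(l, 0) = 1.0;
    sys.X(l, 1) = xs[3 * l];
    sys.X(l, 2) = xs[3 * l + 1];
    sys.X(l, 3) = xs[3 * l + 2];
    sys.w(l) = ws[l];
    sys.z(l) = zs[l];
  }
}

// weighted least squares; returns true with the intercept on success
bool solve_fit(const LocalSystem& sys, int order, int min_neighbors,
               double ridge, double& est) {
  const arma::uword n = sys.w.n_elem;
  if ((int)n < min_neighbors || (order == 1 && n < 4)) return false;
  if (order == 0) {
    // convex combination: clamp against floating-point roundoff
    est = arma::dot(sys.w, sys.z) / arma::accu(sys.w);
    est = std::min(std::max(est, sys.z.min()), sys.z.max());
    return true;
  }
  arma::mat A = sys.X.t() * (sys.X.each_col() % sys.w);
  arma::vec b = sys.X.t() * (sys.w % sys.z);
  for (int t = 1; t < 4; ++t) A(t, t) += ridge;
  // same sqrt(eps) identifiability cut as the R reference engine
  double rc = arma::rcond(A);
  if (!std::isfinite(rc) ||
      rc < std::sqrt(std::numeric_limits<double>::epsilon()))
    return false;
  arma::vec coef;
  if (!arma::solve(coef, A, b, arma::solve_opts::no_approx)) return false;
  if (!coef.is_finite()) return false;
  est = coef(0);
  return true;
}

double weighted_mean(const LocalSystem& sys) {
  if (sys.w.n_elem == 0) return NA_REAL;
  double est = arma::dot(sys.w, sys.z) / arma::accu(sys.w);
  return std::min(std::max(est, sys.z.min()), sys.z.max());
}

}  // namespace

// fallback: 0 = leave_empty, 1 = order0, 2 = expand_once
// [[Rcpp::export]]
List krr_fill_cpp(NumericVector intensity, LogicalVector filled,
                  IntegerVector dims, NumericVector spacing,
                  int ksize, NumericVector bandwidth, int order,
                  int min_neighbors, double ridge, int fallback) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  arma::vec bw(3);
  for (int t = 0; t < 3; ++t) bw[t] = bandwidth[t];

  NumericVector out = clone(intensity);
  IntegerVector prov((R_xlen_t)d1 * d2 * d3);
  for (R_xlen_t l = 0; l < prov.size(); ++l) prov[l] = filled[l] ? 1 : 0;

  LocalSystem sys;
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        R_xlen_t lin = (R_xlen_t)i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (filled[lin]) continue;
        gather(intensity, filled, dims, spacing, bw, ksize, i, j, k, sys);
        double est;
        if (solve_fit(sys, order, min_neighbors, ridge, est)) {
          out[lin] = est;
          prov[lin] = 2;
          continue;
        }
        if (fallback == 0) continue;  // leave_empty
        if (fallback == 2) {          // expand_once: retry, same bandwidth
          gather(intensity, filled, dims, spacing, bw, ksize + 2,
                 i, j, k, sys);
          if (solve_fit(sys, order, min_neighbors, ridge, est)) {
            out[lin] = est;
            prov[lin] = 3;
            continue;
          }
        }
        double wm = weighted_mean(sys);
        if (!ISNA(wm)) {
          out[lin] = wm;
          prov[lin] = 3;
        }
      }
    }
  }
  return List::create(_["intensity"] = out, _["provenance"] = prov);
}
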