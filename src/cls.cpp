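#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Euclidean projection of v onto the probability simplex {x >= 0, sum x = 1}
// (sort-and-threshold algorithm).
static void proj_simplex(std::vector<double> &v) {
  const int k = static_cast<int>(v.size());
  std::vector<double> u(v);
  std::sort(u.begin(), u.end(), std::greater<double>());
  double css = 0.0, tau = 0.0;
  int rho = 0;
  for (int i = 0; i < k; ++i) {
    css += u[i];
    double t = (css - 1.0) / (i + 1);
    if (u[i] - t > 0.0) {
      rho = i + 1;
      tau = t;
    }
  }
  if (rho == 0) tau = (css - 1.0) / k; // cannot happen for finite input
  for (int i = 0; i < k; ++i) v[i] = std::max(v[i] - tau, 0.0);
}

// Minimize ||g - M x||^2 over the simplex {x >= 0, 1'x = 1} by accelerated
// projected gradient descent (FISTA with function restart).  M is r x k with
// k small (<= 9); `tol` bounds the max-norm of the projected gradient step.
// [[Rcpp::export(name = ".cls_simplex")]]
List cls_simplex(NumericMatrix M, NumericVector g, double tol = 1e-9,
                 int maxit = 50000) {
  const int r = M.nrow(), k = M.ncol();
  if (g.size() != r) stop("dimension mismatch between M and g");

  // H = M'M, b = M'g
  std::vector<double> H(k * k), b(k);
  for (int a = 0; a < k; ++a) {
    for (int c = 0; c <= a; ++c) {
      double s = 0.0;
      for (int i = 0; i < r; ++i) s += M(i, a) * M(i, c);
      H[a * k + c] = s;
      H[c * k + a] = s;
    }
    double s = 0.0;
    for (int i = 0; i < r; ++i) s += M(i, a) * g[i];
    b[a] = s;
  }
  // Lipschitz constant of the gradient: 2 * ||M||_2^2 <= 2 * ||M||_F^2
  double fro2 = 0.0;
  for (int a = 0; a < k; ++a) fro2 += H[a * k + a];
  double L = 2.0 * fro2;
  if (L <= 0.0) L = 1.0;
  const double step = 1.0 / L;

  std::vector<double> x(k, 1.0 / k), xprev(x), y(x), grad(k), xn(k);
  double tmom = 1.0;

  auto gradient = [&](const std::vector<double> &z, std::vector<double> &out) {
    for (int a = 0; a < k; ++a) {
      double s = -b[a];
      for (int c = 0; c < k; ++c) s += H[a * k + c] * z[c];
      out[a] = 2.0 * s;
    }
  };
  auto objective = [&](const std::vector<double> &z) {
    // ||g||^2 - 2 b'z + z'Hz (constant ||g||^2 omitted: only differences used)
    double s = 0.0;
    for (int a = 0; a < k; ++a) {
      double hz = 0.0;
      for (int c = 0; c < k; ++c) hz += H[a * k + c] * z[c];
      s += z[a] * (hz - 2.0 * b[a]);
    }
    return s;
  };

  bool converged = false;
  int it = 0;
  double fx = objective(x);
  for (it = 1; it <= maxit; ++it) {
    gradient(y, grad);
    for (int a = 0; a < k; ++a) xn[a] = y[a] - step * grad[a];
    proj_simplex(xn);
    double fxn = objective(xn);
    if (fxn > fx) { // restart momentum from the current iterate
      gradient(x, grad);
      for (int a = 0; a < k; ++a) xn[a] = x[a] - step * grad[a];
      proj_simplex(xn);
      fxn = objective(xn);
      tmom = 1.0;
    }
    double tn = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tmom * tmom));
    for (int a = 0; a < k; ++a) y[a] = xn[a] + ((tmom - 1.0) / tn) * (xn[a] - x[a]);
    xprev = x;
    x = xn;
    fx = fxn;
    tmom = tn;
    if (it % 10 == 0 || it == maxit) {
      gradient(x, grad);
      std::vector<double> px(k);
      for (int a = 0; a < k; ++a) px[a] = x[a] - step * grad[a];
      proj_simplex(px);
      double crit = 0.0;
      for (int a = 0; a < k; ++a) crit = std::max(crit, std::fabs(px[a] - x[a]));
      if (crit <= tol) {
        converged = true;
        break;
      }
    }
  }

  NumericVector xout(k);
  double rss = 0.0;
  for (int i = 0; i < r; ++i) {
    double fit = 0.0;
    for (int a = 0; a < k; ++a) fit += M(i, a) * x[a];
    double e = g[i] - fit;
    rss += e * e;
  }
  for (int a = 0; a < k; ++a) xout[a] = x[a];
  return List::create(_["x"] = xout, _["rss"] = rss,
                      _["iterations"] = it, _["converged"] = converged);
}

// Condensed identity state (1..9) of an ordered pair of label pairs.
static inline int condensed_state_cpp(int a1, int a2, int b1, int b2) {
  const bool ii = (a1 == a2), jj = (b1 == b2);
  if (ii && jj) return (a1 == b1) ? 1 : 2;
  if (ii) return (b1 == a1 || b2 == a1) ? 3 : 4;
  if (jj) return (a1 == b1 || a2 == b1) ? 5 : 6;
  const bool m11 = (a1 == b1), m12 = (a1 == b2), m21 = (a2 == b1), m22 = (a2 == b2);
  if ((m11 && m22) || (m12 && m21)) return 7;
  if (m11 || m12 || m21 || m22) return 8;
  return 9;
}

// [[Rcpp::export(name = ".condensed_state_one")]]
int condensed_state_one(int a1, int a2, int b1, int b2) {
  return condensed_state_cpp(a1, a2, b1, b2);
}

// Realized (gold) condensed-state fractions for all ordered pairs from
// founder-allele labels.  h1, h2: n x L integer matrices of haplotype labels.
// Returns a list of nine n x n matrices of per-pair state fractions.
// [[Rcpp::export(name = ".gold_tally")]]
List gold_tally(IntegerMatrix h1, IntegerMatrix h2) {
  const int n = h1.nrow(), L = h1.ncol();
  if (h2.nrow() != n || h2.ncol() != L) stop("haplotype matrices must match");
  List out(9);
  std::vector<NumericMatrix> D;
  D.reserve(9);
  for (int s = 0; s < 9; ++s) D.push_back(NumericMatrix(n, n));

  for (int i = 0; i < n; ++i) {
    int c1 = 0;
    for (int l = 0; l < L; ++l)
      if (h1(i, l) == h2(i, l)) ++c1;
    D[0](i, i) = static_cast<double>(c1) / L;      // state 1: inbred self
    D[6](i, i) = 1.0 - static_cast<double>(c1) / L; // state 7: outbred self
  }

  // permutation for order reversal: 3<->5, 4<->6, identity elsewhere
  const int swp[9] = {0, 1, 4, 5, 2, 3, 6, 7, 8};
  std::vector<int> cnt(9);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int l = 0; l < L; ++l) {
        int s = condensed_state_cpp(h1(i, l), h2(i, l), h1(j, l), h2(j, l));
        ++cnt[s - 1];
      }
      for (int s = 0; s < 9; ++s) {
        double f = static_cast<double>(cnt[s]) / L;
        D[s](i, j) = f;
        D[swp[s]](j, i) = f;
      }
    }
  }
  for (int s = 0; s < 9; ++s) out[s] = D[s];
  return out;
}
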