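#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Graphical lasso by block coordinate descent (Friedman-style).
// Estimates a sparse precision matrix Theta maximizing
//   log det(Theta) - tr(S Theta) - rho * ||Theta||_1 (off-diagonal),
// returning the covariance estimate W and Theta.  Each column update
// solves a lasso problem by coordinate descent on the current W, with an
// incrementally maintained product vector so a pass costs O(p) plus O(p)
// per coefficient that actually moves.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
List glasso_cpp(NumericMatrix S, double rho, int max_outer = 30,
                int max_inner = 50, double tol = 1e-4) {
  int p = S.nrow();
  NumericMatrix W(p, p), B(p, p);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) W(i, j) = S(i, j);
    W(i, i) = S(i, i) + rho;
  }
  double offscale = 0.0;
  int noff = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) { offscale += std::fabs(S(i, j)); ++noff; }
  offscale = (noff > 0) ? offscale / noff : 1.0;
  if (offscale <= 0) offscale = 1.0;

  std::vector<double> wb(p); // (W_{-j,-j} beta) embedded in full index space
  double maxdiff = 0.0;
  bool converged = false;
  int outer = 0;
  for (outer = 0; outer < max_outer; ++outer) {
    maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      // wb = sum_k W[,k] * B(k,j), k != j
      for (int i = 0; i < p; ++i) wb[i] = 0.0;
      for (int k = 0; k < p; ++k) {
        double bk = B(k, j);
        if (k == j || bk == 0.0) continue;
        const double* wcol = &W(0, k);
        for (int i = 0; i < p; ++i) wb[i] += wcol[i] * bk;
      }
      for (int inner = 0; inner < max_inner; ++inner) {
        double del = 0.0;
        for (int i = 0; i < p; ++i) {
          if (i == j) continue;
          double bi = B(i, j);
          double r = S(i, j) - (wb[i] - W(i, i) * bi);
          double nb = soft(r, rho) / W(i, i);
          double diff = nb - bi;
          if (diff != 0.0) {
            B(i, j) = nb;
            const double* wcol = &W(0, i);
            for (int t = 0; t < p; ++t) wb[t] += wcol[t] * diff;
            double ad = std::fabs(diff);
            if (ad > del) del = ad;
          }
        }
        if (del < tol * offscale) break;
      }
      // write the updated column back into W (w12 = W11 beta = wb off j)
      double cd = 0.0;
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        double nw = wb[i];
        double d = std::fabs(nw - W(i, j));
        if (d > cd) cd = d;
        W(i, j) = nw;
        W(j, i) = nw;
      }
      if (cd > maxdiff) maxdiff = cd;
    }
    if (maxdiff < tol * offscale) { converged = true; break; }
    Rcpp::checkUserInterrupt();
  }

  // recover Theta from the regression coefficients
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int i = 0; i < p; ++i)
      if (i != j) dot += W(i, j) * B(i, j);
    double tjj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = tjj;
    for (int i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -B(i, j) * tjj;
  }
  // symmetrize (columns are solved sequentially, so tiny asymmetries remain)
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  return List::create(_["W"] = W, _["Theta"] = Theta,
                      _["iterations"] = outer + 1,
                      _["converged"] = converged,
                      _["residual"] = maxdiff / offscale);
}
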