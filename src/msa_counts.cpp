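#include <Rcpp.h>
using namespace Rcpp;

// Sequence weights by identity clustering: weight(s) = 1 / |{t : id(s,t) >= thr}|.
// Identity is the fraction of equal symbols over all alignment columns
// (gap == gap counts as a match, the convention of the coupling-analysis
// literature).  enc is an N x L integer matrix, states 1..21.
// [[Rcpp::export]]
NumericVector seq_weights_cpp(IntegerMatrix enc, double threshold) {
  int n = enc.nrow(), L = enc.ncol();
  IntegerVector neigh(n, 1); // self always matches
  for (int s = 0; s < n - 1; ++s) {
    for (int t = s + 1; t < n; ++t) {
      int same = 0;
      for (int j = 0; j < L; ++j)
        if (enc(s, j) == enc(t, j)) ++same;
      if ((double)same / L >= threshold) {
        ++neigh[s];
        ++neigh[t];
      }
    }
  }
  NumericVector w(n);
  for (int s = 0; s < n; ++s) w[s] = 1.0 / neigh[s];
  return w;
}

// Weighted pairwise state counts for every column pair i < j.
// Returns an (L*(L-1)/2) x (q*q) matrix; row p = pair (i,j) in column-major
// pair order (i<j), cell (a,b) stored at (a-1)*q + (b-1).
// [[Rcpp::export]]
NumericMatrix pair_counts_cpp(IntegerMatrix enc, NumericVector w, int q) {
  int n = enc.nrow(), L = enc.ncol();
  int np = L * (L - 1) / 2;
  NumericMatrix out(np, q * q);
  int p = 0;
  for (int i = 0; i < L - 1; ++i) {
    for (int j = i + 1; j < L; ++j, ++p) {
      double* row = &out(p, 0);
      for (int s = 0; s < n; ++s) {
        int a = enc(s, i) - 1, b = enc(s, j) - 1;
        out(p, a * q + b) += w[s];
      }
      (void)row;
    }
  }
  return out;
}

// Weighted single-column state counts: L x q matrix.
// [[Rcpp::export]]
NumericMatrix site_counts_cpp(IntegerMatrix enc, NumericVector w, int q) {
  int n = enc.nrow(), L = enc.ncol();
  NumericMatrix out(L, q);
  for (int j = 0; j < L; ++j)
    for (int s = 0; s < n; ++s)
      out(j, enc(s, j) - 1) += w[s];
  return out;
}
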