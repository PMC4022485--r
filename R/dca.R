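#' Mean-field direct information (DI)
#'
#' Direct coupling analysis in the mean-field approximation.  Weighted,
#' pseudocounted 21-state frequencies (gap as the 21st state) give the
#' connected correlation matrix `C_ij(a,b) = f_ij(a,b) - f_i(a) f_j(b)` on
#' the (q-1)-state reduction (the gap state is the gauge reference).  Direct
#' couplings are `e_ij(a,b) = -(C^-1)_ij(a,b)`, and for each pair the
#' two-site direct distribution `P_dir(a,b) ~ exp(e_ij(a,b)) h_i(a) h_j(b)`
#' is fitted so its marginals match the single-site frequencies; the score
#' is its mutual information against the product of marginals,
#' `DI(i,j) = sum_ab P_dir log(P_dir / (f_i f_j)) >= 0`.
#'
#' @param msa An `msa_set`.  Sequence weights are computed with the default
#'   identity threshold when unset.
#' @param pseudocount_frac Pseudocount fraction `lambda / (lambda + M_eff)`
#'   (default 0.5, the standard mean-field choice).
#' @param max_iter Maximum marginal-matching iterations per pair.
#' @param tol Convergence tolerance on the matched marginals.
#' @return A `coev_result` (method `"DI"`).
#' @export
direct_information <- function(msa, pseudocount_frac = 0.5,
                               max_iter = 20000, tol = 1e-4) {
  if (is.null(msa$weights)) msa <- sequence_weights(msa)
  q <- GAP_STATE
  L <- n_cols(msa)
  ft <- frequencies(msa, pseudocount = 0)
  pc <- pseudocount_frac
  f1 <- (1 - pc) * ft$f1 + pc / q
  qr <- q - 1  # reduced states, gap dropped as gauge

  # connected correlations on the reduced alphabet
  cmat <- matrix(0, L * qr, L * qr)
  blk <- function(i) (i - 1) * qr + seq_len(qr)
  p <- 0
  for (i in seq_len(L)) {
    fii <- diag(f1[i, 1:qr]) - tcrossprod(f1[i, 1:qr])
    cmat[blk(i), blk(i)] <- fii
  }
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      p <- p + 1
      f2 <- (1 - pc) * matrix(ft$f2[p, ], q, q, byrow = TRUE) + pc / q^2
      cij <- f2[1:qr, 1:qr] - tcrossprod(f1[i, 1:qr], f1[j, 1:qr])
      cmat[blk(i), blk(j)] <- cij
      cmat[blk(j), blk(i)] <- t(cij)
    }
  }
  cinv <- tryCatch(solve(cmat), error = function(e)
    abort(paste0("singular covariance matrix; increase pseudocount_frac (",
                 conditionMessage(e), ")")))

  scores <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      w <- matrix(1, q, q)
      w[1:qr, 1:qr] <- exp(-cinv[blk(i), blk(j)])
      scores[i, j] <- scores[j, i] <-
        di_pair(w, f1[i, ], f1[j, ], max_iter, tol)
    }
  }
  coev_result("DI", scores,
              params = list(pseudocount_frac = pc,
                            identity_threshold = 0.8, gap = "21st state"),
              column_map = msa$column_map)
}

# fit single-site fields so the two-site direct distribution matches the
# given marginals, then return its mutual information
di_pair <- function(w, fi, fj, max_iter, tol) {
  q <- length(fi)
  mu1 <- rep(1 / q, q)
  mu2 <- rep(1 / q, q)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    s1 <- as.vector(w %*% mu2)
    s2 <- as.vector(crossprod(w, mu1))
    n1 <- fi / s1; n1 <- n1 / sum(n1)
    n2 <- fj / s2; n2 <- n2 / sum(n2)
    d <- max(abs(n1 - mu1), abs(n2 - mu2))
    mu1 <- n1; mu2 <- n2
    if (d < tol) { ok <- TRUE; break }
  }
  if (!ok)
    abort(sprintf("marginal matching did not converge in %d iterations (residual %.2e)",
                  max_iter, d))
  pdir <- w * tcrossprod(mu1, mu2)
  pdir <- pdir / sum(pdir)
  prod <- tcrossprod(fi, fj)
  nz <- pdir > 0
  max(0, sum(pdir[nz] * log(pdir[nz] / prod[nz])))
}
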