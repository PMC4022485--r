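#' Sparse inverse-covariance coevolution scores (PSICOV-style)
#'
#' Builds the weighted sample covariance matrix of the 21-state indicator
#' variables of every alignment column (gap as the 21st state), shrinks it
#' toward its diagonal until positive definite, and estimates a sparse
#' precision matrix Theta by L1-penalized inverse-covariance estimation
#' (graphical lasso).  The column-pair score is the L1 norm of the
#' amino-acid block of Theta, `score(i,j) = sum_{a,b != gap} |Theta_ij(a,b)|`,
#' followed by the average product correction.
#'
#' States never observed at a column carry no signal and are dropped from
#' the covariance matrix before estimation (their precision entries are
#' zero by construction).
#'
#' @param msa An `msa_set`.  Sequence weights are computed with the default
#'   identity threshold when unset.
#' @param lasso_rho L1 penalty (default 0.005).
#' @param shrink Shrinkage step toward the diagonal per positive-definite
#'   check failure.
#' @param max_outer,max_inner,tol Graphical-lasso iteration controls.
#' @return A `coev_result` (method `"PSICOV"`).
#' @export
psicov_score <- function(msa, lasso_rho = 0.005, shrink = 0.05,
                         max_outer = 30, max_inner = 50, tol = 1e-3) {
  if (!is.finite(lasso_rho) || lasso_rho <= 0)
    abort("lasso_rho must be a positive penalty")
  if (is.null(msa$weights)) msa <- sequence_weights(msa)
  q <- GAP_STATE
  L <- n_cols(msa)
  ft <- frequencies(msa, pseudocount = 0)

  # keep observed states only
  state_keep <- lapply(seq_len(L), function(i) which(ft$f1[i, ] > 0))
  sizes <- lengths(state_keep)
  offsets <- cumsum(c(0, sizes[-L]))
  dim_tot <- sum(sizes)
  smat <- matrix(0, dim_tot, dim_tot)
  bi <- function(i) offsets[i] + seq_len(sizes[i])
  for (i in seq_len(L)) {
    ki <- state_keep[[i]]
    smat[bi(i), bi(i)] <- diag(ft$f1[i, ki], nrow = sizes[i]) -
      tcrossprod(ft$f1[i, ki])
  }
  p <- 0
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      p <- p + 1
      f2 <- matrix(ft$f2[p, ], q, q, byrow = TRUE)
      cij <- f2[state_keep[[i]], state_keep[[j]], drop = FALSE] -
        tcrossprod(ft$f1[i, state_keep[[i]]], ft$f1[j, state_keep[[j]]])
      smat[bi(i), bi(j)] <- cij
      smat[bi(j), bi(i)] <- t(cij)
    }
  }

  # shrink toward the diagonal until positive definite
  alpha <- 0
  target <- diag(mean(diag(smat)), dim_tot)
  repeat {
    shrunk <- (1 - alpha) * smat + alpha * target
    ok <- tryCatch({ chol(shrunk); TRUE }, error = function(e) FALSE)
    if (ok) break
    alpha <- alpha + shrink
    if (alpha > 1) abort("covariance matrix could not be made positive definite")
  }

  fit <- glasso_cpp(shrunk, lasso_rho, max_outer = max_outer,
                    max_inner = max_inner, tol = tol)
  if (!fit$converged)
    abort(sprintf(
      "graphical lasso did not converge in %d sweeps (relative residual %.2e); increase max_outer or lasso_rho",
      fit$iterations, fit$residual))
  theta <- fit$Theta

  raw <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      aa_i <- which(state_keep[[i]] != GAP_STATE)
      aa_j <- which(state_keep[[j]] != GAP_STATE)
      blk <- theta[bi(i)[aa_i], bi(j)[aa_j], drop = FALSE]
      raw[i, j] <- raw[j, i] <- sum(abs(blk))
    }
  }
  out <- apc_correct(coev_result("PSICOV_raw", raw,
                                 params = list(lasso_rho = lasso_rho,
                                               shrink_alpha = alpha,
                                               identity_threshold = 0.8,
                                               gap = "21st state"),
                                 column_map = msa$column_map))
  out$method <- "PSICOV"
  out$params$glasso_iterations <- fit$iterations
  out
}
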