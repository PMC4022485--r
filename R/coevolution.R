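#' Coevolution score objects
#'
#' All five scorers return a `coev_result`: a symmetric L x L score matrix
#' over alignment columns (diagonal set to NA, excluded from ranking), the
#' method id, the parameter record, and the column-to-reference map
#' inherited from the alignment.
#'
#' @param method Method id.
#' @param scores Symmetric matrix.
#' @param params Named list of method settings.
#' @param column_map Optional column-to-residue map.
#' @return A `coev_result`.
#' @export
coev_result <- function(method, scores, params = list(), column_map = NULL) {
  stopifnot(nrow(scores) == ncol(scores))
  diag(scores) <- NA_real_
  if (max(abs(scores - t(scores)), na.rm = TRUE) > 1e-8)
    abort("score matrix must be symmetric")
  scores <- (scores + t(scores)) / 2
  diag(scores) <- NA_real_
  structure(list(method = method, scores = scores, params = params,
                 column_map = column_map),
            class = "coev_result")
}

#' @export
print.coev_result <- function(x, ...) {
  cat(x$method, "coevolution scores:", nrow(x$scores), "x", ncol(x$scores),
      "columns\n")
  invisible(x)
}

#' @export
tidy.coev_result <- function(x, ...) {
  L <- nrow(x$scores)
  idx <- which(upper.tri(x$scores), arr.ind = TRUE)
  out <- tibble::tibble(
    col_a = idx[, 1], col_b = idx[, 2],
    score = x$scores[idx]
  )
  if (!is.null(x$column_map)) {
    out$residue_a <- x$column_map[out$col_a]
    out$residue_b <- x$column_map[out$col_b]
  }
  out$method <- x$method
  out
}

#' @export
glance.coev_result <- function(x, ...) {
  v <- x$scores[upper.tri(x$scores)]
  tibble::tibble(method = x$method, n_columns = nrow(x$scores),
                 n_pairs = sum(!is.na(v)),
                 max_score = max(v, na.rm = TRUE),
                 mean_score = mean(v, na.rm = TRUE))
}

# iterate over column pairs of a freq_tables object, applying f(tab21, i, j)
pairwise_apply <- function(ft, f) {
  L <- ft$L
  out <- matrix(NA_real_, L, L)
  p <- 0
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      p <- p + 1
      tab <- matrix(ft$f2[p, ], ft$q, ft$q, byrow = TRUE)
      out[i, j] <- out[j, i] <- f(tab, i, j)
    }
  }
  out
}

#' Mutual information between alignment columns
#'
#' `MI(i,j) = sum_ab f_ij(a,b) log(f_ij / (f_i f_j))` in nats, computed over
#' the 20 amino-acid states (sequences gapped at either column are excluded
#' and the pair table renormalized).  Columns with no jointly ungapped
#' sequences get a sentinel NA score.
#'
#' @param ft A [frequencies()] result.
#' @return A `coev_result` (method `"MI"`).
#' @export
mutual_information <- function(ft) {
  scores <- pairwise_apply(ft, function(tab, i, j) {
    tt <- tab[1:20, 1:20]
    s <- sum(tt)
    if (s <= 0) return(NA_real_)
    p <- tt / s
    fi <- rowSums(p); fj <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(fi, fj)[nz]))
  })
  coev_result("MI", scores,
              params = list(pseudocount = ft$pseudocount, gap = "excluded"),
              column_map = ft$column_map)
}

#' Average product correction
#'
#' `S'(i,j) = S(i,j) - S_i. * S_.j / S..` with row means and the grand mean
#' taken over off-diagonal entries; removes background and phylogenetic
#' signal shared across columns.  The corrected score can be negative.  For
#' L = 2 the correction degenerates to the score itself and an all-zero
#' matrix is returned with a warning.
#'
#' @param result A `coev_result`.
#' @return A `coev_result` with method suffix `"p"` (e.g. `"MIp"`).
#' @export
apc_correct <- function(result) {
  s <- result$scores
  L <- nrow(s)
  if (L < 3) {
    warn("APC is degenerate for L = 2; returning all-zero scores")
    s[] <- 0
    diag(s) <- NA_real_
    return(coev_result(paste0(result$method, "p"), s, result$params,
                       result$column_map))
  }
  rowm <- rowMeans(s, na.rm = TRUE)
  grand <- mean(s[upper.tri(s)], na.rm = TRUE)
  corr <- if (grand == 0) 0 else outer(rowm, rowm) / grand
  out <- s - corr
  diag(out) <- NA_real_
  coev_result(paste0(result$method, "p"), out,
              c(result$params, list(apc = TRUE)), result$column_map)
}

#' Average-product-corrected mutual information (MIp)
#'
#' @param msa An `msa_set`.
#' @param pseudocount Pseudocount passed to [frequencies()].
#' @param weighted Use sequence weights (default FALSE, the original MIp
#'   convention).
#' @return A `coev_result` (method `"MIp"`).
#' @export
mip <- function(msa, pseudocount = 0, weighted = FALSE) {
  ft <- frequencies(strip_weights(msa, weighted), pseudocount)
  out <- apc_correct(mutual_information(ft))
  out$method <- "MIp"
  out
}

strip_weights <- function(msa, weighted) {
  if (!weighted) msa$weights <- NULL
  msa
}

#' Observed-minus-expected-squared covariance (OMES)
#'
#' For each column pair, over the sequences ungapped at both columns:
#' `OMES(i,j) = sum_ab (N_obs(a,b) - N_ex(a,b))^2 / N_valid` with
#' `N_ex = N_valid f_i(a) f_j(b)` from the marginals of the same valid
#' subset.  Zero iff observed equals expected everywhere.
#'
#' @param msa An `msa_set`.
#' @param weighted Use sequence weights (default FALSE, the original
#'   convention).
#' @return A `coev_result` (method `"OMES"`).
#' @export
omes <- function(msa, weighted = FALSE) {
  msa <- strip_weights(msa, weighted)
  ft <- frequencies(msa, pseudocount = 0)
  meff <- ft$m_eff
  scores <- pairwise_apply(ft, function(tab, i, j) {
    cnt <- tab[1:20, 1:20] * meff   # back to weighted counts
    nvalid <- sum(cnt)
    if (nvalid <= 0) return(NA_real_)
    fi <- rowSums(cnt) / nvalid
    fj <- colSums(cnt) / nvalid
    nex <- nvalid * outer(fi, fj)
    sum((cnt - nex)^2) / nvalid
  })
  coev_result("OMES", scores, params = list(weighted = weighted),
              column_map = msa$column_map)
}

#' Background amino-acid frequencies
#'
#' Mean amino-acid frequencies of well-sampled protein databases, in
#' `AA_ALPHABET` order, used as the reference distribution for the SCA
#' positional weights.
#'
#' @return Named numeric vector of length 20 (sums to 1).
#' @export
sca_background <- function() {
  q <- c(A = 0.073, C = 0.025, D = 0.050, E = 0.061, F = 0.042,
         G = 0.072, H = 0.023, I = 0.053, K = 0.064, L = 0.089,
         M = 0.023, N = 0.043, P = 0.052, Q = 0.040, R = 0.052,
         S = 0.073, T = 0.056, V = 0.063, W = 0.013, Y = 0.033)
  q / sum(q)
}

#' Statistical coupling analysis (SCA) scores
#'
#' Deterministic positional-weight form: each column/state gets a
#' conservation weight `phi_i(a) = |log( f_i(a)(1-q_a) / ((1-f_i(a)) q_a) )|`
#' relative to the background frequencies `q_a`, and the score is the
#' Frobenius norm of the weighted covariance tensor,
#' `SCA(i,j) = sqrt( sum_ab [phi_i(a) phi_j(b) (f_ij(a,b) - f_i(a) f_j(b))]^2 )`.
#' Frequencies are indicator frequencies over all sequences (a gap simply
#' contributes to no amino-acid state).  `phi` is regularized with a small
#' pseudocount so boundary frequencies stay finite.
#'
#' @param msa An `msa_set`.
#' @param background_freqs Background distribution (default
#'   [sca_background()]).
#' @param phi_pseudocount Regularizing mixture weight for the frequencies
#'   entering `phi`.
#' @param weighted Use sequence weights (default FALSE).
#' @return A `coev_result` (method `"SCA"`).
#' @export
sca <- function(msa, background_freqs = sca_background(),
                phi_pseudocount = 0.03, weighted = FALSE) {
  msa <- strip_weights(msa, weighted)
  ft <- frequencies(msa, pseudocount = 0)
  q <- background_freqs
  stopifnot(length(q) == 20)
  f1 <- ft$f1[, 1:20, drop = FALSE]
  freg <- (1 - phi_pseudocount) * f1 +
    phi_pseudocount * matrix(q, nrow = ft$L, ncol = 20, byrow = TRUE)
  qm <- matrix(q, nrow = ft$L, ncol = 20, byrow = TRUE)
  phi <- abs(log(freg * (1 - qm) / ((1 - freg) * qm)))
  scores <- pairwise_apply(ft, function(tab, i, j) {
    cc <- tab[1:20, 1:20] - outer(f1[i, ], f1[j, ])
    wcc <- outer(phi[i, ], phi[j, ]) * cc
    sqrt(sum(wcc^2))
  })
  coev_result("SCA", scores,
              params = list(variant = "positional-weight Frobenius",
                            phi_pseudocount = phi_pseudocount,
                            weighted = weighted),
              column_map = msa$column_map)
}
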