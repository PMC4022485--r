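#' Build an anisotropic network model
#'
#' Standard pairwise Hessian of a C-alpha elastic network: for residues in
#' contact (distance at or below the cutoff) the 3x3 off-diagonal
#' super-element is `-gamma * dr dr^T / |dr|^2` (rank 1 along the bond), and
#' diagonal super-elements are minus the sum of the off-diagonal ones, so
#' rigid-body translations and rotations give six zero modes.
#'
#' @param model A `structure_tbl`.
#' @param cutoff Contact cutoff in Angstrom (default 13).
#' @param gamma Uniform spring constant.
#' @return An object of class `anm_network` holding the 3N x 3N Hessian.
#' @export
build_anm <- function(model, cutoff = 13, gamma = 1) {
  xyz <- ca_coords(model)
  n <- nrow(xyz)
  if (n < 3) abort("need at least 3 residues to build an ANM")
  sv <- svd(scale(xyz, scale = FALSE))$d
  if (sv[2] < 1e-6 * sv[1])
    abort("degenerate (collinear) geometry; ANM undefined")
  structure(list(hessian = anm_hessian(xyz, cutoff, gamma),
                 cutoff = cutoff, gamma = gamma,
                 residue_id = model$residue_id, xyz = xyz),
            class = "anm_network")
}

#' Raw ANM Hessian from a coordinate matrix
#'
#' Low-level builder of the 3N x 3N pairwise Hessian, without the
#' non-degeneracy checks of [build_anm()]; useful for analysing small or
#' degenerate test geometries directly.
#'
#' @param xyz N x 3 coordinate matrix.
#' @param cutoff Contact cutoff (Angstrom).
#' @param gamma Spring constant.
#' @return A 3N x 3N symmetric matrix.
#' @export
anm_hessian <- function(xyz, cutoff = 13, gamma = 1) {
  n <- nrow(xyz)
  d <- as.matrix(dist(xyz))
  h <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, n)) {
      if (d[i, j] <= cutoff && d[i, j] > 0) {
        dr <- xyz[j, ] - xyz[i, ]
        blk <- -gamma * tcrossprod(dr) / sum(dr^2)
        ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
        h[ii, jj] <- blk
        h[jj, ii] <- blk
        h[ii, ii] <- h[ii, ii] - blk
        h[jj, jj] <- h[jj, jj] - blk
      }
    }
  }
  h
}

#' @export
print.anm_network <- function(x, ...) {
  cat("Anisotropic network:", length(x$residue_id), "nodes, cutoff",
      x$cutoff, "A\n")
  invisible(x)
}

#' Pseudoinverse of the ANM Hessian
#'
#' Inverts the Hessian over its nonzero modes after verifying that exactly
#' six numerically zero modes (rigid-body motions) are present.
#'
#' @param net An `anm_network`.
#' @param zero_tol Relative tolerance for zero modes.
#' @return 3N x 3N pseudoinverse matrix.
#' @export
anm_pseudoinverse <- function(net, zero_tol = 1e-8) {
  e <- eigen(net$hessian, symmetric = TRUE)
  lam <- rev(e$values)
  vec <- e$vectors[, rev(seq_along(lam)), drop = FALSE]
  lam_max <- max(lam)
  n_zero <- sum(lam < zero_tol * lam_max)
  if (n_zero != 6)
    abort(sprintf("expected 6 zero modes, found %d (tol %g relative)",
                  n_zero, zero_tol))
  nz <- seq(n_zero + 1, length(lam))
  vec[, nz, drop = FALSE] %*% (t(vec[, nz, drop = FALSE]) / lam[nz])
}

# isotropic average of the squared response of every residue to a unit
# force at residue i: s_k = ||G_ki||_F^2 / 3
prs_closed_form_row <- function(g, i, n) {
  ii <- 3 * (i - 1) + 1:3
  gi2 <- g[, ii, drop = FALSE]^2
  s <- rowSums(gi2)
  colSums(matrix(s, nrow = 3)) / 3
}

#' Response of the structure to perturbing one residue
#'
#' Linear-response displacement magnitudes elicited at every residue by a
#' force applied at residue `i`.  The closed-form mode returns the exact
#' isotropic average over force directions; the stochastic mode reproduces
#' the randomized protocol (repeatedly applying unit forces of uniformly
#' random direction and averaging the squared displacements).
#'
#' @param net An `anm_network`.
#' @param i Author residue id of the perturbed residue.
#' @param mode `"closed_form"` (exact) or `"stochastic"`.
#' @param m_trials Number of random forces in stochastic mode.
#' @param seed RNG seed for stochastic mode.
#' @param ginv Optional precomputed [anm_pseudoinverse()] result.
#' @return Tibble with `residue_id` and `response` (squared displacement).
#' @export
prs_response <- function(net, i, mode = c("closed_form", "stochastic"),
                         m_trials = 1000, seed = NULL, ginv = NULL) {
  mode <- match.arg(mode)
  idx <- match(i, net$residue_id)
  if (is.na(idx)) abort(paste0("unknown residue id: ", i))
  if (is.null(ginv)) ginv <- anm_pseudoinverse(net)
  n <- length(net$residue_id)
  if (mode == "closed_form") {
    s <- prs_closed_form_row(ginv, idx, n)
  } else {
    if (m_trials < 1) abort("m_trials must be >= 1 in stochastic mode")
    ii <- 3 * (idx - 1) + 1:3
    gi <- ginv[, ii, drop = FALSE]
    s <- with_seed(seed, {
      acc <- numeric(n)
      for (t in seq_len(m_trials)) {
        f <- rnorm(3)
        f <- f / sqrt(sum(f^2))
        dr <- gi %*% f
        acc <- acc + colSums(matrix(dr^2, nrow = 3))
      }
      acc / m_trials
    })
  }
  tibble::tibble(residue_id = net$residue_id, response = s)
}

#' Perturbation-response scanning map
#'
#' Scans a unit perturbation over every residue and records the response of
#' every other residue, giving the N x N map whose entry (i, k) is the
#' response at k to a perturbation at i.  With `normalize_rows = TRUE`
#' (default) each row is divided by its self-response, making entries
#' relative responses with unit diagonal; this is what gives the map its
#' directionality.  Row means (diagonal excluded) measure *effectiveness*
#' (effector strength), column means *sensitivity* (sensor strength).
#'
#' @param net An `anm_network`.
#' @param mode `"closed_form"` or `"stochastic"`.
#' @param normalize_rows Divide each row by its diagonal self-response.
#' @param m_trials,seed Stochastic-mode parameters.
#' @return An object of class `prs_map`.
#' @export
prs_map <- function(net, mode = c("closed_form", "stochastic"),
                    normalize_rows = TRUE, m_trials = 1000, seed = NULL) {
  mode <- match.arg(mode)
  ginv <- anm_pseudoinverse(net)
  n <- length(net$residue_id)
  if (mode == "closed_form") {
    g2 <- ginv^2
    b <- kronecker(diag(n), matrix(1, 1, 3))  # block row sums
    s <- b %*% g2 %*% t(b) / 3
    s <- t(s)  # entry (i,k): response of k to forcing i
  } else {
    s <- matrix(0, n, n)
    seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
    for (i in seq_len(n)) {
      s[i, ] <- prs_response(net, net$residue_id[i], mode = "stochastic",
                             m_trials = m_trials, seed = seeds[i],
                             ginv = ginv)$response
    }
  }
  if (any(diag(s) <= 0)) abort("zero self-response (isolated node?)")
  if (normalize_rows) s <- s / diag(s)
  dimnames(s) <- list(net$residue_id, net$residue_id)
  off <- s
  diag(off) <- NA
  structure(list(response = s,
                 effectiveness = rowMeans(off, na.rm = TRUE),
                 sensitivity = colMeans(off, na.rm = TRUE),
                 residue_id = net$residue_id,
                 mode = mode, normalized = normalize_rows),
            class = "prs_map")
}

#' @export
print.prs_map <- function(x, ...) {
  cat("PRS map:", length(x$residue_id), "residues (", x$mode,
      if (x$normalized) ", row-normalized" else "", ")\n")
  invisible(x)
}

#' @export
tidy.prs_map <- function(x, ...) {
  n <- length(x$residue_id)
  tibble::tibble(
    perturbed = rep(x$residue_id, times = n),
    responding = rep(x$residue_id, each = n),
    response = as.vector(x$response)
  )
}

#' @export
glance.prs_map <- function(x, ...) {
  tibble::tibble(n_residues = length(x$residue_id), mode = x$mode,
                 normalized = x$normalized,
                 max_effectiveness = max(x$effectiveness),
                 max_sensitivity = max(x$sensitivity))
}

#' Per-residue marginals of a PRS map
#' @param map A `prs_map`.
#' @return Tibble with `residue_id`, `effectiveness`, `sensitivity`.
#' @export
prs_marginals <- function(map) {
  tibble::tibble(residue_id = map$residue_id,
                 effectiveness = unname(map$effectiveness),
                 sensitivity = unname(map$sensitivity))
}

#' Influence profile of a target residue
#'
#' The column of the PRS map at `target`: how strongly each perturbed
#' residue moves the target (the effectors of that residue appear as
#' peaks).
#'
#' @param map A `prs_map`.
#' @param target Author residue id.
#' @return Tibble with `residue_id` (perturbed residue) and `influence`.
#' @export
influence_profile <- function(map, target) {
  j <- match(target, map$residue_id)
  if (is.na(j)) abort(paste0("unknown residue id: ", target))
  tibble::tibble(residue_id = map$residue_id,
                 influence = unname(map$response[, j]))
}

#' Response profile of a perturbed residue
#'
#' The row of the PRS map at `source`: the displacement response of the
#' whole structure to perturbing that residue.
#'
#' @param map A `prs_map`.
#' @param source Author residue id.
#' @return Tibble with `residue_id` (responding residue) and `response`.
#' @export
response_profile <- function(map, source) {
  i <- match(source, map$residue_id)
  if (is.na(i)) abort(paste0("unknown residue id: ", source))
  tibble::tibble(residue_id = map$residue_id,
                 response = unname(map$response[i, ]))
}

#' Rank effector and sensor residues
#'
#' @param map A `prs_map`.
#' @param top_n Number of residues to report per list.
#' @return List with tibbles `effectors` and `sensors` (ranked, ties broken
#'   by residue id) and the `overlap` of the two id sets.
#' @export
rank_effectors_sensors <- function(map, top_n = 10) {
  rank_one <- function(vals, name) {
    ord <- order(-vals, map$residue_id)
    out <- tibble::tibble(residue_id = map$residue_id[ord],
                          value = unname(vals[ord]),
                          rank = seq_along(ord))
    names(out)[2] <- name
    out[seq_len(min(top_n, nrow(out))), ]
  }
  eff <- rank_one(map$effectiveness, "effectiveness")
  sen <- rank_one(map$sensitivity, "sensitivity")
  list(effectors = eff, sensors = sen,
       overlap = intersect(eff$residue_id, sen$residue_id))
}
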