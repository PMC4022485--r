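#' Build a Gaussian network model
#'
#' Constructs the Kirchhoff (connectivity) matrix of the residue network:
#' two residues are connected when their C-alpha distance is at or below the
#' cutoff.  Off-diagonal entries are -1 within the cutoff, 0 beyond, and the
#' diagonal holds the node degree, so every row sums to zero.  The spring
#' constant `gamma` is a uniform scale factor kept as metadata.
#'
#' @param model A `structure_tbl`.
#' @param cutoff Contact cutoff in Angstrom (default 7.3).
#' @param gamma Uniform spring constant.
#' @return An object of class `gnm_network`.
#' @export
build_gnm <- function(model, cutoff = 7.3, gamma = 1) {
  xyz <- ca_coords(model)
  n <- nrow(xyz)
  if (n < 2) abort("need at least 2 residues to build a network")
  d <- as.matrix(dist(xyz))
  k <- -(d <= cutoff) * 1
  diag(k) <- 0
  diag(k) <- -rowSums(k)
  dimnames(k) <- list(rownames(xyz), rownames(xyz))
  g <- igraph::graph_from_adjacency_matrix(d <= cutoff & diag(n) == 0,
                                           mode = "undirected")
  ncomp <- igraph::components(g)$no
  structure(list(kirchhoff = k, cutoff = cutoff, gamma = gamma,
                 residue_id = model$residue_id,
                 n_components = ncomp,
                 component = igraph::components(g)$membership),
            class = "gnm_network")
}

#' @export
print.gnm_network <- function(x, ...) {
  cat("Gaussian network:", nrow(x$kirchhoff), "nodes, cutoff",
      x$cutoff, "A,", x$n_components, "connected component(s)\n")
  invisible(x)
}

# order modes deterministically: by eigenvalue, then (within numerically
# degenerate groups) by the index of the largest-magnitude component; fix
# sign so the largest-magnitude component is positive
canonicalize_modes <- function(values, vectors, tol) {
  ord <- order(values)
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  grp <- cumsum(c(TRUE, diff(values) > tol * max(abs(values), 1)))
  key <- apply(vectors, 2, function(u) which.max(abs(u)))
  ord2 <- order(grp, key)
  values <- values[ord2]
  vectors <- vectors[, ord2, drop = FALSE]
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  list(values = values, vectors = vectors)
}

#' Decompose a Gaussian network into normal modes
#'
#' Full eigen-decomposition of the Kirchhoff matrix.  Eigenvalues are
#' returned in ascending order; modes with eigenvalue below
#' `zero_tol * lambda_max` are counted as zero modes (one per connected
#' component).  Nonzero modes are indexed k = 1, 2, ... from the lowest
#' frequency.
#'
#' @param net A `gnm_network`.
#' @param zero_tol Relative tolerance for detecting zero modes.
#' @param on_disconnected `"error"` to refuse disconnected networks,
#'   `"largest_component"` to analyse the largest component only.
#' @return An object of class `gnm_modes` with elements `values`, `vectors`,
#'   `n_zero`, `residue_id`.
#' @export
decompose_gnm <- function(net, zero_tol = 1e-8,
                          on_disconnected = c("error", "largest_component")) {
  on_disconnected <- match.arg(on_disconnected)
  k <- net$kirchhoff
  residue_id <- net$residue_id
  if (net$n_components > 1) {
    warn(sprintf("network has %d connected components", net$n_components))
    if (on_disconnected == "error") {
      abort("disconnected network; pass on_disconnected = \"largest_component\" to proceed")
    }
    tab <- table(net$component)
    keep <- net$component == as.integer(names(tab)[which.max(tab)])
    k <- k[keep, keep, drop = FALSE]
    residue_id <- residue_id[keep]
    # degrees within the component are unchanged (no cross-component edges)
  }
  e <- eigen(k, symmetric = TRUE)
  cm <- canonicalize_modes(e$values, e$vectors, zero_tol)
  lam_max <- max(cm$values)
  n_zero <- sum(cm$values < zero_tol * lam_max)
  structure(list(values = cm$values, vectors = cm$vectors,
                 n_zero = n_zero, residue_id = residue_id,
                 gamma = net$gamma),
            class = "gnm_modes")
}

#' @export
print.gnm_modes <- function(x, ...) {
  cat("GNM mode set:", length(x$values), "modes (", x$n_zero, "zero );",
      "lambda_1 =", signif(x$values[x$n_zero + 1], 4), "\n")
  invisible(x)
}

#' @export
tidy.gnm_modes <- function(x, ...) {
  nz <- seq_along(x$values) - x$n_zero
  tibble::tibble(mode = nz, eigenvalue = x$values,
                 zero = nz <= 0)
}

new_mobility_profile <- function(residue_id, values, mode_range, normalized) {
  tibble::new_tibble(
    tibble::tibble(residue_id = residue_id, mobility = values),
    mode_range = mode_range, normalized = normalized,
    class = "mobility_profile", nrow = length(residue_id))
}

#' Mobility profile of a single mode
#'
#' The squared mode shape weighted by inverse eigenvalue,
#' `M_i = u_i^2 / lambda`, so the profile of mode k sums to `1 / lambda_k`.
#'
#' @param ms A `gnm_modes` object.
#' @param k Nonzero-mode index (1 = slowest).
#' @return A `mobility_profile` tibble (`residue_id`, `mobility`).
#' @export
mode_mobility <- function(ms, k) {
  n_nonzero <- length(ms$values) - ms$n_zero
  if (length(k) != 1 || k < 1 || k > n_nonzero)
    abort(sprintf("mode index k must be in 1..%d (nonzero modes)", n_nonzero))
  j <- ms$n_zero + k
  new_mobility_profile(ms$residue_id, ms$vectors[, j]^2 / ms$values[j],
                       mode_range = c(k, k), normalized = FALSE)
}

#' Cumulative mobility over the m slowest modes
#'
#' Sum of the per-mode mobility profiles of the `m` lowest-frequency nonzero
#' modes; the conventional global mobility profile uses the ten slowest.
#'
#' @param ms A `gnm_modes` object.
#' @param m Number of slowest nonzero modes.
#' @param normalize Scale the profile to `[0, 1]` by its maximum (for
#'   plotting); the unnormalized profile is the default.
#' @return A `mobility_profile` tibble.
#' @export
cumulative_mobility <- function(ms, m = 10, normalize = FALSE) {
  n_nonzero <- length(ms$values) - ms$n_zero
  if (m < 1 || m > n_nonzero)
    abort(sprintf("m must be in 1..%d (nonzero modes)", n_nonzero))
  j <- ms$n_zero + seq_len(m)
  vals <- as.vector(ms$vectors[, j, drop = FALSE]^2 %*% (1 / ms$values[j]))
  if (normalize) vals <- vals / max(vals)
  new_mobility_profile(ms$residue_id, vals, mode_range = c(1, m),
                       normalized = normalize)
}

#' Fraction of dynamics captured by the m slowest modes
#'
#' The inverse-eigenvalue weight of the `m` slowest nonzero modes relative
#' to the full nonzero spectrum: `sum_{k<=m} 1/lambda_k / sum_k 1/lambda_k`.
#'
#' @param ms A `gnm_modes` object.
#' @param m Number of slowest nonzero modes (0 returns 0).
#' @return A fraction in `[0, 1]`.
#' @export
dynamics_fraction <- function(ms, m) {
  n_nonzero <- length(ms$values) - ms$n_zero
  if (m == 0) return(0)
  if (m < 0 || m > n_nonzero)
    abort(sprintf("m must be in 0..%d (nonzero modes)", n_nonzero))
  inv <- 1 / ms$values[ms$n_zero + seq_len(n_nonzero)]
  sum(inv[seq_len(m)]) / sum(inv)
}

#' Detect hinge residues from a mobility profile
#'
#' Hinges are residues that are strict local minima of the profile within a
#' `window`-residue neighbourhood on each side and whose mobility lies below
#' the given percentile of the profile.  Returned sorted by mobility
#' (deepest minimum first).
#'
#' @param profile A `mobility_profile` (or any tibble with `residue_id` and
#'   `mobility` columns).
#' @param window Half-width of the local-minimum neighbourhood (residues).
#' @param percentile Upper percentile bound (0-100) a hinge must lie below.
#' @return Integer vector of residue ids.
#' @export
find_hinges <- function(profile, window = 5, percentile = 20) {
  v <- profile$mobility
  n <- length(v)
  if (n < 2 * window + 1) abort("profile too short for the chosen window")
  cut <- quantile(v, percentile / 100)
  hinge <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - window); hi <- min(n, i + window)
    nb <- v[setdiff(lo:hi, i)]
    hinge[i] <- all(v[i] < nb) && v[i] <= cut
  }
  ids <- profile$residue_id[hinge]
  ids[order(v[hinge])]
}
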