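#' Synthetic two-domain bead structure with a known hinge
#'
#' Builds a dumbbell: two compact self-avoiding bead clusters (random
#' sequential packing on a jittered cubic lattice, 3.8 Angstrom spacing)
#' joined by an extended linker whose beads form the planted hinge.  A
#' one-bead stalk protrudes from each lobe so interior linker beads touch
#' only their chain neighbours at the 7.3 Angstrom network cutoff.  The
#' construction is a pure function of its arguments and seed.
#'
#' @param n_lobe1,n_lobe2 Beads per lobe (>= 20 each, stalk included).
#' @param linker_len Number of linker beads (default 4, the
#'   Hsp70-linker-like value).
#' @param seed RNG seed.
#' @param jitter Lattice jitter amplitude (Angstrom).
#' @return A `structure_tbl` with a `domain` column (`D1`, `linker`, `D2`)
#'   and attributes `planted_hinge_ids`, `lobe_sizes`, `seed`.
#' @export
make_two_domain_structure <- function(n_lobe1 = 40, n_lobe2 = 30,
                                      linker_len = 4, seed = 1,
                                      jitter = 0.25) {
  if (n_lobe1 < 20 || n_lobe2 < 20) abort("lobes must have >= 20 beads")
  a <- 3.8
  lobe_coords <- function(n) {
    # compact cluster: the n lattice sites closest to the origin, jittered
    r <- ceiling((3 * n / (4 * pi))^(1 / 3)) + 2
    g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
    g <- g[order(rowSums(g^2), g[, 1], g[, 2], g[, 3]), , drop = FALSE]
    g[seq_len(n), , drop = FALSE] * a +
      matrix(runif(3 * n, -jitter, jitter), n, 3)
  }
  build <- function() {
    l1 <- lobe_coords(n_lobe1 - 1)
    l2 <- lobe_coords(n_lobe2 - 1)
    # stalks protrude along -x/+x so linker ends touch only the stalk tip;
    # the linker is a gentle helix so consecutive bonds are non-parallel
    # (a perfectly straight chain of rank-1 springs has no transverse
    # stiffness and would add spurious zero modes to the ANM)
    tip1 <- l1[which.max(l1[, 1]), ]
    stalk1 <- tip1 + c(a, 0, 0)
    lk <- t(vapply(seq_len(linker_len), function(i)
      stalk1 + c(i * a,
                 0.9 * cos(2.3 * i) + runif(1, -0.1, 0.1),
                 0.9 * sin(2.3 * i) + runif(1, -0.1, 0.1)),
      numeric(3)))
    stalk2 <- stalk1 + c((linker_len + 1) * a, 0, 0)
    tip2_idx <- which.min(l2[, 1])
    shift <- stalk2 + c(a, 0, 0) - l2[tip2_idx, ]
    l2 <- sweep(l2, 2, shift, "+")
    list(xyz = rbind(l1, matrix(stalk1, 1), lk, matrix(stalk2, 1), l2),
         linker_idx = n_lobe1 + seq_len(linker_len))
  }
  out <- NULL
  with_seed(seed, {
    for (try in 1:20) {
      b <- build()
      if (min(dist(b$xyz)) >= 2.5) { out <- b; break }
    }
  })
  if (is.null(out)) abort("could not generate clash-free geometry in 20 attempts")
  n <- nrow(out$xyz)
  df <- tibble::tibble(
    residue_id = seq_len(n),
    insert = "",
    chain = "A",
    aa = "G",
    x = out$xyz[, 1], y = out$xyz[, 2], z = out$xyz[, 3],
    heavy = lapply(seq_len(n), function(i)
      cbind(x = out$xyz[i, 1], y = out$xyz[i, 2], z = out$xyz[i, 3])),
    domain = c(rep("D1", n_lobe1), rep("linker", linker_len),
               rep("D2", n_lobe2))
  )
  st <- new_structure_tbl(df, source_id = sprintf("synthetic-dumbbell-%d", seed))
  attr(st, "planted_hinge_ids") <- out$linker_idx
  attr(st, "lobe_sizes") <- c(n_lobe1, n_lobe2)
  attr(st, "seed") <- seed
  st
}

# sample a column profile over the 20 amino acids (sparse Dirichlet)
dirichlet_profile <- function(alpha = 0.5) {
  g <- stats::rgamma(20, shape = alpha)
  g / sum(g)
}

sample_states <- function(n, prob) {
  sample.int(length(prob), n, replace = TRUE, prob = prob)
}

#' Synthetic alignment with planted couplings
#'
#' Generates an alignment whose background columns are independent draws
#' from per-column Dirichlet profiles, with (i) planted column pairs drawn
#' from a permutation-matched joint table (with probability `coupling` the
#' second state is a fixed bijection of the first; otherwise the two are
#' drawn independently), (ii) conserved columns with a given dominant
#' frequency, and (iii) appended duplicate sequence groups to exercise
#' redundancy weighting.  The realized mutual information of every planted
#' pair is computed from the sampled counts and reported in the truth
#' record.
#'
#' @param L Number of columns.
#' @param N Number of base sequences.
#' @param planted List of `list(cols = c(i, j), coupling = , n_states = )`
#'   entries; couplings in `[0, 1]`, pairs must be disjoint.
#' @param conserved List of `list(col = , dominant_freq = )` entries.
#' @param n_duplicate_groups Number of appended duplicate groups.
#' @param dup_group_size Total copies per duplicate group.
#' @param alpha Dirichlet concentration of background profiles.
#' @param seed RNG seed.
#' @return List with `msa` (an `msa_set`) and `truth` (planted pairs with
#'   realized MI, conserved columns, duplicate groups, seed); class
#'   `synthetic_msa`.
#' @export
make_coupled_msa <- function(L = 100, N = 1000, planted = list(),
                             conserved = list(), n_duplicate_groups = 0,
                             dup_group_size = 2, alpha = 0.5, seed = 1) {
  pl_cols <- unlist(lapply(planted, function(p) p$cols))
  if (anyDuplicated(pl_cols)) abort("planted pairs must be disjoint")
  cons_cols <- vapply(conserved, function(cc) cc$col, numeric(1))
  if (L < 2 * length(planted) + length(conserved))
    abort("L too small for the requested planted/conserved columns")
  with_seed(seed, {
    enc <- matrix(0L, N, L)
    for (j in seq_len(L)) enc[, j] <- sample_states(N, dirichlet_profile(alpha))
    for (cc in conserved) {
      p <- rep((1 - cc$dominant_freq) / 19, 20)
      dom <- sample.int(20, 1)
      p[dom] <- cc$dominant_freq
      enc[, cc$col] <- sample_states(N, p)
    }
    truth_pairs <- list()
    for (pp in planted) {
      ns <- if (is.null(pp$n_states)) 4L else as.integer(pp$n_states)
      if (ns < 2 || ns > 20) abort("n_states must be in 2..20")
      states_a <- sample.int(20, ns)
      states_b <- sample.int(20, ns)
      sigma <- sample.int(ns, ns)   # bijection a -> b
      aidx <- sample.int(ns, N, replace = TRUE)
      coupled <- runif(N) < pp$coupling
      bidx <- ifelse(coupled, sigma[aidx], sample.int(ns, N, replace = TRUE))
      enc[, pp$cols[1]] <- states_a[aidx]
      enc[, pp$cols[2]] <- states_b[bidx]
      tab <- table(factor(aidx, levels = 1:ns), factor(bidx, levels = 1:ns))
      pj <- tab / sum(tab)
      pa <- rowSums(pj); pb <- colSums(pj)
      nz <- pj > 0
      mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
      truth_pairs[[length(truth_pairs) + 1]] <- list(
        col_a = pp$cols[1], col_b = pp$cols[2],
        coupling = pp$coupling, n_states = ns, realized_mi = mi)
    }
    dup_groups <- list()
    if (n_duplicate_groups > 0) {
      src <- sample.int(N, n_duplicate_groups)
      for (g in seq_len(n_duplicate_groups)) {
        extra <- dup_group_size - 1
        rows <- nrow(enc) + seq_len(extra)
        enc <- rbind(enc, matrix(enc[src[g], ], extra, L, byrow = TRUE))
        dup_groups[[g]] <- c(src[g], rows)
      }
    }
    seqs <- apply(enc, 1, function(e) paste0(AA_ALPHABET[e], collapse = ""))
    msa <- msa_set(sprintf("seq%04d", seq_len(nrow(enc))), seqs)
    structure(list(
      msa = msa,
      truth = list(planted_pairs = truth_pairs,
                   conserved_cols = as.integer(cons_cols),
                   duplicate_groups = dup_groups,
                   L = L, N = N, seed = seed)),
      class = "synthetic_msa")
  })
}

#' Independent-column null alignment
#'
#' Background-only generator used for score calibration: every column is an
#' independent draw from its own Dirichlet profile.
#'
#' @param L,N Alignment dimensions.
#' @param alpha Dirichlet concentration.
#' @param seed RNG seed.
#' @return An `msa_set`.
#' @export
null_msa <- function(L = 50, N = 1000, alpha = 0.5, seed = 1) {
  make_coupled_msa(L = L, N = N, planted = list(), conserved = list(),
                   n_duplicate_groups = 0, alpha = alpha, seed = seed)$msa
}

#' Write a synthetic-alignment truth record as JSON
#'
#' @param synth A `synthetic_msa`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_msa_truth <- function(synth, path) {
  jsonlite::write_json(synth$truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a synthetic-structure truth record as JSON
#'
#' @param st A structure from [make_two_domain_structure()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_structure_truth <- function(st, path) {
  jsonlite::write_json(
    list(planted_hinge_ids = attr(st, "planted_hinge_ids"),
         lobe_sizes = attr(st, "lobe_sizes"),
         seed = attr(st, "seed"),
         n_residues = nrow(st)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
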