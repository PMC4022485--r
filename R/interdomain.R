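#' Interdomain submatrix of a coevolution score matrix
#'
#' Extracts the rectangular block of scores between two residue groups
#' (e.g. NBD rows x SBD columns) using the alignment's column-to-residue
#' map.  The candidate pair space is counted either from the full group
#' sizes (the printed-table convention, default) or from the columns
#' actually present in the alignment.
#'
#' @param result A `coev_result` with a column map.
#' @param groups Named list of two residue-id vectors (default
#'   [dnak_groups()]).
#' @param denominator `"domain"` counts `|A| * |B|` from the group sizes,
#'   `"mapped"` from the mapped columns only.
#' @return An object of class `interdomain_matrix` with the score block and
#'   row/column residue ids.
#' @export
interdomain_submatrix <- function(result, groups = dnak_groups(),
                                  denominator = c("domain", "mapped")) {
  denominator <- match.arg(denominator)
  if (is.null(result$column_map))
    abort("scores must be mapped to reference residues (see map_to_reference)")
  stopifnot(length(groups) == 2)
  cm <- result$column_map
  rows <- which(cm %in% groups[[1]])
  cols <- which(cm %in% groups[[2]])
  if (length(rows) == 0 || length(cols) == 0)
    abort("no mapped columns fall in one of the groups")
  sub <- result$scores[rows, cols, drop = FALSE]
  dimnames(sub) <- list(cm[rows], cm[cols])
  n_full <- length(groups[[1]]) * length(groups[[2]])
  n_mapped <- length(rows) * length(cols)
  structure(list(scores = sub,
                 residues_a = cm[rows], residues_b = cm[cols],
                 group_names = names(groups),
                 method = result$method,
                 n_pairs = if (denominator == "domain") n_full else n_mapped,
                 n_pairs_full = n_full, n_pairs_mapped = n_mapped),
            class = "interdomain_matrix")
}

#' @export
print.interdomain_matrix <- function(x, ...) {
  cat("Interdomain", x$method, "scores:", length(x$residues_a), "x",
      length(x$residues_b), "mapped residues;", x$n_pairs,
      "candidate pairs\n")
  invisible(x)
}

#' Number of candidate interdomain pairs
#' @param groups Named list of two residue-id vectors.
#' @return `|A| * |B|`.
#' @export
interdomain_pair_count <- function(groups = dnak_groups()) {
  stopifnot(length(groups) == 2)
  length(groups[[1]]) * length(groups[[2]])
}

#' Top-ranked interdomain pairs
#'
#' Ranks the interdomain score block in descending order and keeps the top
#' fraction of the candidate pair space (default 0.06%, the printed-table
#' convention; `ceiling(0.0006 * 82,256) = 50` for the DnaK partition), or
#' an explicit `k_override`.  Ties are broken by (row id, column id); a
#' fully tied block is flagged degenerate.
#'
#' @param sub An `interdomain_matrix`.
#' @param fraction Fraction of the candidate pair space to keep.
#' @param k_override Explicit number of pairs (overrides `fraction`).
#' @return Tibble with `residue_a`, `residue_b`, `score`, `rank`, `method`;
#'   attribute `degenerate` flags an all-tied block.
#' @export
top_pairs <- function(sub, fraction = 0.0006, k_override = NULL) {
  k <- if (!is.null(k_override)) k_override
       else ceiling(fraction * sub$n_pairs)
  if (k < 1) abort("fraction/k_override give an empty selection")
  df <- tibble::tibble(
    residue_a = rep(sub$residues_a, times = length(sub$residues_b)),
    residue_b = rep(sub$residues_b, each = length(sub$residues_a)),
    score = as.vector(sub$scores)
  )
  df <- df[!is.na(df$score), , drop = FALSE]
  if (k > nrow(df)) {
    warn(sprintf("requested %d pairs but only %d scored pairs; clamping",
                 k, nrow(df)))
    k <- nrow(df)
  }
  df <- df[order(-df$score, df$residue_a, df$residue_b), , drop = FALSE]
  out <- df[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  out$method <- sub$method
  degenerate <- length(unique(df$score)) == 1
  if (degenerate) warn("all scores tied; ranking is by residue order only")
  attr(out, "degenerate") <- degenerate
  out
}

#' Consensus interdomain pairs across methods
#'
#' A pair enters the consensus when it appears in the per-method top
#' selection of at least `min_methods` methods.  Pairs are ordered by
#' (number of supporting methods, best per-method rank); the order in which
#' method results are supplied does not matter.
#'
#' @param results List of `coev_result` objects (at least two).
#' @param groups Named list of two residue-id vectors.
#' @param fraction Top fraction per method (see [top_pairs()]).
#' @param min_methods Minimum number of supporting methods (default 2).
#' @param k_override Explicit per-method k.
#' @param denominator Pair-space convention (see [interdomain_submatrix()]).
#' @return Tibble with `residue_a`, `residue_b`, `n_methods`,
#'   `supporting_methods` (comma-separated, method-name order), `best_rank`;
#'   attribute `degenerate` is TRUE when any method's block was all-tied.
#' @export
consensus_pairs <- function(results, groups = dnak_groups(),
                            fraction = 0.0006, min_methods = 2,
                            k_override = NULL,
                            denominator = c("domain", "mapped")) {
  denominator <- match.arg(denominator)
  if (length(results) < 2)
    abort("consensus requires results from at least 2 methods")
  tops <- lapply(results, function(r) {
    top_pairs(interdomain_submatrix(r, groups, denominator),
              fraction = fraction, k_override = k_override)
  })
  degenerate <- any(vapply(tops, function(t) isTRUE(attr(t, "degenerate")),
                           logical(1)))
  all_pairs <- dplyr::bind_rows(tops)
  methods_order <- sort(unique(all_pairs$method))
  out <- all_pairs |>
    dplyr::group_by(.data$residue_a, .data$residue_b) |>
    dplyr::summarise(
      n_methods = dplyr::n_distinct(.data$method),
      supporting_methods = paste(sort(unique(.data$method)), collapse = ","),
      best_rank = min(.data$rank),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_methods >= min_methods) |>
    dplyr::arrange(dplyr::desc(.data$n_methods), .data$best_rank,
                   .data$residue_a, .data$residue_b)
  # per-method rank columns
  for (m in methods_order) {
    tm <- all_pairs[all_pairs$method == m, c("residue_a", "residue_b", "rank")]
    names(tm)[3] <- paste0("rank_", m)
    out <- dplyr::left_join(out, tm, by = c("residue_a", "residue_b"))
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Cumulative interdomain coevolution propensity
#'
#' Per-residue sums of the interdomain score block: row sums give the
#' propensity of group-A residues, column sums that of group-B residues.
#'
#' @param sub An `interdomain_matrix`.
#' @param axis `"a"`, `"b"`, or `"both"`.
#' @return Tibble with `residue_id`, `group`, `propensity`, `method`.
#' @export
cumulative_propensity <- function(sub, axis = c("both", "a", "b")) {
  axis <- match.arg(axis)
  out <- list()
  if (axis %in% c("a", "both")) {
    out$a <- tibble::tibble(residue_id = sub$residues_a,
                            group = sub$group_names[1],
                            propensity = unname(rowSums(sub$scores, na.rm = TRUE)),
                            method = sub$method)
  }
  if (axis %in% c("b", "both")) {
    out$b <- tibble::tibble(residue_id = sub$residues_b,
                            group = sub$group_names[2],
                            propensity = unname(colSums(sub$scores, na.rm = TRUE)),
                            method = sub$method)
  }
  dplyr::bind_rows(out)
}

#' Structural classification of residue pairs
#'
#' Classifies each pair by the Table-1-style convention: minimum heavy-atom
#' distance at or below `contact_cutoff` is a `"contact"`; C-alpha distance
#' beyond `distant_cutoff` is `"distant"`; anything in between is
#' `"neighboring_no_contact"`.  Pairs with a residue missing from the
#' structure are `"unresolved"`.  When heavy atoms are not loaded the
#' C-alpha distance stands in for the contact test.
#'
#' @param structure A `structure_tbl`.
#' @param pairs Tibble with columns `residue_a`, `residue_b` (or a
#'   length-two vector for a single pair).
#' @param contact_cutoff Heavy-atom contact threshold (Angstrom).
#' @param distant_cutoff C-alpha distance beyond which a pair is distant.
#' @return The pairs tibble with `distance_ca`, `distance_heavy`,
#'   `contact_class` added.
#' @export
classify_pair <- function(structure, pairs, contact_cutoff = 4.5,
                          distant_cutoff = 30) {
  if (!is.data.frame(pairs))
    pairs <- tibble::tibble(residue_a = pairs[1], residue_b = pairs[2])
  n <- nrow(pairs)
  dca <- dhv <- rep(NA_real_, n)
  cls <- character(n)
  has_heavy <- "heavy" %in% names(structure) &&
    !all(vapply(structure$heavy, is.null, logical(1)))
  for (r in seq_len(n)) {
    a <- pairs$residue_a[r]; b <- pairs$residue_b[r]
    if (!(a %in% structure$residue_id) || !(b %in% structure$residue_id)) {
      cls[r] <- "unresolved"
      next
    }
    dca[r] <- residue_distance(structure, a, b, "ca")
    dhv[r] <- if (has_heavy) residue_distance(structure, a, b, "heavy_min")
              else dca[r]
    cls[r] <- if (dhv[r] <= contact_cutoff) "contact"
              else if (dca[r] > distant_cutoff) "distant"
              else "neighboring_no_contact"
  }
  pairs$distance_ca <- dca
  pairs$distance_heavy <- dhv
  pairs$contact_class <- cls
  pairs
}

#' Annotate consensus pairs with structural contact classes
#'
#' Convenience wrapper producing the Table-1-style consensus table:
#' consensus pairs with supporting methods, ranks, distances and contact
#' classification.
#'
#' @param consensus A [consensus_pairs()] tibble.
#' @param structure A `structure_tbl`.
#' @param ... Passed to [classify_pair()].
#' @return The annotated tibble.
#' @export
annotate_consensus <- function(consensus, structure, ...) {
  classify_pair(structure, consensus, ...)
}
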