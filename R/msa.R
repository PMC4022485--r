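#' Multiple sequence alignments
#'
#' An `msa_set` holds the aligned sequences (uppercase, `-` for gaps), an
#' integer encoding (1..20 for the amino acids in `AA_ALPHABET` order, 21
#' for gap or unknown), optional per-sequence weights, an optional
#' column-to-reference-residue map, and any per-column annotation lines read
#' from Stockholm input.
#'
#' @param ids Sequence identifiers.
#' @param seqs Aligned sequences (equal-length character strings).
#' @param weights Optional positive per-sequence weights.
#' @param column_map Optional integer vector, one entry per column, giving
#'   the reference residue id (NA for unmapped columns).
#' @param annotations Named list of per-column annotation strings.
#' @return An object of class `msa_set`.
#' @export
msa_set <- function(ids, seqs, weights = NULL, column_map = NULL,
                    annotations = list()) {
  seqs <- toupper(gsub("[.~]", "-", seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- ids[lens != lens[1]][1]
    abort(paste0("ragged alignment: sequence '", bad, "' has length ",
                 lens[ids == bad][1], ", expected ", lens[1]))
  }
  L <- lens[1]
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  enc <- matrix(match(chars, AA_ALPHABET, nomatch = GAP_STATE), nrow = n)
  if (!is.null(weights)) {
    stopifnot(length(weights) == n, all(weights > 0))
  }
  if (!is.null(column_map)) {
    stopifnot(length(column_map) == L)
    mapped <- column_map[!is.na(column_map)]
    if (anyDuplicated(mapped)) abort("column_map must be injective")
  }
  structure(list(ids = as.character(ids), seqs = seqs, enc = enc,
                 weights = weights, column_map = column_map,
                 annotations = annotations),
            class = "msa_set")
}

#' @export
print.msa_set <- function(x, ...) {
  cat("MSA:", length(x$ids), "sequences x", ncol(x$enc), "columns")
  if (!is.null(x$weights))
    cat("; M_eff =", signif(sum(x$weights), 5))
  if (!is.null(x$column_map))
    cat(";", sum(!is.na(x$column_map)), "columns mapped to reference")
  cat("\n")
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param msa An `msa_set`.
#' @return Integer.
#' @export
n_seqs <- function(msa) nrow(msa$enc)

#' @rdname n_seqs
#' @export
n_cols <- function(msa) ncol(msa$enc)

#' Read a multiple sequence alignment
#'
#' FASTA input is read with Biostrings; Stockholm input with a small reader
#' that preserves `#=GC` per-column annotation lines (e.g. the reference
#' annotation `RF`), which are kept in `annotations`.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension/sniffing), `"fasta"`, `"stockholm"`.
#' @return An `msa_set`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    msa_set(names(ss), as.character(ss))
  } else {
    read_stockholm(path)
  }
}

read_stockholm <- function(path) {
  lines <- readLines(path)
  seqs <- list()
  ann <- list()
  for (ln in lines) {
    if (grepl("^#=GC\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      ann[[f[2]]] <- paste0(ann[[f[2]]], f[3])
    } else if (grepl("^#", ln) || grepl("^//", ln) || !nzchar(trimws(ln))) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) == 2) seqs[[f[1]]] <- paste0(seqs[[f[1]]], f[2])
    }
  }
  if (length(seqs) == 0) abort("no sequences found in Stockholm file")
  msa_set(names(seqs), unlist(seqs), annotations = ann)
}

#' Write an alignment to FASTA or Stockholm
#'
#' @param msa An `msa_set`.
#' @param path Output file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return The path, invisibly.
#' @export
write_msa <- function(msa, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    out <- character(2 * length(msa$ids))
    out[c(TRUE, FALSE)] <- paste0(">", msa$ids)
    out[c(FALSE, TRUE)] <- msa$seqs
    writeLines(out, path)
  } else {
    w <- max(nchar(msa$ids), 12)
    body <- sprintf(paste0("%-", w, "s %s"), msa$ids, msa$seqs)
    gc <- if (length(msa$annotations) > 0) {
      sprintf(paste0("%-", w, "s %s"),
              paste("#=GC", names(msa$annotations)),
              unlist(msa$annotations))
    } else character(0)
    writeLines(c("# STOCKHOLM 1.0", body, gc, "//"), path)
  }
  invisible(path)
}

#' Map alignment columns to reference residue numbering
#'
#' Columns where the reference sequence is non-gap are assigned consecutive
#' residue ids starting at `ref_start`; gap columns of the reference remain
#' unmapped.  This is what lets alignment columns be named by structure
#' residues.
#'
#' @param msa An `msa_set`.
#' @param ref_id Identifier of the reference row.
#' @param ref_start Residue id of its first non-gap position.
#' @return The `msa_set` with `column_map` set.
#' @export
map_to_reference <- function(msa, ref_id, ref_start = 1) {
  r <- match(ref_id, msa$ids)
  if (is.na(r)) abort(paste0("reference id '", ref_id, "' not in alignment"))
  nongap <- msa$enc[r, ] != GAP_STATE
  if (!any(nongap)) abort("reference row is all gaps")
  cm <- rep(NA_integer_, n_cols(msa))
  cm[nongap] <- seq(ref_start, length.out = sum(nongap))
  msa$column_map <- cm
  msa
}

#' Redundancy-correcting sequence weights
#'
#' Each sequence is down-weighted by the number of alignment members within
#' the given fractional identity, `w_s = 1 / |{t : identity(s,t) >=
#' threshold}|` (the set includes `s` itself).  The effective number of
#' sequences is `M_eff = sum(w)`.
#'
#' @param msa An `msa_set`.
#' @param identity_threshold Fractional identity (default 0.8).
#' @return The `msa_set` with `weights` set.
#' @export
sequence_weights <- function(msa, identity_threshold = 0.8) {
  msa$weights <- as.numeric(seq_weights_cpp(msa$enc, identity_threshold))
  msa
}

#' Effective number of sequences
#' @param msa An `msa_set` (weights default to 1 when unset).
#' @return `M_eff`.
#' @export
m_eff <- function(msa) {
  if (is.null(msa$weights)) n_seqs(msa) else sum(msa$weights)
}

#' Filter alignment columns
#'
#' Drops columns whose gap fraction exceeds `max_gap_fraction` and,
#' optionally, columns not mapped to the reference.  The column map is
#' subset accordingly.
#'
#' @param msa An `msa_set`.
#' @param max_gap_fraction Columns with a larger gap fraction are dropped.
#' @param mapped_only Also drop unmapped columns.
#' @return The filtered `msa_set`.
#' @export
filter_columns <- function(msa, max_gap_fraction = 0.5, mapped_only = FALSE) {
  gapfrac <- colMeans(msa$enc == GAP_STATE)
  keep <- gapfrac <= max_gap_fraction
  if (mapped_only) {
    if (is.null(msa$column_map)) abort("mapped_only requires a column map")
    keep <- keep & !is.na(msa$column_map)
  }
  subset_columns(msa, which(keep))
}

subset_columns <- function(msa, cols) {
  enc <- msa$enc[, cols, drop = FALSE]
  seqs <- apply(enc, 1, function(e)
    paste0(c(AA_ALPHABET, "-")[e], collapse = ""))
  msa_set(msa$ids, seqs, weights = msa$weights,
          column_map = if (!is.null(msa$column_map)) msa$column_map[cols],
          annotations = lapply(msa$annotations, function(a)
            paste0(strsplit(a, "")[[1]][cols], collapse = "")))
}

#' Weighted single- and pairwise-column frequency tables
#'
#' Frequencies over the 21-state alphabet (20 amino acids + gap) with a
#' symmetric pseudocount: `f_i(a) = (lambda/q + c_i(a)) / (lambda + M_eff)`
#' where `c_i` are weighted counts, and the analogous `lambda/q^2` form for
#' pairs.  `lambda = 0` gives raw weighted frequencies.
#'
#' @param msa An `msa_set` (unset weights count each sequence once).
#' @param pseudocount Pseudocount mass `lambda`.
#' @return An object of class `freq_tables` with single-site matrix `f1`
#'   (L x 21), pair matrix `f2` (choose(L,2) x 441, rows in (i<j) order),
#'   `m_eff`, and `pseudocount`.
#' @export
frequencies <- function(msa, pseudocount = 0) {
  q <- GAP_STATE
  w <- if (is.null(msa$weights)) rep(1, n_seqs(msa)) else msa$weights
  meff <- sum(w)
  c1 <- site_counts_cpp(msa$enc, w, q)
  c2 <- pair_counts_cpp(msa$enc, w, q)
  f1 <- (pseudocount / q + c1) / (pseudocount + meff)
  f2 <- (pseudocount / q^2 + c2) / (pseudocount + meff)
  L <- n_cols(msa)
  structure(list(f1 = f1, f2 = f2, L = L, q = q, m_eff = meff,
                 pseudocount = pseudocount,
                 column_map = msa$column_map),
            class = "freq_tables")
}

# row index of pair (i, j), i < j, in the f2 matrix
pair_index <- function(i, j, L) {
  stopifnot(i < j)
  (i - 1) * L - i * (i - 1) / 2 + (j - i)
}

#' Extract the pairwise frequency table of a column pair
#' @param ft A `freq_tables` object.
#' @param i,j Column indices (order-free).
#' @return A 21 x 21 matrix, rows indexing the state at the smaller column.
#' @export
pair_freq <- function(ft, i, j) {
  flip <- i > j
  if (flip) { tmp <- i; i <- j; j <- tmp }
  m <- matrix(ft$f2[pair_index(i, j, ft$L), ], ft$q, ft$q, byrow = TRUE)
  if (flip) t(m) else m
}

#' Shannon-entropy conservation profile
#'
#' Per-column Shannon entropy over the 20 amino acids (gaps excluded and
#' frequencies renormalized), in nats by default.  Fully conserved columns
#' score 0; a uniform column scores `log(20)`.
#'
#' @param msa An `msa_set`.
#' @param base Logarithm base (`exp(1)` for nats).
#' @return Tibble with `column`, `residue_id` (NA when unmapped), `entropy`.
#' @export
shannon_entropy <- function(msa, base = exp(1)) {
  w <- if (is.null(msa$weights)) rep(1, n_seqs(msa)) else msa$weights
  cnt <- site_counts_cpp(msa$enc, w, GAP_STATE)[, 1:20, drop = FALSE]
  h <- apply(cnt, 1, function(cc) {
    tot <- sum(cc)
    if (tot == 0) return(NA_real_)
    p <- cc[cc > 0] / tot
    -sum(p * log(p, base = base))
  })
  tibble::tibble(
    column = seq_len(n_cols(msa)),
    residue_id = if (is.null(msa$column_map)) NA_integer_ else msa$column_map,
    entropy = h
  )
}
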