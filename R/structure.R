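#' Read a protein structure into a residue-level model
#'
#' Parses a PDB or mmCIF file and extracts one node per residue possessing a
#' C-alpha atom.  Author residue numbering is kept as deposited (no
#' re-indexing), insertion-coded residues are kept in file order, and
#' alternate locations are resolved to the highest-occupancy conformer
#' (alphabetically first on ties).  Hetero groups (nucleotide, ions, water)
#' are excluded by default; `include_hetatm = TRUE` adds one centroid node
#' per hetero group for users who want the bound ligand in the network.
#'
#' @param path Path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param chain Chain identifier.  May be omitted when the file holds a
#'   single chain; otherwise an error lists the available chains.
#' @param model_index Model to read from multi-model files (1-based).
#' @param include_hetatm Include hetero groups as centroid nodes.
#'
#' @return A `structure_tbl`: a tibble with one row per residue and columns
#'   `residue_id`, `chain`, `aa` (one-letter code), `x`, `y`, `z` (C-alpha,
#'   Angstrom) and `heavy` (list column of heavy-atom coordinate matrices),
#'   carrying the file identifier as attribute `source_id`.
#' @export
read_structure <- function(path, chain = NULL, model_index = 1,
                           include_hetatm = FALSE) {
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = (model_index > 1), rm.alt = FALSE,
                    verbose = FALSE)
  }
  at <- pdb$atom
  if (model_index > 1) {
    xyz <- pdb$xyz
    if (nrow(xyz) < model_index)
      abort(sprintf("model_index %d requested but file has %d model(s)",
                    model_index, nrow(xyz)))
    co <- matrix(xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
  }

  chains <- unique(at$chain[at$type == "ATOM"])
  if (is.null(chain)) {
    if (length(chains) != 1)
      abort(paste0("multiple chains present; specify one of: ",
                   paste(chains, collapse = ", ")))
    chain <- chains
  }
  if (!chain %in% unique(at$chain))
    abort(paste0("chain '", chain, "' not found; available chains: ",
                 paste(sort(unique(at$chain)), collapse = ", ")))
  at <- at[at$chain == chain, , drop = FALSE]

  het <- at[at$type != "ATOM", , drop = FALSE]
  at <- at[at$type == "ATOM", , drop = FALSE]

  # alternate locations: keep highest occupancy per (residue, atom name),
  # alphabetically first conformer on ties
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(seq_len(nrow(at)))  # file order
  pick <- tapply(seq_len(nrow(at)), key, function(idx) {
    idx[order(-occ[idx], alt[idx])][1]
  })
  at <- at[sort(unlist(pick)), , drop = FALSE]

  ins <- at$insert
  ins[is.na(ins)] <- ""
  res_key <- paste(at$resno, ins, sep = "\r")
  res_order <- unique(res_key)  # file order

  is_h <- !is.na(at$elesy) & toupper(at$elesy) == "H"
  is_h <- is_h | (is.na(at$elesy) & grepl("^[0-9]*H", at$elety))

  rows <- vector("list", length(res_order))
  skipped <- character(0)
  for (r in seq_along(res_order)) {
    sel <- which(res_key == res_order[r])
    ca <- sel[at$elety[sel] == "CA"]
    if (length(ca) == 0) {
      skipped <- c(skipped, paste0(at$resid[sel[1]], at$resno[sel[1]]))
      next
    }
    ca <- ca[1]
    hv <- sel[!is_h[sel]]
    rows[[r]] <- list(
      residue_id = at$resno[ca],
      insert = ins[ca],
      chain = chain,
      aa = bio3d::aa321(at$resid[ca]),
      x = at$x[ca], y = at$y[ca], z = at$z[ca],
      heavy = list(cbind(x = at$x[hv], y = at$y[hv], z = at$z[hv]))
    )
  }
  kept <- !vapply(rows, is.null, logical(1))
  if (length(skipped) > 0) {
    # a single missing C-alpha is always tolerable; beyond that refuse
    # structures losing more than 10% of their residues
    if (length(skipped) > max(1, 0.1 * length(res_order)))
      abort(sprintf("%d of %d residues lack a C-alpha atom (> 10%%)",
                    length(skipped), length(res_order)))
    warn(paste0("skipping ", length(skipped),
                " residue(s) without C-alpha: ",
                paste(head(skipped, 5), collapse = ", "),
                if (length(skipped) > 5) ", ..." else ""))
  }
  df <- dplyr::bind_rows(lapply(rows[kept], tibble::as_tibble_row))

  if (include_hetatm && nrow(het) > 0) {
    hkey <- paste(het$resno, het$resid, sep = "\r")
    for (k in unique(hkey)) {
      sel <- which(hkey == k)
      df <- dplyr::bind_rows(df, tibble::tibble(
        residue_id = het$resno[sel[1]], insert = "", chain = chain,
        aa = "X",
        x = mean(het$x[sel]), y = mean(het$y[sel]), z = mean(het$z[sel]),
        heavy = list(cbind(x = het$x[sel], y = het$y[sel], z = het$z[sel]))
      ))
    }
  }
  if (any(!is.finite(c(df$x, df$y, df$z))))
    abort("non-finite coordinates in structure")
  new_structure_tbl(df, source_id = basename(path))
}

new_structure_tbl <- function(df, source_id = NA_character_) {
  tibble::new_tibble(df, source_id = source_id,
                     class = "structure_tbl", nrow = nrow(df))
}

#' Coordinates of a structure as an N x 3 matrix
#' @param model A `structure_tbl`.
#' @return Numeric matrix of C-alpha coordinates with residue ids as rownames.
#' @export
ca_coords <- function(model) {
  m <- cbind(model$x, model$y, model$z)
  rownames(m) <- as.character(model$residue_id)
  m
}

#' Distance between two residues
#'
#' @param model A `structure_tbl`.
#' @param i,j Author residue ids.
#' @param convention `"ca"` for C-alpha--C-alpha distance, `"heavy_min"` for
#'   the minimum over all heavy-atom pairs (requires heavy atoms loaded).
#' @return Distance in Angstrom.
#' @export
residue_distance <- function(model, i, j, convention = c("ca", "heavy_min")) {
  convention <- match.arg(convention)
  ri <- match(i, model$residue_id)
  rj <- match(j, model$residue_id)
  if (is.na(ri)) abort(paste0("unknown residue id: ", i))
  if (is.na(rj)) abort(paste0("unknown residue id: ", j))
  if (convention == "ca") {
    sqrt(sum((c(model$x[ri], model$y[ri], model$z[ri]) -
              c(model$x[rj], model$y[rj], model$z[rj]))^2))
  } else {
    hi <- model$heavy[[ri]]
    hj <- model$heavy[[rj]]
    if (is.null(hi) || is.null(hj))
      abort("heavy_min requires heavy atoms to be loaded")
    d2 <- outer(rowSums(hi^2), rowSums(hj^2), "+") - 2 * hi %*% t(hj)
    sqrt(max(0, min(d2)))
  }
}

#' Write the per-residue annotation table
#'
#' @param model A `structure_tbl` (ideally after [annotate_domains()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_residue_table <- function(model, path) {
  df <- tibble::tibble(
    residue_id = model$residue_id,
    chain = model$chain,
    aa = model$aa,
    label = if ("domain" %in% names(model)) model$domain else "other"
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a C-alpha trace as PDB, optionally encoding a profile as B-factors
#'
#' Writes one `ATOM` record per residue so per-residue profiles (mobility,
#' effectiveness, propensity) can be inspected in molecular viewers via the
#' B-factor column.
#'
#' @param model A `structure_tbl`.
#' @param path Output path.
#' @param bfactor Optional numeric vector (length = residues) written into
#'   the B-factor column; defaults to zero.
#' @return The path, invisibly.
#' @export
write_ca_pdb <- function(model, path, bfactor = NULL) {
  n <- nrow(model)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  if (length(bfactor) != n) abort("bfactor length must equal residue count")
  aa3 <- vapply(model$aa, function(a) {
    out <- bio3d::aa123(a)
    if (is.na(out) || nchar(out) != 3) "UNK" else out
  }, character(1))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), aa3, substr(model$chain, 1, 1), model$residue_id,
    model$x, model$y, model$z, 1.0, pmin(pmax(bfactor, -99), 999)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Expected location of the reference DnaK coordinates
#'
#' The qualitative DnaK checks (hinge positions, captured-dynamics
#' fraction, contact classification of the strongest interdomain pairs)
#' run against the ATP-bound DnaK crystal structure, PDB entry 4B9Q, which
#' is not redistributed with the package.  Download `4B9Q.pdb` from the
#' PDB and place it at the path this function returns (the package's
#' `extdata` directory), or point `options(allomap.dnak_structure = ...)`
#' at a copy.
#'
#' @return Path where the structure is looked up (may not exist).
#' @export
dnak_structure_file <- function() {
  opt <- getOption("allomap.dnak_structure")
  if (!is.null(opt)) return(opt)
  file.path(system.file("extdata", package = "allomap"), "4B9Q.pdb")
}
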