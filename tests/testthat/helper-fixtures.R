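# Fixtures built in code: tiny PDB files, toy alignments, bead geometries.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", elety), alt, resid, chain, resno, x, y, z,
          occ, b)
}

# three glycines along x, 3.8 A apart, CA + N atoms
write_three_residue_pdb <- function(path, drop_ca_of = integer(0)) {
  serial <- 0
  lines <- character(0)
  for (r in 1:3) {
    x <- 3.8 * (r - 1)
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "N", "GLY", "A", r, x, 1.2, 0))
    if (!(r %in% drop_ca_of)) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", "A", r, x, 0, 0))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# structure_tbl straight from coordinates (helper for network tests)
structure_from_xyz <- function(xyz, ids = seq_len(nrow(xyz))) {
  allomap:::new_structure_tbl(tibble::tibble(
    residue_id = as.integer(ids), insert = "", chain = "A", aa = "G",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    heavy = lapply(seq_len(nrow(xyz)), function(i) matrix(xyz[i, ], 1, 3))
  ), source_id = "fixture")
}

# path graph of three beads 3.8 A apart
p3_structure <- function() {
  structure_from_xyz(cbind(c(0, 3.8, 7.6), 0, 0))
}

# equilateral triangle within the GNM cutoff
k3_structure <- function() {
  structure_from_xyz(rbind(c(0, 0, 0), c(4, 0, 0), c(2, 2 * sqrt(3), 0)))
}

# random non-degenerate 3-D cloud whose ANM at the default cutoff has
# exactly the six rigid-body zero modes (dense enough that no node can
# pivot freely)
random_cloud <- function(n, seed = 1, spread = 4.5) {
  set.seed(seed)
  repeat {
    xyz <- matrix(rnorm(3 * n, sd = spread), n, 3)
    if (min(dist(xyz)) <= 2) next
    ev <- eigen(allomap::anm_hessian(xyz, cutoff = 13), symmetric = TRUE,
                only.values = TRUE)$values
    if (sum(ev < 1e-8 * max(ev)) == 6) return(xyz)
  }
}

msa_from_strings <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  msa_set(ids, seqs)
}

# brute-force mutual information of two encoded columns (gap-excluded),
# independent of the package's frequency machinery
brute_mi <- function(a, b) {
  ok <- a != "-" & b != "-"
  tab <- table(a[ok], b[ok])
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  as.numeric(s)
}

column_chars <- function(msa, col) {
  vapply(strsplit(msa$seqs, ""), `[[`, character(1), col)
}

# standard planted-coupling fixture used by recovery tests
planted_fixture <- function(L, N, n_pairs, seed, coupling = 0.75,
                            span = L / 2) {
  planted <- lapply(seq_len(n_pairs), function(k)
    list(cols = c(k, span + k), coupling = coupling, n_states = 4))
  make_coupled_msa(L = L, N = N, planted = planted, seed = seed)
}

top_pairs_of_result <- function(result, k = 20) {
  td <- tidy(result)
  td <- td[order(-td$score, td$col_a, td$col_b), , drop = FALSE]
  td[seq_len(k), c("col_a", "col_b")]
}

count_recovered <- function(top, truth_pairs) {
  sum(vapply(truth_pairs, function(p)
    any(top$col_a == p$col_a & top$col_b == p$col_b), logical(1)))
}
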