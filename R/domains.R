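#' Domain partitions
#'
#' A domain map is a tibble with columns `label`, `start`, `end`, one row per
#' closed residue-id interval.  Intervals belonging to different labels must
#' not overlap; a label may own several intervals (e.g. discontinuous
#' subdomain IA).  Residues outside every interval resolve to the sentinel
#' label `"other"`.
#'
#' @param label,start,end Vectors defining the intervals.
#' @return A validated domain-map tibble.
#' @export
domain_map <- function(label, start, end) {
  map <- tibble::tibble(label = as.character(label),
                        start = as.integer(start), end = as.integer(end))
  validate_domain_map(map)
}

validate_domain_map <- function(map) {
  stopifnot(all(c("label", "start", "end") %in% names(map)))
  if (any(map$end < map$start)) abort("domain interval with end < start")
  n <- nrow(map)
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
      if (map$start[b] <= map$end[a] && map$start[a] <= map$end[b]) {
        if (map$label[a] != map$label[b]) {
          abort(sprintf(
            "overlapping intervals across labels: %s [%d-%d] and %s [%d-%d]",
            map$label[a], map$start[a], map$end[a],
            map$label[b], map$start[b], map$end[b]))
        } else {
          abort(sprintf("overlapping intervals within label %s: [%d-%d], [%d-%d]",
                        map$label[a], map$start[a], map$end[a],
                        map$start[b], map$end[b]))
        }
      }
    }
  }
  map
}

#' Default DnaK domain partition
#'
#' Subdomains of the nucleotide-binding domain (IA, IB, IIA, IIB), the
#' interdomain linker (V389-L392) and the substrate-binding domain of
#' *E. coli* DnaK, in author numbering of the ATP-bound structure.
#'
#' @return A domain-map tibble.
#' @export
dnak_domain_map <- function() {
  domain_map(
    label = c("IA", "IA", "IB", "IIA", "IIA", "IIB", "linker", "SBD"),
    start = c(3, 112, 39, 185, 310, 229, 389, 393),
    end   = c(38, 184, 111, 228, 388, 309, 392, 604)
  )
}

#' Default DnaK interdomain residue groups
#'
#' The NBD side of the interdomain pair space spans residues 1-388 (the two
#' residues preceding subdomain IA included, as the conventional NBD
#' boundary), the SBD side 393-604, giving the 388 x 212 = 82,256 candidate
#' pair space.
#'
#' @return Named list of residue-id vectors.
#' @export
dnak_groups <- function() {
  list(NBD = 1:388, SBD = 393:604)
}

#' Look up domain labels for residue ids
#' @param ids Integer residue ids.
#' @param map Domain-map tibble.
#' @return Character vector of labels (`"other"` where unlabeled).
#' @export
domain_lookup <- function(ids, map) {
  map <- validate_domain_map(map)
  out <- rep("other", length(ids))
  for (r in seq_len(nrow(map))) {
    hit <- ids >= map$start[r] & ids <= map$end[r]
    out[hit] <- map$label[r]
  }
  out
}

#' Attach domain labels to a structure
#'
#' @param model A `structure_tbl`.
#' @param map Domain-map tibble; defaults to the DnaK partition.
#' @return The structure with a `domain` column added/replaced.
#' @export
annotate_domains <- function(model, map = dnak_domain_map()) {
  model$domain <- domain_lookup(model$residue_id, map)
  model
}

#' Residue ids covered by a set of domain labels
#' @param map Domain-map tibble.
#' @param labels Labels to collect.
#' @return Sorted integer vector of residue ids.
#' @export
domain_residues <- function(map, labels) {
  map <- validate_domain_map(map)
  sel <- map[map$label %in% labels, , drop = FALSE]
  sort(unique(unlist(mapply(seq, sel$start, sel$end, SIMPLIFY = FALSE))))
}
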