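# coevolution result with a prescribed score matrix and full column map
result_with_scores <- function(scores, residues = seq_len(nrow(scores)),
                               method = "TEST") {
  coev_result(method, scores, column_map = as.integer(residues))
}

test_that("the DnaK partition spans exactly 82,256 interdomain pairs and k = 50", {
  expect_identical(interdomain_pair_count(dnak_groups()), 82256L)
  s <- matrix(0, 604, 604)
  r <- result_with_scores(s, residues = 1:604)
  sub <- interdomain_submatrix(r, dnak_groups())
  expect_equal(sub$n_pairs_full, 82256)
  expect_equal(ceiling(0.0006 * sub$n_pairs_full), 50)
})

test_that("a toy 3/2 split yields six pairs matching the full matrix entries", {
  set.seed(2)
  s <- matrix(runif(25), 5, 5)
  s <- (s + t(s)) / 2
  r <- result_with_scores(s)
  sub <- interdomain_submatrix(r, list(A = 1:3, B = 4:5))
  expect_equal(dim(sub$scores), c(3, 2))
  expect_equal(sub$n_pairs, 6)
  for (i in 1:3) for (j in 4:5) {
    expect_equal(sub$scores[i, j - 3], r$scores[i, j])
  }
  expect_error(interdomain_submatrix(r, list(A = 100:110, B = 4:5)),
               "no mapped columns")
})

test_that("top_pairs ranks by score with deterministic tie-breaking", {
  s <- matrix(0, 5, 5)
  s[1, 4] <- s[4, 1] <- 0.9
  s[2, 5] <- s[5, 2] <- 0.7
  s[3, 4] <- s[4, 3] <- 0.5
  sub <- interdomain_submatrix(result_with_scores(s), list(A = 1:3, B = 4:5))
  tp <- top_pairs(sub, k_override = 2)
  expect_equal(tp$residue_a, c(1, 2))
  expect_equal(tp$residue_b, c(4, 5))
  expect_equal(tp$rank, 1:2)
  # all-equal scores: tie-break order, flagged degenerate
  ties <- interdomain_submatrix(result_with_scores(matrix(1, 5, 5)),
                                list(A = 1:3, B = 4:5))
  expect_warning(tpt <- top_pairs(ties, k_override = 3), "tied")
  expect_true(attr(tpt, "degenerate"))
  expect_equal(tpt$residue_a, c(1, 1, 2))
  # clamping
  expect_warning(top_pairs(sub, k_override = 100), "clamping")
})

test_that("fraction-based k uses the ceiling of the candidate pair space", {
  s <- matrix(seq(0, 1, length.out = 36), 6, 6)
  s <- (s + t(s)) / 2
  sub <- interdomain_submatrix(result_with_scores(s), list(A = 1:3, B = 4:6))
  # 9 pairs * 0.2 -> ceil(1.8) = 2
  expect_equal(nrow(top_pairs(sub, fraction = 0.2)), 2)
})

test_that("consensus of identical methods is their common top-k; disjoint is empty", {
  set.seed(4)
  s <- matrix(runif(64), 8, 8)
  s <- (s + t(s)) / 2
  r1 <- result_with_scores(s, method = "M1")
  r2 <- result_with_scores(s, method = "M2")
  groups <- list(A = 1:4, B = 5:8)
  cons <- consensus_pairs(list(r1, r2), groups, k_override = 5)
  expect_equal(nrow(cons), 5)
  expect_true(all(cons$n_methods == 2))
  # disjoint top sets
  s2 <- -s
  r3 <- result_with_scores(s2, method = "M3")
  cons2 <- consensus_pairs(list(r1, r3), groups, k_override = 3)
  expect_equal(nrow(cons2), 0)
  expect_error(consensus_pairs(list(r1), groups), "at least 2")
})

test_that("consensus shrinks monotonically with min_methods and ignores input order", {
  set.seed(8)
  mk <- function(nm) {
    s <- matrix(runif(100), 10, 10)
    result_with_scores((s + t(s)) / 2, method = nm)
  }
  rs <- list(mk("A"), mk("B"), mk("C"))
  groups <- list(G1 = 1:5, G2 = 6:10)
  keys <- function(cc) paste(cc$residue_a, cc$residue_b)
  c1 <- consensus_pairs(rs, groups, k_override = 10, min_methods = 1)
  c2 <- consensus_pairs(rs, groups, k_override = 10, min_methods = 2)
  c3 <- consensus_pairs(rs, groups, k_override = 10, min_methods = 3)
  expect_true(all(keys(c2) %in% keys(c1)))
  expect_true(all(keys(c3) %in% keys(c2)))
  shuffled <- consensus_pairs(rs[c(3, 1, 2)], groups, k_override = 10,
                              min_methods = 2)
  expect_equal(shuffled, c2)
})

test_that("cumulative propensity equals brute-force opposite-domain summation", {
  m22 <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] by row
  sub <- list(scores = m22, residues_a = 1:2, residues_b = 3:4,
              group_names = c("A", "B"), method = "T", n_pairs = 4)
  class(sub) <- "interdomain_matrix"
  pr <- cumulative_propensity(sub)
  expect_equal(pr$propensity[pr$group == "A"], c(3, 7))
  expect_equal(pr$propensity[pr$group == "B"], c(4, 6))
  zero <- sub; zero$scores <- matrix(0, 2, 2)
  expect_equal(cumulative_propensity(zero)$propensity, rep(0, 4))
  # oracle: full-matrix summation restricted to opposite-domain partners
  set.seed(11)
  s <- matrix(runif(81), 9, 9); s <- (s + t(s)) / 2
  r <- result_with_scores(s)
  groups <- list(A = 1:5, B = 6:9)
  sub2 <- interdomain_submatrix(r, groups)
  pr2 <- cumulative_propensity(sub2)
  for (res in 1:5) {
    expect_equal(pr2$propensity[pr2$residue_id == res],
                 unname(sum(r$scores[res, 6:9])))
  }
  for (res in 6:9) {
    expect_equal(pr2$propensity[pr2$residue_id == res],
                 unname(sum(r$scores[1:5, res])))
  }
})

test_that("planted interdomain pairs carry the top propensities", {
  sm <- planted_fixture(L = 30, N = 500, n_pairs = 3, seed = 77, span = 15)
  msa <- map_to_reference(sm$msa, sm$msa$ids[1], 1)
  msa$column_map <- 1:30  # identity map: every column is a residue
  r <- mip(msa)
  sub <- interdomain_submatrix(r, list(A = 1:15, B = 16:30))
  pr <- cumulative_propensity(sub)
  planted_a <- vapply(sm$truth$planted_pairs, `[[`, numeric(1), "col_a")
  top_a <- pr$residue_id[pr$group == "A"][order(-pr$propensity[pr$group == "A"])][1:3]
  expect_true(length(intersect(top_a, planted_a)) >= 2)
})

test_that("pair classification follows the contact and distance thresholds", {
  df <- tibble::tibble(
    residue_id = 1:4, insert = "", chain = "A", aa = "A",
    x = c(0, 10, 50, 30), y = 0, z = 0,
    heavy = list(rbind(c(0, 0, 0), c(4, 0, 0)),
                 rbind(c(10, 0, 0), c(7, 0, 0)),
                 rbind(c(50, 0, 0)),
                 rbind(c(30, 0, 0))))
  st <- allomap:::new_structure_tbl(df)
  out <- classify_pair(st, tibble::tibble(residue_a = c(1, 1, 1),
                                          residue_b = c(2, 3, 99)))
  expect_equal(out$contact_class, c("contact", "distant", "unresolved"))
  expect_equal(out$distance_heavy[1], 3)
  expect_equal(out$distance_ca[2], 50)
  mid <- classify_pair(st, c(2, 4))
  expect_equal(mid$contact_class, "neighboring_no_contact")
})
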