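test_that("FASTA alignments read with the right dimensions and round-trip", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE-", ">b", "ACDEF", ">c", "AC-EF", ">d", "ACDEF"),
             path)
  msa <- read_msa(path)
  expect_equal(n_seqs(msa), 4)
  expect_equal(n_cols(msa), 5)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_msa(msa, out)
  msa2 <- read_msa(out)
  expect_equal(msa2$ids, msa$ids)
  expect_equal(msa2$seqs, msa$seqs)
})

test_that("ragged alignments are rejected naming the offending row", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">bad", "ACD"), path)
  expect_error(read_msa(path), "bad")
})

test_that("Stockholm input preserves per-column annotation and round-trips", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "seq1         ACDE-",
               "seq2         AC-EF",
               "#=GC RF      xxxx.",
               "//"), path)
  msa <- read_msa(path)
  expect_equal(n_seqs(msa), 2)
  expect_equal(msa$annotations$RF, "xxxx.")
  out <- withr::local_tempfile(fileext = ".sto")
  write_msa(msa, out, format = "stockholm")
  msa2 <- read_msa(out)
  expect_equal(msa2$seqs, msa$seqs)
  expect_equal(msa2$annotations$RF, "xxxx.")
})

test_that("reference mapping assigns consecutive ids to non-gap columns", {
  msa <- msa_from_strings(c("AC-DE", "ACQDE"), ids = c("ref", "other"))
  m <- map_to_reference(msa, "ref", ref_start = 10)
  expect_equal(m$column_map, c(10L, 11L, NA, 12L, 13L))
  expect_equal(sum(!is.na(m$column_map)), 4)  # non-gap length of reference
  allgap <- msa_from_strings(c("----", "ACDE"), ids = c("ref", "x"))
  expect_error(map_to_reference(allgap, "ref"), "all gaps")
  expect_error(map_to_reference(msa, "nope"), "not in alignment")
})

test_that("identity weighting downweights duplicate sequences", {
  msa <- msa_from_strings(c("ACDEF", "ACDEF"))
  w <- sequence_weights(msa)$weights
  expect_equal(w, c(0.5, 0.5))
  expect_equal(m_eff(sequence_weights(msa)), 1)
  distinct <- msa_from_strings(c("ACDEF", "KLMNP", "QRSTV"))
  expect_equal(sequence_weights(distinct)$weights, rep(1, 3))
  k <- 5
  copies <- msa_from_strings(rep("ACDEFGHIKL", k))
  expect_equal(sequence_weights(copies)$weights, rep(1 / k, k))
})

test_that("weights are invariant under sequence reordering", {
  seqs <- c("ACDEFACDEF", "ACDEFACDEW", "KLMNPKLMNP", "KLMNPKLMNP")
  w1 <- sequence_weights(msa_from_strings(seqs))$weights
  perm <- c(3, 1, 4, 2)
  w2 <- sequence_weights(msa_from_strings(seqs[perm]))$weights
  expect_equal(w2, w1[perm])
})

test_that("column filtering drops gapped and unmapped columns as stated", {
  # 5-column toy; hand-counted gap fractions 0, 0, 0.75, 0.25, 1.0
  msa <- msa_from_strings(c("AA-A-", "AAAA-", "AC---", "AC-C-"))
  gapfrac <- colMeans(msa$enc == 21L)
  expect_equal(gapfrac, c(0, 0, 0.75, 0.25, 1))
  f <- filter_columns(msa, max_gap_fraction = 0.5)
  expect_equal(n_cols(f), 3)  # hand count of surviving columns
  expect_equal(n_cols(filter_columns(msa, max_gap_fraction = 1)), 5)
  mm <- map_to_reference(msa, msa$ids[1], 1)
  fm <- filter_columns(mm, max_gap_fraction = 1, mapped_only = TRUE)
  expect_equal(n_cols(fm), 3)  # ref row is non-gap at columns 1, 2, 4
})

test_that("frequency tables obey normalization, marginalization and limits", {
  one <- msa_from_strings("A")
  expect_equal(frequencies(one)$f1[1, 1], 1)
  # lambda -> infinity gives the uniform distribution
  big <- frequencies(one, pseudocount = 1e12)
  expect_equal(big$f1[1, ], rep(1 / 21, 21), tolerance = 1e-6)
  set.seed(7)
  seqs <- replicate(12, paste0(sample(c("A", "C", "D", "-"), 6, TRUE),
                               collapse = ""))
  ft <- frequencies(msa_from_strings(seqs), pseudocount = 0.7)
  expect_equal(rowSums(ft$f1), rep(1, 6), tolerance = 1e-10)
  for (i in 1:5) for (j in (i + 1):6) {
    tab <- pair_freq(ft, i, j)
    expect_equal(rowSums(tab), ft$f1[i, ], tolerance = 1e-10)
    expect_equal(colSums(tab), ft$f1[j, ], tolerance = 1e-10)
    expect_equal(pair_freq(ft, j, i), t(tab))
  }
})

test_that("Shannon entropy hits its closed-form anchor points and bounds", {
  msa <- msa_from_strings(c("AAW", "ACW", "ACW", "ACW"))
  h <- shannon_entropy(msa)$entropy
  expect_equal(h[c(1, 3)], c(0, 0))           # fully conserved columns
  expect_equal(h[2], -0.25 * log(0.25) - 0.75 * log(0.75))
  two <- msa_from_strings(c("A", "C"))
  expect_equal(shannon_entropy(two)$entropy, log(2))
  unif <- msa_from_strings(AA20)
  expect_equal(shannon_entropy(unif)$entropy, log(20))
  set.seed(1)
  rnd <- msa_from_strings(replicate(30, paste0(
    sample(c(AA20, "-"), 8, TRUE), collapse = "")))
  hr <- shannon_entropy(rnd)$entropy
  expect_true(all(hr >= 0 & hr <= log(20), na.rm = TRUE))
})

test_that("entropy in other bases rescales", {
  two <- msa_from_strings(c("A", "C"))
  expect_equal(shannon_entropy(two, base = 2)$entropy, 1)
})
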