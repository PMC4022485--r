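test_that("the Kirchhoff matrix of a path of three beads is the P3 Laplacian", {
  net <- build_gnm(p3_structure(), cutoff = 7.3)
  expected <- rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1))
  expect_equal(unname(net$kirchhoff), expected)
  expect_equal(rowSums(net$kirchhoff), c("1" = 0, "2" = 0, "3" = 0))
})

test_that("beads beyond the cutoff give a disconnected zero network", {
  st <- structure_from_xyz(rbind(c(0, 0, 0), c(10, 0, 0)))
  net <- build_gnm(st, cutoff = 7.3)
  expect_equal(unname(net$kirchhoff), matrix(0, 2, 2))
  expect_equal(net$n_components, 2)
  expect_error(build_gnm(st[1, , drop = FALSE]), "at least 2")
})

test_that("small-graph spectra match closed forms", {
  msp3 <- decompose_gnm(build_gnm(p3_structure()))
  expect_equal(msp3$values, c(0, 1, 3), tolerance = 1e-12)
  expect_equal(msp3$n_zero, 1)
  msk3 <- decompose_gnm(build_gnm(k3_structure(), cutoff = 7.3))
  expect_equal(msk3$values, c(0, 3, 3), tolerance = 1e-12)
})

test_that("the spectrum of a random connected network matches a dense eigensolver", {
  xyz <- random_cloud(30, seed = 5)
  net <- build_gnm(structure_from_xyz(xyz), cutoff = 13)
  ms <- decompose_gnm(net)
  oracle <- sort(eigen(net$kirchhoff, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ms$values, oracle, tolerance = 1e-8)
  # eigenpairs satisfy the eigen equation
  for (k in c(2, 10, 30)) {
    expect_equal(as.vector(net$kirchhoff %*% ms$vectors[, k]),
                 ms$values[k] * ms$vectors[, k], tolerance = 1e-8)
  }
})

test_that("disconnected networks have one zero mode per component", {
  st <- structure_from_xyz(rbind(c(0, 0, 0), c(3.8, 0, 0),
                                 c(50, 0, 0), c(53.8, 0, 0)))
  net <- build_gnm(st)
  expect_warning(
    expect_error(decompose_gnm(net), "disconnected"),
    "2 connected components")
  suppressWarnings(
    ms <- decompose_gnm(net, on_disconnected = "largest_component"))
  expect_equal(ms$n_zero, 1)
  expect_equal(length(ms$residue_id), 2)
})

test_that("mode mobility matches the exact P3 profile and sums to 1/lambda", {
  ms <- decompose_gnm(build_gnm(p3_structure()))
  m1 <- mode_mobility(ms, 1)
  expect_equal(m1$mobility, c(0.5, 0, 0.5))
  m2 <- mode_mobility(ms, 2)
  expect_equal(sum(m2$mobility), 1 / 3)
  expect_true(all(m1$mobility >= 0))
  expect_error(mode_mobility(ms, 0), "must be in")
  expect_error(mode_mobility(ms, 3), "must be in")
})

test_that("degenerate K3 modes jointly give a uniform profile", {
  ms <- decompose_gnm(build_gnm(k3_structure(), cutoff = 7.3))
  both <- mode_mobility(ms, 1)$mobility + mode_mobility(ms, 2)$mobility
  expect_equal(both, rep(both[1], 3), tolerance = 1e-12)
})

test_that("cumulative mobility sums per-mode profiles (exact P3 values)", {
  ms <- decompose_gnm(build_gnm(p3_structure()))
  expect_equal(cumulative_mobility(ms, 1)$mobility, mode_mobility(ms, 1)$mobility)
  # hand sum: mode1 (1/2, 0, 1/2); mode2 u=(1,-2,1)/sqrt(6), lambda=3
  expect_equal(cumulative_mobility(ms, 2)$mobility, c(5 / 9, 2 / 9, 5 / 9))
  expect_error(cumulative_mobility(ms, 3), "must be in")
})

test_that("mobility cross-checks against the Kirchhoff pseudoinverse diagonal", {
  xyz <- random_cloud(25, seed = 9)
  net <- build_gnm(structure_from_xyz(xyz), cutoff = 13)
  ms <- decompose_gnm(net)
  total <- Reduce(`+`, lapply(seq_len(length(ms$values) - 1),
                              function(k) mode_mobility(ms, k)$mobility))
  e <- eigen(net$kirchhoff, symmetric = TRUE)
  nz <- e$values > 1e-8 * max(e$values)
  pinv_diag <- diag(e$vectors[, nz] %*% (t(e$vectors[, nz]) / e$values[nz]))
  expect_equal(total, pinv_diag, tolerance = 1e-8)
})

test_that("dynamics fraction is exact on P3, monotone, and reaches 1", {
  ms <- decompose_gnm(build_gnm(p3_structure()))
  expect_equal(dynamics_fraction(ms, 1), 0.75)
  expect_equal(dynamics_fraction(ms, 0), 0)
  expect_equal(dynamics_fraction(ms, 2), 1)
  ms2 <- decompose_gnm(build_gnm(structure_from_xyz(random_cloud(20, seed = 2)),
                                 cutoff = 13))
  fr <- vapply(0:19, function(m) dynamics_fraction(ms2, m), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[20], 1)
})

test_that("hinge detection finds the P3 middle bead and rejects flat profiles", {
  ms <- decompose_gnm(build_gnm(p3_structure()))
  prof <- mode_mobility(ms, 1)
  expect_equal(find_hinges(prof, window = 1, percentile = 40), 2L)
  flat <- prof
  flat$mobility <- rep(1, 3)
  expect_length(find_hinges(flat, window = 1, percentile = 20), 0)
  expect_error(find_hinges(prof, window = 5), "too short")
})

test_that("the planted linker of a synthetic dumbbell appears among the hinges", {
  st <- make_two_domain_structure(30, 30, 4, seed = 42)
  ms <- decompose_gnm(build_gnm(st))
  prof <- cumulative_mobility(ms, 2)
  hinges <- find_hinges(prof, window = 5, percentile = 20)
  expect_true(any(hinges %in% attr(st, "planted_hinge_ids")))
})
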