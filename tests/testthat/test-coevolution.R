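test_that("substitution scores follow the gap rules and BLOSUM50", {
  m <- substitutionModel()
  expect_identical(substitutionScore("A", "-", m), -8L)
  expect_identical(substitutionScore("-", "W", m), -8L)
  expect_identical(substitutionScore("-", "-", m), 0L)
  expect_identical(substitutionScore("A", "A", m), 5L)
  expect_identical(substitutionScore("W", "W", m), 15L)
  expect_identical(substitutionScore("R", "K", m), 3L)
  expect_error(substitutionScore("Z", "A", m), "alphabet")
  # symmetry over the whole alphabet
  s <- thermosector:::scoreMatrix(m)
  expect_identical(s, t(s))
  # configurable gap scores
  m2 <- substitutionModel(gapVsResidue = -4L, gapVsGap = 1L)
  expect_identical(substitutionScore("G", "-", m2), -4L)
  expect_identical(substitutionScore("-", "-", m2), 1L)
})

test_that("pinned BLOSUM50 matches an independently shipped copy", {
  skip_if_not_installed("Biostrings")
  ref <- NULL
  utils::data("BLOSUM50", package = "Biostrings", envir = environment())
  ref <- get("BLOSUM50", envir = environment())
  aa <- residueAlphabet()[1:20]
  expect_identical(unname(thermosector:::BLOSUM50_AA),
                   unname(matrix(as.integer(ref[aa, aa]), 20, 20)))
})

test_that("brute-force RCA reproduces a hand-enumerated 4x2 example", {
  aln <- msaFromStrings(s1 = "AD", s2 = "AD", s3 = "CE", s4 = "CE")
  r <- rcaMatrixBruteforce(aln)
  # independent enumeration of the 6 sequence pairs
  oracle <- oracleRCA(aln)
  expect_equal(correlations(r), oracle, tolerance = 1e-12)
  # same pair partition but different score spreads: strong, not perfect
  expect_gt(correlations(r)[1, 2], 0.5)
  expect_lt(correlations(r)[1, 2], 1)
})

test_that("identical columns correlate at 1; constant columns degenerate", {
  aln <- msaFromStrings(s1 = "AAC", s2 = "AAC", s3 = "DDC", s4 = "EEC")
  r <- rcaMatrixBruteforce(aln)
  expect_equal(correlations(r)[1, 2], 1, tolerance = 1e-12)
  expect_true(3L %in% degeneratePositions(r))
  expect_equal(correlations(r)[3, ], rep(0, 3))
  expect_equal(correlations(r)[, 3], rep(0, 3))
  expect_error(rcaMatrixBruteforce(msaFromStrings(s1 = "A", s2 = "C")),
               "at least 3")
})

test_that("fast RCA equals brute force, also with duplicated rows", {
  for (seed in 1:5) {
    aln <- randomMSA(12, 6, gapFraction = ifelse(seed %% 2, 0, 0.2),
                     seed = seed)
    rf <- correlations(rcaMatrix(aln))
    rb <- correlations(rcaMatrixBruteforce(aln))
    expect_lt(max(abs(rf - rb)), 1e-9)
  }
  # duplicating every sequence changes the matrix (duplicate self-pairs
  # enter the pair population) and must still match brute force
  aln <- randomMSA(8, 5, seed = 11)
  m <- residueMatrix(aln)
  dup <- rbind(m, m)
  rownames(dup) <- paste0("d", seq_len(nrow(dup)))
  alnDup <- proteinMSA(setNames(apply(dup, 1, paste, collapse = ""),
                                rownames(dup)))
  rd <- correlations(rcaMatrix(alnDup))
  expect_lt(max(abs(rd - correlations(rcaMatrixBruteforce(alnDup)))), 1e-9)
  expect_gt(max(abs(rd - correlations(rcaMatrix(aln)))), 1e-6)
})

test_that("RCA is invariant to sequence order and equivariant to columns", {
  aln <- randomMSA(15, 7, gapFraction = 0.1, seed = 3)
  m <- residueMatrix(aln)
  permS <- withr::with_seed(5, sample(nrow(m)))
  alnS <- proteinMSA(setNames(apply(m[permS, ], 1, paste, collapse = ""),
                              rownames(m)[permS]))
  expect_equal(correlations(rcaMatrix(alnS)), correlations(rcaMatrix(aln)),
               tolerance = 1e-12)
  permC <- withr::with_seed(6, sample(ncol(m)))
  alnC <- proteinMSA(setNames(apply(m[, permC], 1, paste, collapse = ""),
                              rownames(m)))
  expect_equal(correlations(rcaMatrix(alnC)),
               correlations(rcaMatrix(aln))[permC, permC],
               tolerance = 1e-12)
})

test_that("correlation entries are bounded and symmetric", {
  aln <- randomMSA(20, 10, gapFraction = 0.15, seed = 8)
  r <- correlations(rcaMatrix(aln))
  expect_true(all(abs(r) <= 1 + 1e-9))
  expect_identical(r, t(r))
})

test_that("eigen-decomposition is ordered, sign-fixed and reconstructs", {
  expect_equal(eigenValues(eigendecompose(diag(3))), rep(1, 3))
  # rank-1 closed form
  v <- c(3, 4) / 5
  eg <- eigendecompose(tcrossprod(v), selectedModes = 1)
  expect_equal(eigenValues(eg), c(1, 0), tolerance = 1e-12)
  expect_equal(abs(eigenVectors(eg)[, 1]), v, tolerance = 1e-12)
  # sign rule: largest-magnitude component positive
  expect_gt(max(eigenVectors(eg)[, 1]), 0)

  a <- withr::with_seed(10, matrix(rnorm(100), 10))
  r <- (a + t(a)) / 2
  eg2 <- eigendecompose(r, selectedModes = 2:4)
  expect_true(all(diff(eigenValues(eg2)) <= 1e-12))
  expect_equal(sum(eigenValues(eg2)), sum(diag(r)), tolerance = 1e-8)
  recon <- eigenVectors(eg2) %*% (eigenValues(eg2) * t(eigenVectors(eg2)))
  expect_lt(max(abs(recon - r)), 1e-8)
  for (k in 1:10) {
    col <- eigenVectors(eg2)[, k]
    expect_gt(col[which.max(abs(col))], 0)
  }
  expect_error(eigendecompose(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("mode approximation is additive and complete", {
  a <- withr::with_seed(12, matrix(rnorm(25), 5))
  r <- (a + t(a)) / 2
  eg <- eigendecompose(r, selectedModes = 2:4)
  expect_lt(max(abs(modeApproximation(eg, 1:5) - r)), 1e-8)
  expect_equal(modeApproximation(eg, 2:4),
               r - modeApproximation(eg, c(1, 5)), tolerance = 1e-8)
  expect_error(modeApproximation(eg, integer(0)), "empty")
  expect_error(modeApproximation(eg, 7), "outside")
})

test_that("a planted 2-block matrix keeps block sign structure in mode space", {
  blocks <- c(rep(1, 4), rep(2, 4))
  r <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.6, -0.2))
  diag(r) <- 1
  eg <- eigendecompose(r, selectedModes = 2)
  m2 <- modeApproximation(eg, 2)
  within1 <- m2[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
  within2 <- m2[5:8, 5:8][upper.tri(matrix(0, 4, 4))]
  expect_true(all(within1 > 0))
  expect_true(all(within2 > 0))
})
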