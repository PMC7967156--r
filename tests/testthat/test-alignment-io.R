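test_that("aligned FASTA parsing normalizes case, dots and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 desc", "ac-D", ">s2", "ACDD", ">s3", "A.dD"), f)
  aln <- readAlignment(f)
  expect_s4_class(aln, "ProteinMSA")
  expect_equal(nSequences(aln), 3L)
  expect_equal(nPositions(aln), 4L)
  expect_equal(residueMatrix(aln)["s1", ], c("A", "C", "-", "D"))
  expect_equal(residueMatrix(aln)["s3", ], c("A", "-", "D", "D"))

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "AXC", ">s2", "ABC"), f2)
  expect_warning(aln2 <- readAlignment(f2), "non-standard")
  expect_equal(unname(residueMatrix(aln2)["s1", 2]), "-")
  expect_equal(unname(residueMatrix(aln2)["s2", 2]), "-")
})

test_that("ragged, empty and duplicate-id alignments are hard errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACD", ">b", "AC"), f)
  expect_error(readAlignment(f), "ragged.*'b'")
  f2 <- withr::local_tempfile(fileext = ".fa")
  file.create(f2)
  expect_error(readAlignment(f2), "empty")
  expect_error(proteinMSA(c(a = "AC", a = "AD")), "unique")
})

test_that("Stockholm round-trips a hand-written fixture, '.' as gap", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF ID test",
               "seq1 AC.D",
               "seq2 A-CD",
               "",
               "seq1 GH",
               "seq2 G.",
               "//"), f)
  aln <- readAlignment(f)
  expect_equal(nSequences(aln), 2L)
  expect_equal(nPositions(aln), 6L)
  expect_equal(residueMatrix(aln)["seq1", ], c("A", "C", "-", "D", "G", "H"))
  expect_equal(residueMatrix(aln)["seq2", ], c("A", "-", "C", "D", "G", "-"))
})

test_that("reference projection keeps non-gap reference columns, 1-based", {
  aln <- msaFromStrings(ref = "A-CD", s2 = "ACDD", s3 = "GGGG")
  pr <- projectToReference(aln, "ref")
  expect_equal(nPositions(pr$alignment), 3L)
  expect_equal(refPositions(pr$map), 1:3)
  expect_equal(refResidues(pr$map), c("A", "C", "D"))
  expect_equal(residueMatrix(pr$alignment)["s2", ], c("A", "D", "D"))

  # gap-free reference: identity projection
  aln2 <- msaFromStrings(ref = "ACD", s2 = "AC-")
  pr2 <- projectToReference(aln2, "ref")
  expect_equal(residueMatrix(pr2$alignment), residueMatrix(aln2))

  # idempotence: projecting a projected alignment is the identity
  pr3 <- projectToReference(pr$alignment, "ref")
  expect_identical(residueMatrix(pr3$alignment),
                   residueMatrix(pr$alignment))
  expect_identical(refPositions(pr3$map), refPositions(pr$map))

  expect_error(projectToReference(aln, "nope"), "not present")
  aln3 <- msaFromStrings(ref = "---", s2 = "ACD")
  expect_error(projectToReference(aln3, "ref"), "all gaps")
})

test_that("projection enumerated column-by-column on a 5-sequence fixture", {
  aln <- msaFromStrings(ref = "AC--DE-G",
                        s1  = "ACWWDEWG",
                        s2  = "GGGGGGGG",
                        s3  = "AC-W-EWG",
                        s4  = "--WWDE--")
  pr <- projectToReference(aln, "ref")
  expect_equal(nPositions(pr$alignment), 5L)  # C minus 3 reference gaps
  expect_equal(unname(pr$map@columnOfPosition), 1:5)
  expect_equal(pr$alignment@sourceColumns, c(1L, 2L, 5L, 6L, 8L))
  expect_equal(unname(residueMatrix(pr$alignment)["s4", ]),
               c("-", "-", "D", "E", "-"))
})

test_that("label tables validate the closed set and default to unknown", {
  aln <- msaFromStrings(s1 = "ACD", s2 = "ACD", s3 = "GHK")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tlabel",
               "s1\tthermophilic",
               "s2\tMesophilic"), f)
  expect_warning(lab <- attachLabels(aln, f), "defaulted to 'unknown'")
  expect_equal(as.character(thermalLabels(lab)[c("s1", "s2", "s3")]),
               c("thermophilic", "mesophilic", "unknown"))

  # synonym and case handling
  lab2 <- labelTable(c("a", "b"), c("Unrecognized", "THERMOPHILIC"))
  expect_equal(as.character(thermalLabels(lab2)),
               c("unknown", "thermophilic"))

  # invalid label names the line
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tlabel", "s1\thot"), f2)
  expect_error(attachLabels(aln, f2), "line.*2")

  # conflicting duplicates are an integrity error
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tlabel", "s1\tthermophilic",
               "s1\tmesophilic", "s2\tmesophilic"), f3)
  expect_error(attachLabels(aln, f3), "conflicting")
})

test_that("subsetting by thermal class filters rows and enforces depth", {
  ids <- paste0("s", 1:10)
  seqs <- setNames(rep("ACDE", 10), ids)
  aln <- proteinMSA(seqs)
  lab <- labelTable(ids, rep(c("thermophilic", "mesophilic"), c(4, 6)))
  sub <- subsetByLabel(aln, lab, "mesophilic", minSubsetSize = 5)
  expect_equal(nSequences(sub), 6L)
  expect_equal(nPositions(sub), 4L)
  expect_error(subsetByLabel(aln, lab, "thermophilic"), "at least 5")
  expect_error(subsetByLabel(aln, lab, "unknown"), "0 sequence")
})

test_that("column frequencies sum to one and match hand counts", {
  aln <- msaFromStrings(s1 = "A", s2 = "A", s3 = "C", s4 = "D",
                        s5 = "D", s6 = "-")
  fp <- columnFrequencies(aln, 1)
  expect_s4_class(fp, "FrequencyProfile")
  q <- fp@freqs
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_equal(unname(q[c("A", "C", "D", "-")]),
               c(2, 1, 2, 1) / 6, tolerance = 1e-12)
  expect_equal(fp@support, 6L)

  # uniform column
  aln2 <- msaFromStrings(s1 = "AA", s2 = "AA", s3 = "A-", s4 = "A-")
  expect_equal(unname(columnFrequencies(aln2, 1)@freqs["A"]), 1)
  expect_equal(unname(columnFrequencies(aln2, 2)@freqs[c("A", "-")]),
               c(0.5, 0.5))
})

test_that("frequencies are invariant to sequence order after projection", {
  aln <- randomMSA(12, 8, gapFraction = 0.2, seed = 42)
  perm <- withr::with_seed(9, sample(nSequences(aln)))
  alnP <- proteinMSA(setNames(
    apply(residueMatrix(aln)[perm, ], 1, paste, collapse = ""),
    sequenceIDs(aln)[perm]))
  for (pos in c(1, 4, 8))
    expect_equal(columnFrequencies(aln, pos)@freqs,
                 columnFrequencies(alnP, pos)@freqs)
})
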