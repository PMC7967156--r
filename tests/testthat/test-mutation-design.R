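# Build an EntropyProfiles by hand so the selection rules can be tested
# against exactly known frequencies.
mkProfiles <- function(thermoFreq, mesoFreq, theta) {
  n <- length(theta)
  aa <- residueAlphabet()
  new("EntropyProfiles", positions = seq_len(n), theta = theta,
      Dthermo = matrix(0, n, 21, dimnames = list(NULL, aa)),
      Dmeso = matrix(0, n, 21, dimnames = list(NULL, aa)),
      freqThermo = thermoFreq, freqMeso = mesoFreq,
      supportThermo = rep(10L, n), supportMeso = rep(10L, n),
      background = setNames(rep(1 / 21, 21), aa))
}
freqRow <- function(...) {
  v <- setNames(rep(0, 21), residueAlphabet())
  x <- c(...)
  v[names(x)] <- x
  v
}

test_that("target sector selection maximizes mean theta, ties are errors", {
  mkAssign <- function(members, n) {
    s <- rep(NA_integer_, n)
    for (i in seq_along(members)) s[members[[i]]] <- i
    new("SectorAssignment", sectorOf = s, k = length(members),
        coordinates = matrix(0, n, 3), modes = 2:4,
        meanTheta = numeric(0), contiguity = numeric(0))
  }
  theta <- c(0.47, 0.47, 0.13, 0.13, 0.2, 0.2, 0.25, 0.25)
  prof <- mkProfiles(matrix(0, 8, 21), matrix(0, 8, 21), theta)
  asg <- mkAssign(list(1:2, 3:4, 5:6, 7:8), 8)
  sel <- selectTargetSector(asg, prof)
  expect_equal(sel$sector, 1L)
  expect_equal(sel$report$mean_theta, c(0.47, 0.13, 0.2, 0.25))
  # single sector: trivially selected
  expect_equal(selectTargetSector(mkAssign(list(1:8), 8), prof)$sector, 1L)
  # exact tie is a hard error demanding a manual choice
  thetaTie <- c(0.4, 0.4, 0.4, 0.4, 0.1, 0.1, 0.1, 0.1)
  profTie <- mkProfiles(matrix(0, 8, 21), matrix(0, 8, 21), thetaTie)
  expect_error(selectTargetSector(mkAssign(list(1:2, 3:4, 5:8), 8), profTie),
               "tie")
})

test_that("site selection filters by theta and sorts descending", {
  s <- rep(NA_integer_, 3); s[1:3] <- 1L
  asg <- new("SectorAssignment", sectorOf = s, k = 1L,
             coordinates = matrix(0, 3, 3), modes = 2:4,
             meanTheta = numeric(0), contiguity = numeric(0))
  prof <- mkProfiles(matrix(0, 3, 21), matrix(0, 3, 21), c(0.6, 0.4, 0.55))
  expect_equal(selectMutationSites(asg, prof, 1, 0.5), c(1L, 3L))
  expect_equal(selectMutationSites(asg, prof, 1, 0), c(1L, 3L, 2L))
  expect_warning(out <- selectMutationSites(asg, prof, 1, 2), "no position")
  expect_length(out, 0L)
})

test_that("replacement ranking follows frequency, exclusions and demotion", {
  # plain case: wild type S is also the meso consensus
  ft <- rbind(freqRow(K = 0.5, A = 0.3, S = 0.1, G = 0.1))
  fm <- rbind(freqRow(S = 0.8, A = 0.2))
  prof <- mkProfiles(ft, fm, 0.9)
  cand <- rankReplacements(1, prof, wildType = "S")
  expect_equal(cand$candidate[1:3], c("K", "A", "G"))
  expect_true(all(cand$rule_note == ""))
  expect_false("S" %in% cand$candidate)
  expect_false("-" %in% cand$candidate)

  # shared consensus between classes (not the wild type) is demoted
  ft2 <- rbind(freqRow(G = 0.6, N = 0.3, K = 0.1))
  fm2 <- rbind(freqRow(G = 0.7, A = 0.3))
  prof2 <- mkProfiles(ft2, fm2, 0.9)
  cand2 <- rankReplacements(1, prof2, wildType = "A")
  expect_equal(cand2$candidate[1:2], c("N", "G"))
  expect_equal(cand2$rule_note[2], "shared-consensus demotion")

  # wild type already the shared consensus: plain exclusion, no demotion
  cand3 <- rankReplacements(1, prof2, wildType = "G")
  expect_equal(cand3$candidate[1], "N")
  expect_true(all(cand3$rule_note == ""))

  # frequency ties break alphabetically
  ft4 <- rbind(freqRow(V = 0.4, N = 0.4, A = 0.2))
  prof4 <- mkProfiles(ft4, rbind(freqRow(A = 1)), 0.9)
  cand4 <- rankReplacements(1, prof4, wildType = "A")
  expect_equal(cand4$candidate[1:2], c("N", "V"))

  # thermophilic column all wild type: empty candidate list with warning
  ft5 <- rbind(freqRow(A = 1))
  prof5 <- mkProfiles(ft5, ft5, 0.9)
  expect_warning(cand5 <- rankReplacements(1, prof5, wildType = "A"),
                 "no eligible")
  expect_equal(nrow(cand5), 0L)
})

test_that("ranking is a permutation of the observed thermophilic residues", {
  fam <- generateFamily(seed = 9)
  prof <- thetaProfile(dropReference(fam$alignment), fam$labels, fam$map)
  for (pos in c(5, 35, 44)) {
    wt <- refResidues(fam$map)[pos]
    cand <- rankReplacements(pos, prof, wt)
    present <- names(which(prof@freqThermo[pos, residueAlphabet()[1:20]] > 0))
    expect_setequal(cand$candidate, setdiff(present, wt))
    expect_false(is.unsorted(cand$rank))
  }
})

test_that("single-mutant assembly formats rank-1 proposals only", {
  ft <- rbind(freqRow(K = 0.6, A = 0.4), freqRow(V = 0.9, L = 0.1))
  fm <- rbind(freqRow(S = 1), freqRow(D = 1))
  prof <- mkProfiles(ft, fm, c(0.8, 0.7))
  singles <- proposeSingleMutants(c(1, 2), prof,
                                  refResidues = c("S", "D"))
  firsts <- singles[singles$rank == 1, ]
  expect_equal(firsts$mutation, c("S1K", "D2V"))
  expect_true(all(singles$mutation[singles$rank > 1] == ""))
  expect_equal(nrow(proposeSingleMutants(integer(0), prof, character(0))), 0L)
})

test_that("double mutants pair the anchor with every other single", {
  ft <- rbind(freqRow(K = 0.6, A = 0.4), freqRow(V = 0.9, L = 0.1),
              freqRow(N = 1))
  fm <- rbind(freqRow(S = 1), freqRow(D = 1), freqRow(G = 1))
  prof <- mkProfiles(ft, fm, c(0.9, 0.7, 0.8))
  singles <- proposeSingleMutants(1:3, prof, c("S", "D", "G"))
  d <- enumerateDoubleMutants(singles, anchor = "S1K")
  expect_equal(d$combo, c("S1K/D2V", "S1K/G3N"))
  # auto anchor: highest theta site
  dAuto <- enumerateDoubleMutants(singles)
  expect_true(all(dAuto$anchor == "S1K"))
  expect_equal(nrow(dAuto), 2L)
  expect_error(enumerateDoubleMutants(singles, anchor = "X9Y"),
               "not among")
  one <- singles[singles$ref_position == 1, ]
  expect_warning(d0 <- enumerateDoubleMutants(one), "fewer than 2")
  expect_equal(nrow(d0), 0L)
})

test_that("plans are deterministic and never propose wild type or gap", {
  fam <- generateFamily(seed = 10)
  aln <- dropReference(fam$alignment)
  prof <- thetaProfile(aln, fam$labels, fam$map)
  corr <- rcaMatrix(aln)
  eig <- eigendecompose(corr)
  b <- nullBoundaries(aln, seed = 10)
  sig <- selectSignificantPositions(eig, b, corr)
  asg <- clusterSectors(eig, sig, k = 3, seed = 10)
  p1 <- designMutations(asg, prof, refResidues(fam$map))
  p2 <- designMutations(asg, prof, refResidues(fam$map))
  expect_identical(singleMutants(p1), singleMutants(p2))
  expect_identical(doubleMutants(p1), doubleMutants(p2))
  s <- singleMutants(p1)
  expect_true(all(s$candidate != s$wild_type))
  expect_true(all(s$candidate != "-"))
  expect_true(all(s$theta > p1@siteThreshold))
})
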