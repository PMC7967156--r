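# Small in-code fixtures shared across test files.

msaFromStrings <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("s", seq_along(seqs))
  proteinMSA(seqs)
}

# random aligned family with optional gaps, closed alphabet
randomMSA <- function(m, n, gapFraction = 0, seed = 1) {
  aa <- residueAlphabet()[1:20]
  withr::with_seed(seed, {
    mat <- matrix(sample(aa, m * n, replace = TRUE), m, n)
    if (gapFraction > 0)
      mat[matrix(runif(m * n) < gapFraction, m, n)] <- "-"
    rownames(mat) <- paste0("s", seq_len(m))
    proteinMSA(setNames(apply(mat, 1, paste, collapse = ""),
                        rownames(mat)))
  })
}

# strip the reference row the way the pipeline does
dropReference <- function(aln, refId = "REF") {
  keep <- setdiff(sequenceIDs(aln), refId)
  new("ProteinMSA",
      residues = residueMatrix(aln)[keep, , drop = FALSE],
      sourceColumns = aln@sourceColumns)
}

# independent brute-force RCA oracle: plain double loops, no shared code
# with the package internals beyond the score lookup rules
oracleRCA <- function(aln, gapVsResidue = -8, gapVsGap = 0) {
  m <- residueMatrix(aln)
  M <- nrow(m); N <- ncol(m)
  blos <- thermosector:::BLOSUM50_AA
  score <- function(a, b) {
    ga <- a == "-"; gb <- b == "-"
    if (ga && gb) return(gapVsGap)
    if (ga || gb) return(gapVsResidue)
    blos[a, b]
  }
  pairs <- utils::combn(M, 2)
  X <- matrix(0, ncol(pairs), N)
  for (p in seq_len(ncol(pairs)))
    for (j in seq_len(N))
      X[p, j] <- score(m[pairs[1, p], j], m[pairs[2, p], j])
  r <- matrix(0, N, N)
  sdev <- apply(X, 2, function(x) sqrt(mean((x - mean(x))^2)))
  for (i in seq_len(N))
    for (j in seq_len(N)) {
      if (sdev[i] == 0 || sdev[j] == 0) next
      r[i, j] <- mean((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))) /
        (sdev[i] * sdev[j])
    }
  diag(r)[sdev > 0] <- 1
  r
}
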