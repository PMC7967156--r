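## Residue correlation analysis (RCA): Pearson correlation, over all
## unordered sequence pairs, of BLOSUM-scored substitution events at two
## positions, followed by eigen-decomposition of the resulting matrix.

## Shared post-processing: assemble a CorrelationMatrix from the pairwise
## second-moment pieces, zeroing degenerate positions.
buildCorrelation <- function(r, ssq, tol = 1e-8) {
  degenerate <- ssq <= tol
  r[degenerate, ] <- 0
  r[, degenerate] <- 0
  diag(r)[!degenerate] <- 1
  r <- (r + t(r)) / 2
  r <- clamp(r, -1, 1)
  new("CorrelationMatrix", r = r, degenerate = degenerate)
}

#' RCA matrix by explicit pair enumeration
#'
#' Reference implementation: enumerates all M(M-1)/2 unordered sequence
#' pairs, scores the substitution event at every position, and computes
#' the Pearson correlation (population normalization over the pair count)
#' between positions. Quadratic in M; intended as the oracle for
#' [rcaMatrix()] and for small alignments.
#'
#' @param aln a [ProteinMSA-class] with at least 3 sequences.
#' @param model a [SubstitutionModel-class].
#' @return A [CorrelationMatrix-class].
#' @export
rcaMatrixBruteforce <- function(aln, model = substitutionModel()) {
  m <- nSequences(aln)
  if (m < 3L) stop("RCA needs at least 3 sequences, got ", m)
  codes <- encodeResidues(residueMatrix(aln))
  s <- scoreMatrix(model)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)  # k < l
  np <- nrow(pairs)
  n <- nPositions(aln)
  x <- matrix(0, np, n)
  for (j in seq_len(n)) {
    cj <- codes[, j]
    x[, j] <- s[cbind(cj[pairs[, 1]], cj[pairs[, 2]])]
  }
  xc <- sweep(x, 2, colMeans(x))
  ssq <- colSums(xc^2)
  ssq[ssq <= 1e-6 * np] <- 0
  denom <- sqrt(outer(ssq, ssq))
  r <- crossprod(xc)
  nz <- denom > 0
  r[nz] <- r[nz] / denom[nz]
  r[!nz] <- 0
  buildCorrelation(r, ssq)
}

#' RCA matrix (count-collapsed computation)
#'
#' Identical to [rcaMatrixBruteforce()] within 1e-9 per entry, but
#' collapses the sum over sequence pairs into sums over joint symbol-pair
#' counts: for positions i and j, the 21 x 21 contingency table C of
#' (symbol at i, symbol at j) across sequences gives the ordered-pair
#' score sum as `sum(C * (S %*% C %*% S))`, from which self-pairs are
#' subtracted and the unordered-pair Pearson correlation is formed.
#' Cost O(N^2 (M + A^3)) instead of O(N^2 M^2).
#'
#' @inheritParams rcaMatrixBruteforce
#' @return A [CorrelationMatrix-class].
#' @export
rcaMatrix <- function(aln, model = substitutionModel()) {
  m <- nSequences(aln)
  if (m < 3L) stop("RCA needs at least 3 sequences, got ", m)
  codes <- encodeResidues(residueMatrix(aln))
  s <- scoreMatrix(model)
  s2 <- s * s
  ds <- diag(s)
  n <- nPositions(aln)
  np <- m * (m - 1) / 2

  ## per-position count vectors and moment sums over unordered pairs
  cnt <- t(apply(codes, 2, tabulate, nbins = 21L))   # N x 21
  sum1 <- numeric(n); sum2 <- numeric(n)
  for (i in seq_len(n)) {
    ni <- cnt[i, ]
    self1 <- sum(ni * ds)
    self2 <- sum(ni * ds^2)
    sum1[i] <- (drop(ni %*% s %*% ni) - self1) / 2
    sum2[i] <- (drop(ni %*% s2 %*% ni) - self2) / 2
  }
  mu <- sum1 / np
  ssq <- sum2 - np * mu^2
  ## integer scores: a genuinely variable column has pair-score sum of
  ## squares >= O(1), so anything at rounding scale is exact degeneracy
  ssq[ssq <= 1e-6 * np] <- 0

  r <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    ci <- codes[, i]
    for (j in seq((i + 1L), n)) {
      idx <- ci + 21L * (codes[, j] - 1L)
      cij <- matrix(tabulate(idx, nbins = 441L), 21L, 21L)
      selfCross <- drop(ds %*% cij %*% ds)
      cross <- (sum(cij * (s %*% cij %*% s)) - selfCross) / 2
      cov <- cross - np * mu[i] * mu[j]
      den <- sqrt(ssq[i] * ssq[j])
      r[i, j] <- r[j, i] <- if (den > 0) cov / den else 0
    }
  }
  buildCorrelation(r, ssq)
}

#' Eigen-decomposition of an RCA matrix
#'
#' Eigenvalues in descending order; each eigenvector's sign is fixed so
#' that its largest-magnitude component is positive, making downstream
#' boundaries and clustering reproducible (eigenvector sign is otherwise
#' arbitrary).
#'
#' @param corr a [CorrelationMatrix-class] (or plain symmetric matrix).
#' @param selectedModes 1-based mode indices carried for downstream
#'   analysis (default 2:4; mode 1 is treated as phylogenetic noise).
#' @return An [EigenSystem-class].
#' @export
eigendecompose <- function(corr, selectedModes = 2:4) {
  r <- if (is(corr, "CorrelationMatrix")) correlations(corr) else corr
  if (max(abs(r - t(r))) > 1e-8)
    stop("matrix is not symmetric within 1e-8")
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  v <- e$vectors
  for (k in seq_len(ncol(v))) {
    i0 <- which.max(abs(v[, k]))
    if (v[i0, k] < 0) v[, k] <- -v[, k]
  }
  n <- length(e$values)
  selectedModes <- as.integer(selectedModes)
  selectedModes <- selectedModes[selectedModes <= n]
  sys <- new("EigenSystem", values = e$values, vectors = v,
             selectedModes = selectedModes)
  recon <- v %*% (e$values * t(v))
  if (max(abs(recon - r)) > 1e-8)
    stop("eigen reconstruction exceeds 1e-8")
  sys
}

#' Low-rank mode approximation of the correlation matrix
#'
#' Returns `sum over k in modes of lambda_k v_k v_k^T`; with the default
#' modes 2-4 this is the noise-cleaned correlation matrix used for
#' sector identification.
#'
#' @param eig an [EigenSystem-class].
#' @param modes 1-based mode indices (default the system's selected
#'   modes).
#' @return N x N numeric matrix.
#' @export
modeApproximation <- function(eig, modes = selectedModes(eig)) {
  if (length(modes) == 0L) stop("empty mode list")
  modes <- as.integer(modes)
  if (any(modes < 1L | modes > length(eig@values)))
    stop("mode indices outside 1..", length(eig@values))
  v <- eig@vectors[, modes, drop = FALSE]
  v %*% (eig@values[modes] * t(v))
}
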