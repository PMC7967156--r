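## Relative-entropy vectors of the thermophilic and mesophilic
## sub-alignments and the divergence angle theta between them.

#' Background symbol frequencies of the trimmed MSA
#'
#' The gap component is the overall gap fraction of the alignment; the 20
#' amino-acid components are their frequencies among non-gap cells scaled
#' by (1 - gap fraction). All 21 entries are floored at `qFloor` and
#' renormalized so no relative-entropy component can diverge.
#'
#' @param aln a projected [ProteinMSA-class].
#' @param qFloor flooring constant (default 1e-4).
#' @return A [BackgroundFrequencies-class].
#' @export
backgroundFrequencies <- function(aln, qFloor = 1e-4) {
  m <- residueMatrix(aln)
  isGap <- m == GAP_CHAR
  gapFrac <- mean(isGap)
  if (gapFrac >= 1) stop("alignment is all gaps")
  aaCounts <- tabulate(match(m[!isGap], AA20), nbins = 20L)
  q <- c(aaCounts / sum(aaCounts) * (1 - gapFrac), gapFrac)
  names(q) <- ALPHABET21
  q <- pmax(q, qFloor)
  q <- q / sum(q)
  new("BackgroundFrequencies", q = q, qFloor = qFloor,
      rawGapFraction = gapFrac)
}

#' Relative-entropy vector of a frequency profile
#'
#' Componentwise binary Kullback-Leibler divergence (natural log) of the
#' observed frequency f against the background q:
#' `D = f log(f/q) + (1-f) log((1-f)/(1-q))`, with 0 log 0 = 0. This is
#' the large-M form of the log-binomial surprise of observing f at a
#' position whose symbols are drawn from q; unlike the exact form it does
#' not scale with the sub-alignment size, so thermophilic and mesophilic
#' profiles of very different depth remain comparable.
#'
#' @param freqs a [FrequencyProfile-class] or a named 21-vector.
#' @param q a [BackgroundFrequencies-class] or a named 21-vector.
#' @param exact if TRUE, return the exact per-sequence log-binomial
#'   surprise `-(1/M) log P(Binom(M, q) = round(M f))` instead
#'   (comparison only; requires `support`).
#' @param support sub-alignment depth M, needed when `exact = TRUE`.
#' @return Non-negative numeric 21-vector.
#' @export
relativeEntropyVector <- function(freqs, q, exact = FALSE, support = NULL) {
  f <- if (is(freqs, "FrequencyProfile")) freqs@freqs else freqs
  qv <- if (is(q, "BackgroundFrequencies")) backgroundQ(q) else q
  stopifnot(length(f) == 21L, length(qv) == 21L)
  if (exact) {
    m <- if (!is.null(support)) support
         else if (is(freqs, "FrequencyProfile")) freqs@support
         else stop("exact form needs the sub-alignment size 'support'")
    return(-dbinom(round(f * m), m, qv, log = TRUE) / m)
  }
  d <- ifelse(f > 0, f * log(f / qv), 0) +
       ifelse(f < 1, (1 - f) * log((1 - f) / (1 - qv)), 0)
  pmax(d, 0)
}

#' Relative-entropy angle between two divergence vectors
#'
#' `theta = acos(Dt . Dm / (|Dt| |Dm|))`, clamped into [0, pi/2]. A
#' zero-norm vector (profile exactly at background) yields theta = 0:
#' such positions carry no divergence evidence and must not rank as
#' design candidates.
#'
#' @param dThermo,dMeso non-negative 21-vectors.
#' @return Angle in radians, in [0, pi/2].
#' @export
entropyAngle <- function(dThermo, dMeso) {
  if (identical(unname(dThermo), unname(dMeso))) return(0)  # exact zero
  nt <- sqrt(sum(dThermo^2)); nm <- sqrt(sum(dMeso^2))
  if (nt == 0 || nm == 0) return(0)
  acos(clamp(sum(dThermo * dMeso) / (nt * nm), -1, 1))
}

#' Thermophile/mesophile divergence profile of an alignment
#'
#' For every reference position: frequency profiles of the thermophilic
#' and mesophilic sub-alignments, relative-entropy vectors against the
#' shared background of the full MSA (unknown-label sequences count
#' toward the background but toward neither profile), and the angle
#' theta between the two vectors.
#'
#' @param aln projected [ProteinMSA-class].
#' @param labels a [LabelTable-class].
#' @param map optional [ReferenceMap-class]; default treats columns as
#'   positions 1..N.
#' @param background optional [BackgroundFrequencies-class]; computed
#'   from `aln` when NULL. A fixed literature table can be supplied here.
#' @param qFloor background flooring constant (default 1e-4).
#' @param minSubsetSize minimum labeled sequences per class (default 5).
#' @return An [EntropyProfiles-class].
#' @export
thetaProfile <- function(aln, labels, map = NULL, background = NULL,
                         qFloor = 1e-4, minSubsetSize = 5L) {
  thermo <- subsetByLabel(aln, labels, "thermophilic", minSubsetSize)
  meso <- subsetByLabel(aln, labels, "mesophilic", minSubsetSize)
  if (is.null(background)) background <- backgroundFrequencies(aln, qFloor)
  q <- backgroundQ(background)
  ft <- frequencyMatrix(thermo)
  fm <- frequencyMatrix(meso)
  n <- nPositions(aln)
  dt <- matrix(0, n, 21L, dimnames = list(NULL, ALPHABET21))
  dm <- dt
  theta <- numeric(n)
  for (i in seq_len(n)) {
    dt[i, ] <- relativeEntropyVector(ft[i, ], q)
    dm[i, ] <- relativeEntropyVector(fm[i, ], q)
    theta[i] <- entropyAngle(dt[i, ], dm[i, ])
  }
  positions <- if (is.null(map)) seq_len(n) else map@refPositions
  new("EntropyProfiles", positions = as.integer(positions), theta = theta,
      Dthermo = dt, Dmeso = dm, freqThermo = ft, freqMeso = fm,
      supportThermo = rep(nSequences(thermo), n),
      supportMeso = rep(nSequences(meso), n),
      background = q)
}

#' Mean divergence angle over a position subset
#'
#' @param profiles an [EntropyProfiles-class].
#' @param positions non-empty set of reference positions.
#' @return Arithmetic mean of theta over the subset.
#' @export
meanTheta <- function(profiles, positions) {
  if (length(positions) == 0L) stop("empty position set")
  idx <- match(positions, profiles@positions)
  if (anyNA(idx))
    stop("positions not in the profile: ",
         paste(positions[is.na(idx)], collapse = ", "))
  mean(profiles@theta[idx])
}
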