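#' ProteinMSA: an aligned protein family
#'
#' Holds an M x C residue matrix over the closed 21-symbol alphabet
#' (20 amino acids + gap), with unique sequence identifiers as row names
#' and the original source-column indices as an integer vector (so that a
#' projected alignment remembers which columns of the parent MSA it kept).
#'
#' @slot residues character matrix, M x C, symbols in `residueAlphabet()`,
#'   rownames are unique sequence ids.
#' @slot sourceColumns integer vector of length C; original column indices.
#' @export
setClass("ProteinMSA",
  representation(residues = "matrix", sourceColumns = "integer"))

setValidity("ProteinMSA", function(object) {
  m <- object@residues
  if (!is.character(m)) return("residues must be a character matrix")
  if (nrow(m) < 2L) return("an alignment needs at least 2 sequences")
  if (ncol(m) < 1L) return("an alignment needs at least 1 column")
  ids <- rownames(m)
  if (is.null(ids) || anyDuplicated(ids))
    return("sequence ids must be present and unique")
  if (!all(m %in% ALPHABET21))
    return("residue symbols outside the 21-letter alphabet")
  if (length(object@sourceColumns) != ncol(m))
    return("sourceColumns length must equal the number of columns")
  TRUE
})

#' ReferenceMap: reference-position to alignment-column mapping
#'
#' Produced by [projectToReference()]. Position numbering is 1-based over
#' the ungapped reference sequence, so positions match the residue names
#' used in mutation nomenclature (e.g. R206).
#'
#' @slot referenceId id of the reference sequence.
#' @slot refPositions strictly increasing 1-based reference positions.
#' @slot columnOfPosition integer; alignment column for each reference
#'   position (names are the positions).
#' @slot refResidues reference amino acid at each position.
#' @export
setClass("ReferenceMap",
  representation(referenceId = "character", refPositions = "integer",
                 columnOfPosition = "integer", refResidues = "character"))

setValidity("ReferenceMap", function(object) {
  p <- object@refPositions
  if (length(p) < 1L) return("empty reference map")
  if (any(diff(p) <= 0L)) return("refPositions must be strictly increasing")
  if (length(object@columnOfPosition) != length(p))
    return("columnOfPosition must pair with refPositions")
  if (anyDuplicated(object@columnOfPosition))
    return("columnOfPosition must be injective")
  if (length(object@refResidues) != length(p))
    return("refResidues must pair with refPositions")
  TRUE
})

#' LabelTable: thermal-class labels for alignment sequences
#'
#' Maps each sequence id to one of `thermophilic`, `mesophilic`, `unknown`.
#'
#' @slot labels named factor with levels thermophilic/mesophilic/unknown.
#' @export
setClass("LabelTable", representation(labels = "factor"))

THERMAL_LEVELS <- c("thermophilic", "mesophilic", "unknown")

setValidity("LabelTable", function(object) {
  l <- object@labels
  if (!identical(levels(l), THERMAL_LEVELS))
    return("labels must have levels thermophilic, mesophilic, unknown")
  if (is.null(names(l)) || anyDuplicated(names(l)))
    return("labels must be named by unique sequence ids")
  if (anyNA(l)) return("labels must not contain NA")
  TRUE
})

#' FrequencyProfile: per-position symbol frequencies
#'
#' @slot position 1-based reference position.
#' @slot freqs named 21-vector of symbol fractions (20 aa + gap), sums to 1.
#' @slot support number of sequences counted.
#' @export
setClass("FrequencyProfile",
  representation(position = "integer", freqs = "numeric", support = "integer"))

setValidity("FrequencyProfile", function(object) {
  f <- object@freqs
  if (length(f) != 21L || !identical(names(f), ALPHABET21))
    return("freqs must be a named 21-vector over the alphabet")
  if (any(f < 0)) return("frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) return("frequencies must sum to 1")
  TRUE
})

#' SubstitutionModel: substitution-event scoring rules
#'
#' BLOSUM50 scores between amino acids, a fixed score for a residue
#' aligned to a gap (default -8) and for two gaps (default 0).
#'
#' @slot aaScores symmetric 20 x 20 integer matrix (BLOSUM50).
#' @slot gapVsResidue integer score for exactly one gap.
#' @slot gapVsGap integer score for two gaps.
#' @export
setClass("SubstitutionModel",
  representation(aaScores = "matrix", gapVsResidue = "integer",
                 gapVsGap = "integer"))

setValidity("SubstitutionModel", function(object) {
  s <- object@aaScores
  if (!identical(dim(s), c(20L, 20L))) return("aaScores must be 20 x 20")
  if (!identical(rownames(s), AA20) || !identical(colnames(s), AA20))
    return("aaScores must be named by the 20 amino acids")
  if (!isTRUE(all.equal(s, t(s)))) return("aaScores must be symmetric")
  TRUE
})

#' CorrelationMatrix: residue correlation analysis (RCA) matrix
#'
#' Pearson correlations, over all unordered sequence pairs, of
#' BLOSUM-scored substitution events between pairs of alignment positions.
#' Degenerate positions (zero substitution-score variance) are flagged and
#' their rows/columns zeroed, diagonal included.
#'
#' @slot r symmetric N x N numeric matrix.
#' @slot degenerate logical mask of degenerate positions.
#' @export
setClass("CorrelationMatrix",
  representation(r = "matrix", degenerate = "logical"))

setValidity("CorrelationMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("r must be square")
  if (length(object@degenerate) != nrow(r))
    return("degenerate mask must match matrix size")
  if (max(abs(r - t(r))) > 1e-12) return("r must be symmetric")
  if (any(abs(r) > 1 + 1e-9)) return("|r| must not exceed 1")
  d <- object@degenerate
  if (any(r[d, , drop = FALSE] != 0)) return("degenerate rows must be zero")
  if (nrow(r) > 0 && any(abs(diag(r)[!d] - 1) > 1e-12))
    return("diagonal must be 1 at non-degenerate positions")
  TRUE
})

#' EigenSystem: eigen-decomposition of an RCA matrix
#'
#' Eigenvalues in descending order with sign-fixed unit eigenvectors
#' (largest-magnitude component positive). Mode indexing is 1-based:
#' mode 1 carries the phylogenetic ("historical") signal and is excluded
#' from sector analysis by default; modes 2-4 are the default signal modes.
#'
#' @slot values numeric, descending eigenvalues.
#' @slot vectors N x N matrix, column k is the mode-k eigenvector.
#' @slot selectedModes integer, 1-based mode indices used downstream.
#' @export
setClass("EigenSystem",
  representation(values = "numeric", vectors = "matrix",
                 selectedModes = "integer"))

setValidity("EigenSystem", function(object) {
  v <- object@values
  if (any(diff(v) > 1e-12)) return("eigenvalues must be descending")
  if (ncol(object@vectors) != length(v))
    return("one eigenvector per eigenvalue required")
  nrm <- sqrt(colSums(object@vectors^2))
  if (any(abs(nrm - 1) > 1e-8)) return("eigenvectors must be unit norm")
  if (any(object@selectedModes < 1L) ||
      any(object@selectedModes > length(v)))
    return("selectedModes out of range")
  TRUE
})

#' NullBoundaries: significance boundaries from the column-shuffling null
#'
#' Per selected mode, the mean/std of eigenvector components pooled over
#' shuffling trials and the resulting cutoff `nSigma * sigma` on the
#' centered absolute component.
#'
#' @slot perMode data.frame with columns mode, mu, sigma, cutoff.
#' @slot nTrials number of shuffling trials pooled.
#' @slot nSigma cutoff multiplier.
#' @slot seed RNG seed used for the trials.
#' @export
setClass("NullBoundaries",
  representation(perMode = "data.frame", nTrials = "integer",
                 nSigma = "numeric", seed = "integer"))

setValidity("NullBoundaries", function(object) {
  pm <- object@perMode
  need <- c("mode", "mu", "sigma", "cutoff")
  if (!all(need %in% names(pm))) return("perMode must have mode/mu/sigma/cutoff")
  if (any(pm$sigma <= 0)) return("sigma must be positive")
  if (any(abs(pm$cutoff - object@nSigma * pm$sigma) > 1e-12))
    return("cutoff must equal nSigma * sigma")
  TRUE
})

#' SectorAssignment: protein sectors in eigenvector mode space
#'
#' Significant positions clustered by k-means on their selected-mode
#' eigenvector coordinates; remaining positions are background. Sector ids
#' are relabeled deterministically by descending size (ties by smallest
#' member position).
#'
#' @slot sectorOf integer vector over all positions; NA means background.
#' @slot k number of sectors.
#' @slot coordinates N x (number of modes) matrix of mode components.
#' @slot modes 1-based mode indices the coordinates come from.
#' @slot meanTheta per-sector mean relative-entropy angle (filled by the
#'   design stage; may be empty).
#' @slot contiguity per-sector median gap between consecutive member
#'   positions (1 = perfectly contiguous; NA for singletons).
#' @export
setClass("SectorAssignment",
  representation(sectorOf = "integer", k = "integer", coordinates = "matrix",
                 modes = "integer", meanTheta = "numeric",
                 contiguity = "numeric"))

setValidity("SectorAssignment", function(object) {
  s <- object@sectorOf
  k <- object@k
  mem <- s[!is.na(s)]
  if (length(mem) && (min(mem) < 1L || max(mem) > k))
    return("sector ids must lie in 1..k")
  if (length(mem) && length(unique(mem)) != k)
    return("all k sectors must be non-empty")
  if (nrow(object@coordinates) != length(s))
    return("coordinates must cover every position")
  TRUE
})

#' BackgroundFrequencies: family-wide background symbol frequencies
#'
#' The 21-vector q used in the relative-entropy computation: gap frequency
#' of the trimmed MSA as the gap component, amino-acid frequencies over
#' non-gap cells scaled by (1 - q_gap), floored at `qFloor` and
#' renormalized.
#'
#' @slot q named 21-vector, sums to 1.
#' @slot qFloor flooring constant.
#' @slot rawGapFraction gap fraction before flooring.
#' @export
setClass("BackgroundFrequencies",
  representation(q = "numeric", qFloor = "numeric", rawGapFraction = "numeric"))

setValidity("BackgroundFrequencies", function(object) {
  q <- object@q
  if (length(q) != 21L || !identical(names(q), ALPHABET21))
    return("q must be a named 21-vector over the alphabet")
  if (abs(sum(q) - 1) > 1e-9) return("q must sum to 1")
  ## flooring happens before renormalization, which can shrink entries by
  ## at most the total floored mass
  minAllowed <- object@qFloor / (1 + 21 * object@qFloor)
  if (any(q < minAllowed - 1e-15))
    return("q entries must be >= the renormalized floor")
  TRUE
})

#' EntropyProfiles: thermophile/mesophile divergence per position
#'
#' Per reference position: relative-entropy vectors of the thermophilic
#' and mesophilic sub-alignments against the shared background, the angle
#' theta between them, and the underlying per-class frequency profiles.
#'
#' @slot positions reference positions (1-based).
#' @slot theta relative-entropy angle per position, in [0, pi/2].
#' @slot Dthermo,Dmeso N x 21 relative-entropy component matrices.
#' @slot freqThermo,freqMeso N x 21 per-class frequency matrices.
#' @slot supportThermo,supportMeso sequence counts behind each profile.
#' @slot background the shared [BackgroundFrequencies] q vector.
#' @export
setClass("EntropyProfiles",
  representation(positions = "integer", theta = "numeric",
                 Dthermo = "matrix", Dmeso = "matrix",
                 freqThermo = "matrix", freqMeso = "matrix",
                 supportThermo = "integer", supportMeso = "integer",
                 background = "numeric"))

setValidity("EntropyProfiles", function(object) {
  n <- length(object@positions)
  if (length(object@theta) != n) return("theta must cover every position")
  if (any(object@theta < -1e-12 | object@theta > pi / 2 + 1e-12))
    return("theta must lie in [0, pi/2]")
  if (any(object@Dthermo < -1e-12) || any(object@Dmeso < -1e-12))
    return("relative-entropy components must be non-negative")
  if (nrow(object@Dthermo) != n || nrow(object@Dmeso) != n)
    return("D matrices must cover every position")
  TRUE
})

#' MutationPlan: ranked stabilizing mutation proposals
#'
#' Singles: one ranked replacement list per selected site, first choice
#' formatted as e.g. `R206F`. Doubles: the anchor single (highest-theta
#' site by default) paired with every other single.
#'
#' @slot targetSector sector id the sites were drawn from.
#' @slot siteThreshold theta threshold that gated the sites.
#' @slot singles data.frame of ranked candidates (all ranks, all sites).
#' @slot doubles data.frame of anchor/partner pairs.
#' @export
setClass("MutationPlan",
  representation(targetSector = "integer", siteThreshold = "numeric",
                 singles = "data.frame", doubles = "data.frame"))

setValidity("MutationPlan", function(object) {
  s <- object@singles
  if (nrow(s)) {
    if (any(s$candidate == s$wild_type))
      return("a proposed replacement equals the wild type")
    if (any(s$candidate == GAP_CHAR)) return("gap proposed as a replacement")
  }
  d <- object@doubles
  if (nrow(d) && anyDuplicated(d[, c("anchor", "partner")]))
    return("duplicate double-mutant pairs")
  TRUE
})

#' GeneratorConfig: synthetic family generator settings
#'
#' See [familyConfig()] for field semantics and defaults.
#'
#' @slot nThermo,nMeso,nUnknown sequence counts per thermal class.
#' @slot nPositions alignment width.
#' @slot sectorSpecs list of planted covarying groups
#'   (positions, nStates, concentration).
#' @slot divergentSites data.frame (position, thermoAA, mesoAA, weight).
#' @slot backgroundConcentration Dirichlet concentration of independent
#'   background columns.
#' @slot nClades,cladeBias global clade confounder: every sequence
#'   belongs to one of `nClades` clades whose preferred residue replaces
#'   the column draw with probability `cladeBias`, planting the
#'   phylogeny-like signal that dominates mode 1 in real families.
#' @slot gapRate per-cell gap probability.
#' @export
setClass("GeneratorConfig",
  representation(nThermo = "integer", nMeso = "integer", nUnknown = "integer",
                 nPositions = "integer", sectorSpecs = "list",
                 divergentSites = "data.frame",
                 backgroundConcentration = "numeric",
                 nClades = "integer", cladeBias = "numeric",
                 gapRate = "numeric"))

setValidity("GeneratorConfig", function(object) {
  allpos <- unlist(lapply(object@sectorSpecs, `[[`, "positions"))
  if (anyDuplicated(allpos)) return("sector position sets must be disjoint")
  if (length(allpos) && max(allpos) > object@nPositions)
    return("sector positions exceed nPositions")
  ds <- object@divergentSites
  if (nrow(ds)) {
    if (any(ds$weight <= 0 | ds$weight > 1))
      return("divergent-site weights must lie in (0, 1]")
    if (any(ds$position > object@nPositions))
      return("divergent-site positions exceed nPositions")
    if (anyDuplicated(ds$position)) return("duplicate divergent sites")
  }
  if (object@gapRate < 0 || object@gapRate >= 1)
    return("gapRate must lie in [0, 1)")
  if (object@nClades < 1L) return("nClades must be at least 1")
  if (object@cladeBias < 0 || object@cladeBias >= 1)
    return("cladeBias must lie in [0, 1)")
  TRUE
})
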