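## BLOSUM50 substitution scores, pinned in-source so scoring never depends
## on a runtime download. Row/column order is the package alphabet
## (alphabetical one-letter codes). Values are the published BLOSUM50
## matrix (Henikoff & Henikoff log-odds, half-bit scale).
BLOSUM50_AA <- matrix(c(
    5, -1, -2, -1, -3,  0, -2, -1, -1, -2, -1, -1, -1, -1, -2,  1,  0,  0, -3, -2,
   -1, 13, -4, -3, -2, -3, -3, -2, -3, -2, -2, -2, -4, -3, -4, -1, -1, -1, -5, -3,
   -2, -4,  8,  2, -5, -1, -1, -4, -1, -4, -4,  2, -1,  0, -2,  0, -1, -4, -5, -3,
   -1, -3,  2,  6, -3, -3,  0, -4,  1, -3, -2,  0, -1,  2,  0, -1, -1, -3, -3, -2,
   -3, -2, -5, -3,  8, -4, -1,  0, -4,  1,  0, -4, -4, -4, -3, -3, -2, -1,  1,  4,
    0, -3, -1, -3, -4,  8, -2, -4, -2, -4, -3,  0, -2, -2, -3,  0, -2, -4, -3, -3,
   -2, -3, -1,  0, -1, -2, 10, -4,  0, -3, -1,  1, -2,  1,  0, -1, -2, -4, -3,  2,
   -1, -2, -4, -4,  0, -4, -4,  5, -3,  2,  2, -3, -3, -3, -4, -3, -1,  4, -3, -1,
   -1, -3, -1,  1, -4, -2,  0, -3,  6, -3, -2,  0, -1,  2,  3,  0, -1, -3, -3, -2,
   -2, -2, -4, -3,  1, -4, -3,  2, -3,  5,  3, -4, -4, -2, -3, -3, -1,  1, -2, -1,
   -1, -2, -4, -2,  0, -3, -1,  2, -2,  3,  7, -2, -3,  0, -2, -2, -1,  1, -1,  0,
   -1, -2,  2,  0, -4,  0,  1, -3,  0, -4, -2,  7, -2,  0, -1,  1,  0, -3, -4, -2,
   -1, -4, -1, -1, -4, -2, -2, -3, -1, -4, -3, -2, 10, -1, -3, -1, -1, -3, -4, -3,
   -1, -3,  0,  2, -4, -2,  1, -3,  2, -2,  0,  0, -1,  7,  1,  0, -1, -3, -1, -1,
   -2, -4, -2,  0, -3, -3,  0, -4,  3, -3, -2, -1, -3,  1,  7, -1, -1, -3, -3, -1,
    1, -1,  0, -1, -3,  0, -1, -3,  0, -3, -2,  1, -1,  0, -1,  5,  2, -2, -4, -2,
    0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1,  0, -1, -1, -1,  2,  5,  0, -3, -2,
    0, -1, -4, -3, -1, -4, -4,  4, -3,  1,  1, -3, -3, -3, -3, -2,  0,  5, -3, -1,
   -3, -5, -5, -3,  1, -3, -3, -3, -3, -2, -1, -4, -4, -1, -3, -4, -3, -3, 15,  2,
   -2, -3, -3, -2,  4, -3,  2, -1, -2, -1,  0, -2, -3, -1, -1, -2, -2, -1,  2,  8),
  nrow = 20, byrow = TRUE, dimnames = list(AA20, AA20))
storage.mode(BLOSUM50_AA) <- "integer"

#' Substitution-event scoring model
#'
#' Scores the substitution event between the residues of two sequences at
#' one alignment position: BLOSUM50 between amino acids, a fixed gap
#' penalty when exactly one of the two is a gap (default -8), and zero
#' when both are gaps.
#'
#' @param gapVsResidue score for residue-vs-gap (default -8).
#' @param gapVsGap score for gap-vs-gap (default 0).
#' @return A [SubstitutionModel-class].
#' @export
#' @examples
#' m <- substitutionModel()
#' substitutionScore("A", "-", m)  # -8
substitutionModel <- function(gapVsResidue = -8L, gapVsGap = 0L) {
  new("SubstitutionModel", aaScores = BLOSUM50_AA,
      gapVsResidue = as.integer(gapVsResidue),
      gapVsGap = as.integer(gapVsGap))
}

## Full 21 x 21 score matrix including the gap row/column.
scoreMatrix <- function(model) {
  s <- matrix(model@gapVsResidue, 21L, 21L,
              dimnames = list(ALPHABET21, ALPHABET21))
  s[1:20, 1:20] <- model@aaScores
  s[21L, 21L] <- model@gapVsGap
  s
}

#' Score one substitution event
#'
#' @param a,b symbols from `residueAlphabet()`.
#' @param model a [SubstitutionModel-class].
#' @return Integer score.
#' @export
substitutionScore <- function(a, b, model = substitutionModel()) {
  s <- scoreMatrix(model)
  ia <- match(a, ALPHABET21); ib <- match(b, ALPHABET21)
  if (anyNA(ia) || anyNA(ib))
    stop("symbols outside the 21-letter alphabet: ",
         paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  s[cbind(ia, ib)]
}
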