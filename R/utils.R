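#' @importFrom methods new validObject is slot slotNames show setValidity
#' @importFrom stats kmeans median rgamma runif sd setNames dbinom
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

## 21-symbol alphabet: the 20 standard amino acids (alphabetical one-letter
## codes) plus the gap symbol, which is a first-class 21st state throughout.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"
ALPHABET21 <- c(AA20, GAP_CHAR)

## Ambiguity / non-standard codes normalized to gap at read time: they have
## no frequency slot in the 21-state model.
NONSTANDARD_AA <- c("B", "J", "Z", "X", "U", "O")

#' Alphabet used throughout the package
#'
#' Returns the closed residue alphabet: the 20 standard amino acids in
#' alphabetical one-letter-code order, followed by the gap symbol `"-"`.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' residueAlphabet()
residueAlphabet <- function() ALPHABET21

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so library calls never perturb user-level randomness.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## Integer codes 1..21 for a character matrix over ALPHABET21.
encodeResidues <- function(m) {
  codes <- match(m, ALPHABET21)
  if (anyNA(codes)) {
    bad <- unique(m[is.na(codes)])
    stop("symbols outside the 21-letter alphabet: ", paste(bad, collapse = ", "))
  }
  dim(codes) <- dim(m)
  codes
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
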