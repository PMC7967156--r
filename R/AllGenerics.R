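#' @name accessors
#' @title Accessors for thermosector classes
#' @param x an object.
#' @description Small accessor generics; user code should use these rather
#'   than reaching into slots.
NULL

#' @rdname accessors
#' @export
setGeneric("sequenceIDs", function(x) standardGeneric("sequenceIDs"))
#' @rdname accessors
#' @export
setGeneric("residueMatrix", function(x) standardGeneric("residueMatrix"))
#' @rdname accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname accessors
#' @export
setGeneric("nPositions", function(x) standardGeneric("nPositions"))
#' @rdname accessors
#' @export
setGeneric("refPositions", function(x) standardGeneric("refPositions"))
#' @rdname accessors
#' @export
setGeneric("refResidues", function(x) standardGeneric("refResidues"))
#' @rdname accessors
#' @export
setGeneric("thermalLabels", function(x) standardGeneric("thermalLabels"))
#' @rdname accessors
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))
#' @rdname accessors
#' @export
setGeneric("degeneratePositions",
           function(x) standardGeneric("degeneratePositions"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))
#' @rdname accessors
#' @export
setGeneric("selectedModes", function(x) standardGeneric("selectedModes"))
#' @rdname accessors
#' @export
setGeneric("sectorOf", function(x) standardGeneric("sectorOf"))
#' @rdname accessors
#' @export
setGeneric("sectorMembers", function(x) standardGeneric("sectorMembers"))
#' @rdname accessors
#' @export
setGeneric("thetaValues", function(x) standardGeneric("thetaValues"))
#' @rdname accessors
#' @export
setGeneric("backgroundQ", function(x) standardGeneric("backgroundQ"))
#' @rdname accessors
#' @export
setGeneric("singleMutants", function(x) standardGeneric("singleMutants"))
#' @rdname accessors
#' @export
setGeneric("doubleMutants", function(x) standardGeneric("doubleMutants"))

setMethod("sequenceIDs", "ProteinMSA", function(x) rownames(x@residues))
setMethod("residueMatrix", "ProteinMSA", function(x) x@residues)
setMethod("nSequences", "ProteinMSA", function(x) nrow(x@residues))
setMethod("nPositions", "ProteinMSA", function(x) ncol(x@residues))

setMethod("refPositions", "ReferenceMap", function(x) x@refPositions)
setMethod("refResidues", "ReferenceMap", function(x) x@refResidues)

setMethod("thermalLabels", "LabelTable", function(x) x@labels)

setMethod("correlations", "CorrelationMatrix", function(x) x@r)
setMethod("degeneratePositions", "CorrelationMatrix",
          function(x) which(x@degenerate))
setMethod("nPositions", "CorrelationMatrix", function(x) nrow(x@r))

setMethod("eigenValues", "EigenSystem", function(x) x@values)
setMethod("eigenVectors", "EigenSystem", function(x) x@vectors)
setMethod("selectedModes", "EigenSystem", function(x) x@selectedModes)
setMethod("nPositions", "EigenSystem", function(x) length(x@values))

setMethod("sectorOf", "SectorAssignment", function(x) x@sectorOf)
setMethod("sectorMembers", "SectorAssignment", function(x) {
  s <- x@sectorOf
  lapply(setNames(seq_len(x@k), paste0("sector", seq_len(x@k))),
         function(k) which(!is.na(s) & s == k))
})

setMethod("thetaValues", "EntropyProfiles",
          function(x) setNames(x@theta, x@positions))
setMethod("nPositions", "EntropyProfiles", function(x) length(x@positions))
setMethod("backgroundQ", "BackgroundFrequencies", function(x) x@q)

setMethod("singleMutants", "MutationPlan", function(x) x@singles)
setMethod("doubleMutants", "MutationPlan", function(x) x@doubles)

setMethod("show", "ProteinMSA", function(object) {
  cat("ProteinMSA:", nSequences(object), "sequences x",
      nPositions(object), "columns\n")
  gf <- mean(object@residues == GAP_CHAR)
  cat(sprintf("  gap fraction %.3f\n", gf))
})

setMethod("show", "ReferenceMap", function(object) {
  cat("ReferenceMap onto", object@referenceId, ":",
      length(object@refPositions), "reference positions\n")
})

setMethod("show", "LabelTable", function(object) {
  tb <- table(object@labels)
  cat("LabelTable:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix (RCA):", nrow(object@r), "x", ncol(object@r),
      "|", sum(object@degenerate), "degenerate position(s)\n")
})

setMethod("show", "EigenSystem", function(object) {
  v <- object@values
  cat("EigenSystem:", length(v), "modes; top eigenvalues",
      paste(sprintf("%.3f", head(v, 4)), collapse = ", "),
      "| selected modes", paste(object@selectedModes, collapse = ","), "\n")
})

setMethod("show", "SectorAssignment", function(object) {
  sizes <- vapply(sectorMembers(object), length, integer(1))
  cat("SectorAssignment:", object@k, "sectors (sizes",
      paste(sizes, collapse = ", "), ");",
      sum(is.na(object@sectorOf)), "background position(s)\n")
})

setMethod("show", "EntropyProfiles", function(object) {
  cat("EntropyProfiles:", length(object@positions), "positions;",
      sprintf("theta range [%.3f, %.3f]; support thermo=%d meso=%d\n",
              min(object@theta), max(object@theta),
              object@supportThermo[1], object@supportMeso[1]))
})

setMethod("show", "MutationPlan", function(object) {
  firsts <- object@singles[object@singles$rank == 1L, , drop = FALSE]
  cat("MutationPlan: target sector", object@targetSector,
      "| theta >", object@siteThreshold, "\n")
  if (nrow(firsts))
    cat("  singles:", paste(firsts$mutation, collapse = ", "), "\n")
  if (nrow(object@doubles))
    cat("  doubles:", paste(paste0(object@doubles$anchor, "/",
                                   object@doubles$partner), collapse = ", "),
        "\n")
})
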