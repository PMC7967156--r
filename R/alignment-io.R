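## Alignment input, validation, reference projection and labeling.

#' Construct a ProteinMSA from character sequences
#'
#' Normalizes case, maps `.` to the gap symbol and the ambiguity codes
#' B, J, Z, X, U, O to gap (with a warning giving counts), then validates
#' the closed alphabet.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param sourceColumns original column indices (default `1:C`).
#' @return A [ProteinMSA-class] object.
#' @export
#' @examples
#' proteinMSA(c(s1 = "AC-D", s2 = "ACDD", s3 = "A-DD"))
proteinMSA <- function(seqs, sourceColumns = NULL) {
  if (length(seqs) == 0L) stop("no sequences given")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique names")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1]][1]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(seqs[[bad]]), " but '", ids[1], "' has length ", lens[1])
  }
  m <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE))),
              nrow = length(seqs), byrow = TRUE,
              dimnames = list(ids, NULL))
  m[m == "."] <- GAP_CHAR
  ns <- m %in% NONSTANDARD_AA
  if (any(ns)) {
    counts <- table(m[ns])
    warning("normalized non-standard residues to gap: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
    m[ns] <- GAP_CHAR
  }
  bad <- setdiff(unique(as.vector(m)), ALPHABET21)
  if (length(bad))
    stop("unrecognized residue symbols: ", paste(bad, collapse = ", "))
  if (is.null(sourceColumns)) sourceColumns <- seq_len(ncol(m))
  new("ProteinMSA", residues = m, sourceColumns = as.integer(sourceColumns))
}

#' Read a protein multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm. Symbols are uppercased; `-` and `.`
#' become the gap symbol; non-standard residues (B, J, Z, X, U, O) are
#' normalized to gap with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"fasta"` or `"stockholm"`.
#' @return A [ProteinMSA-class] object.
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sto", "stk", "stockholm")) "stockholm" else "fasta"
  }
  seqs <- switch(format,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      if (length(ss) == 0L) stop("empty alignment file: ", path)
      setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    },
    stockholm = readStockholm(path))
  proteinMSA(seqs)
}

## Minimal Stockholm 1.0 reader: concatenates multi-block sequence lines,
## ignores '#' annotation and the terminating '//'.
readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  seqs <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "#") || startsWith(ln, "//")) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1]
    seqs[id] <- paste0(if (id %in% names(seqs)) seqs[[id]] else "", parts[2])
  }
  if (length(seqs) == 0L) stop("no sequences in Stockholm file: ", path)
  seqs
}

#' Project an alignment onto its reference sequence
#'
#' Keeps exactly the columns where the reference row is non-gap and
#' numbers them 1..N in ungapped reference order, so downstream results
#' can be reported in the reference's residue numbering (S41, R206, ...).
#'
#' @param aln a [ProteinMSA-class].
#' @param referenceId id of the reference sequence in `aln`.
#' @return list with elements `alignment` (projected [ProteinMSA-class])
#'   and `map` (a [ReferenceMap-class]).
#' @export
projectToReference <- function(aln, referenceId) {
  m <- residueMatrix(aln)
  if (!referenceId %in% rownames(m))
    stop("reference id '", referenceId, "' not present in the alignment")
  refRow <- m[referenceId, ]
  keep <- which(refRow != GAP_CHAR)
  if (length(keep) == 0L)
    stop("reference row '", referenceId, "' is all gaps")
  proj <- new("ProteinMSA", residues = m[, keep, drop = FALSE],
              sourceColumns = aln@sourceColumns[keep])
  n <- length(keep)
  map <- new("ReferenceMap", referenceId = referenceId,
             refPositions = seq_len(n),
             columnOfPosition = setNames(seq_len(n), seq_len(n)),
             refResidues = unname(refRow[keep]))
  list(alignment = proj, map = map)
}

#' Build a label table in memory
#'
#' @param ids sequence ids.
#' @param labels thermal classes; `"unrecognized"` is accepted as a
#'   synonym of `"unknown"`. Case-insensitive.
#' @return A [LabelTable-class].
#' @export
labelTable <- function(ids, labels) {
  labels <- tolower(as.character(labels))
  labels[labels == "unrecognized"] <- "unknown"
  bad <- which(!labels %in% THERMAL_LEVELS)
  if (length(bad))
    stop("labels outside {thermophilic, mesophilic, unknown}: ",
         paste(unique(labels[bad]), collapse = ", "))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    agree <- vapply(dup, function(d)
      length(unique(labels[ids == d])) == 1L, logical(1))
    if (!all(agree))
      stop("conflicting labels for duplicated sequence_id(s): ",
           paste(dup[!agree], collapse = ", "))
    keep <- !duplicated(ids)
    ids <- ids[keep]; labels <- labels[keep]
  }
  new("LabelTable",
      labels = setNames(factor(labels, levels = THERMAL_LEVELS), ids))
}

#' Attach thermal-class labels to an alignment
#'
#' Reads a TSV with header columns `sequence_id` and `label`, validates
#' the closed label set, and defaults alignment sequences missing from
#' the table to `unknown` (with a warning).
#'
#' @param aln a [ProteinMSA-class].
#' @param table a file path to the TSV, or a data.frame with the same
#'   columns.
#' @return A [LabelTable-class] covering every alignment sequence.
#' @export
attachLabels <- function(aln, table) {
  if (is.character(table)) {
    df <- read.delim(table, header = TRUE, sep = "\t",
                     colClasses = "character")
  } else {
    df <- as.data.frame(table)
  }
  if (!all(c("sequence_id", "label") %in% names(df)))
    stop("label table must have columns sequence_id and label")
  labels <- tolower(trimws(df$label))
  labels[labels == "unrecognized"] <- "unknown"
  bad <- which(!labels %in% THERMAL_LEVELS)
  if (length(bad))
    stop("invalid label(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), ": ",
         paste(unique(labels[bad]), collapse = ", "))
  dup <- unique(df$sequence_id[duplicated(df$sequence_id)])
  if (length(dup)) {
    agree <- vapply(dup, function(d)
      length(unique(labels[df$sequence_id == d])) == 1L, logical(1))
    if (!all(agree))
      stop("conflicting labels for duplicated sequence_id(s): ",
           paste(dup[!agree], collapse = ", "))
  }
  lab <- setNames(labels, df$sequence_id)[!duplicated(df$sequence_id)]
  ids <- sequenceIDs(aln)
  missing <- setdiff(ids, names(lab))
  if (length(missing)) {
    warning(length(missing), " sequence(s) absent from the label table ",
            "defaulted to 'unknown': ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  }
  full <- setNames(rep("unknown", length(ids)), ids)
  known <- intersect(ids, names(lab))
  full[known] <- lab[known]
  new("LabelTable",
      labels = setNames(factor(full, levels = THERMAL_LEVELS), ids))
}

#' Row-subset an alignment by thermal class
#'
#' @param aln a [ProteinMSA-class].
#' @param labels a [LabelTable-class].
#' @param which one of `"thermophilic"`, `"mesophilic"`, `"unknown"`.
#' @param minSubsetSize minimum sequences required (default 5); below
#'   this, downstream entropy estimates are meaningless.
#' @return A [ProteinMSA-class] with the selected rows, columns untouched.
#' @export
subsetByLabel <- function(aln, labels, which = THERMAL_LEVELS,
                          minSubsetSize = 5L) {
  which <- match.arg(which)
  lab <- thermalLabels(labels)
  ids <- intersect(sequenceIDs(aln), names(lab)[lab == which])
  if (length(ids) < minSubsetSize)
    stop("only ", length(ids), " sequence(s) labeled '", which,
         "' but at least ", minSubsetSize, " are required")
  new("ProteinMSA",
      residues = residueMatrix(aln)[ids, , drop = FALSE],
      sourceColumns = aln@sourceColumns)
}

#' Per-position symbol frequencies
#'
#' Fractions of the 21 symbols (20 amino acids + gap) in the alignment
#' column of a reference position.
#'
#' @param aln a projected [ProteinMSA-class].
#' @param position 1-based reference position.
#' @param map the [ReferenceMap-class] from [projectToReference()]. When
#'   `NULL`, positions are taken as plain column indices.
#' @return A [FrequencyProfile-class].
#' @export
columnFrequencies <- function(aln, position, map = NULL) {
  col <- if (is.null(map)) position else {
    if (!position %in% map@refPositions)
      stop("position ", position, " not in the reference map")
    map@columnOfPosition[[as.character(position)]]
  }
  if (col < 1L || col > nPositions(aln))
    stop("position ", position, " outside the alignment")
  column <- residueMatrix(aln)[, col]
  counts <- tabulate(match(column, ALPHABET21), nbins = 21L)
  new("FrequencyProfile", position = as.integer(position),
      freqs = setNames(counts / length(column), ALPHABET21),
      support = length(column))
}

## Frequency matrix (N x 21) over all columns; shared by several modules.
frequencyMatrix <- function(aln) {
  codes <- encodeResidues(residueMatrix(aln))
  f <- t(apply(codes, 2, tabulate, nbins = 21L)) / nrow(codes)
  colnames(f) <- ALPHABET21
  f
}

#' Write an alignment as aligned FASTA
#'
#' @param aln a [ProteinMSA-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(aln, path) {
  seqs <- apply(residueMatrix(aln), 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(seqs, sequenceIDs(aln))), path)
  invisible(path)
}

#' Write a reference map as TSV
#'
#' Columns: ref_position, alignment_column, ref_residue.
#'
#' @param map a [ReferenceMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReferenceMap <- function(map, path) {
  df <- data.frame(ref_position = map@refPositions,
                   alignment_column = unname(map@columnOfPosition),
                   ref_residue = map@refResidues)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
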