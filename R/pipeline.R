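## End-to-end orchestration: project -> RCA -> eigen -> null boundaries ->
## significant positions -> sectors -> theta profile -> mutation plan,
## with TSV artifacts and a JSON run manifest.

#' Pipeline configuration
#'
#' All defaults are the method's shipped constants: BLOSUM50 scoring with
#' gap penalty -8 and gap-gap 0, signal modes 2-4, 10 shuffling trials
#' with a 2.39-sigma boundary (family-wise 5% Gaussian null retention
#' over 3 two-sided mode tests), k = 4 sectors, theta threshold 0.5, and
#' a background floor of 1e-4.
#'
#' @param msa path to the aligned FASTA/Stockholm MSA (or a
#'   [ProteinMSA-class]).
#' @param labels path to the label TSV (or a [LabelTable-class]).
#' @param referenceId id of the reference/target sequence.
#' @param gapPenalty residue-vs-gap substitution score.
#' @param gapGap gap-vs-gap substitution score.
#' @param modes 1-based signal modes.
#' @param nullTrials shuffling trials for the null.
#' @param nullSigma boundary multiplier.
#' @param k number of sectors.
#' @param thetaThreshold mutation-site gate.
#' @param qFloor background flooring constant.
#' @param minSubsetSize minimum labeled sequences per thermal class.
#' @param nRestarts k-means restarts.
#' @param weightModes eigenvalue-weight mode coordinates before
#'   clustering.
#' @param anchor anchor single for double mutants, or `"auto"`.
#' @param excludeReference drop the reference row from all statistics
#'   (default TRUE; it is a designated target, not a family observation).
#' @param seed RNG seed for the whole run.
#' @param outDir output directory.
#' @return Named list of settings.
#' @export
pipelineConfig <- function(msa, labels, referenceId,
                           gapPenalty = -8L, gapGap = 0L, modes = 2:4,
                           nullTrials = 10L, nullSigma = 2.39, k = 4L,
                           thetaThreshold = 0.5, qFloor = 1e-4,
                           minSubsetSize = 5L, nRestarts = 100L,
                           weightModes = FALSE, anchor = "auto",
                           excludeReference = TRUE, seed = 1L,
                           outDir = tempfile("thermosector_run")) {
  list(msa = msa, labels = labels, referenceId = referenceId,
       gapPenalty = gapPenalty, gapGap = gapGap, modes = modes,
       nullTrials = nullTrials, nullSigma = nullSigma, k = k,
       thetaThreshold = thetaThreshold, qFloor = qFloor,
       minSubsetSize = minSubsetSize, nRestarts = nRestarts,
       weightModes = weightModes, anchor = anchor,
       excludeReference = excludeReference, seed = seed, outDir = outDir)
}

writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stageCall <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full thermostability design pipeline
#'
#' Executes reference projection, RCA, eigen-decomposition, the
#' column-shuffling null with Gaussian boundaries, significance
#' selection, k-means sector clustering, the thermophile/mesophile
#' relative-entropy angle profile, target-sector selection and mutation
#' planning; writes every artifact plus a JSON manifest to the output
#' directory.
#'
#' @param config from [pipelineConfig()].
#' @return Invisibly, a list with all intermediate objects and
#'   `outDir`.
#' @export
runPipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  warningsSeen <- character(0)
  collectWarnings <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      warningsSeen <<- c(warningsSeen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  tic <- function(stage, expr) {
    st <- Sys.time()
    out <- stageCall(stage, collectWarnings(expr))
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    out
  }

  inputChecksums <- list()
  aln <- tic("read_alignment", {
    if (is.character(config$msa)) {
      inputChecksums$msa <- unname(tools::md5sum(config$msa))
      readAlignment(config$msa)
    } else config$msa
  })
  labels <- tic("attach_labels", {
    if (is.character(config$labels)) {
      inputChecksums$labels <- unname(tools::md5sum(config$labels))
      attachLabels(aln, config$labels)
    } else config$labels
  })

  proj <- tic("project_to_reference",
              projectToReference(aln, config$referenceId))
  projAln <- proj$alignment
  map <- proj$map

  ## the reference row is a designated target, not a family observation
  statAln <- if (config$excludeReference) {
    keep <- setdiff(sequenceIDs(projAln), config$referenceId)
    new("ProteinMSA",
        residues = residueMatrix(projAln)[keep, , drop = FALSE],
        sourceColumns = projAln@sourceColumns)
  } else projAln

  model <- substitutionModel(config$gapPenalty, config$gapGap)
  corr <- tic("rca_matrix", rcaMatrix(statAln, model))
  eig <- tic("eigendecompose",
             eigendecompose(corr, selectedModes = config$modes))
  bounds <- tic("null_boundaries",
                nullBoundaries(statAln, model, config$modes,
                               config$nullTrials, config$nullSigma,
                               seed = config$seed))
  sig <- tic("select_significant_positions",
             selectSignificantPositions(eig, bounds, corr))
  assignment <- tic("cluster_sectors",
                    clusterSectors(eig, sig, k = config$k,
                                   seed = config$seed,
                                   nRestarts = config$nRestarts,
                                   weightModes = config$weightModes))
  profiles <- tic("theta_profile",
                  thetaProfile(statAln, labels, map,
                               qFloor = config$qFloor,
                               minSubsetSize = config$minSubsetSize))
  plan <- tic("mutation_design",
              designMutations(assignment, profiles, refResidues(map),
                              thetaThreshold = config$thetaThreshold,
                              anchor = config$anchor))
  target <- selectTargetSector(assignment, profiles)
  assignment@meanTheta <- setNames(target$report$mean_theta,
                                   target$report$sector)

  od <- config$outDir
  pos <- map@refPositions
  rr <- refResidues(map)
  writeTSV(data.frame(ref_position = pos,
                      setNames(as.data.frame(correlations(corr)),
                               paste0("p", pos))),
           file.path(od, "correlation_matrix.tsv"))
  writeTSV(data.frame(mode = seq_along(eigenValues(eig)),
                      eigenvalue = eigenValues(eig)),
           file.path(od, "eigen_values.tsv"))
  writeTSV(data.frame(ref_position = pos,
                      setNames(as.data.frame(eigenVectors(eig)),
                               paste0("v", seq_along(pos)))),
           file.path(od, "eigen_vectors.tsv"))
  writeTSV(bounds@perMode, file.path(od, "null_boundaries.tsv"))
  sec <- sectorOf(assignment)
  writeTSV(data.frame(ref_position = pos, ref_residue = rr,
                      sector = ifelse(is.na(sec), "background", sec),
                      assignment@coordinates),
           file.path(od, "sectors.tsv"))
  topAA <- function(fm) AA20[apply(fm[, AA20, drop = FALSE], 1,
                                   which.max)]
  writeTSV(data.frame(ref_position = pos, ref_residue = rr,
                      theta = profiles@theta,
                      support_thermo = profiles@supportThermo,
                      support_meso = profiles@supportMeso,
                      top_thermo_aa = topAA(profiles@freqThermo),
                      top_meso_aa = topAA(profiles@freqMeso)),
           file.path(od, "theta.tsv"))
  writeTSV(singleMutants(plan),
           file.path(od, "mutation_plan_singles.tsv"))
  writeTSV(doubleMutants(plan),
           file.path(od, "mutation_plan_doubles.tsv"))

  firsts <- singleMutants(plan)
  firsts <- firsts[firsts$rank == 1L & nzchar(firsts$mutation), ,
                   drop = FALSE]
  summaryLines <- c(
    sprintf("thermosector run: %d sequences x %d positions",
            nSequences(statAln), nPositions(statAln)),
    sprintf("target sector: %d (mean theta %.4f)", plan@targetSector,
            target$report$mean_theta[plan@targetSector]),
    "sector report:",
    sprintf("  sector %d: size %d, mean theta %.4f, contiguity %s",
            target$report$sector, target$report$size,
            target$report$mean_theta,
            ifelse(is.na(target$report$contiguity), "NA",
                   sprintf("%.1f", target$report$contiguity))),
    sprintf("single mutants (theta > %.2f): %s", config$thetaThreshold,
            if (nrow(firsts)) paste(firsts$mutation, collapse = ", ")
            else "(none)"),
    sprintf("double mutants: %s",
            if (nrow(doubleMutants(plan)))
              paste(doubleMutants(plan)$combo, collapse = ", ")
            else "(none)"))
  writeLines(summaryLines, file.path(od, "summary.txt"))

  cfgOut <- config[setdiff(names(config), c("msa", "labels"))]
  cfgFile <- file.path(od, "config.txt")
  writeLines(paste(names(cfgOut),
                   vapply(cfgOut, function(x)
                     paste(format(x), collapse = ","), ""),
                   sep = "="), cfgFile)
  manifest <- list(
    tool = "thermosector",
    version = as.character(packageVersion("thermosector")),
    config = cfgOut,
    config_hash = unname(tools::md5sum(cfgFile)),
    input_checksums = inputChecksums,
    timings_sec = timings,
    warnings = warningsSeen,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(outDir = od, alignment = statAln, map = map,
                 labels = labels, model = model, correlation = corr,
                 eigen = eig, boundaries = bounds,
                 significant = sig, assignment = assignment,
                 profiles = profiles, plan = plan,
                 sectorReport = target$report,
                 elapsed = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))))
}

#' Diagnostic theta averages over named position subsets
#'
#' For each named subset (e.g. substrate-contact residues) reports the
#' mean relative-entropy angle and the sector composition.
#'
#' @param result output of [runPipeline()].
#' @param positionSubsets named list of reference-position vectors.
#' @return data.frame with one row per subset.
#' @export
runDiagnostics <- function(result, positionSubsets) {
  stopifnot(is.list(positionSubsets), length(positionSubsets) > 0L)
  profiles <- result$profiles
  assignment <- result$assignment
  rows <- lapply(names(positionSubsets), function(nm) {
    p <- positionSubsets[[nm]]
    unknown <- setdiff(p, profiles@positions)
    if (length(unknown))
      stop("unknown position(s) in subset '", nm, "': ",
           paste(unknown, collapse = ", "))
    sec <- sectorOf(assignment)[match(p, profiles@positions)]
    comp <- table(factor(ifelse(is.na(sec), "background", sec)))
    data.frame(subset = nm, n = length(p),
               mean_theta = meanTheta(profiles, p),
               sectors = paste(names(comp), comp, sep = ":",
                               collapse = ","))
  })
  do.call(rbind, rows)
}
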