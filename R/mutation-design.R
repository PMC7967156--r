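## Stability-sector selection, theta-gated site selection, and ranked
## replacement amino acids from the thermophilic profile.

## Fixed 5-class side-chain classification used for annotation only.
SIDECHAIN_CLASS <- c(
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
  I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
  W = "hydrophobic",
  S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
  C = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  G = "special", P = "special")

#' Select the stability-related target sector
#'
#' The sector with the largest mean relative-entropy angle theta over its
#' member positions. The report also lists each sector's primary-sequence
#' contiguity: sequence-contiguous sectors tend to carry domain/function
#' roles and a user may prefer to avoid them, but contiguity is advisory
#' and never applied automatically.
#'
#' @param assignment a [SectorAssignment-class].
#' @param profiles an [EntropyProfiles-class].
#' @return list with `sector` (the selected id) and `report` (data.frame
#'   sector / size / mean_theta / contiguity).
#' @export
selectTargetSector <- function(assignment, profiles) {
  members <- sectorMembers(assignment)
  if (length(members) == 0L) stop("no sectors")
  mt <- vapply(members, function(p) meanTheta(profiles, p), numeric(1))
  report <- data.frame(sector = seq_along(members),
                       size = vapply(members, length, integer(1)),
                       mean_theta = unname(mt),
                       contiguity = unname(sectorContiguity(assignment)))
  ord <- order(-report$mean_theta)
  best <- ord[1]
  if (length(ord) > 1L &&
      report$mean_theta[best] - report$mean_theta[ord[2]] <= 1e-12)
    stop("tie in mean theta between sectors ", best, " and ", ord[2],
         "; choose the target sector manually")
  list(sector = as.integer(best), report = report)
}

#' Select mutation sites in a sector by theta threshold
#'
#' Member positions with theta strictly above the threshold, sorted by
#' descending theta.
#'
#' @param assignment a [SectorAssignment-class].
#' @param profiles an [EntropyProfiles-class].
#' @param sector sector id.
#' @param threshold theta threshold (default 0.5).
#' @return Integer vector of positions (possibly empty, with a warning).
#' @export
selectMutationSites <- function(assignment, profiles, sector,
                                threshold = 0.5) {
  if (threshold < 0) stop("threshold must be non-negative")
  members <- sectorMembers(assignment)[[sector]]
  th <- thetaValues(profiles)[as.character(members)]
  keep <- members[th > threshold]
  if (length(keep) == 0L) {
    warning("no position in sector ", sector, " has theta > ", threshold)
    return(integer(0))
  }
  keep[order(-th[th > threshold])]
}

#' Ranked replacement amino acids for one site
#'
#' Candidates are the amino acids present in the thermophilic profile at
#' the position, ordered by descending thermophilic frequency (ties
#' alphabetical), excluding gap and the wild type. If the most frequent
#' thermophilic amino acid is also the most frequent mesophilic one (and
#' is not the wild type), it is demoted below the second-ranked candidate
#' (`rule_note = "shared-consensus demotion"`): a residue common to both
#' thermal classes carries no thermoadaptive signal. The full ranked list
#' is returned so that experimentally unsuccessful proposals can be
#' walked down to the next candidate.
#'
#' @param position reference position.
#' @param profiles an [EntropyProfiles-class] (holds the per-class
#'   frequency profiles).
#' @param wildType the reference residue at the position.
#' @return data.frame with columns ref_position, wild_type, theta, rank,
#'   candidate, thermo_freq, meso_freq, sidechain_change, rule_note
#'   (zero rows if no eligible candidate, with a warning).
#' @export
rankReplacements <- function(position, profiles, wildType) {
  idx <- match(position, profiles@positions)
  if (is.na(idx)) stop("position ", position, " not in the profiles")
  ft <- profiles@freqThermo[idx, AA20]
  fm <- profiles@freqMeso[idx, AA20]

  ## class consensus residues, gap excluded, ties alphabetical
  aaOrder <- function(f) AA20[order(-f, AA20)]
  topThermo <- aaOrder(ft)[1]
  topMeso <- aaOrder(fm)[1]

  cand <- aaOrder(ft)
  cand <- cand[ft[cand] > 0 & cand != wildType]
  if (length(cand) == 0L) {
    warning("no eligible replacement at position ", position,
            " (thermophilic column is all gap or wild type)")
    return(data.frame(ref_position = integer(0), wild_type = character(0),
                      theta = numeric(0), rank = integer(0),
                      candidate = character(0), thermo_freq = numeric(0),
                      meso_freq = numeric(0), sidechain_change = logical(0),
                      rule_note = character(0)))
  }
  note <- setNames(rep("", length(cand)), cand)
  if (topThermo == topMeso && topThermo != wildType &&
      cand[1] == topThermo && length(cand) > 1L) {
    cand <- c(cand[2], cand[1], cand[-(1:2)])
    note <- note[cand]
    note[2] <- "shared-consensus demotion"
  }
  data.frame(ref_position = as.integer(position), wild_type = wildType,
             theta = profiles@theta[idx], rank = seq_along(cand),
             candidate = cand, thermo_freq = unname(ft[cand]),
             meso_freq = unname(fm[cand]),
             sidechain_change =
               unname(SIDECHAIN_CLASS[cand] != SIDECHAIN_CLASS[wildType]),
             rule_note = unname(note), row.names = NULL)
}

#' Propose single mutants for a set of sites
#'
#' One ranked candidate list per site; the first choice defines the
#' mutation string `{wild type}{position}{candidate}` (e.g. `R206F`).
#'
#' @param sites positions from [selectMutationSites()].
#' @param profiles an [EntropyProfiles-class].
#' @param refResidues character vector of reference residues indexed by
#'   position (e.g. `refResidues(map)` of the projected alignment).
#' @return data.frame of all ranks for all sites, with a `mutation`
#'   column filled on rank-1 rows.
#' @export
proposeSingleMutants <- function(sites, profiles, refResidues) {
  template <- data.frame(ref_position = integer(0), wild_type = character(0),
                         theta = numeric(0), rank = integer(0),
                         candidate = character(0), thermo_freq = numeric(0),
                         meso_freq = numeric(0), sidechain_change = logical(0),
                         rule_note = character(0), mutation = character(0))
  if (length(sites) == 0L) return(template)
  rows <- lapply(sites, function(p)
    rankReplacements(p, profiles, refResidues[p]))
  singles <- do.call(rbind, rows)
  rownames(singles) <- NULL
  if (is.null(singles) || nrow(singles) == 0L) return(template)
  singles$mutation <- ifelse(
    singles$rank == 1L,
    paste0(singles$wild_type, singles$ref_position, singles$candidate),
    "")
  singles
}

#' Enumerate double mutants around an anchor single
#'
#' Pairs the anchor (by default the first-choice mutation at the
#' highest-theta site) with every other first-choice single.
#'
#' @param singles data.frame from [proposeSingleMutants()].
#' @param anchor a mutation string present among the rank-1 singles, or
#'   `"auto"`.
#' @return data.frame with columns anchor, partner, combo (zero rows
#'   with a warning when fewer than 2 singles exist).
#' @export
enumerateDoubleMutants <- function(singles, anchor = "auto") {
  firsts <- singles[singles$rank == 1L & nzchar(singles$mutation), ,
                    drop = FALSE]
  empty <- data.frame(anchor = character(0), partner = character(0),
                      combo = character(0))
  if (nrow(firsts) < 2L) {
    warning("fewer than 2 single mutants; no double mutants proposed")
    return(empty)
  }
  if (identical(anchor, "auto")) {
    anchor <- firsts$mutation[which.max(firsts$theta)]
  } else if (!anchor %in% firsts$mutation) {
    stop("anchor '", anchor, "' is not among the proposed singles")
  }
  partners <- setdiff(firsts$mutation, anchor)
  data.frame(anchor = anchor, partner = partners,
             combo = paste0(anchor, "/", partners))
}

#' Full mutation plan for an analyzed family
#'
#' Convenience wrapper: pick the target sector (largest mean theta),
#' gate its sites by the theta threshold, rank replacements, and
#' enumerate doubles around the auto anchor.
#'
#' @param assignment a [SectorAssignment-class].
#' @param profiles an [EntropyProfiles-class].
#' @param refResidues reference residues indexed by position.
#' @param thetaThreshold site gate (default 0.5).
#' @param anchor anchor mutation for doubles, or `"auto"`.
#' @return A [MutationPlan-class].
#' @export
designMutations <- function(assignment, profiles, refResidues,
                            thetaThreshold = 0.5, anchor = "auto") {
  target <- selectTargetSector(assignment, profiles)
  sites <- selectMutationSites(assignment, profiles, target$sector,
                               thetaThreshold)
  singles <- proposeSingleMutants(sites, profiles, refResidues)
  doubles <- if (sum(singles$rank == 1L & nzchar(singles$mutation)) >= 2L)
    enumerateDoubleMutants(singles, anchor) else
    data.frame(anchor = character(0), partner = character(0),
               combo = character(0))
  new("MutationPlan", targetSector = target$sector,
      siteThreshold = thetaThreshold, singles = singles, doubles = doubles)
}
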