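## Column-shuffling null, Gaussian significance boundaries, and k-means
## sector clustering in eigenvector mode space.

#' Independently shuffle every alignment column
#'
#' Destroys all between-position correlation while preserving each
#' column's symbol multiset (hence every frequency profile) exactly.
#'
#' @param aln a [ProteinMSA-class].
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return A [ProteinMSA-class] of the same shape.
#' @export
shuffleColumns <- function(aln, seed = NULL) {
  m <- residueMatrix(aln)
  withSeed(seed, {
    for (j in seq_len(ncol(m))) m[, j] <- m[sample(nrow(m)), j]
  })
  new("ProteinMSA", residues = m, sourceColumns = aln@sourceColumns)
}

#' Null distribution of eigenvector components under column shuffling
#'
#' For each of `nTrials` shuffles: recompute the RCA matrix,
#' eigendecompose, and collect the components of the selected-mode
#' eigenvectors. Samples are pooled across trials per mode
#' (N x nTrials values per mode).
#'
#' @param aln a [ProteinMSA-class].
#' @param model a [SubstitutionModel-class].
#' @param modes 1-based mode indices (default 2:4).
#' @param nTrials number of shuffling trials (default 10).
#' @param seed RNG seed; trial t uses `seed + t - 1`.
#' @return Named list (one element per mode) of pooled component samples.
#' @export
nullComponentDistribution <- function(aln, model = substitutionModel(),
                                      modes = 2:4, nTrials = 10L,
                                      seed = 1L) {
  if (nTrials < 1L) stop("nTrials must be at least 1")
  pooled <- setNames(vector("list", length(modes)), as.character(modes))
  for (t in seq_len(nTrials)) {
    shuf <- shuffleColumns(aln, seed = seed + t - 1L)
    eig <- eigendecompose(rcaMatrix(shuf, model), selectedModes = modes)
    for (k in seq_along(modes))
      pooled[[k]] <- c(pooled[[k]], eig@vectors[, modes[k]])
  }
  pooled
}

#' Gaussian fit of pooled null components
#'
#' Maximum-likelihood normal fit (sample mean, population standard
#' deviation); the boundary is `nSigma * sigma` on the centered absolute
#' component.
#'
#' @param samples numeric vector (at least 20 values).
#' @param nSigma cutoff multiplier (default 2.39, the Gaussian
#'   quantile giving a family-wise 5% null retention over 3 two-sided
#'   mode tests).
#' @return list with `mu`, `sigma`, `cutoff`.
#' @export
fitGaussianBoundary <- function(samples, nSigma = 2.39) {
  if (length(samples) < 20L)
    stop("need at least 20 samples for a Gaussian fit, got ",
         length(samples))
  mu <- mean(samples)
  sigma <- sqrt(mean((samples - mu)^2))
  if (sigma <= 0)
    stop("degenerate null: all samples identical")
  list(mu = mu, sigma = sigma, cutoff = nSigma * sigma)
}

#' Significance boundaries from the shuffling null
#'
#' Convenience wrapper: pools null eigenvector components per mode
#' ([nullComponentDistribution()]) and fits the Gaussian boundary to
#' each ([fitGaussianBoundary()]).
#'
#' @inheritParams nullComponentDistribution
#' @param nSigma cutoff multiplier (default 2.39; see
#'   [fitGaussianBoundary()]).
#' @return A [NullBoundaries-class].
#' @export
nullBoundaries <- function(aln, model = substitutionModel(), modes = 2:4,
                           nTrials = 10L, nSigma = 2.39, seed = 1L) {
  pooled <- nullComponentDistribution(aln, model, modes, nTrials, seed)
  fits <- lapply(pooled, fitGaussianBoundary, nSigma = nSigma)
  perMode <- data.frame(mode = as.integer(names(pooled)),
                        mu = vapply(fits, `[[`, 0, "mu"),
                        sigma = vapply(fits, `[[`, 0, "sigma"),
                        cutoff = vapply(fits, `[[`, 0, "cutoff"),
                        row.names = NULL)
  new("NullBoundaries", perMode = perMode, nTrials = as.integer(nTrials),
      nSigma = nSigma, seed = as.integer(seed))
}

#' Positions with significant coevolution signal
#'
#' Retains position i iff at least one selected mode k has
#' `|v_k(i) - mu_k| > cutoff_k` — the complement of the removal rule
#' "all selected-mode weights within the boundaries". Degenerate
#' positions are always excluded.
#'
#' @param eig an [EigenSystem-class].
#' @param boundaries a [NullBoundaries-class] covering the selected modes.
#' @param corr the [CorrelationMatrix-class] (for the degeneracy mask);
#'   optional.
#' @return Sorted integer vector of retained positions.
#' @export
selectSignificantPositions <- function(eig, boundaries, corr = NULL) {
  pm <- boundaries@perMode
  modes <- selectedModes(eig)
  if (!all(modes %in% pm$mode))
    stop("boundaries do not cover selected modes ",
         paste(setdiff(modes, pm$mode), collapse = ", "))
  n <- nPositions(eig)
  keep <- rep(FALSE, n)
  for (k in modes) {
    row <- pm[pm$mode == k, ]
    keep <- keep | (abs(eig@vectors[, k] - row$mu) > row$cutoff)
  }
  if (!is.null(corr)) keep[corr@degenerate] <- FALSE
  which(keep)
}

## k-means++ seeding (Arthur & Vassilvitskii): first center uniform,
## subsequent centers with probability proportional to squared distance
## to the nearest chosen center.
kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster significant positions into protein sectors
#'
#' k-means on the selected-mode eigenvector coordinates of the retained
#' positions, k-means++ initialization, `nRestarts` restarts keeping the
#' best within-cluster sum of squares. Sector ids are relabeled
#' deterministically by descending size, ties broken by the smallest
#' member position.
#'
#' @param eig an [EigenSystem-class].
#' @param positions retained positions from
#'   [selectSignificantPositions()].
#' @param k number of sectors (default 4).
#' @param seed RNG seed.
#' @param nRestarts k-means restarts (default 100).
#' @param weightModes if TRUE, scale each coordinate axis by its
#'   eigenvalue before clustering (default FALSE: raw components).
#' @return A [SectorAssignment-class].
#' @export
clusterSectors <- function(eig, positions, k = 4L, seed = 1L,
                           nRestarts = 100L, weightModes = FALSE) {
  positions <- sort(as.integer(positions))
  if (length(positions) < k)
    stop("only ", length(positions), " retained position(s) but k = ", k,
         "; use a smaller k")
  modes <- selectedModes(eig)
  coords <- eig@vectors[, modes, drop = FALSE]
  colnames(coords) <- paste0("v", modes)
  x <- coords[positions, , drop = FALSE]
  if (weightModes) x <- sweep(x, 2, eig@values[modes], `*`)

  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      centers <- kmeansppCenters(x, k)
      centers <- centers[!duplicated(centers), , drop = FALSE]
      km <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)
        best <- km
    }
  })

  ## deterministic relabeling: size descending, ties by smallest member
  cl <- best$cluster
  ids <- sort(unique(cl))
  size <- vapply(ids, function(i) sum(cl == i), integer(1))
  firstPos <- vapply(ids, function(i) min(positions[cl == i]), integer(1))
  ord <- order(-size, firstPos)
  relabel <- integer(max(ids)); relabel[ids[ord]] <- seq_along(ids)
  newCl <- relabel[cl]

  n <- nPositions(eig)
  sectorOf <- rep(NA_integer_, n)
  sectorOf[positions] <- newCl
  k <- length(ids)
  assign <- new("SectorAssignment", sectorOf = sectorOf, k = as.integer(k),
                coordinates = coords, modes = as.integer(modes),
                meanTheta = numeric(0), contiguity = numeric(0))
  assign@contiguity <- sectorContiguity(assign)
  assign
}

#' Primary-sequence contiguity of each sector
#'
#' Median gap between consecutive member positions in reference
#' numbering: 1 means a perfectly contiguous run; large values mean a
#' dispersed sector. Diagnostic only — reported, never used to exclude a
#' sector automatically. Singleton sectors have no defined score (NA).
#'
#' @param assignment a [SectorAssignment-class].
#' @return Named numeric vector, one score per sector.
#' @export
sectorContiguity <- function(assignment) {
  members <- sectorMembers(assignment)
  vapply(members, function(p) {
    if (length(p) < 2L) return(NA_real_)
    median(diff(sort(p)))
  }, numeric(1))
}
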