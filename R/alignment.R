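## Multi-sample alignment of mass-spectral peak lists.
##
## Peaks from different samples are joined into features when their relative
## mass difference is at most tolPpm. In one dimension, single-linkage
## clustering at a ppm threshold is equivalent to splitting the sorted mass
## vector at gaps exceeding the tolerance; joinMassLists() exploits this
## ("fast join"), while bruteForceJoin() clusters the full pairwise graph and
## serves as an independent oracle.

.ACQUISITION_WINDOW <- c(92, 2000)

.ppm <- function(lo, hi) (hi - lo) / lo * 1e6  # relative to the smaller mass

#' Read a per-sample peak list
#'
#' Parses a CSV with columns \code{mz}, \code{intensity} and optionally
#' \code{sn} (signal-to-noise). Rows are validated (numeric, positive
#' intensity, m/z inside the 92-2000 Da acquisition window) and returned
#' sorted by m/z; offending rows are reported with their line numbers.
#'
#' @param path file path.
#' @param sampleId sample label; defaults to the file name without extension.
#' @return a \code{data.frame} of class \code{"PeakList"} with attribute
#'   \code{sampleId}.
#' @export
readPeakList <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  need <- c("mz", "intensity")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("peak list ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  peakList(df$mz, df$intensity, sn = df$sn, sampleId = sampleId,
           context = path)
}

#' Construct a validated peak list
#'
#' @param mz,intensity numeric vectors; \code{intensity} must be positive and
#'   \code{mz} inside the acquisition window (92, 2000) Da.
#' @param sn optional signal-to-noise values.
#' @param sampleId sample label.
#' @param context label used in error messages (e.g. a file path).
#' @return sorted \code{"PeakList"} data.frame.
#' @export
peakList <- function(mz, intensity, sn = NULL, sampleId = "sample",
                     context = sampleId) {
  n <- length(mz)
  mz <- suppressWarnings(as.numeric(mz))
  intensity <- suppressWarnings(as.numeric(intensity))
  bad <- which(is.na(mz) | is.na(intensity) | intensity <= 0 |
                 mz <= .ACQUISITION_WINDOW[1] | mz >= .ACQUISITION_WINDOW[2])
  if (length(bad))
    stop("invalid peak rows in ", context, " (1-based data rows): ",
         paste(utils::head(bad, 20), collapse = ", "))
  df <- data.frame(mz = mz, intensity = intensity)
  df$sn <- if (!is.null(sn)) as.numeric(sn) else rep(NA_real_, nrow(df))
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("PeakList", "data.frame")
  attr(df, "sampleId") <- sampleId
  df
}

## Pool peak lists into one long table with sample indices.
.poolPeaks <- function(peakLists) {
  ids <- names(peakLists)
  if (is.null(ids))
    ids <- vapply(seq_along(peakLists), function(i) {
      sid <- attr(peakLists[[i]], "sampleId")
      if (is.null(sid)) paste0("S", i) else sid
    }, character(1))
  pooled <- do.call(rbind, lapply(seq_along(peakLists), function(i) {
    pl <- peakLists[[i]]
    data.frame(mz = pl$mz, intensity = pl$intensity,
               sn = if ("sn" %in% colnames(pl)) pl$sn else NA_real_,
               sample = i)
  }))
  list(pooled = pooled[order(pooled$mz), , drop = FALSE], ids = ids)
}

## Subdivide one linkage cluster (rows sorted by mz): enforce the span cap of
## 2 x tolPpm (greedy, left to right), then resolve same-sample conflicts by
## keeping the most intense peak and demoting the rest to singleton features.
## Returns a list of row-index groups.
.subdivideCluster <- function(mz, sample, intensity, tolPpm) {
  groups <- list()
  start <- 1
  for (i in seq_along(mz)) {
    if (.ppm(mz[start], mz[i]) > 2 * tolPpm) {
      groups[[length(groups) + 1L]] <- start:(i - 1)
      start <- i
    }
  }
  groups[[length(groups) + 1L]] <- start:length(mz)
  out <- list()
  for (g in groups) {
    dup <- duplicated(sample[g]) | duplicated(sample[g], fromLast = TRUE)
    if (any(dup)) {
      keep <- logical(length(g))
      for (s in unique(sample[g])) {
        rows <- which(sample[g] == s)
        keep[rows[which.max(intensity[g][rows])]] <- TRUE
      }
      out[[length(out) + 1L]] <- g[keep]
      for (idx in g[!keep]) out[[length(out) + 1L]] <- idx  # demoted
    } else {
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

.assembleAligned <- function(pooled, groups, ids, tolPpm) {
  nFeat <- length(groups)
  mzOut <- numeric(nFeat)
  mat <- matrix(0, nrow = nFeat, ncol = length(ids))
  snMat <- matrix(NA_real_, nrow = nFeat, ncol = length(ids))
  for (k in seq_len(nFeat)) {
    g <- groups[[k]]
    mzOut[k] <- stats::weighted.mean(pooled$mz[g], pooled$intensity[g])
    mat[k, pooled$sample[g]] <- pooled$intensity[g]
    snMat[k, pooled$sample[g]] <- pooled$sn[g]
  }
  ord <- order(mzOut)
  mzOut <- mzOut[ord]
  mat <- mat[ord, , drop = FALSE]
  snMat <- snMat[ord, , drop = FALSE]
  ## exact consensus-mass ties (possible after conflict demotion) are nudged
  ## so the strictly-increasing invariant holds
  while (any(d <- duplicated(mzOut)))
    mzOut[d] <- mzOut[d] * (1 + 1e-12)
  colnames(mat) <- ids
  colnames(snMat) <- ids
  x <- AlignedMatrix(mzOut, mat, sampleIds = ids,
                     metadata = list(tolPpm = tolPpm))
  SummarizedExperiment::assays(x)$sn <- snMat
  x
}

#' Join peak lists across samples ("fast join")
#'
#' Pools all peaks, sorts by m/z and splits at gaps whose relative difference
#' (computed against the smaller mass) exceeds \code{tolPpm}; this is exactly
#' single-linkage clustering at the ppm threshold. Chained clusters whose
#' total span exceeds \code{2 * tolPpm} are subdivided greedily from the left
#' to bound within-feature spread. When a cluster contains two peaks from the
#' same sample the more intense one is kept and the other is demoted to its
#' own feature, preserving one-peak-per-sample-per-feature. Consensus mass is
#' the intensity-weighted mean of member masses.
#'
#' @param peakLists list of peak lists (see \code{\link{readPeakList}});
#'   names, or \code{sampleId} attributes, become sample labels.
#' @param tolPpm join tolerance in ppm (default 0.5).
#' @return an \code{\link{AlignedMatrix}}.
#' @export
joinMassLists <- function(peakLists, tolPpm = 0.5) {
  stopifnot(length(peakLists) >= 1, tolPpm > 0)
  pp <- .poolPeaks(peakLists)
  pooled <- pp$pooled
  if (!nrow(pooled))
    return(AlignedMatrix(numeric(0),
                         matrix(0, 0, length(pp$ids)), pp$ids))
  gapBreak <- which(.ppm(pooled$mz[-nrow(pooled)], pooled$mz[-1]) > tolPpm)
  bounds <- c(0, gapBreak, nrow(pooled))
  groups <- list()
  for (b in seq_len(length(bounds) - 1)) {
    rows <- (bounds[b] + 1):bounds[b + 1]
    sub <- .subdivideCluster(pooled$mz[rows], pooled$sample[rows],
                             pooled$intensity[rows], tolPpm)
    groups <- c(groups, lapply(sub, function(g) rows[g]))
  }
  .assembleAligned(pooled, groups, pp$ids, tolPpm)
}

#' Brute-force single-linkage join (oracle)
#'
#' Builds the full pairwise ppm-distance graph over all pooled peaks, takes
#' connected components at the tolerance threshold, and applies the same
#' span-cap and same-sample conflict rules as \code{\link{joinMassLists}}.
#' Quadratic in the number of peaks; intended for validation on small inputs.
#'
#' @inheritParams joinMassLists
#' @return an \code{\link{AlignedMatrix}}.
#' @export
bruteForceJoin <- function(peakLists, tolPpm = 0.5) {
  stopifnot(length(peakLists) >= 1, tolPpm > 0)
  pp <- .poolPeaks(peakLists)
  pooled <- pp$pooled
  n <- nrow(pooled)
  if (!n)
    return(AlignedMatrix(numeric(0), matrix(0, 0, length(pp$ids)), pp$ids))
  adj <- outer(pooled$mz, pooled$mz,
               function(a, b) abs(a - b) / pmin(a, b) * 1e6) <= tolPpm
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  groups <- list()
  for (cl in unique(comp)) {
    rows <- which(comp == cl)
    rows <- rows[order(pooled$mz[rows])]
    sub <- .subdivideCluster(pooled$mz[rows], pooled$sample[rows],
                             pooled$intensity[rows], tolPpm)
    groups <- c(groups, lapply(sub, function(gg) rows[gg]))
  }
  .assembleAligned(pooled, groups, pp$ids, tolPpm)
}

#' Remove singlet features
#'
#' Drops features detected in fewer than \code{minSamples} samples
#' (default 2, i.e. peaks occurring only once in the dataset are removed).
#'
#' @param x an \code{\link{AlignedMatrix}}.
#' @param minSamples minimum number of samples with non-zero intensity.
#' @return filtered \code{AlignedMatrix}; warns when nothing survives.
#' @export
removeSingletons <- function(x, minSamples = 2) {
  keep <- rowSums(intensityMatrix(x) > 0) >= minSamples
  if (!any(keep)) warning("all features removed as singletons")
  x[keep, ]
}

#' Write an aligned matrix as wide CSV
#'
#' First column is the consensus mass, one column per sample.
#'
#' @param x an \code{\link{AlignedMatrix}}.
#' @param path output file.
#' @export
writeAlignedMatrix <- function(x, path) {
  df <- data.frame(mz = consensusMass(x), intensityMatrix(x),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
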