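## Normalization, detection-limit harmonization, occurrence filtering and
## replicate averaging. The canonical order is
##   normalizeToSum -> harmonizeDetectionLimit -> occurrenceFilter
## (then averageReplicates when borehole-level datasets are needed); the
## steps do not commute, so the order is part of the contract.

.getMatrix <- function(x) {
  if (methods::is(x, "AlignedMatrix")) intensityMatrix(x) else as.matrix(x)
}

.setMatrix <- function(x, y) {
  if (methods::is(x, "AlignedMatrix")) {
    SummarizedExperiment::assay(x, "intensity") <- y
    x
  } else y
}

#' Normalize intensities to the per-sample sum
#'
#' Each sample column is divided by its total intensity so relative
#' intensities sum to 1 over detected features.
#'
#' @param x an \code{\link{AlignedMatrix}} / \code{AnnotatedMatrix} or a
#'   plain feature x sample matrix.
#' @return same type as the input.
#' @export
normalizeToSum <- function(x) {
  y <- .getMatrix(x)
  tot <- colSums(y)
  if (any(tot <= 0)) {
    bad <- colnames(y)[tot <= 0]
    if (is.null(bad)) bad <- which(tot <= 0)
    stop("sample(s) with zero total intensity: ", paste(bad, collapse = ", "))
  }
  .setMatrix(x, sweep(y, 2, tot, "/"))
}

#' Harmonize the detection limit across samples
#'
#' The largest per-sample minimum non-zero relative intensity becomes the
#' common detection limit; every entry strictly below it is set to 0
#' (entries exactly at the threshold are kept). Expects a normalized matrix.
#'
#' @inheritParams normalizeToSum
#' @return same type as the input; the threshold is attached as attribute
#'   \code{"detectionLimit"} (or metadata entry for S4 input).
#' @export
harmonizeDetectionLimit <- function(x) {
  y <- .getMatrix(x)
  mins <- apply(y, 2, function(col) {
    nz <- col[col > 0]
    if (length(nz)) min(nz) else NA_real_
  })
  thr <- max(mins, na.rm = TRUE)
  y[y < thr] <- 0
  out <- .setMatrix(x, y)
  if (methods::is(out, "AlignedMatrix")) {
    md <- metadata(out)
    md$detectionLimit <- thr
    metadata(out) <- md
  } else {
    attr(out, "detectionLimit") <- thr
  }
  out
}

#' Occurrence filter
#'
#' Retains features detected (non-zero) in at least \code{minSamples}
#' samples (default 3).
#'
#' @inheritParams normalizeToSum
#' @param minSamples minimum occurrence count.
#' @return same type as the input.
#' @export
occurrenceFilter <- function(x, minSamples = 3) {
  y <- .getMatrix(x)
  keep <- rowSums(y > 0) >= minSamples
  if (methods::is(x, "AlignedMatrix")) x[keep, ] else y[keep, , drop = FALSE]
}

#' Average replicate samples into groups
#'
#' Columns mapped to the same group (e.g. borehole) are replaced by their
#' arithmetic mean and the result is renormalized to sum 1 per group.
#'
#' @inheritParams normalizeToSum
#' @param grouping named character vector mapping sample id to group, or a
#'   two-column data.frame (sample, group).
#' @return same type as the input, one column per group.
#' @export
averageReplicates <- function(x, grouping) {
  y <- .getMatrix(x)
  if (is.data.frame(grouping))
    grouping <- stats::setNames(as.character(grouping[[2]]),
                                as.character(grouping[[1]]))
  ids <- colnames(y)
  unmapped <- setdiff(ids, names(grouping))
  if (length(unmapped))
    stop("unmapped sample(s): ", paste(unmapped, collapse = ", "))
  groups <- unique(grouping[ids])
  out <- vapply(groups, function(g) {
    cols <- ids[grouping[ids] == g]
    rowMeans(y[, cols, drop = FALSE])
  }, numeric(nrow(y)))
  out <- as.matrix(out)
  colnames(out) <- groups
  out <- sweep(out, 2, colSums(out), "/")
  if (methods::is(x, "AlignedMatrix")) {
    rd <- as.data.frame(rowData(x))
    md <- metadata(x)
    md$grouping <- grouping
    newx <- AlignedMatrix(rd$mz, out, sampleIds = groups,
                          rowData = rd[, setdiff(colnames(rd), "mz"),
                                       drop = FALSE],
                          metadata = md)
    if (methods::is(x, "AnnotatedMatrix")) methods::new("AnnotatedMatrix",
                                                        newx)
    else newx
  } else out
}
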