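#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assays assays<- assayNames rowData rowData<- colData
NULL

#' AlignedMatrix: a feature x sample intensity matrix
#'
#' Extends \code{SummarizedExperiment}. Rows are mass features produced by
#' joining per-sample peak lists at a fixed ppm tolerance; \code{rowData}
#' carries the consensus m/z (\code{mz}); the single assay
#' (\code{"intensity"}) holds non-negative intensities with 0 meaning the
#' feature was not detected in that sample.
#'
#' @export
setClass("AlignedMatrix", contains = "SummarizedExperiment")

setValidity("AlignedMatrix", function(object) {
  rd <- rowData(object)
  if (!"mz" %in% colnames(rd)) return("rowData must contain 'mz'")
  mz <- rd$mz
  if (nrow(object) && (anyNA(mz) || any(diff(mz) <= 0)))
    return("consensus masses must be strictly increasing")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  y <- assay(object, "intensity")
  if (anyNA(y) || any(y < 0)) return("intensities must be non-negative")
  TRUE
})

#' Construct an AlignedMatrix
#'
#' @param mz numeric vector of consensus masses (strictly increasing).
#' @param intensities numeric matrix, features x samples.
#' @param sampleIds character vector of sample labels.
#' @param rowData optional extra per-feature columns (data.frame).
#' @param metadata optional list of provenance information.
#' @return an \code{AlignedMatrix}.
#' @export
AlignedMatrix <- function(mz, intensities, sampleIds = colnames(intensities),
                          rowData = NULL, metadata = list()) {
  intensities <- as.matrix(intensities)
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(intensities)))
  colnames(intensities) <- sampleIds
  rd <- DataFrame(mz = as.numeric(mz))
  if (!is.null(rowData)) rd <- cbind(rd, DataFrame(rowData))
  se <- SummarizedExperiment(assays = list(intensity = intensities),
                             rowData = rd, metadata = metadata)
  new("AlignedMatrix", se)
}

#' AnnotatedMatrix: a formula-annotated AlignedMatrix
#'
#' Extends \code{\link{AlignedMatrix}}; \code{rowData} additionally carries
#' the assigned molecular formula (element counts, Hill string, mass error in
#' ppm, DBE, elemental ratios) plus logical flags \code{assigned},
#' \code{isotopologue} and \code{iso_verified}. Unassigned features are kept
#' with \code{assigned = FALSE} and are excluded from formula-level analyses.
#'
#' @aliases AnnotatedMatrix
#' @export
setClass("AnnotatedMatrix", contains = "AlignedMatrix")

setValidity("AnnotatedMatrix", function(object) {
  rd <- rowData(object)
  need <- c("assigned", "formula", "error_ppm", .ELEMENTS)
  missing <- setdiff(need, colnames(rd))
  if (length(missing))
    return(paste("rowData lacks:", paste(missing, collapse = ", ")))
  tol <- metadata(object)$params$tolPpm
  if (!is.null(tol)) {
    err <- abs(rd$error_ppm[rd$assigned])
    if (length(err) && any(err > tol + 1e-9))
      return("assigned feature exceeds the mass-error tolerance")
  }
  TRUE
})

#' InterdomainNetwork: molecular formula / ASV association graph
#'
#' Bipartite-flavoured (but not strictly bipartite) co-occurrence network in
#' which nodes are molecular formulas (kind \code{"MF"}) or amplicon sequence
#' variants (kind \code{"ASV"}) and edges connect pairs whose proportionality
#' \code{|rho|} meets the cutoff. Module assignments, within-module degree
#' z-scores, participation coefficients and topological roles are filled in
#' by \code{\link{greedyModularity}} and \code{\link{nodeRoles}}.
#'
#' @slot nodes data.frame: id, kind, label, degree, module, z, p, role.
#' @slot edges data.frame: from, to, rho, sign.
#' @slot graph the underlying \code{igraph} object.
#' @slot cutoff numeric |rho| threshold used to admit edges.
#' @slot q Newman-Girvan modularity of the stored partition (NA before
#'   \code{greedyModularity} is run).
#' @aliases InterdomainNetwork
#' @export
setClass("InterdomainNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        graph = "ANY", cutoff = "numeric", q = "numeric"))

setValidity("InterdomainNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (nrow(ed)) {
    if (any(abs(ed$rho) < object@cutoff - 1e-12))
      return("edge below the |rho| cutoff")
    if (!all(c(ed$from, ed$to) %in% nd$id))
      return("edge endpoint not among nodes")
  }
  if (nrow(nd) && !all(nd$kind %in% c("MF", "ASV")))
    return("node kind must be 'MF' or 'ASV'")
  ok_roles <- c("peripheral", "connector", "module hub", "network hub",
                "unclassified", NA)
  if (nrow(nd) && !all(nd$role %in% ok_roles))
    return("unknown node role")
  TRUE
})

#' @describeIn AlignedMatrix-class consensus m/z of each feature.
#' @param x an \code{AlignedMatrix}.
#' @export
consensusMass <- function(x) rowData(x)$mz

#' @describeIn AlignedMatrix-class the intensity assay as a base matrix.
#' @export
intensityMatrix <- function(x) {
  y <- assay(x, "intensity")
  rownames(y) <- NULL
  y
}

#' @describeIn AlignedMatrix-class sample labels.
#' @export
sampleIds <- function(x) colnames(x)

#' Per-feature annotation table
#'
#' @param x an \code{AnnotatedMatrix} (or \code{AlignedMatrix}).
#' @param annotatedOnly drop unassigned and isotopologue features.
#' @return base data.frame of rowData.
#' @export
formulaData <- function(x, annotatedOnly = FALSE) {
  rd <- as.data.frame(rowData(x))
  if (annotatedOnly && "assigned" %in% colnames(rd)) {
    keep <- rd$assigned
    if ("isotopologue" %in% colnames(rd)) keep <- keep & !rd$isotopologue
    rd <- rd[keep, , drop = FALSE]
  }
  rd
}

#' @describeIn InterdomainNetwork-class node table.
#' @param net an \code{InterdomainNetwork}.
#' @export
networkNodes <- function(net) net@nodes

#' @describeIn InterdomainNetwork-class edge table.
#' @export
networkEdges <- function(net) net@edges

#' @describeIn InterdomainNetwork-class underlying igraph object.
#' @export
networkGraph <- function(net) net@graph

#' @describeIn InterdomainNetwork-class modularity Q of the stored partition.
#' @export
modularityScore <- function(net) net@q

setMethod("show", "AlignedMatrix", function(object) {
  cat(class(object), "with", nrow(object), "features x",
      ncol(object), "samples\n")
  if (nrow(object)) {
    mz <- consensusMass(object)
    cat("  m/z range:", sprintf("%.5f - %.5f", min(mz), max(mz)), "\n")
  }
  rd <- rowData(object)
  if ("assigned" %in% colnames(rd))
    cat("  assigned formulas:", sum(rd$assigned), "\n")
})

setMethod("show", "InterdomainNetwork", function(object) {
  nd <- object@nodes
  cat("InterdomainNetwork:", nrow(nd), "nodes (",
      sum(nd$kind == "MF"), "MF,", sum(nd$kind == "ASV"), "ASV ),",
      nrow(object@edges), "edges, cutoff |rho| >=", object@cutoff, "\n")
  if (!is.na(object@q))
    cat("  modules:", length(unique(stats::na.omit(nd$module))),
        " modularity Q =", round(object@q, 3), "\n")
})
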