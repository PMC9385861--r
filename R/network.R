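## The interdomain proportionality network: compositional preprocessing
## (prevalence filter, zero replacement, clr), the proportionality measure
## rho, permutation-based FDR selection of the |rho| cutoff, graph
## construction, fast-greedy modularity and z/P topological node roles.

#' Prevalence and abundance filtering of the paired matrices
#'
#' Molecular-formula features and ASVs are kept when present (non-zero) in at
#' least \code{minSamples} samples; ASVs additionally require a maximum
#' relative abundance of at least \code{minAbundance}.
#'
#' @param mfMatrix features x samples matrix of relative intensities.
#' @param asvMatrix ASVs x samples matrix of relative abundances.
#' @param minSamples prevalence threshold (default 5).
#' @param minAbundance minimum peak relative abundance for ASVs
#'   (default 0.001, i.e. 0.1\%).
#' @return list with filtered \code{mf} and \code{asv} matrices.
#' @export
prevalenceFilter <- function(mfMatrix, asvMatrix, minSamples = 5,
                             minAbundance = 0.001) {
  mfMatrix <- as.matrix(mfMatrix)
  asvMatrix <- as.matrix(asvMatrix)
  if (!identical(sort(colnames(mfMatrix)), sort(colnames(asvMatrix))))
    stop("MF and ASV matrices must share the same sample set")
  asvMatrix <- asvMatrix[, colnames(mfMatrix), drop = FALSE]
  mfKeep <- rowSums(mfMatrix > 0) >= minSamples
  asvKeep <- rowSums(asvMatrix > 0) >= minSamples &
    apply(asvMatrix, 1, max) >= minAbundance
  list(mf = mfMatrix[mfKeep, , drop = FALSE],
       asv = asvMatrix[asvKeep, , drop = FALSE])
}

#' Replace zeros by the per-feature minimum / 10
#'
#' @param m non-negative matrix with at least one non-zero entry per row.
#' @return matrix with zeros replaced.
#' @export
replaceZeros <- function(m) {
  m <- as.matrix(m)
  for (i in seq_len(nrow(m))) {
    nz <- m[i, m[i, ] > 0]
    if (!length(nz))
      stop("all-zero feature at row ", i, " (filter before zero replacement)")
    m[i, m[i, ] == 0] <- min(nz) / 10
  }
  m
}

#' Centered log-ratio transform
#'
#' Per sample column: log value minus the mean log over the block's
#' features. Each dataset (MF block, ASV block) is transformed separately
#' before stacking.
#'
#' @param m strictly positive matrix (features x samples).
#' @return clr-transformed matrix; columns sum to 0.
#' @export
clrTransform <- function(m) {
  m <- as.matrix(m)
  if (any(m <= 0)) stop("clr requires strictly positive entries")
  lg <- log(m)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Proportionality measure rho
#'
#' For clr-transformed rows g_i, rho(i, j) = 1 - var(g_i - g_j) /
#' (var(g_i) + var(g_j)) = 2 cov(g_i, g_j) / (var(g_i) + var(g_j)),
#' in [-1, 1] with unit diagonal. Pairs involving a zero-variance feature
#' are set to 0 and recorded in attribute \code{"zeroVariance"}.
#'
#' @param x clr matrix (features x samples), e.g. the row-stacked MF and ASV
#'   blocks transformed separately.
#' @return symmetric matrix of rho values.
#' @export
proportionalityRho <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("need at least 3 samples")
  v <- apply(x, 1, stats::var)
  C <- stats::cov(t(x))
  denom <- outer(v, v, "+")
  rho <- 2 * C / denom
  zero <- v <= .Machine$double.eps * 100
  if (any(zero)) {
    rho[zero, ] <- 0
    rho[, zero] <- 0
  }
  diag(rho) <- 1
  rownames(rho) <- colnames(rho) <- rownames(x)
  attr(rho, "zeroVariance") <- which(zero)
  rho
}

## between-block |rho| exceedance counts on a cutoff grid
.betweenCounts <- function(rhoBlock, grid) {
  a <- abs(rhoBlock)
  vapply(grid, function(cc) sum(a >= cc), numeric(1))
}

## cross-block rho from centered rows (variances fixed, covariances cheap)
.crossRho <- function(mfC, asvC, vMf, vAsv, n) {
  cross <- tcrossprod(mfC, asvC) / (n - 1)
  2 * cross / outer(vMf, vAsv, "+")
}

#' Permutation-FDR selection of the |rho| cutoff
#'
#' For each candidate cutoff c, the false-discovery rate is estimated as the
#' mean over permutations of the number of between-block pairs with
#' |rho_perm| >= c, divided by the observed count at c. Permutations shuffle
#' the sample labels of the ASV block while the MF block stays fixed,
#' preserving within-block covariance. The smallest cutoff achieving
#' FDR < \code{targetFdr} is returned; if none does, the largest grid value
#' is returned with a warning.
#'
#' @param mfClr,asvClr clr-transformed blocks (features x samples, same
#'   sample order).
#' @param nPerm number of permutations (>= 10; default 100).
#' @param targetFdr target FDR (default 0.05).
#' @param grid candidate cutoffs (default 0.05 to 0.95 by 0.05).
#' @param seed integer seed.
#' @return list: \code{cutoff}, \code{table} (grid, observed counts, mean
#'   permuted counts, FDR estimate).
#' @export
fdrCutoff <- function(mfClr, asvClr, nPerm = 100, targetFdr = 0.05,
                      grid = seq(0.05, 0.95, by = 0.05), seed = 1) {
  stopifnot(nPerm >= 10)
  mfClr <- as.matrix(mfClr); asvClr <- as.matrix(asvClr)
  n <- ncol(mfClr)
  if (ncol(asvClr) != n) stop("blocks must share samples")
  mfC <- mfClr - rowMeans(mfClr)
  asvC <- asvClr - rowMeans(asvClr)
  vMf <- rowSums(mfC^2) / (n - 1)
  vAsv <- rowSums(asvC^2) / (n - 1)
  obs <- .betweenCounts(.crossRho(mfC, asvC, vMf, vAsv, n), grid)
  set.seed(seed)
  permSum <- numeric(length(grid))
  for (b in seq_len(nPerm)) {
    idx <- sample.int(n)
    asvP <- asvClr[, idx, drop = FALSE]
    asvPC <- asvP - rowMeans(asvP)
    permSum <- permSum +
      .betweenCounts(.crossRho(mfC, asvPC, vAsv = vAsv, vMf = vMf, n = n),
                     grid)
  }
  permMean <- permSum / nPerm
  fdr <- ifelse(obs > 0, permMean / obs, ifelse(permMean > 0, 1, 0))
  ok <- which(fdr < targetFdr)
  if (length(ok)) {
    cutoff <- grid[min(ok)]
  } else {
    cutoff <- max(grid)
    warning("no cutoff achieved the target FDR; returning max grid value")
  }
  list(cutoff = cutoff,
       table = data.frame(cutoff = grid, observed = obs,
                          permuted = permMean, fdr = fdr))
}

#' Build the interdomain network
#'
#' Admits every feature pair with |rho| >= cutoff as an edge (positive and
#' negative associations both enter; the sign is an edge attribute) and keeps
#' nodes with at least one edge.
#'
#' @param rho symmetric proportionality matrix over the stacked features
#'   (row names must be unique).
#' @param kinds character vector ("MF" or "ASV") per row of \code{rho}.
#' @param cutoff |rho| threshold in (0, 1] (default 0.85).
#' @param nodeMetadata optional data.frame keyed by \code{id} with extra node
#'   columns (e.g. taxonomy or formula).
#' @return an \code{\link{InterdomainNetwork}}; empty input yields a valid
#'   empty network with a warning.
#' @export
buildNetwork <- function(rho, kinds, cutoff = 0.85, nodeMetadata = NULL) {
  stopifnot(cutoff > 0, cutoff <= 1)
  ids <- rownames(rho)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(rho)))
  ut <- upper.tri(rho)
  hit <- which(ut & abs(rho) >= cutoff, arr.ind = TRUE)
  edges <- data.frame(from = ids[hit[, 1]], to = ids[hit[, 2]],
                      rho = rho[hit],
                      sign = ifelse(rho[hit] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  nodeIds <- sort(unique(c(edges$from, edges$to)))
  if (!nrow(edges)) warning("no edge passes the cutoff; empty network")
  nodes <- data.frame(id = nodeIds,
                      kind = kinds[match(nodeIds, ids)],
                      stringsAsFactors = FALSE)
  if (!is.null(nodeMetadata))
    nodes <- merge(nodes, nodeMetadata, by = "id", all.x = TRUE,
                   sort = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  nodes$degree <- if (nrow(nodes)) igraph::degree(g) else integer(0)
  nodes$module <- rep(NA_integer_, nrow(nodes))
  nodes$z <- rep(NA_real_, nrow(nodes))
  nodes$p <- rep(NA_real_, nrow(nodes))
  nodes$role <- rep(NA_character_, nrow(nodes))
  rownames(nodes) <- NULL
  methods::new("InterdomainNetwork", nodes = nodes, edges = edges,
               graph = g, cutoff = cutoff, q = NA_real_)
}

#' Fast-greedy modularity optimization
#'
#' Agglomerative greedy maximization of Newman-Girvan modularity on the
#' unweighted, undirected edge set (igraph's fast-greedy community
#' detection); rho magnitudes are edge attributes only and do not weight the
#' agglomeration.
#'
#' @param net an \code{\link{InterdomainNetwork}} with at least one edge.
#' @return the network with \code{module} filled in and the modularity
#'   \code{Q} stored (see \code{\link{modularityScore}}).
#' @export
greedyModularity <- function(net) {
  if (!nrow(net@edges)) stop("network has no edges")
  g <- igraph::simplify(net@graph)
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  ## cut the merge tree at the community count maximizing Q; ties resolve
  ## to the coarsest partition
  nComp <- igraph::count_components(g)
  ks <- rev(seq(nComp, igraph::vcount(g)))
  qs <- vapply(ks, function(k)
    igraph::modularity(g, igraph::cut_at(cl, no = k)), numeric(1))
  best <- ks[which.max(qs)]
  memb <- igraph::cut_at(cl, no = best)
  names(memb) <- igraph::V(g)$name
  net@nodes$module <- as.integer(memb[net@nodes$id])
  net@q <- igraph::modularity(g, memb)
  net
}

#' Exhaustive modularity maximization (oracle)
#'
#' Enumerates every partition of the node set (restricted growth strings;
#' feasible up to ~13 nodes) and returns the maximum Newman-Girvan
#' modularity. Used to validate the greedy optimizer on small graphs.
#'
#' @param net an \code{\link{InterdomainNetwork}} or an igraph object.
#' @return list: \code{q} (maximum modularity), \code{membership}.
#' @export
bruteForceModularity <- function(net) {
  g <- if (methods::is(net, "InterdomainNetwork")) net@graph else net
  g <- igraph::simplify(g)
  n <- igraph::vcount(g)
  if (n > 13) stop("exhaustive search is limited to 13 nodes")
  el <- igraph::as_edgelist(g, names = FALSE)
  res <- brute_modularity_cpp(n, el[, 1] - 1L, el[, 2] - 1L)
  list(q = res$q, membership = res$membership + 1L)
}

#' z/P topological node roles
#'
#' Computes, per node, the within-module degree z-score
#' z = (kappa - mean kappa_module) / sd kappa_module (0 when sd = 0) and the
#' participation coefficient P = 1 - sum_s (k_is / k_i)^2 over modules s.
#' Canonical role thresholds: peripheral (z <= 2.5, P <= 0.62), connector
#' (z <= 2.5, P > 0.62), module hub (z > 2.5, P <= 0.62), network hub
#' (z > 2.5, P > 0.62). \code{printedVariant = TRUE} instead labels
#' z > 2.5 nodes as network hubs when P > 0.62, module hubs when P = 0.62
#' and \code{"unclassified"} below.
#'
#' @param net an \code{\link{InterdomainNetwork}} with modules assigned
#'   (see \code{\link{greedyModularity}}).
#' @param printedVariant use the alternative module-hub threshold (see
#'   above; default \code{FALSE}).
#' @return the network with \code{z}, \code{p} and \code{role} filled in.
#' @export
nodeRoles <- function(net, printedVariant = FALSE) {
  nodes <- net@nodes
  if (anyNA(nodes$module)) stop("assign modules first (greedyModularity)")
  g <- igraph::simplify(net@graph)
  ids <- igraph::V(g)$name
  memb <- nodes$module[match(ids, nodes$id)]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  nMod <- max(memb)
  ## within-module degree of every node toward every module
  kPerMod <- vapply(seq_len(nMod), function(m)
    rowSums(adj[, memb == m, drop = FALSE]), numeric(length(ids)))
  kPerMod <- matrix(kPerMod, nrow = length(ids))
  kappa <- kPerMod[cbind(seq_along(ids), memb)]
  z <- numeric(length(ids))
  for (m in seq_len(nMod)) {
    rows <- which(memb == m)
    mu <- mean(kappa[rows])
    sdv <- stats::sd(kappa[rows])
    z[rows] <- if (is.na(sdv) || sdv == 0) 0 else (kappa[rows] - mu) / sdv
  }
  p <- ifelse(k > 0, 1 - rowSums((kPerMod / pmax(k, 1))^2), 0)
  role <- character(length(ids))
  if (!printedVariant) {
    role[z <= 2.5 & p <= 0.62] <- "peripheral"
    role[z <= 2.5 & p > 0.62] <- "connector"
    role[z > 2.5 & p <= 0.62] <- "module hub"
    role[z > 2.5 & p > 0.62] <- "network hub"
  } else {
    role[z <= 2.5 & p <= 0.62] <- "peripheral"
    role[z <= 2.5 & p > 0.62] <- "connector"
    role[z > 2.5] <- "unclassified"
    role[z > 2.5 & p >= 0.62] <- "module hub"
    role[z > 2.5 & p > 0.62] <- "network hub"
  }
  ord <- match(nodes$id, ids)
  nodes$z <- z[ord]
  nodes$p <- p[ord]
  nodes$role <- role[ord]
  net@nodes <- nodes
  methods::validObject(net)
  net
}

#' Per-module summary
#'
#' @param net an \code{\link{InterdomainNetwork}} with modules assigned.
#' @return data.frame: module id, node counts by kind, edge count.
#' @export
moduleSummary <- function(net) {
  nodes <- net@nodes
  if (anyNA(nodes$module)) stop("assign modules first")
  memb <- stats::setNames(nodes$module, nodes$id)
  edges <- net@edges
  out <- lapply(sort(unique(nodes$module)), function(m) {
    inMod <- nodes$module == m
    data.frame(module = m,
               n_nodes = sum(inMod),
               n_mf = sum(inMod & nodes$kind == "MF"),
               n_asv = sum(inMod & nodes$kind == "ASV"),
               n_edges_within = sum(memb[edges$from] == m &
                                      memb[edges$to] == m))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write the network as GraphML and edge-list TSV
#'
#' @param net an \code{\link{InterdomainNetwork}}.
#' @param graphmlPath,edgeListPath output files (either may be NULL).
#' @export
writeNetwork <- function(net, graphmlPath = NULL, edgeListPath = NULL) {
  if (!is.null(graphmlPath)) {
    g <- net@graph
    for (col in c("kind", "module", "z", "p", "role")) {
      vals <- net@nodes[[col]][match(igraph::V(g)$name, net@nodes$id)]
      g <- igraph::set_vertex_attr(g, col, value = vals)
    }
    igraph::write_graph(g, graphmlPath, format = "graphml")
  }
  if (!is.null(edgeListPath))
    utils::write.table(net@edges, edgeListPath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(net)
}
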