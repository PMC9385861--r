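# Fixture builders shared across test files; everything is generated in
# code so tests stay self-contained.

# aligned matrix straight from mz / intensity inputs
toyAligned <- function(mz, intensities,
                       sampleIds = colnames(intensities)) {
  AlignedMatrix(mz, intensities, sampleIds = sampleIds)
}

# a small pair of endmembers over a given formula library: endmember A
# weights lignin-like formulas up, endmember B the aliphatic classes
toyEndmembers <- function(lib, docA = 5.4, docB = 0.9) {
  wA <- ifelse(lib$class == "lignin-like", 3, 1)
  wB <- ifelse(lib$class %in% c("unsaturated oxygen-poor",
                                "unsaturated hydrocarbon-like"), 3, 1)
  chemA <- c(na = 1500, k = 60, ca = 90, mg = 220, d18o = -6, d2h = -55,
             so4 = 470, cl = 3400)
  chemB <- c(na = 3000, k = 12, ca = 5200, mg = 31, d18o = -12, d2h = -95,
             so4 = 600, cl = 14500)
  list(endmemberSpec("A", lib, wA / sum(wA), chemA, docA),
       endmemberSpec("B", lib, wB / sum(wB), chemB, docB))
}

# network object from a 0/1 adjacency matrix (edges get rho = 1)
netFromAdjacency <- function(adj, kinds = NULL, cutoff = 0.5) {
  n <- nrow(adj)
  if (is.null(rownames(adj)))
    rownames(adj) <- colnames(adj) <- sprintf("n%02d", seq_len(n))
  if (is.null(kinds)) kinds <- rep(c("MF", "ASV"), length.out = n)
  rho <- adj * 1
  diag(rho) <- 1
  buildNetwork(rho, kinds, cutoff = cutoff)
}

cliqueEdges <- function(nodes) t(utils::combn(nodes, 2))

# chain of three 4-cliques (12 nodes) with single-edge bridges
cliqueChainAdjacency <- function() {
  adj <- matrix(0, 12, 12)
  for (e in list(cliqueEdges(1:4), cliqueEdges(5:8), cliqueEdges(9:12),
                 rbind(c(4, 5), c(8, 9)))) {
    adj[e] <- 1
    adj[e[, c(2, 1), drop = FALSE]] <- 1
  }
  adj
}

twoTrianglesAdjacency <- function() {
  adj <- matrix(0, 6, 6)
  e <- rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4))
  adj[e] <- 1
  adj[e[, c(2, 1)]] <- 1
  adj
}

writeTempPeakCsv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
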