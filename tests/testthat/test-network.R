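test_that("prevalence filtering applies the occurrence and abundance rules", {
  set.seed(2)
  mf <- matrix(runif(40), 4, 10,
               dimnames = list(paste0("MF", 1:4), paste0("S", 1:10)))
  mf[1, 1:6] <- 0                      # present in 4 of 10 -> removed
  asv <- matrix(runif(30), 3, 10,
                dimnames = list(paste0("ASV", 1:3), paste0("S", 1:10)))
  asv[2, ] <- 0.0009                   # peaks below 0.1% -> removed
  asv[3, ] <- 0.0011
  out <- prevalenceFilter(mf, asv)
  expect_equal(rownames(out$mf), paste0("MF", 2:4))
  expect_equal(rownames(out$asv), c("ASV1", "ASV3"))
  # thresholds at zero are the identity
  out0 <- prevalenceFilter(mf, asv, minSamples = 0, minAbundance = 0)
  expect_equal(dim(out0$mf), dim(mf))
  expect_equal(dim(out0$asv), dim(asv))
  colnames(asv)[1] <- "other"
  expect_error(prevalenceFilter(mf, asv), "sample set")
})

test_that("zero replacement uses the per-feature minimum over ten", {
  m <- rbind(f1 = c(0, 0.02, 0.04), f2 = c(0.1, 0.2, 0.3))
  out <- replaceZeros(m)
  expect_equal(out["f1", ], c(0.002, 0.02, 0.04), ignore_attr = TRUE)
  expect_equal(out["f2", ], m["f2", ])            # no zeros: identity
  expect_error(replaceZeros(rbind(c(0, 0, 0))), "all-zero")
})

test_that("clr columns are centered log ratios", {
  expect_equal(unname(clrTransform(cbind(c(1, 1, 1, 1)))), cbind(rep(0, 4)))
  out <- clrTransform(cbind(c(1, 10)))
  expect_equal(unname(out[, 1]), c(-log(10) / 2, log(10) / 2),
               tolerance = 1e-9)
  set.seed(4)
  m <- matrix(rexp(50) + 0.01, 10)
  expect_equal(unname(colSums(clrTransform(m))), rep(0, 5),
               tolerance = 1e-9)
  expect_error(clrTransform(cbind(c(1, 0))), "positive")
})

test_that("proportionality rho has the defining fixed points", {
  set.seed(6)
  g <- matrix(rnorm(40), 4, 10)
  g[2, ] <- g[1, ] + 2          # shifted copy: rho = 1
  g[3, ] <- -g[1, ]             # mirrored: rho = -1
  rho <- proportionalityRho(g)
  expect_equal(diag(rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rho, t(rho))
  expect_equal(rho[1, 2], 1, tolerance = 1e-12)
  expect_equal(rho[1, 3], -1, tolerance = 1e-12)
  # invariant to sample reordering
  perm <- sample(10)
  expect_equal(proportionalityRho(g[, perm]), rho)
  # independent rows drift to 0 with many samples
  set.seed(7)
  big <- matrix(rnorm(2 * 4000), 2)
  expect_lt(abs(proportionalityRho(big)[1, 2]), 0.05)
  # zero-variance feature: pairs flagged and set to 0
  g0 <- rbind(g, 0)
  rho0 <- proportionalityRho(g0)
  expect_equal(rho0[5, 1], 0)
  expect_equal(unname(attr(rho0, "zeroVariance")), 5)
})

test_that("separate-block clr differs from joint clr in the resulting rho", {
  set.seed(8)
  mf <- matrix(rexp(50) + 0.01, 5, 10)
  asv <- matrix(rexp(30) + 0.01, 3, 10)
  sep <- proportionalityRho(rbind(clrTransform(mf), clrTransform(asv)))
  joint <- proportionalityRho(clrTransform(rbind(mf, asv)))
  expect_gt(max(abs(sep - joint)), 1e-6)
})

test_that("the permutation FDR estimate is near 1 on pure noise and the
           selected cutoff admits planted links", {
  set.seed(9)
  mfN <- clrTransform(matrix(rexp(200) + 0.01, 20, 10))
  asvN <- clrTransform(matrix(rexp(100) + 0.01, 10, 10))
  res <- fdrCutoff(mfN, asvN, nPerm = 30, seed = 1)
  lowCut <- res$table$fdr[res$table$cutoff <= 0.2]
  expect_gt(mean(lowCut), 0.5)   # noise: permuted counts match observed

  sim <- generateInterdomainData(latentStrength = 3, noiseSd = 0.1,
                                 seed = 10)
  mfClr <- clrTransform(replaceZeros(sim$mf))
  asvClr <- clrTransform(replaceZeros(sim$asv))
  sel <- fdrCutoff(mfClr, asvClr, nPerm = 30, seed = 2)
  rho <- proportionalityRho(rbind(mfClr, asvClr))
  links <- sim$truthLinks
  planted <- abs(rho[cbind(links$mf, links$asv)])
  expect_gte(mean(planted >= sel$cutoff), 0.9)
})

test_that("the selected cutoff makes false discoveries rare on null data", {
  # latent strength 0: any between-block discovery is false; the realized
  # false-discovery proportion at the permutation-selected cutoff stays
  # within twice the 5% target
  fdp <- vapply(1:60, function(i) {
    s <- generateInterdomainData(nMfs = 40, nAsvs = 20, nSamples = 10,
                                 nModules = 10, mfPerModule = 3,
                                 asvPerModule = 2, latentStrength = 0,
                                 noiseSd = 0.3, seed = 4000 + i)
    mc <- clrTransform(replaceZeros(s$mf))
    ac <- clrTransform(replaceZeros(s$asv))
    cut <- suppressWarnings(
      fdrCutoff(mc, ac, nPerm = 20, seed = 5000 + i)$cutoff)
    r <- proportionalityRho(rbind(mc, ac))
    as.numeric(any(abs(r[1:40, 41:60]) >= cut))
  }, numeric(1))
  expect_lte(mean(fdp), 0.10)
})

test_that("network construction thresholds edges and keeps signed rho", {
  rho <- diag(3)
  rownames(rho) <- colnames(rho) <- c("MF1", "MF2", "ASV1")
  rho[1, 3] <- rho[3, 1] <- 0.9
  rho[2, 3] <- rho[3, 2] <- -0.4
  net <- buildNetwork(rho, c("MF", "MF", "ASV"), cutoff = 0.85)
  expect_equal(nrow(networkNodes(net)), 2)
  expect_equal(nrow(networkEdges(net)), 1)
  expect_equal(networkEdges(net)$sign, "positive")
  expect_warning(buildNetwork(rho, c("MF", "MF", "ASV"), cutoff = 0.95),
                 "empty")
  # negative edges pass on |rho|
  rho[2, 3] <- rho[3, 2] <- -0.9
  net <- buildNetwork(rho, c("MF", "MF", "ASV"), cutoff = 0.85)
  expect_setequal(networkEdges(net)$sign, c("positive", "negative"))
})

test_that("fast-greedy modularity matches hand values on canonical graphs", {
  net <- netFromAdjacency(twoTrianglesAdjacency())
  net <- greedyModularity(net)
  expect_equal(modularityScore(net), 0.5, tolerance = 1e-12)
  expect_equal(length(unique(networkNodes(net)$module)), 2)

  complete <- matrix(1, 5, 5) - diag(5)
  netc <- greedyModularity(netFromAdjacency(complete))
  expect_equal(modularityScore(netc), 0, tolerance = 1e-12)
  expect_equal(length(unique(networkNodes(netc)$module)), 1)
})

test_that("greedy modularity agrees with the exhaustive oracle", {
  net <- greedyModularity(netFromAdjacency(cliqueChainAdjacency()))
  bf <- bruteForceModularity(net)
  expect_equal(modularityScore(net), bf$q, tolerance = 1e-12)
  bf6 <- bruteForceModularity(netFromAdjacency(twoTrianglesAdjacency()))
  expect_equal(bf6$q, 0.5, tolerance = 1e-12)
})

test_that("participation and z follow their definitions", {
  # hub node 1 wired to all of module A = {1..5}; node 6 bridges evenly
  adj <- matrix(0, 9, 9)
  wire <- function(i, j) adj[rbind(c(i, j), c(j, i))] <<- 1
  for (j in 2:5) wire(1, j)
  wire(6, 2); wire(6, 7)          # node 6: one edge in A, one in B
  wire(7, 8); wire(8, 9); wire(9, 7)
  net <- netFromAdjacency(adj)
  net@nodes$module <- c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L)[
    match(net@nodes$id, sprintf("n%02d", 1:9))]
  out <- nodeRoles(net)
  nd <- networkNodes(out)
  rownames(nd) <- nd$id
  # node 6 splits its two edges across both modules: P = 0.5
  expect_equal(nd["n06", "p"], 0.5)
  # all-inside nodes have P = 0
  expect_equal(nd["n02", "p"], 0)
  expect_equal(nd["n03", "p"], 0)
  # node 7: two of three edges inside its module
  expect_equal(nd["n07", "p"], 1 - (2 / 3)^2 - (1 / 3)^2)
  # hand z-scores in module A (within-module degrees 4,2,1,1,1,1)
  kappa <- c(4, 2, 1, 1, 1, 1)
  expect_equal(nd["n01", "z"], (4 - mean(kappa)) / sd(kappa))
  expect_equal(nd["n03", "z"], (1 - mean(kappa)) / sd(kappa))
  expect_true(all(nd$role %in% c("peripheral", "connector", "module hub",
                                 "network hub")))
})

test_that("role thresholds classify the four z/P quadrants", {
  # star-in-module hub: 1 center + 12 leaves -> z > 2.5, P = 0
  adj <- matrix(0, 17, 17)
  for (j in 2:13) adj[1, j] <- adj[j, 1] <- 1
  # connector node 14: single edges into four modules
  for (j in c(2, 15, 16, 17)) adj[14, j] <- adj[j, 14] <- 1
  adj[15, 16] <- adj[16, 15] <- 1
  net <- netFromAdjacency(adj)
  ids <- net@nodes$id
  modmap <- rep(1L, 17)
  modmap[14] <- 2L
  modmap[15] <- 3L; modmap[16] <- 4L
  modmap[17] <- 5L
  net@nodes$module <- modmap[match(ids, sprintf("n%02d", 1:17))]
  out <- networkNodes(nodeRoles(net))
  rownames(out) <- out$id
  expect_gt(out["n01", "z"], 2.5)
  expect_equal(out["n01", "role"], "module hub")
  expect_equal(out["n14", "p"], 0.75)
  expect_equal(out["n14", "role"], "connector")
  expect_equal(out["n05", "role"], "peripheral")
})

test_that("planted modules are recovered exactly without noise", {
  sim <- generateInterdomainData(nMfs = 40, nAsvs = 20, nSamples = 10,
                                 nModules = 5, mfPerModule = 4,
                                 asvPerModule = 2, latentStrength = 2,
                                 noiseSd = 0, seed = 13)
  mfClr <- clrTransform(replaceZeros(sim$mf))
  asvClr <- clrTransform(replaceZeros(sim$asv))
  rho <- proportionalityRho(rbind(mfClr, asvClr))
  net <- buildNetwork(rho, c(rep("MF", 40), rep("ASV", 20)), cutoff = 0.85)
  net <- greedyModularity(net)
  nd <- networkNodes(net)
  plantedIds <- names(sim$membership)
  common <- intersect(nd$id, plantedIds)
  ari <- mclust::adjustedRandIndex(nd$module[match(common, nd$id)],
                                   sim$membership[common])
  expect_gte(ari, 0.999)
  # at least as many components as planted modules
  comp <- igraph::components(networkGraph(net))
  expect_gte(comp$no, 5)
})

test_that("module summaries and serialization cover node metadata", {
  net <- greedyModularity(netFromAdjacency(twoTrianglesAdjacency()))
  net <- nodeRoles(net)
  ms <- moduleSummary(net)
  expect_equal(nrow(ms), 2)
  expect_equal(ms$n_edges_within, c(3, 3))
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  writeNetwork(net, gml, tsv)
  expect_true(file.size(gml) > 0)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 6)
})
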