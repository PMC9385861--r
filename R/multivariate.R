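## Dissimilarity, ordination and constrained ordination with permutation
## inference. These are standard community-ecology computations and are
## delegated to vegan; the functions here fix the conventions used across
## the package (samples as rows, seeds, symmetric Procrustes scaling) and
## return light-weight result records.

#' Bray-Curtis dissimilarities between samples
#'
#' @param profiles sample x feature matrix of non-negative relative
#'   intensities/abundances, or an \code{\link{AlignedMatrix}} (whose columns
#'   are samples and will be transposed).
#' @return a \code{dist} object with sample labels.
#' @export
brayCurtis <- function(profiles) {
  if (methods::is(profiles, "AlignedMatrix")) {
    y <- t(intensityMatrix(profiles))
    rownames(y) <- sampleIds(profiles)
    profiles <- y
  }
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("negative entries in profiles")
  tot <- rowSums(profiles)
  if (any(tot <= 0))
    stop("zero-sum sample(s): ",
         paste(rownames(profiles)[tot <= 0], collapse = ", "))
  vegan::vegdist(profiles, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS (vegan::metaMDS on a precomputed dissimilarity):
#' iterative stress minimization with monotone regression, best of
#' \code{nStarts} random starts.
#'
#' @param d a \code{dist} of dissimilarities.
#' @param k number of axes (default 2).
#' @param nStarts random starts (default 20).
#' @param seed integer seed; fixed seed gives identical results.
#' @return list: \code{points} (centered sample x k coordinates),
#'   \code{stress}, \code{converged}, \code{seed}.
#' @export
runNMDS <- function(d, k = 2, nStarts = 20, seed = 1) {
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 samples")
  if (n <= k + 1)
    warning("k close to sample count; stress is degenerate")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = nStarts, trymax = nStarts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  list(points = pts, stress = fit$stress, converged = fit$converges,
       seed = seed)
}

#' Distance-based redundancy analysis
#'
#' Principal-coordinate decomposition of \code{d} followed by redundancy
#' analysis on standardized predictors (vegan::dbrda). Negative eigenvalues
#' are dropped from the explained-variation ratio (no correction); the
#' permutation p-value comes from \code{anova.cca} with free row permutation.
#'
#' @param d a \code{dist} of dissimilarities.
#' @param predictors data.frame of sample-level predictors (rows in the same
#'   order as \code{d} labels).
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutation test.
#' @return list: \code{explainedFraction} (constrained / total inertia over
#'   positive eigenvalues), \code{pseudoF}, \code{pValue}, \code{nPerm},
#'   \code{negativeEigenvalues} (sum of dropped negative eigenvalues).
#' @export
runDbRDA <- function(d, predictors, nPerm = 999, seed = 1) {
  predictors <- as.data.frame(predictors)
  n <- attr(d, "Size")
  if (nrow(predictors) != n) stop("predictor rows must match samples")
  if (anyNA(predictors)) stop("predictors contain missing values")
  keep <- vapply(predictors, function(v) stats::sd(v) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping constant predictor(s): ",
            paste(names(predictors)[!keep], collapse = ", "))
    predictors <- predictors[, keep, drop = FALSE]
  }
  predictors <- as.data.frame(scale(predictors))
  fit <- vegan::dbrda(d ~ ., data = predictors)
  if (!is.null(fit$CCA$alias) && length(fit$CCA$alias))
    warning("collinear predictors aliased: ",
            paste(fit$CCA$alias, collapse = ", "))
  posTotal <- fit$CCA$tot.chi + fit$CA$tot.chi
  explained <- fit$CCA$tot.chi / posTotal
  set.seed(seed)
  an <- stats::anova(fit, permutations = nPerm)
  list(explainedFraction = explained,
       pseudoF = an$F[1],
       pValue = an[["Pr(>F)"]][1],
       nPerm = nPerm,
       negativeEigenvalues = sum(fit$CA$imaginary.chi %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Procrustes congruence test
#'
#' Optimal translation, rotation and symmetric scaling of configuration
#' \code{b} onto \code{a}; reports the residual m-squared (both
#' configurations scaled to unit total variance) and a permutation p-value
#' (PROTEST-style row permutation of \code{b}).
#'
#' @param a,b ordination results (as from \code{\link{runNMDS}}) or plain
#'   coordinate matrices with identical row sets and dimension.
#' @param nPerm permutations (default 999); with \code{nPerm = 0} only
#'   m-squared is computed and the p-value is \code{NA}.
#' @param seed integer seed.
#' @return list: \code{m2}, \code{pValue}, \code{nPerm}.
#' @export
procrustesTest <- function(a, b, nPerm = 999, seed = 1) {
  pts <- function(x) if (is.list(x) && !is.null(x$points)) x$points else
    as.matrix(x)
  A <- pts(a); B <- pts(b)
  if (!all(dim(A) == dim(B)))
    stop("configurations must share samples and dimension")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("configurations must cover the same samples in the same order")
  if (nPerm == 0) {
    fit <- vegan::procrustes(A, B, symmetric = TRUE)
    return(list(m2 = fit$ss, pValue = NA_real_, nPerm = 0))
  }
  set.seed(seed)
  fit <- vegan::protest(A, B, permutations = nPerm)
  list(m2 = fit$ss, pValue = fit$signif, nPerm = nPerm)
}

#' Write a distance matrix as CSV
#'
#' @param d a \code{dist}.
#' @param path output file.
#' @export
writeDistanceMatrix <- function(d, path) {
  m <- as.matrix(d)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}
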