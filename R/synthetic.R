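## Synthetic-data generator with known ground truth.
##
## The generator emulates the study design the downstream statistics expect:
## two chemical endmembers (a Baltic-like surface water and an old
## saline groundwater) mixed along a per-sample fraction, a shared
## terrigenous formula core present in every sample, multiplicative
## lognormal intensity noise, sub-ppm mass error, contaminant peaks,
## 13C isotopologues, hydrochemistry affine in the mixing fraction, and
## planted MF-ASV association modules that share a latent log-scale factor.
## All randomness flows through explicit integer seeds.

.CHEM_VARS <- c("na", "k", "ca", "mg", "d18o", "d2h", "so4", "cl")

#' Endmember specification
#'
#' @param name label.
#' @param formulas formula table (see \code{\link{molecularFormula}}).
#' @param intensities relative intensity per formula; must be non-negative
#'   and sum to 1 (within 1e-9).
#' @param chem named numeric vector over the eight hydrochemistry variables
#'   (na, k, ca, mg, d18o, d2h, so4, cl).
#' @param docMgL DOC concentration in mg/L.
#' @return list of class \code{"EndmemberSpec"}.
#' @export
endmemberSpec <- function(name, formulas, intensities, chem, docMgL) {
  if (!nrow(formulas)) stop("empty formula pool for endmember ", name)
  if (length(intensities) != nrow(formulas))
    stop("intensity profile length mismatch")
  if (any(intensities < 0) || abs(sum(intensities) - 1) > 1e-9)
    stop("intensity profile must be non-negative and sum to 1")
  missing <- setdiff(.CHEM_VARS, names(chem))
  if (length(missing))
    stop("chem profile lacks: ", paste(missing, collapse = ", "))
  structure(list(name = name, formulas = formulas,
                 intensities = intensities, chem = chem[.CHEM_VARS],
                 docMgL = docMgL),
            class = "EndmemberSpec")
}

#' Planted MF-ASV association module
#'
#' @param moduleId integer module label.
#' @param mfMembers,asvMembers character ids of member features; member sets
#'   must be disjoint across modules.
#' @param latentStrength multiplicative factor on the shared log-scale
#'   latent variable; 0 means no association.
#' @return list of class \code{"PlantedAssociation"}.
#' @export
plantedAssociation <- function(moduleId, mfMembers, asvMembers,
                               latentStrength = 1) {
  stopifnot(latentStrength >= 0)
  structure(list(moduleId = as.integer(moduleId),
                 mfMembers = as.character(mfMembers),
                 asvMembers = as.character(asvMembers),
                 latentStrength = latentStrength),
            class = "PlantedAssociation")
}

## draw one chemically valid formula inside a van Krevelen class region
.sampleFormulaInClass <- function(className, maxTries = 2000) {
  b <- .VK_CLASSES[.VK_CLASSES$class == className, ]
  if (!nrow(b)) stop("unknown compound class: ", className)
  eps <- 1e-3
  for (try in seq_len(maxTries)) {
    c <- sample(8:36, 1)
    oc <- stats::runif(1, b$oc_lo + if (b$oc_lo_open) eps else 0,
                       b$oc_hi - if (b$oc_hi_open) eps else 0)
    hc <- stats::runif(1, b$hc_lo + if (b$hc_lo_open) eps else 0,
                       b$hc_hi - if (b$hc_hi_open) eps else 0)
    o <- round(oc * c)
    h <- round(hc * c)
    ## fix hydrogen parity so DBE is an integer (no heteroatoms here)
    for (hh in c(h, h + 1, h - 1)) {
      cand <- data.frame(c = c, h = hh, n = 0L, o = o, s = 0L, p = 0L)
      if (hh < 1) next
      if (!isValidFormula(cand)) next
      if (compoundClass(cand) != className) next
      return(cand)
    }
  }
  stop("no valid formula found for class '", className,
       "' within the element bounds")
}

#' Generate a library of molecular formulas by compound class
#'
#' Draws chemically valid CHO formulas whose O/C and H/C ratios fall inside
#' the requested van Krevelen class regions. Deterministic for a fixed seed.
#'
#' @param nPerClass named integer vector (names = class labels, see
#'   \code{\link{compoundClassBoundaries}}) or a single count applied to all
#'   seven classes.
#' @param seed integer seed.
#' @return formula table with a \code{class} column; empty request yields an
#'   empty table.
#' @export
generateFormulaLibrary <- function(nPerClass, seed = 1) {
  if (is.null(names(nPerClass))) {
    if (length(nPerClass) != 1)
      stop("nPerClass must be named or a single count")
    nPerClass <- stats::setNames(rep(nPerClass, nrow(.VK_CLASSES)),
                                 .VK_CLASSES$class)
  }
  unknown <- setdiff(names(nPerClass), .VK_CLASSES$class)
  if (length(unknown))
    stop("unknown class(es): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  rows <- list()
  for (cl in names(nPerClass)) {
    got <- list()
    seen <- character(0)
    guard <- 0
    while (length(got) < nPerClass[[cl]]) {
      f <- .sampleFormulaInClass(cl)
      key <- formulaString(f)
      if (!key %in% seen) {
        seen <- c(seen, key)
        got[[length(got) + 1L]] <- f
      }
      guard <- guard + 1
      if (guard > 50 * max(nPerClass[[cl]], 1))
        stop("cannot draw ", nPerClass[[cl]], " distinct formulas for ",
             "class '", cl, "'")
    }
    if (length(got)) {
      block <- do.call(rbind, got)
      block$class <- cl
      rows[[cl]] <- block
    }
  }
  if (!length(rows)) {
    out <- molecularFormula(1, 2)[0, ]
    out$class <- character(0)
    return(out)
  }
  counts <- do.call(rbind, rows)
  out <- molecularFormula(counts$c, counts$h, counts$n, counts$o,
                          counts$s, counts$p)
  out$class <- counts$class
  rownames(out) <- NULL
  out
}

#' Generate per-sample peak lists along a two-endmember mixing gradient
#'
#' Per sample, the true intensity of each formula is the mixing-weighted
#' combination of the two endmember profiles; observed intensities carry
#' multiplicative lognormal noise of coefficient of variation
#' \code{noiseCv}, observed masses carry Gaussian ppm error (sd
#' \code{massErrorPpm}, truncated at 3 sd), hydrochemistry is affine in the
#' mixing fraction plus Gaussian noise. Optional contaminant peaks appear in
#' every sample and optional 13C isotopologues accompany every peak at
#' ratio 0.0107 x C.
#'
#' @param endmembers list of two \code{\link{endmemberSpec}} objects.
#' @param mixingFractions numeric vector in [0, 1]: fraction of endmember 1
#'   per sample.
#' @param massErrorPpm mass-error spread in ppm (default 0.25; observed
#'   deviations stay within 3 x this value).
#' @param noiseCv relative intensity noise (default 0.1).
#' @param contaminants optional formula table of contaminant peaks.
#' @param addIsotopologues add 13C companion peaks (default FALSE).
#' @param chemNoiseSd relative sd of hydrochemistry noise (default 0.02).
#' @param mode \code{"neg"}: emit [M-H]- ion m/z (neutral mass minus a
#'   proton); \code{"neutral"}: emit neutral masses.
#' @param snFloorFraction the synthetic noise floor as a fraction of the
#'   smallest true intensity, used to fill the \code{sn} column
#'   (default 0.2, so every true peak has sn >= 5).
#' @param seed integer seed.
#' @return list: \code{peakLists} (named list of peak-list data frames),
#'   \code{chemistry} (sample x variable data.frame including \code{doc}),
#'   \code{truth} (list: \code{formulas}, \code{intensities} feature x
#'   sample matrix of true mixed intensities, \code{mixingFractions}).
#' @export
generateSamplePeakLists <- function(endmembers, mixingFractions,
                                    massErrorPpm = 0.25, noiseCv = 0.1,
                                    contaminants = NULL,
                                    addIsotopologues = FALSE,
                                    chemNoiseSd = 0.02,
                                    mode = c("neg", "neutral"),
                                    snFloorFraction = 0.2, seed = 1) {
  stopifnot(length(endmembers) == 2,
            all(mixingFractions >= 0 & mixingFractions <= 1))
  mode <- match.arg(mode)
  emA <- endmembers[[1]]; emB <- endmembers[[2]]
  set.seed(seed)
  pool <- rbind(emA$formulas[, c(.ELEMENTS)], emB$formulas[, c(.ELEMENTS)])
  pool <- pool[!duplicated(formulaString(pool)), , drop = FALSE]
  pool <- molecularFormula(pool$c, pool$h, pool$n, pool$o, pool$s, pool$p)
  pool <- pool[order(pool$mass), ]
  rownames(pool) <- NULL
  key <- pool$formula
  wA <- stats::setNames(rep(0, nrow(pool)), key)
  wB <- wA
  wA[emA$formulas$formula] <- emA$intensities
  wB[emB$formulas$formula] <- emB$intensities
  nS <- length(mixingFractions)
  sampleNames <- sprintf("S%02d", seq_len(nS))
  truth <- outer(wA, mixingFractions) + outer(wB, 1 - mixingFractions)
  colnames(truth) <- sampleNames
  sdlog <- sqrt(log(1 + noiseCv^2))
  minTruth <- min(truth[truth > 0])
  noiseFloor <- snFloorFraction * minTruth
  peakLists <- list()
  for (j in seq_len(nS)) {
    present <- truth[, j] > 0
    mz <- pool$mass[present]
    intensity <- truth[present, j]
    carbon <- pool$c[present]
    if (noiseCv > 0)
      intensity <- intensity *
        stats::rlnorm(length(intensity), -sdlog^2 / 2, sdlog)
    if (!is.null(contaminants) && nrow(contaminants)) {
      mz <- c(mz, contaminants$mass)
      intensity <- c(intensity, rep(stats::median(truth[present, j]),
                                    nrow(contaminants)))
      carbon <- c(carbon, contaminants$c)
    }
    if (addIsotopologues) {
      isoMz <- mz + .ISOTOPE_SHIFT[["c13"]]
      isoInt <- intensity * .ISOTOPE_RATIO[["c13"]] * carbon
      mz <- c(mz, isoMz)
      intensity <- c(intensity, isoInt)
    }
    if (massErrorPpm > 0) {
      err <- stats::rnorm(length(mz), 0, massErrorPpm)
      err <- pmin(pmax(err, -3 * massErrorPpm), 3 * massErrorPpm)
      mz <- mz * (1 + err * 1e-6)
    }
    if (mode == "neg") mz <- mz - .PROTON_MASS
    pl <- peakList(mz, intensity, sn = intensity / noiseFloor,
                   sampleId = sampleNames[j])
    peakLists[[sampleNames[j]]] <- pl
  }
  chem <- vapply(.CHEM_VARS, function(v) {
    base <- mixingFractions * emA$chem[[v]] +
      (1 - mixingFractions) * emB$chem[[v]]
    if (chemNoiseSd > 0)
      base <- base + stats::rnorm(nS, 0, chemNoiseSd * max(abs(base), 1e-9))
    base
  }, numeric(nS))
  chem <- as.data.frame(matrix(chem, nrow = nS,
                               dimnames = list(sampleNames, .CHEM_VARS)))
  chem$doc <- mixingFractions * emA$docMgL +
    (1 - mixingFractions) * emB$docMgL
  chem <- cbind(sample = sampleNames, chem)
  rownames(chem) <- NULL
  list(peakLists = peakLists, chemistry = chem,
       truth = list(formulas = pool, intensities = truth,
                    mixingFractions = stats::setNames(mixingFractions,
                                                      sampleNames)))
}

.RANK_POOL <- list(
  domain = "Bacteria",
  phylum = c("Patescibacteria", "Proteobacteria", "Desulfobacterota",
             "Campylobacterota", "Chloroflexota"),
  class = c("Paceibacteria", "Gammaproteobacteria", "Desulfobacteria",
            "Campylobacteria", "Anaerolineae"))

.makeTaxonomy <- function(n) {
  phyla <- sample(.RANK_POOL$phylum, n, replace = TRUE)
  cls <- sample(.RANK_POOL$class, n, replace = TRUE)
  paste("Bacteria", phyla, cls,
        paste0("o__", seq_len(n)), paste0("f__", seq_len(n)),
        paste0("g__", seq_len(n)), paste0("s__", seq_len(n)), sep = ";")
}

#' Generate an ASV relative-abundance table with planted associations
#'
#' Log abundances are a per-ASV baseline plus, for planted module members,
#' \code{latentStrength} times a shared standard-normal latent factor per
#' module and sample, plus Gaussian noise; columns are closed to sum 1.
#' When \code{mfMatrix} is supplied, its rows named in the planted modules
#' receive the same latent factors (and the matrix is re-closed), so that
#' member MF-ASV pairs are proportional on the clr scale as
#' \code{latentStrength} grows.
#'
#' @param nAsvs number of ASVs.
#' @param nSamples number of samples (must match \code{mfMatrix} columns
#'   when given).
#' @param planted list of \code{\link{plantedAssociation}} objects; ASV
#'   member ids must be of the form \code{"ASV<i>"} with i <= nAsvs.
#' @param noiseSd sd of the log-scale noise (default 0.3).
#' @param mfMatrix optional features x samples matrix whose planted MF
#'   members get the shared latent factors.
#' @param seed integer seed.
#' @return list: \code{asv} (relative-abundance matrix with rownames
#'   ASV1..), \code{taxonomy} (character vector, 7 semicolon-separated
#'   ranks), \code{mf} (modified MF matrix or NULL), \code{truthLinks}
#'   (data.frame of planted MF-ASV pairs with module ids), \code{membership}
#'   (named module id per planted feature).
#' @export
generateAsvTable <- function(nAsvs, nSamples, planted = list(),
                             noiseSd = 0.3, mfMatrix = NULL, seed = 1) {
  set.seed(seed)
  asvIds <- paste0("ASV", seq_len(nAsvs))
  allMembers <- unlist(lapply(planted, function(p)
    c(p$mfMembers, p$asvMembers)))
  if (anyDuplicated(allMembers))
    stop("planted member sets must be disjoint across modules")
  for (p in planted) {
    bad <- setdiff(p$asvMembers, asvIds)
    if (length(bad))
      stop("unknown ASV id(s) in module ", p$moduleId, ": ",
           paste(bad, collapse = ", "))
    if (!is.null(mfMatrix)) {
      bad <- setdiff(p$mfMembers, rownames(mfMatrix))
      if (length(bad))
        stop("unknown MF id(s) in module ", p$moduleId, ": ",
             paste(bad, collapse = ", "))
    }
  }
  if (!is.null(mfMatrix) && ncol(mfMatrix) != nSamples)
    stop("mfMatrix column count must equal nSamples")
  base <- stats::rnorm(nAsvs, 0, 1)
  logA <- matrix(base, nAsvs, nSamples) +
    matrix(stats::rnorm(nAsvs * nSamples, 0, noiseSd), nAsvs)
  rownames(logA) <- asvIds
  latent <- lapply(planted, function(p)
    stats::rnorm(nSamples))
  names(latent) <- vapply(planted, function(p) as.character(p$moduleId),
                          character(1))
  membership <- integer(0)
  for (k in seq_along(planted)) {
    p <- planted[[k]]
    shift <- p$latentStrength * latent[[k]]
    for (a in p$asvMembers)
      logA[a, ] <- logA[a, ] + shift
    membership[c(p$mfMembers, p$asvMembers)] <- p$moduleId
  }
  asv <- exp(logA)
  asv <- sweep(asv, 2, colSums(asv), "/")
  colnames(asv) <- sprintf("S%02d", seq_len(nSamples))
  mfOut <- NULL
  if (!is.null(mfMatrix)) {
    logM <- log(pmax(mfMatrix, .Machine$double.xmin))
    for (k in seq_along(planted)) {
      p <- planted[[k]]
      shift <- p$latentStrength * latent[[k]]
      for (f in p$mfMembers)
        logM[f, ] <- logM[f, ] + shift
    }
    mfOut <- exp(logM)
    mfOut[mfMatrix == 0] <- 0
    mfOut <- sweep(mfOut, 2, colSums(mfOut), "/")
    colnames(mfOut) <- colnames(asv)
  }
  links <- do.call(rbind, lapply(planted, function(p) {
    if (!length(p$mfMembers) || !length(p$asvMembers)) return(NULL)
    expand.grid(mf = p$mfMembers, asv = p$asvMembers,
                stringsAsFactors = FALSE)[, 1:2] |>
      cbind(module = p$moduleId)
  }))
  list(asv = asv, taxonomy = stats::setNames(.makeTaxonomy(nAsvs), asvIds),
       mf = mfOut, truthLinks = links, membership = membership)
}

#' Generate a paired MF/ASV dataset with planted modules
#'
#' Convenience wrapper around \code{\link{generateAsvTable}} that also
#' simulates the background MF matrix: planted modules of
#' \code{mfPerModule} formulas and \code{asvPerModule} ASVs share latent
#' log-scale factors of the given strength.
#'
#' @param nMfs,nAsvs total feature counts.
#' @param nSamples number of samples.
#' @param nModules number of planted modules.
#' @param mfPerModule,asvPerModule members per module.
#' @param latentStrength shared-factor strength (0 = null data).
#' @param noiseSd log-scale noise sd.
#' @param seed integer seed.
#' @return list: \code{mf}, \code{asv} (relative matrices), \code{taxonomy},
#'   \code{planted}, \code{truthLinks}, \code{membership}.
#' @export
generateInterdomainData <- function(nMfs = 60, nAsvs = 30, nSamples = 10,
                                    nModules = 10, mfPerModule = 4,
                                    asvPerModule = 2, latentStrength = 2,
                                    noiseSd = 0.1, seed = 1) {
  stopifnot(nModules * mfPerModule <= nMfs,
            nModules * asvPerModule <= nAsvs)
  set.seed(seed)
  mfIds <- paste0("MF", seq_len(nMfs))
  asvIds <- paste0("ASV", seq_len(nAsvs))
  baseMf <- exp(matrix(stats::rnorm(nMfs, 0, 1), nMfs, nSamples) +
                  matrix(stats::rnorm(nMfs * nSamples, 0, noiseSd), nMfs))
  rownames(baseMf) <- mfIds
  colnames(baseMf) <- sprintf("S%02d", seq_len(nSamples))
  planted <- lapply(seq_len(nModules), function(m) {
    plantedAssociation(
      m,
      mfIds[((m - 1) * mfPerModule + 1):(m * mfPerModule)],
      asvIds[((m - 1) * asvPerModule + 1):(m * asvPerModule)],
      latentStrength)
  })
  out <- generateAsvTable(nAsvs, nSamples, planted, noiseSd = noiseSd,
                          mfMatrix = baseMf, seed = seed + 1)
  list(mf = out$mf, asv = out$asv, taxonomy = out$taxonomy,
       planted = planted, truthLinks = out$truthLinks,
       membership = out$membership)
}

#' Write synthetic outputs to disk
#'
#' Peak lists as per-sample CSV (mz, intensity, sn), the ASV table as TSV
#' (rows = ASVs, one column per sample, final \code{taxonomy} column with 7
#' semicolon-separated ranks), chemistry as CSV keyed by sample id, and
#' ground truth as JSON.
#'
#' @param sim output of \code{\link{generateSamplePeakLists}}.
#' @param dir output directory (created if needed).
#' @param asvSim optional output of \code{\link{generateAsvTable}} /
#'   \code{\link{generateInterdomainData}}.
#' @return the directory, invisibly.
#' @export
writeSyntheticData <- function(sim, dir, asvSim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(sim$peakLists))
    utils::write.csv(sim$peakLists[[sid]],
                     file.path(dir, paste0("peaks_", sid, ".csv")),
                     row.names = FALSE)
  utils::write.csv(sim$chemistry, file.path(dir, "chemistry.csv"),
                   row.names = FALSE)
  truth <- list(
    formulas = sim$truth$formulas$formula,
    mixingFractions = as.list(sim$truth$mixingFractions))
  if (!is.null(asvSim)) {
    df <- data.frame(asv = rownames(asvSim$asv), asvSim$asv,
                     taxonomy = asvSim$taxonomy[rownames(asvSim$asv)],
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, "asv_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(asvSim$truthLinks))
      truth$links <- asvSim$truthLinks
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
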