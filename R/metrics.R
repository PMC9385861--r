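## DOM molecular descriptors: modified aromaticity index, van Krevelen
## compound classes, intensity-weighted elemental ratios, the molecular
## lability boundary fraction MLB_w and the AbioS contribution.

## van Krevelen class regions. Bounds are (value, open?) pairs: lo/hi on O/C
## and H/C; *_open = TRUE means a strict inequality at that edge.
.VK_CLASSES <- data.frame(
  class = c("unsaturated oxygen-poor", "unsaturated",
            "amino sugar- and carbohydrate-like",
            "unsaturated hydrocarbon-like", "condensed aromatics",
            "lignin-like", "tannin-like"),
  oc_lo = c(0, 0.29, 0.60, 0, 0, 0.29, 0.65),
  oc_lo_open = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
  oc_hi = c(0.29, 0.60, 1.20, 0.29, 0.40, 0.65, 1.20),
  oc_hi_open = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  hc_lo = c(1.6, 1.5, 1.5, 1.0, 0, 0.7, 0.5),
  hc_lo_open = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
  hc_hi = c(2.5, 2.5, 2.5, 1.6, 0.7, 1.5, 1.5),
  hc_hi_open = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' van Krevelen compound-class boundaries
#'
#' @return data.frame of the seven class regions with their O/C and H/C
#'   bounds (columns \code{*_open} mark strict inequalities).
#' @export
compoundClassBoundaries <- function() .VK_CLASSES

#' Modified aromaticity index (AI_mod)
#'
#' \deqn{AI_{mod} = \frac{1 + C - 0.5 O - S - 0.5 (H + N + P)}
#'                       {C - 0.5 O - N - S - P}}
#' Negative values and degenerate denominators (<= 0) are clamped to 0.
#'
#' @param formula formula table (columns \code{c,h,n,o,s,p}).
#' @return numeric vector in [0, Inf) (typically [0, 1]).
#' @examples
#' aiMod(molecularFormula(6, 6))   # benzene: 2/3
#' @export
aiMod <- function(formula) {
  num <- 1 + formula$c - 0.5 * formula$o - formula$s -
    0.5 * (formula$h + formula$n + formula$p)
  den <- formula$c - 0.5 * formula$o - formula$n - formula$s - formula$p
  out <- ifelse(den <= 0 | num < 0, 0, num / den)
  out
}

#' Assign van Krevelen compound classes
#'
#' Classifies formulas by their O/C and H/C ratios into the seven regions
#' returned by \code{\link{compoundClassBoundaries}}. A point matching zero
#' regions, or more than one (the regions overlap at some edges), is labelled
#' \code{"unclassified"}.
#'
#' @param formula formula table, or \code{NULL} when \code{oc}/\code{hc} are
#'   given directly.
#' @param oc,hc optional numeric vectors of O/C and H/C ratios.
#' @return character vector of class labels.
#' @export
compoundClass <- function(formula = NULL, oc = NULL, hc = NULL) {
  if (!is.null(formula)) {
    oc <- formula$o / formula$c
    hc <- formula$h / formula$c
  }
  stopifnot(length(oc) == length(hc))
  hits <- matrix(FALSE, length(oc), nrow(.VK_CLASSES))
  for (j in seq_len(nrow(.VK_CLASSES))) {
    b <- .VK_CLASSES[j, ]
    inOc <- (if (b$oc_lo_open) oc > b$oc_lo else oc >= b$oc_lo) &
      (if (b$oc_hi_open) oc < b$oc_hi else oc <= b$oc_hi)
    inHc <- (if (b$hc_lo_open) hc > b$hc_lo else hc >= b$hc_lo) &
      (if (b$hc_hi_open) hc < b$hc_hi else hc <= b$hc_hi)
    hits[, j] <- inOc & inHc
  }
  nHit <- rowSums(hits)
  out <- rep("unclassified", length(oc))
  one <- nHit == 1
  out[one] <- .VK_CLASSES$class[apply(hits[one, , drop = FALSE], 1,
                                      which)]
  out
}

#' Intensity-weighted per-sample DOM summary
#'
#' For each sample, computes intensity-weighted elemental ratios (H/C_MF,
#' O/C_MF, N/C_MF, S/C_MF, P/C_MF), the weighted mean mass (mz_MF), the
#' weighted aromaticity AI_mod_w, the molecular lability fraction MLB_w
#' (summed weight of formulas with H/C above 1.5), the percentage of
#' intensity on AbioS-listed formulas, and the intensity fraction per
#' compound class. Weights are relative intensities renormalized over
#' annotated (non-isotopologue) features.
#'
#' @param x an \code{\link{AnnotatedMatrix}}.
#' @param samples sample ids (default: all).
#' @param abiosList optional formula table (or character vector of Hill
#'   strings) of sulfur-bearing reference formulas diagnostic of abiotic
#'   sulfurization; the package ships no list, supply a published one.
#' @param mlbBoundary H/C boundary for MLB_w (default 1.5, strict ">").
#' @return data.frame, one row per sample: \code{hc_mf, oc_mf, nc_mf, sc_mf,
#'   pc_mf, mz_mf, ai_mod_w, mlb_w, abios_pct} and one \code{frac_<class>}
#'   column per compound class (including unclassified).
#' @export
weightedSampleSummary <- function(x, samples = sampleIds(x),
                                  abiosList = NULL, mlbBoundary = 1.5) {
  rd <- formulaData(x)
  keep <- rd$assigned
  if ("isotopologue" %in% colnames(rd)) keep <- keep & !rd$isotopologue
  rd <- rd[keep, , drop = FALSE]
  y <- intensityMatrix(x)[keep, , drop = FALSE]
  if (!nrow(rd)) stop("no annotated features")
  ai <- aiMod(rd)
  cls <- compoundClass(rd)
  classLevels <- c(.VK_CLASSES$class, "unclassified")
  abios <- character(0)
  if (!is.null(abiosList))
    abios <- if (is.data.frame(abiosList)) abiosList$formula
             else as.character(abiosList)
  rows <- lapply(samples, function(s) {
    w <- y[, s]
    tot <- sum(w)
    if (tot <= 0) stop("sample ", s, " has zero annotated intensity")
    w <- w / tot
    cf <- vapply(classLevels, function(cl) sum(w[cls == cl]), numeric(1))
    out <- data.frame(
      sample = s,
      hc_mf = sum(w * rd$hc), oc_mf = sum(w * rd$oc),
      nc_mf = sum(w * rd$nc), sc_mf = sum(w * rd$sc),
      pc_mf = sum(w * rd$pc),
      mz_mf = sum(w * rd$mz),
      ai_mod_w = sum(w * ai),
      mlb_w = sum(w[rd$hc > mlbBoundary]),
      abios_pct = 100 * sum(w[rd$formula %in% abios]))
    cf <- as.data.frame(as.list(cf))
    names(cf) <- paste0("frac_", gsub("[^a-z0-9]+", "_",
                                      tolower(classLevels)))
    cbind(out, cf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-wise contrasts of a DOM metric
#'
#' Mean and standard deviation of a chosen per-sample metric per group of
#' samples (e.g. water type), supporting contrasts such as S/C_MF in anoxic
#' groundwaters versus surface water.
#'
#' @param x an \code{\link{AnnotatedMatrix}}.
#' @param groups named character vector mapping sample id to group.
#' @param metric column of \code{\link{weightedSampleSummary}} output, e.g.
#'   \code{"sc_mf"} or \code{"mlb_w"}.
#' @param ... passed to \code{weightedSampleSummary}.
#' @return data.frame: group, n, mean, sd.
#' @export
groupContrast <- function(x, groups, metric, ...) {
  summ <- weightedSampleSummary(x, samples = names(groups), ...)
  if (!metric %in% colnames(summ))
    stop("unknown metric: ", metric)
  vals <- summ[[metric]]
  out <- lapply(unique(groups), function(g) {
    v <- vals[groups[summ$sample] == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Attach per-formula metrics to an annotated matrix
#'
#' Adds \code{ai_mod} and \code{class} columns to the rowData.
#'
#' @param x an \code{\link{AnnotatedMatrix}}.
#' @return the matrix with extended rowData.
#' @export
addFormulaMetrics <- function(x) {
  rd <- formulaData(x)
  ai <- rep(NA_real_, nrow(rd))
  cls <- rep(NA_character_, nrow(rd))
  idx <- which(rd$assigned)
  if (length(idx)) {
    ai[idx] <- aiMod(rd[idx, ])
    cls[idx] <- compoundClass(rd[idx, ])
  }
  rowData(x)$ai_mod <- ai
  rowData(x)$class <- cls
  x
}
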