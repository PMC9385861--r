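## Elemental arithmetic for CHNOSP molecular formulas.
##
## Formulas are represented throughout the package as plain data frames with
## integer columns c, h, n, o, s, p; derived quantities (monoisotopic mass,
## DBE, elemental ratios) are attached by molecularFormula(). Keeping the
## representation columnar makes formula tables directly usable as rowData of
## the SummarizedExperiment-based containers.

## Monoisotopic masses (Da), 12C scale.
.ATOMIC_MASS <- c(
  c = 12,
  h = 1.00782503207,
  n = 14.0030740048,
  o = 15.9949146196,
  s = 31.97207100,
  p = 30.97376163
)

## Mass of a proton; converts [M-H]- ion m/z to neutral mass.
.PROTON_MASS <- 1.00727646

## Isotopologue mass shifts (Da) and per-atom intensity ratios relative to
## the monoisotopic peak.
.ISOTOPE_SHIFT <- c(c13 = 1.0033548, n15 = 0.9970349, s34 = 1.9957959)
.ISOTOPE_RATIO <- c(c13 = 0.0107, n15 = 0.00364, s34 = 0.0442)

## Element count limits used for formula assignment.
.ELEMENT_LIMITS <- list(
  c = c(1L, 100L), h = c(1L, 100L), o = c(0L, 70L),
  n = c(0L, 4L), s = c(0L, 2L), p = c(0L, 1L)
)

.ELEMENTS <- c("c", "h", "n", "o", "s", "p")

#' Construct a table of molecular formulas
#'
#' Builds a validated formula table from element counts and attaches the
#' derived quantities used throughout the package: monoisotopic neutral mass,
#' double-bond equivalents (DBE) and elemental ratios relative to carbon.
#'
#' @param c,h,n,o,s,p integer vectors of element counts (recycled).
#' @param strict if \code{TRUE} (default), element counts outside the
#'   assignment limits C1-100 H1-100 O0-70 N0-4 S0-2 P0-1, non-integer or
#'   negative DBE raise an error; if \code{FALSE} such rows are kept and can
#'   be inspected with \code{\link{isValidFormula}}.
#' @return a \code{data.frame} with columns \code{c,h,n,o,s,p}, \code{mass}
#'   (Da), \code{dbe}, \code{hc}, \code{oc}, \code{nc}, \code{sc}, \code{pc}
#'   and \code{formula} (Hill notation).
#' @examples
#' molecularFormula(c = 16, h = 32, o = 2)   # palmitic acid, 256.24 Da
#' @export
molecularFormula <- function(c, h, n = 0L, o = 0L, s = 0L, p = 0L,
                             strict = TRUE) {
  counts <- data.frame(c = as.integer(c), h = as.integer(h),
                       n = as.integer(n), o = as.integer(o),
                       s = as.integer(s), p = as.integer(p))
  if (any(rowSums(counts) == 0))
    stop("formula with all element counts zero")
  if (strict) {
    bad <- !isValidFormula(counts)
    if (any(bad))
      stop("invalid formula at row(s): ", paste(which(bad), collapse = ", "))
  }
  counts$mass <- exactMass(counts)
  counts$dbe <- dbe(counts)
  counts$hc <- counts$h / counts$c
  counts$oc <- counts$o / counts$c
  counts$nc <- counts$n / counts$c
  counts$sc <- counts$s / counts$c
  counts$pc <- counts$p / counts$c
  counts$formula <- formulaString(counts)
  counts
}

#' Monoisotopic neutral mass of a formula
#'
#' @param formula data.frame with columns \code{c,h,n,o,s,p}.
#' @return numeric vector of masses in Da.
#' @export
exactMass <- function(formula) {
  m <- rep(0, nrow(formula))
  for (el in .ELEMENTS) m <- m + formula[[el]] * .ATOMIC_MASS[[el]]
  if (any(m <= 0)) stop("formula with non-positive mass")
  m
}

#' Double-bond equivalents
#'
#' DBE = 1 + C - H/2 + (N + P)/2; counts rings plus pi bonds. Formulas with
#' negative or non-integer DBE are chemically invalid.
#'
#' @inheritParams exactMass
#' @return numeric vector (integer-valued for valid formulas).
#' @export
dbe <- function(formula) {
  1 + formula$c - formula$h / 2 + (formula$n + formula$p) / 2
}

#' Check chemical validity of formula rows
#'
#' A row is valid when every element count lies within the assignment limits
#' (C1-100, H1-100, O0-70, N0-4, S0-2, P0-1), DBE is a non-negative integer,
#' and (optionally) O does not exceed C + 2.
#'
#' @inheritParams exactMass
#' @param oxygenCap apply the O <= C + 2 sanity cap (default \code{TRUE}).
#' @return logical vector.
#' @export
isValidFormula <- function(formula, oxygenCap = TRUE) {
  ok <- rep(TRUE, nrow(formula))
  for (el in .ELEMENTS) {
    lim <- .ELEMENT_LIMITS[[el]]
    ok <- ok & formula[[el]] >= lim[1] & formula[[el]] <= lim[2]
  }
  d <- dbe(formula)
  ok <- ok & d >= 0 & abs(d - round(d)) < 1e-9
  if (oxygenCap) ok <- ok & formula$o <= formula$c + 2
  ok
}

#' Hill-notation formula strings
#'
#' @inheritParams exactMass
#' @return character vector, e.g. \code{"C16H32O2"}.
#' @export
formulaString <- function(formula) {
  hill <- c("c", "h", "n", "o", "p", "s")  # C, H, then alphabetical
  sym <- c(c = "C", h = "H", n = "N", o = "O", p = "P", s = "S")
  out <- character(nrow(formula))
  for (el in hill) {
    cnt <- formula[[el]]
    piece <- ifelse(cnt == 0, "",
                    ifelse(cnt == 1, sym[[el]], paste0(sym[[el]], cnt)))
    out <- paste0(out, piece)
  }
  out
}

#' Parse formula strings into element counts
#'
#' Accepts Hill-style strings over the elements C, H, N, O, S, P
#' (e.g. \code{"C10H15NO2S"}).
#'
#' @param x character vector.
#' @return formula table as from \code{\link{molecularFormula}}.
#' @export
parseFormula <- function(x) {
  counts <- matrix(0L, nrow = length(x), ncol = 6,
                   dimnames = list(NULL, .ELEMENTS))
  for (i in seq_along(x)) {
    tokens <- regmatches(x[i], gregexpr("[A-Z][a-z]?[0-9]*", x[i]))[[1]]
    if (!length(tokens) || nchar(paste(tokens, collapse = "")) != nchar(x[i]))
      stop("cannot parse formula string: ", x[i])
    for (tok in tokens) {
      el <- tolower(gsub("[0-9]", "", tok))
      if (!el %in% .ELEMENTS)
        stop("unsupported element '", el, "' in ", x[i])
      num <- gsub("[A-Za-z]", "", tok)
      counts[i, el] <- counts[i, el] + if (nzchar(num)) as.integer(num) else 1L
    }
  }
  counts <- as.data.frame(counts)
  molecularFormula(counts$c, counts$h, counts$n, counts$o, counts$s, counts$p)
}
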