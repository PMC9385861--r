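## CHNOSP molecular formula assignment for aligned neutral masses.
##
## The candidate search solves for the hydrogen count given each feasible
## (C, N, O, S, P) combination, which visits only formulas that can match the
## measured mass; bruteForceCandidates() enumerates the complete element grid
## instead and is used as an independent oracle on small problems.

#' Default contaminant formulas
#'
#' Four common surfactant-type contaminants (likely tubing-derived) that are
#' removed from annotated output: C16H32O2, C12H26O4S, C17H28O3S and
#' C10H15NO2S.
#'
#' @return formula table (see \code{\link{molecularFormula}}).
#' @export
defaultContaminants <- function() {
  parseFormula(c("C16H32O2", "C12H26O4S", "C17H28O3S", "C10H15NO2S"))
}

#' Assignment parameter set
#'
#' @param tolPpm mass tolerance in ppm for candidate matching (default 0.5).
#' @param mdl method detection limit applied to the signal-to-noise column
#'   when present, otherwise to intensity divided by the smallest observed
#'   intensity (default 3).
#' @param isotopeIntensityTol allowed relative deviation of an isotopologue
#'   intensity ratio from its theoretical value (default 0.5, i.e. 500 per
#'   mil).
#' @param contaminants formula table of contaminants removed from the
#'   annotated output (default \code{\link{defaultContaminants}}).
#' @param maxHetero maximum N + S + P; candidates above it are dropped unless
#'   the heteroatoms are nitrogen only (up to N4).
#' @param oxygenCap apply the O <= C + 2 sanity cap (default TRUE).
#' @param ionMode \code{"neg"}: measured m/z are [M-H]- ions and the neutral
#'   mass is m/z + 1.00727646; \code{"neutral"}: input masses are already
#'   neutral.
#' @param isotopeFailAction what to do with a candidate that fails
#'   isotopologue verification: \code{"demote"} (kept, ranked last, flagged)
#'   or \code{"remove"}.
#' @param maxMass upper mass limit for assignment (default 1000 Da); heavier
#'   features are retained unannotated.
#' @return a list of class \code{"AssignmentParams"}.
#' @export
assignmentParams <- function(tolPpm = 0.5, mdl = 3, isotopeIntensityTol = 0.5,
                             contaminants = defaultContaminants(),
                             maxHetero = 3, oxygenCap = TRUE,
                             ionMode = c("neg", "neutral"),
                             isotopeFailAction = c("demote", "remove"),
                             maxMass = 1000) {
  stopifnot(tolPpm > 0, mdl >= 0, isotopeIntensityTol >= 0)
  structure(list(tolPpm = tolPpm, mdl = mdl,
                 isotopeIntensityTol = isotopeIntensityTol,
                 contaminants = contaminants, maxHetero = maxHetero,
                 oxygenCap = oxygenCap, ionMode = match.arg(ionMode),
                 isotopeFailAction = match.arg(isotopeFailAction),
                 maxMass = maxMass),
            class = "AssignmentParams")
}

## order candidates: |ppm error|, then fewer heteroatoms, then fewer atoms
.orderCandidates <- function(cand) {
  cand[order(abs(cand$error_ppm),
             cand$n + cand$s + cand$p,
             cand$c + cand$h + cand$n + cand$o + cand$s + cand$p), ,
       drop = FALSE]
}

#' Enumerate formula candidates for a neutral mass
#'
#' Returns every chemically valid formula (element limits C1-100 H1-100
#' O0-70 N0-4 S0-2 P0-1, integer DBE >= 0, optional O <= C + 2) whose exact
#' mass lies within \code{tolPpm} of \code{neutralMass}, sorted by absolute
#' mass error (ties: fewer heteroatoms, then fewer atoms).
#'
#' @param neutralMass neutral monoisotopic mass in Da (0, 1000].
#' @param params an \code{\link{assignmentParams}} object.
#' @return formula table with an \code{error_ppm} column.
#' @export
enumerateCandidates <- function(neutralMass, params = assignmentParams()) {
  if (length(neutralMass) != 1 || is.na(neutralMass) || neutralMass <= 0)
    stop("neutralMass must be a single positive number")
  if (neutralMass > params$maxMass)
    stop("mass exceeds the assignment range (", params$maxMass, " Da)")
  tolDa <- params$tolPpm * 1e-6 * neutralMass
  mH <- .ATOMIC_MASS[["h"]]
  hetero <- expand.grid(n = 0:.ELEMENT_LIMITS$n[2],
                        s = 0:.ELEMENT_LIMITS$s[2],
                        p = 0:.ELEMENT_LIMITS$p[2])
  out <- vector("list", nrow(hetero))
  cMax <- min(.ELEMENT_LIMITS$c[2], floor(neutralMass / .ATOMIC_MASS[["c"]]))
  for (i in seq_len(nrow(hetero))) {
    n <- hetero$n[i]; s <- hetero$s[i]; p <- hetero$p[i]
    base <- n * .ATOMIC_MASS[["n"]] + s * .ATOMIC_MASS[["s"]] +
      p * .ATOMIC_MASS[["p"]]
    if (base > neutralMass + tolDa) next
    cs <- seq_len(max(cMax, 1))
    oMaxPer <- pmin(.ELEMENT_LIMITS$o[2],
                    if (params$oxygenCap) cs + 2L else Inf)
    grid <- data.frame(c = rep(cs, oMaxPer + 1L),
                       o = unlist(lapply(oMaxPer, function(m) 0:m)))
    rem <- neutralMass - base - grid$c * .ATOMIC_MASS[["c"]] -
      grid$o * .ATOMIC_MASS[["o"]]
    ## hydrogens must land within the mass window
    hLo <- ceiling((rem - tolDa) / mH)
    hHi <- floor((rem + tolDa) / mH)
    keep <- which(hHi >= hLo & hHi >= .ELEMENT_LIMITS$h[1] &
                    hLo <= .ELEMENT_LIMITS$h[2])
    if (!length(keep)) next
    rows <- lapply(keep, function(k) {
      h <- max(hLo[k], .ELEMENT_LIMITS$h[1]):min(hHi[k],
                                                 .ELEMENT_LIMITS$h[2])
      data.frame(c = grid$c[k], h = h, n = n, o = grid$o[k], s = s, p = p)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  cand <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(cand) || !nrow(cand)) return(.emptyCandidates())
  cand <- cand[isValidFormula(cand, oxygenCap = params$oxygenCap), ,
               drop = FALSE]
  if (!nrow(cand)) return(.emptyCandidates())
  cand <- molecularFormula(cand$c, cand$h, cand$n, cand$o, cand$s, cand$p)
  cand$error_ppm <- (cand$mass - neutralMass) / neutralMass * 1e6
  cand <- cand[abs(cand$error_ppm) <= params$tolPpm + 1e-12, , drop = FALSE]
  rownames(cand) <- NULL
  .orderCandidates(cand)
}

.emptyCandidates <- function() {
  out <- molecularFormula(1, 2)[0, ]
  out$error_ppm <- numeric(0)
  out
}

#' Exhaustive candidate enumeration (oracle)
#'
#' Enumerates the complete element-count grid inside the assignment limits,
#' computes every exact mass and filters by tolerance and validity. Slower
#' than \code{\link{enumerateCandidates}} but structurally independent of it;
#' used to validate the optimized search.
#'
#' @inheritParams enumerateCandidates
#' @return formula table with an \code{error_ppm} column.
#' @export
bruteForceCandidates <- function(neutralMass, params = assignmentParams()) {
  if (length(neutralMass) != 1 || is.na(neutralMass) || neutralMass <= 0)
    stop("neutralMass must be a single positive number")
  tolDa <- params$tolPpm * 1e-6 * neutralMass
  cMax <- min(.ELEMENT_LIMITS$c[2], floor((neutralMass + tolDa) / 12))
  hMax <- min(.ELEMENT_LIMITS$h[2],
              floor((neutralMass + tolDa) / .ATOMIC_MASS[["h"]]))
  oMax <- min(.ELEMENT_LIMITS$o[2],
              floor((neutralMass + tolDa) / .ATOMIC_MASS[["o"]]))
  hetero <- expand.grid(n = 0:.ELEMENT_LIMITS$n[2],
                        s = 0:.ELEMENT_LIMITS$s[2],
                        p = 0:.ELEMENT_LIMITS$p[2])
  pieces <- list()
  for (i in seq_len(nrow(hetero))) {
    grid <- expand.grid(c = 1:cMax, h = 1:hMax, o = 0:oMax)
    grid$n <- hetero$n[i]; grid$s <- hetero$s[i]; grid$p <- hetero$p[i]
    mass <- grid$c * .ATOMIC_MASS[["c"]] + grid$h * .ATOMIC_MASS[["h"]] +
      grid$n * .ATOMIC_MASS[["n"]] + grid$o * .ATOMIC_MASS[["o"]] +
      grid$s * .ATOMIC_MASS[["s"]] + grid$p * .ATOMIC_MASS[["p"]]
    hit <- abs(mass - neutralMass) <= tolDa
    if (any(hit)) pieces[[length(pieces) + 1L]] <- grid[hit, , drop = FALSE]
  }
  cand <- do.call(rbind, pieces)
  if (is.null(cand) || !nrow(cand)) return(.emptyCandidates())
  cand <- cand[isValidFormula(cand, oxygenCap = params$oxygenCap), ,
               drop = FALSE]
  if (!nrow(cand)) return(.emptyCandidates())
  cand <- molecularFormula(cand$c, cand$h, cand$n, cand$o, cand$s, cand$p)
  cand$error_ppm <- (cand$mass - neutralMass) / neutralMass * 1e6
  cand <- cand[abs(cand$error_ppm) <= params$tolPpm + 1e-12, , drop = FALSE]
  rownames(cand) <- NULL
  .orderCandidates(cand)
}

## heteroelement rule: N + S + P <= maxHetero, except pure-N formulas (N4 ok)
.heteroAllowed <- function(cand, maxHetero = 3) {
  (cand$n + cand$s + cand$p <= maxHetero) | (cand$s + cand$p == 0)
}

#' Verify a candidate formula against its isotopologue peaks
#'
#' For each heavy isotope whose light element is present in the candidate
#' (13C, and 15N / 34S when N or S > 0), looks for a companion feature at the
#' parent mass plus the isotopic mass shift (within \code{tolPpm}) and
#' compares its intensity ratio to the theoretical per-atom abundance
#' (0.0107 x C for 13C, 0.00364 x N, 0.0442 x S). The check fails when a
#' companion is present but its ratio deviates by more than
#' \code{isotopeIntensityTol} (relative), or when no companion exists even
#' though the expected companion intensity is above the detection floor.
#' Absence of a companion that would be undetectable is non-disqualifying.
#'
#' @param x an \code{\link{AlignedMatrix}} (neutral-mass scale).
#' @param feature row index of the parent feature.
#' @param candidate single-row formula table.
#' @param params an \code{\link{assignmentParams}} object.
#' @param neutralMass optional parent neutral masses corresponding to rows of
#'   \code{x} (defaults to the consensus masses).
#' @param detectionFloor smallest intensity considered observable (defaults
#'   to the smallest non-zero intensity in the matrix).
#' @return list with elements \code{pass} (logical) and \code{evidence}
#'   (data.frame, one row per isotope checked).
#' @export
verifyIsotopologue <- function(x, feature, candidate,
                               params = assignmentParams(),
                               neutralMass = NULL, detectionFloor = NULL) {
  y <- intensityMatrix(x)
  if (is.null(neutralMass)) neutralMass <- consensusMass(x)
  if (is.null(detectionFloor)) {
    nz <- y[y > 0]
    detectionFloor <- if (length(nz)) min(nz) else 0
  }
  parentMass <- neutralMass[feature]
  parentInt <- sum(y[feature, ])
  isoFor <- c(c13 = "c", n15 = "n", s34 = "s")
  rows <- list()
  pass <- TRUE
  for (iso in names(isoFor)) {
    count <- candidate[[isoFor[[iso]]]]
    if (count == 0) next
    expRatio <- .ISOTOPE_RATIO[[iso]] * count
    target <- parentMass + .ISOTOPE_SHIFT[[iso]]
    hit <- which(abs(neutralMass - target) / target * 1e6 <= params$tolPpm)
    status <- "absent_undetectable"; obsRatio <- NA_real_
    if (length(hit)) {
      ## companion ratio measured on samples where the parent is present
      hit <- hit[which.min(abs(neutralMass[hit] - target))]
      present <- y[feature, ] > 0
      obsRatio <- sum(y[hit, present]) / sum(y[feature, present])
      ok <- abs(obsRatio - expRatio) <= params$isotopeIntensityTol * expRatio
      status <- if (ok) "verified" else "ratio_mismatch"
      if (!ok) pass <- FALSE
    } else if (expRatio * parentInt >= params$mdl * detectionFloor) {
      status <- "absent_expected"
      pass <- FALSE
    }
    rows[[iso]] <- data.frame(isotope = iso, expected_ratio = expRatio,
                              observed_ratio = obsRatio, status = status)
  }
  list(pass = pass, evidence = do.call(rbind, rows))
}

## flag features that are themselves 13C isotopologues of an assigned parent
.flagIsotopologues <- function(neutralMass, y, assignedIdx, carbon, params) {
  iso <- logical(length(neutralMass))
  for (i in assignedIdx) {
    target <- neutralMass[i] + .ISOTOPE_SHIFT[["c13"]]
    hit <- which(abs(neutralMass - target) / target * 1e6 <= params$tolPpm)
    for (j in hit) {
      expRatio <- .ISOTOPE_RATIO[["c13"]] * carbon[i]
      present <- y[i, ] > 0
      if (!any(present)) next
      obs <- sum(y[j, present]) / sum(y[i, present])
      if (abs(obs - expRatio) <= params$isotopeIntensityTol * expRatio)
        iso[j] <- TRUE
    }
  }
  iso
}

#' Assign molecular formulas to an aligned matrix
#'
#' Runs the full assignment chain per feature: ion-to-neutral conversion
#' (for \code{ionMode = "neg"}), candidate enumeration within tolerance,
#' the heteroelement rule (drop N+S+P > 3 unless nitrogen-only up to N4),
#' isotopologue verification (failing candidates demoted or removed per
#' \code{isotopeFailAction}), selection of the smallest-|error| survivor,
#' flagging of features that are themselves 13C isotopologues of an assigned
#' parent, and removal of features matching the contaminant list. Features
#' above the mass range or without a surviving candidate are retained
#' unannotated.
#'
#' @param x an \code{\link{AlignedMatrix}}.
#' @param params an \code{\link{assignmentParams}} object.
#' @return an \code{\link{AnnotatedMatrix}}.
#' @export
assignFormulas <- function(x, params = assignmentParams()) {
  if (!nrow(x)) stop("empty matrix")
  y <- intensityMatrix(x)
  mz <- consensusMass(x)
  neutral <- if (params$ionMode == "neg") mz + .PROTON_MASS else mz
  nz <- y[y > 0]
  detectionFloor <- if (length(nz)) min(nz) else 0
  n <- length(mz)
  ann <- data.frame(neutral_mass = neutral, assigned = FALSE,
                    formula = NA_character_, error_ppm = NA_real_,
                    c = NA_integer_, h = NA_integer_, n = NA_integer_,
                    o = NA_integer_, s = NA_integer_, p = NA_integer_,
                    dbe = NA_real_, hc = NA_real_, oc = NA_real_,
                    nc = NA_real_, sc = NA_real_, pc = NA_real_,
                    iso_verified = NA, isotopologue = FALSE)
  for (i in seq_len(n)) {
    if (neutral[i] > params$maxMass) next
    cand <- enumerateCandidates(neutral[i], params)
    if (!nrow(cand)) next
    cand <- cand[.heteroAllowed(cand, params$maxHetero), , drop = FALSE]
    if (!nrow(cand)) next
    chosen <- NULL; verified <- NA
    demoted <- NULL
    for (k in seq_len(nrow(cand))) {
      v <- verifyIsotopologue(x, i, cand[k, ], params,
                              neutralMass = neutral,
                              detectionFloor = detectionFloor)
      if (v$pass) {
        chosen <- cand[k, ]; verified <- TRUE
        break
      }
      if (is.null(demoted)) demoted <- cand[k, ]
    }
    if (is.null(chosen) && params$isotopeFailAction == "demote" &&
        !is.null(demoted)) {
      chosen <- demoted; verified <- FALSE
    }
    if (is.null(chosen)) next
    ann$assigned[i] <- TRUE
    ann$formula[i] <- chosen$formula
    ann$error_ppm[i] <- chosen$error_ppm
    for (el in .ELEMENTS) ann[[el]][i] <- chosen[[el]]
    ann$dbe[i] <- chosen$dbe
    for (r in c("hc", "oc", "nc", "sc", "pc")) ann[[r]][i] <- chosen[[r]]
    ann$iso_verified[i] <- verified
  }
  ann$isotopologue <- .flagIsotopologues(neutral, y, which(ann$assigned),
                                         ann$c, params)
  ann$assigned <- ann$assigned & !ann$isotopologue
  ## contaminant removal applies to features, not candidates
  contam <- ann$assigned & !is.na(ann$formula) &
    ann$formula %in% params$contaminants$formula
  rowData(x) <- cbind(rowData(x)[, "mz", drop = FALSE],
                      S4Vectors::DataFrame(ann))
  md <- metadata(x)
  md$params <- params
  md$nContaminantsRemoved <- sum(contam)
  metadata(x) <- md
  out <- methods::new("AnnotatedMatrix", x[!contam, ])
  out
}

#' Write an annotated matrix as TSV
#'
#' Columns: consensus mass, neutral mass, Hill formula, mass error (ppm),
#' element counts, DBE, then one intensity column per sample.
#'
#' @param x an \code{\link{AnnotatedMatrix}}.
#' @param path output file.
#' @export
writeAnnotatedMatrix <- function(x, path) {
  rd <- formulaData(x)
  df <- cbind(rd[, intersect(c("mz", "neutral_mass", "formula", "error_ppm",
                               "c", "h", "n", "o", "s", "p", "dbe",
                               "ai_mod", "class"), colnames(rd))],
              intensityMatrix(x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
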