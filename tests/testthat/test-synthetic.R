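test_that("formula library respects class regions and determinism", {
  expect_equal(nrow(generateFormulaLibrary(0, seed = 1)), 0)

  lib <- generateFormulaLibrary(c("lignin-like" = 5), seed = 3)
  expect_equal(nrow(lib), 5)
  expect_true(all(lib$oc > 0.29 & lib$oc <= 0.65))
  expect_true(all(lib$hc > 0.7 & lib$hc < 1.5))

  full <- generateFormulaLibrary(6, seed = 9)
  expect_true(all(isValidFormula(full)))
  expect_equal(compoundClass(full), full$class)
  expect_identical(generateFormulaLibrary(6, seed = 9), full)
  expect_error(generateFormulaLibrary(c(bogus = 3), seed = 1), "unknown")
})

test_that("noise-free peak lists reproduce the endmember mixture exactly", {
  lib <- generateFormulaLibrary(3, seed = 5)
  em <- toyEndmembers(lib)
  sim <- generateSamplePeakLists(em, c(1, 0.5, 0), massErrorPpm = 0,
                                 noiseCv = 0, mode = "neutral", seed = 1)
  pl <- sim$peakLists
  # m/z exactly the formula masses
  expect_equal(pl$S01$mz, sort(lib$mass), tolerance = 1e-12)
  # 50:50 intensities are the exact mixture
  key <- sim$truth$formulas$formula
  w <- (em[[1]]$intensities[match(key, lib$formula)] +
          em[[2]]$intensities[match(key, lib$formula)]) / 2
  expect_equal(unname(sim$truth$intensities[, "S02"]), w)
  expect_equal(pl$S02$intensity, w[order(sim$truth$formulas$mass)])
  # m/z strictly increasing within each sample
  for (p in pl) expect_true(all(diff(p$mz) > 0))
})

test_that("pure endmember samples contain only that endmember's formulas", {
  libA <- generateFormulaLibrary(c("lignin-like" = 4), seed = 2)
  libB <- generateFormulaLibrary(c("tannin-like" = 4), seed = 4)
  chem <- c(na = 1, k = 1, ca = 1, mg = 1, d18o = 0, d2h = 0, so4 = 1,
            cl = 1)
  emA <- endmemberSpec("A", libA, rep(0.25, 4), chem, 5)
  emB <- endmemberSpec("B", libB, rep(0.25, 4), chem, 1)
  sim <- generateSamplePeakLists(list(emA, emB), c(1, 0), massErrorPpm = 0,
                                 noiseCv = 0, mode = "neutral", seed = 1)
  expect_setequal(sim$peakLists$S01$mz, libA$mass)
  expect_setequal(sim$peakLists$S02$mz, libB$mass)
})

test_that("13C isotopologues appear at the binomial one-heavy-atom ratio", {
  f <- molecularFormula(10, 16, o = 4)  # C10
  chem <- c(na = 1, k = 1, ca = 1, mg = 1, d18o = 0, d2h = 0, so4 = 1,
            cl = 1)
  em <- endmemberSpec("A", f, 1, chem, 5)
  sim <- generateSamplePeakLists(list(em, em), 1, massErrorPpm = 0,
                                 noiseCv = 0, addIsotopologues = TRUE,
                                 mode = "neutral", seed = 1)
  p <- sim$peakLists$S01
  expect_equal(nrow(p), 2)
  expect_equal(p$mz[2] - p$mz[1], 1.0033548, tolerance = 1e-7)
  # 10 carbons x 1.07% per carbon
  expect_equal(p$intensity[2] / p$intensity[1], 0.107, tolerance = 1e-9)
})

test_that("observed mass errors stay within three spreads", {
  lib <- generateFormulaLibrary(4, seed = 6)
  em <- toyEndmembers(lib)
  sim <- generateSamplePeakLists(em, seq(0, 1, length.out = 5),
                                 massErrorPpm = 0.25, noiseCv = 0,
                                 mode = "neutral", seed = 8)
  truthMass <- sort(sim$truth$formulas$mass)
  for (p in sim$peakLists) {
    # nearest true mass per observed peak (ppm)
    err <- vapply(p$mz, function(m)
      min(abs(m - truthMass) / truthMass * 1e6), numeric(1))
    expect_true(all(err <= 3 * 0.25 + 1e-9))
  }
})

test_that("a shared formula core is present in every sample", {
  lib <- generateFormulaLibrary(4, seed = 12)
  em <- toyEndmembers(lib)   # both endmembers cover the whole library
  sim <- generateSamplePeakLists(em, seq(0, 1, length.out = 6),
                                 massErrorPpm = 0.1, noiseCv = 0.1,
                                 seed = 2)
  expect_true(all(sim$truth$intensities > 0))
  for (p in sim$peakLists) expect_equal(nrow(p), nrow(lib))
})

test_that("hydrochemistry is affine in the mixing fraction", {
  lib <- generateFormulaLibrary(3, seed = 1)
  em <- toyEndmembers(lib)
  fr <- seq(0, 1, length.out = 7)
  sim <- generateSamplePeakLists(em, fr, massErrorPpm = 0, noiseCv = 0,
                                 chemNoiseSd = 0, seed = 1)
  for (v in c("na", "ca", "cl", "d18o"))
    expect_equal(sim$chemistry[[v]],
                 fr * em[[1]]$chem[[v]] + (1 - fr) * em[[2]]$chem[[v]])
  expect_equal(sim$chemistry$doc, fr * 5.4 + (1 - fr) * 0.9)
})

test_that("planted modules drive proportional clr profiles", {
  # two ASVs in one module, huge strength, zero noise: clr rows differ by a
  # constant shift, so rho = 1
  pa <- plantedAssociation(1, character(0), c("ASV1", "ASV2"), 5)
  out <- generateAsvTable(6, 8, list(pa), noiseSd = 0, seed = 3)
  expect_equal(colSums(out$asv), rep(1, 8), ignore_attr = TRUE)
  clr <- clrTransform(out$asv)
  d <- clr["ASV1", ] - clr["ASV2", ]
  expect_equal(var(d), 0, tolerance = 1e-20)
  rho <- proportionalityRho(clr[1:2, ])
  expect_equal(rho["ASV1", "ASV2"], 1, tolerance = 1e-12)
})

test_that("ASV tables have the requested shape and sane taxonomy", {
  out <- generateAsvTable(229, 10, seed = 7)
  expect_equal(dim(out$asv), c(229, 10))
  expect_equal(unname(colSums(out$asv)), rep(1, 10))
  expect_true(all(lengths(strsplit(out$taxonomy, ";")) == 7))
  expect_error(
    generateAsvTable(5, 4, list(plantedAssociation(1, character(0),
                                                   "ASV99"))),
    "unknown ASV")
  # members must be disjoint across modules
  expect_error(
    generateAsvTable(5, 4, list(
      plantedAssociation(1, character(0), "ASV1"),
      plantedAssociation(2, character(0), "ASV1"))),
    "disjoint")
})

test_that("synthetic outputs serialize to the documented formats", {
  lib <- generateFormulaLibrary(2, seed = 1)
  em <- toyEndmembers(lib)
  sim <- generateSamplePeakLists(em, c(0.2, 0.8), seed = 1)
  asv <- generateAsvTable(4, 2, seed = 1)
  dir <- tempfile()
  writeSyntheticData(sim, dir, asvSim = asv)
  expect_true(file.exists(file.path(dir, "peaks_S01.csv")))
  expect_true(file.exists(file.path(dir, "chemistry.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  tab <- utils::read.delim(file.path(dir, "asv_table.tsv"),
                           check.names = FALSE)
  expect_equal(colnames(tab), c("asv", "S01", "S02", "taxonomy"))
})
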