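test_that("AI_mod matches closed-form substitutions", {
  expect_equal(aiMod(molecularFormula(6, 6)), 2 / 3, tolerance = 1e-12)
  expect_equal(aiMod(molecularFormula(1, 4)), 0)          # numerator 0
  # C14H6O2: (1 + 14 - 1 - 3) / (14 - 1)
  expect_equal(aiMod(molecularFormula(14, 6, o = 2)), 11 / 13,
               tolerance = 1e-12)
  # saturated, oxygen-rich formulas clamp at zero
  expect_equal(aiMod(molecularFormula(6, 14, o = 8, strict = FALSE)), 0)
})

test_that("compound classes honour every printed boundary", {
  cc <- function(oc, hc) compoundClass(oc = oc, hc = hc)
  expect_equal(cc(0.50, 1.00), "lignin-like")
  expect_equal(cc(0.20, 0.50), "condensed aromatics")
  # point inside both unsaturated oxygen-poor and unsaturated
  # hydrocarbon-like regions
  expect_equal(cc(0.25, 1.60), "unclassified")
  expect_equal(cc(0.25, 1.61), "unsaturated oxygen-poor")
  expect_equal(cc(0.25, 1.59), "unsaturated hydrocarbon-like")
  expect_equal(cc(0.45, 1.8), "unsaturated")
  expect_equal(cc(0.8, 2.0), "amino sugar- and carbohydrate-like")
  expect_equal(cc(0.8, 1.0), "tannin-like")
  # class edges
  expect_equal(cc(0.29, 1.0), "unsaturated hydrocarbon-like")
  expect_equal(cc(0.291, 1.0), "lignin-like")
  expect_equal(cc(0.65, 1.49), "lignin-like")
  expect_equal(cc(0.651, 1.49), "tannin-like")
  # H/C exactly 1.5 leaves the open lignin bound and enters the closed
  # carbohydrate / unsaturated bounds
  expect_equal(cc(0.65, 1.5), "amino sugar- and carbohydrate-like")
  expect_equal(cc(0.5, 1.5), "unsaturated")
  expect_equal(cc(0.4, 0.7), "condensed aromatics")
  expect_equal(cc(0.41, 0.65), "unclassified")
  expect_equal(cc(1.3, 1.0), "unclassified")   # outside all regions
  # O/C exactly 0.6, H/C 1.5: unsaturated and carbohydrate regions overlap
  expect_equal(cc(0.6, 1.5), "unclassified")
})

test_that("weighted summaries combine intensities and elemental ratios", {
  f <- molecularFormula(c(10, 10), c(10, 20), o = c(2, 2))  # H/C 1 and 2
  al <- toyAligned(sort(f$mass), {
    y <- matrix(c(1, 1, 3, 1), 2, 2)
    rownames(y) <- NULL; colnames(y) <- c("eq", "skew"); y
  })
  ann <- assignFormulas(al, assignmentParams(ionMode = "neutral"))
  s <- weightedSampleSummary(ann)
  expect_equal(s$hc_mf[s$sample == "eq"], 1.5)
  expect_equal(s$mlb_w[s$sample == "eq"], 0.5)
  expect_equal(s$hc_mf[s$sample == "skew"], 1.25)
  expect_equal(s$abios_pct, c(0, 0))
  # class fractions sum to one and ignore intensity rescaling
  fracCols <- grep("^frac_", colnames(s))
  expect_equal(unname(rowSums(s[, fracCols])), c(1, 1), tolerance = 1e-9)
  al2 <- toyAligned(sort(f$mass), {
    y <- matrix(c(10, 10, 30, 10), 2, 2)
    colnames(y) <- c("eq", "skew"); y
  })
  ann2 <- assignFormulas(al2, assignmentParams(ionMode = "neutral"))
  expect_equal(weightedSampleSummary(ann2)[, fracCols], s[, fracCols])
})

test_that("MLB_w computed two ways agrees to machine precision", {
  lib <- generateFormulaLibrary(4, seed = 17)
  em <- toyEndmembers(lib)
  sim <- generateSamplePeakLists(em, c(0.2, 0.5, 0.9), massErrorPpm = 0,
                                 noiseCv = 0, mode = "neutral", seed = 1)
  al <- joinMassLists(sim$peakLists)
  ann <- assignFormulas(al, assignmentParams(ionMode = "neutral"))
  s <- weightedSampleSummary(ann)
  rd <- formulaData(ann, annotatedOnly = TRUE)
  y <- intensityMatrix(ann)[formulaData(ann)$assigned &
                              !formulaData(ann)$isotopologue, ,
                            drop = FALSE]
  for (j in seq_along(s$sample)) {
    w <- y[, j] / sum(y[, j])
    indicator <- sum(w * as.numeric(rd$hc > 1.5))
    expect_equal(s$mlb_w[j], indicator, tolerance = 1e-12)
  }
})

test_that("AbioS percentages count listed formulas only", {
  f <- molecularFormula(c(10, 12), c(12, 16), o = c(3, 4), s = c(1, 0))
  al <- toyAligned(sort(f$mass), cbind(s1 = c(1, 3)[order(f$mass)]))
  ann <- assignFormulas(al, assignmentParams(ionMode = "neutral"))
  s <- weightedSampleSummary(ann, abiosList = f$formula[1])
  expect_equal(s$abios_pct, 25)
  expect_equal(s$sc_mf, (1 * 0.1 + 3 * 0) / 4)
})

test_that("group contrasts rank a sulfur-enriched endmember correctly", {
  fS <- molecularFormula(c(12, 14), c(16, 18), o = c(4, 5), s = c(1, 1))
  fO <- molecularFormula(c(12, 14), c(14, 16), o = c(5, 6))
  lib <- rbind(fS, fO)
  chem <- c(na = 1, k = 1, ca = 1, mg = 1, d18o = 0, d2h = 0, so4 = 1,
            cl = 1)
  emS <- endmemberSpec("S", lib, c(0.4, 0.4, 0.1, 0.1), chem, 1)
  emO <- endmemberSpec("O", lib, c(0.05, 0.05, 0.45, 0.45), chem, 5)
  sim <- generateSamplePeakLists(list(emS, emO), c(1, 1, 0, 0),
                                 massErrorPpm = 0, noiseCv = 0.01,
                                 mode = "neutral", seed = 3)
  al <- joinMassLists(sim$peakLists)
  ann <- assignFormulas(al, assignmentParams(ionMode = "neutral"))
  groups <- c(S01 = "sulfur", S02 = "sulfur", S03 = "plain", S04 = "plain")
  gc <- groupContrast(ann, groups, "sc_mf")
  expect_gt(gc$mean[gc$group == "sulfur"], gc$mean[gc$group == "plain"])
  expect_error(groupContrast(ann, groups, "nope"), "unknown metric")
  # identical samples give zero spread
  sameGroups <- c(S01 = "g", S02 = "g")
  sim0 <- generateSamplePeakLists(list(emS, emO), c(1, 1),
                                  massErrorPpm = 0, noiseCv = 0,
                                  mode = "neutral", seed = 3)
  ann0 <- assignFormulas(joinMassLists(sim0$peakLists),
                         assignmentParams(ionMode = "neutral"))
  gc0 <- groupContrast(ann0, sameGroups, "sc_mf")
  expect_equal(gc0$sd, 0)
})

test_that("lignin-dominated endmembers give a lignin-led class profile", {
  lib <- generateFormulaLibrary(5, seed = 23)
  em <- toyEndmembers(lib)
  sim <- generateSamplePeakLists(em, 1, massErrorPpm = 0, noiseCv = 0,
                                 mode = "neutral", seed = 1)
  ann <- addFormulaMetrics(
    assignFormulas(joinMassLists(sim$peakLists),
                   assignmentParams(ionMode = "neutral")))
  s <- weightedSampleSummary(ann)
  fracCols <- grep("^frac_", colnames(s), value = TRUE)
  expect_equal(fracCols[which.max(s[1, fracCols])], "frac_lignin_like")
})
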