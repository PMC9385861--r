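test_that("candidate enumeration finds the generating formula", {
  cand <- enumerateCandidates(256.24023)
  expect_true("C16H32O2" %in% cand$formula)
  expect_lt(abs(cand$error_ppm[cand$formula == "C16H32O2"]), 0.1)

  cand <- enumerateCandidates(16.03130)
  expect_equal(cand$formula, "CH4")

  expect_error(enumerateCandidates(-5), "positive")
  expect_error(enumerateCandidates(1500), "range")
})

test_that("optimized enumeration equals exhaustive brute force", {
  lib <- generateFormulaLibrary(3, seed = 21)
  masses <- lib$mass[lib$mass <= 600][1:8]
  params <- assignmentParams()
  for (m in masses) {
    fast <- enumerateCandidates(m, params)
    slow <- bruteForceCandidates(m, params)
    expect_identical(fast$formula, slow$formula)
    expect_equal(fast$error_ppm, slow$error_ppm, tolerance = 1e-12)
  }
})

test_that("the heteroelement rule drops rich combinations but keeps N4", {
  h <- deepDOM:::.heteroAllowed
  expect_false(h(data.frame(n = 2, s = 2, p = 1)))  # 5 heteroelements
  expect_true(h(data.frame(n = 4, s = 0, p = 0)))   # N4 exception
  expect_true(h(data.frame(n = 1, s = 1, p = 1)))   # exactly 3
  expect_false(h(data.frame(n = 2, s = 2, p = 0)))  # 4, not nitrogen-only
})

test_that("isotopologue verification follows ratio and detectability rules", {
  f <- molecularFormula(20, 22, o = 8)  # C20
  parent <- f$mass
  good <- parent + 1.0033548
  al <- toyAligned(c(parent, good),
                   cbind(s1 = c(100, 100 * 0.214), s2 = c(80, 80 * 0.214)),
                   sampleIds = c("s1", "s2"))
  params <- assignmentParams(ionMode = "neutral")
  v <- verifyIsotopologue(al, 1, f, params)
  expect_true(v$pass)
  expect_equal(v$evidence$expected_ratio, 20 * 0.0107)

  # companion ten times too intense -> gross mismatch
  bad <- toyAligned(c(parent, good),
                    cbind(s1 = c(100, 100 * 2.14), s2 = c(80, 80 * 2.14)),
                    sampleIds = c("s1", "s2"))
  v <- verifyIsotopologue(bad, 1, f, params)
  expect_false(v$pass)
  expect_equal(v$evidence$status[1], "ratio_mismatch")

  # weak parent, no companion, expected companion below the floor -> pass
  weak <- toyAligned(c(parent, parent + 40),
                     cbind(s1 = c(1, 2000), s2 = c(1, 1500)),
                     sampleIds = c("s1", "s2"))
  v <- verifyIsotopologue(weak, 1, f, params)
  expect_true(v$pass)
  expect_equal(v$evidence$status[1], "absent_undetectable")
})

test_that("assignment removes contaminant features and flags isotopologues", {
  contam <- defaultContaminants()
  f <- molecularFormula(12, 16, o = 6)
  mz <- c(f$mass, contam$mass[1], f$mass + 1.0033548)
  intensity <- c(100, 50, 100 * 12 * 0.0107)
  ord <- order(mz)
  al <- toyAligned(mz[ord], matrix(rep(intensity[ord], 4), 3, 4))
  ann <- assignFormulas(al, assignmentParams(ionMode = "neutral"))
  rd <- formulaData(ann)
  # contaminant feature dropped entirely
  expect_false(contam$formula[1] %in% rd$formula[rd$assigned])
  expect_equal(nrow(ann), 2)
  # the 13C companion is flagged, not annotated
  expect_true(any(rd$isotopologue))
  expect_equal(sum(rd$assigned), 1)
  expect_equal(rd$formula[rd$assigned], f$formula)
})

test_that("noise-free synthetic data round-trips through assignment", {
  lib <- generateFormulaLibrary(6, seed = 31)
  em <- toyEndmembers(lib)
  sim <- generateSamplePeakLists(em, seq(0, 1, length.out = 6),
                                 massErrorPpm = 0, noiseCv = 0,
                                 mode = "neg", seed = 1)
  al <- joinMassLists(sim$peakLists)
  ann <- assignFormulas(al, assignmentParams(ionMode = "neg"))
  rd <- formulaData(ann)
  truth <- sim$truth$formulas
  hits <- rd$assigned & rd$formula %in% truth$formula
  expect_gte(sum(hits) / nrow(truth), 0.99)
  # recomputed mass error within tolerance for every assignment
  err <- abs(rd$error_ppm[rd$assigned])
  expect_true(all(err <= 0.5 + 1e-9))
})

test_that("ion-mode conversion shifts the neutral mass by a proton", {
  f <- molecularFormula(10, 12, o = 5)
  alNeg <- toyAligned(f$mass - 1.00727646, cbind(a = 10, b = 12))
  ann <- assignFormulas(alNeg, assignmentParams(ionMode = "neg"))
  rd <- formulaData(ann)
  expect_true(rd$assigned[1])
  expect_equal(rd$formula[1], f$formula)
})
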