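# Denormalization, ranking, composition statistics and molecular weight.

test_that("denormalization is the exact inverse of the target normalization", {
  ref <- loadReferenceSet()
  y <- matrix(ref$pIC50, dimnames = list(NULL, "pIC50"))
  np <- fitNormalization(y)
  yn <- applyNormalization(np, y)
  expect_equal(denormalizeOutput(as.numeric(yn)), ref$pIC50)
  expect_equal(denormalizeOutput(0), min(ref$pIC50))
  expect_equal(denormalizeOutput(1), max(ref$pIC50))
})

test_that("printed outputs reproduce printed predicted IC50 within 0.1%", {
  cand <- loadCandidateSet()
  ic50 <- 10^(-denormalizeOutput(cand$BPNN_output))
  expect_true(all(abs(ic50 - cand$Predicted_IC50_uM) /
                  cand$Predicted_IC50_uM < 0.001))
})

test_that("predicted IC50 is strictly decreasing in network output", {
  out <- seq(-0.9, 0.95, by = 0.05)
  ic50 <- 10^(-denormalizeOutput(out))
  expect_true(all(diff(ic50) < 0))
})

test_that("candidate ranking follows predicted IC50 with lexicographic ties", {
  cand <- loadCandidateSet()
  rk <- rankCandidates(setNames(cand$BPNN_output, cand$Sequence))
  expect_equal(rk$sequence[1], "WTQRF")
  expect_equal(rk$sequence[2], "AHRYH")
  expect_equal(rk$sequence[7], "PTTKT")
  expect_equal(rk$rank, 1:7)
  tie <- rankCandidates(c(BBBBB = 0.5, AAAAA = 0.5))
  expect_equal(tie$sequence, c("AAAAA", "BBBBB"))
  single <- rankCandidates(c(WTQRF = 0.2))
  expect_equal(single$rank, 1L)
})

test_that("composition statistics reproduce the reported fractions", {
  ref <- loadReferenceSet()
  st <- compositionStats(ref$Sequence)
  expect_equal(unname(st["frac1or2Hydrophobic"]), 0.75)
  expect_equal(unname(st["fracCtermAromaticOrHydrophobic"]), 0.50)
  expect_equal(unname(st["fracPenultHydrophilic"]), 2 / 3, tolerance = 1e-12)
})

test_that("composition statistics respect degenerate schemes", {
  peps <- c("AAAAA", "KKKKK", "WTQRF")
  noHydrophobic <- residueScheme(hydrophobic = character(),
                                 hydrophilic = "K", aromatic = "W")
  st <- compositionStats(peps, noHydrophobic)
  expect_equal(unname(st["frac1or2Hydrophobic"]), 0)
  allHydrophilic <- residueScheme(hydrophobic = character(),
                                  hydrophilic = pentaQSAR::AA_CODES)
  expect_equal(unname(compositionStats(peps, allHydrophilic)["fracPenultHydrophilic"]), 1)
  expect_error(compositionStats("AAAA"), "length 5")
  expect_error(residueScheme(hydrophobic = "A", hydrophilic = "A"), "disjoint")
})

test_that("molecular weight matches published and standard values", {
  expect_equal(molecularWeight("WTQRF"), 736.83, tolerance = 5e-5 * 736.83)
  expect_equal(molecularWeight("G"), 75.07, tolerance = 1e-4 * 75)
  expect_equal(molecularWeight(""), 18.02, tolerance = 1e-3)
  expect_error(molecularWeight("AXA"), "non-canonical")
})
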