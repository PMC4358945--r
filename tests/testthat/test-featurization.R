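# Molecular graph construction, computed descriptors and min-max
# normalization.

test_that("peptide graphs carry the exact molecular formula", {
  expect_formula_equal(buildMolecularGraph("GG")$formula,
                       peptideFormulaOracle("GG"))  # C4H8N2O3
  expect_formula_equal(buildMolecularGraph("G")$formula,
                       peptideFormulaOracle("G"))   # C2H5NO2
  for (s in c("WTQRF", "ARHPH", "CPMSV"))
    expect_formula_equal(buildMolecularGraph(s)$formula, peptideFormulaOracle(s))
})

test_that("WTQRF atom counts are consistent with its average molecular weight", {
  f <- buildMolecularGraph("WTQRF")$formula
  masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
  expect_equal(sum(masses[names(f)] * f), 736.83, tolerance = 1e-3)
})

test_that("ring and aromatic-ring counts match the printed candidate rows", {
  # indole counts 2 rings; imidazole and indole count as aromatic
  counts <- sapply(c("WTQRF", "FTPVL", "PTTKT"),
                   function(s) structuralCounts(buildMolecularGraph(s)))
  expect_equal(unname(counts["Ring", ]), c(3, 2, 1))
  expect_equal(unname(counts["AR", ]), c(3, 1, 0))
})

test_that("appending an alanine strictly increases molar refractivity", {
  for (base in c("GG", "WTQ")) {
    mr0 <- thermoDescriptors(buildMolecularGraph(base))[["MR"]]
    mr1 <- thermoDescriptors(buildMolecularGraph(paste0(base, "A")))[["MR"]]
    expect_gt(mr1, mr0)
  }
})

test_that("computed MR ranks agree with the fixture table (Spearman >= 0.8)", {
  ref <- loadReferenceSet()
  des <- featurizePeptides(ref$Sequence, mode = "computed", quiet = TRUE)
  expect_gte(cor(des$MR, ref$MR, method = "spearman"), 0.8)
})

test_that("computed integer counts are stable (regression lock)", {
  # OpenBabel-convention counts frozen at first computation; agreement with
  # the fixture table is not required (different software, unpublished
  # conventions) but any drift should be deliberate.
  locked <- list(
    ARHPH = c(Rotbond = 17, Ring = 3, AR = 2, HBA = 16, HBD = 10),
    LPYPY = c(Rotbond = 13, Ring = 4, AR = 2, HBA = 13, HBD = 6),
    WVPSV = c(Rotbond = 13, Ring = 3, AR = 2, HBA = 12, HBD = 7))
  for (s in names(locked))
    expect_equal(structuralCounts(buildMolecularGraph(s)), locked[[s]])
})

test_that("fractional PSA lies in [0, 1] and LogD is imputed with a warning", {
  for (s in c("GG", "WTQRF", "KDERF"))
    expect_true(all(thermoDescriptors(buildMolecularGraph(s))[["PSA"]] >= 0 &
                    thermoDescriptors(buildMolecularGraph(s))[["PSA"]] <= 1))
  expect_warning(computeDescriptors("GG"), "LogD")
  d <- computeDescriptors("GG", quiet = TRUE)
  expect_equal(d$LogD, d$ALogP)
})

test_that("min-max normalization maps extremes to 0/1 and round-trips", {
  ref <- loadReferenceSet()
  y <- matrix(ref$pIC50, dimnames = list(NULL, "pIC50"))
  np <- fitNormalization(y)
  yn <- applyNormalization(np, y)
  expect_equal(unname(yn[ref$Sequence == "KDERF", 1]), 0)  # activity minimum
  expect_equal(unname(yn[ref$Sequence == "SLPQN", 1]), 1)  # activity maximum
  X <- as.matrix(ref[, c("ALogP", "MR", "Apol", "LogD", "Rotbond",
                         "Ring", "AR", "HBA", "HBD", "PSA")])
  npX <- fitNormalization(X)
  expect_equal(invertNormalization(npX, applyNormalization(npX, X)), X)
})

test_that("candidate descriptors can fall outside the fitted training hull", {
  ref <- loadReferenceSet()
  np <- fitNormalization(as.matrix(ref[, "MR", drop = FALSE]))
  ghgak <- applyNormalization(np, matrix(107.89, dimnames = list(NULL, "MR")))
  expect_lt(ghgak[1, 1], 0)  # below the fitted minimum 111.291
})

test_that("degenerate columns are flagged and mapped to constant zero", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(np <- fitNormalization(m), "degenerate")
  expect_equal(applyNormalization(np, m)[, "b"], c(0, 0, 0))
})

test_that("fixture featurization retrieves printed rows and rejects unknowns", {
  d <- featurizePeptides(c("WTQRF", "SLPQN"), mode = "fixture")
  expect_equal(d["WTQRF", "MR"], 186.729)
  expect_equal(d["SLPQN", "MR"], 127.519)
  expect_error(featurizePeptides("AAAAA", mode = "fixture"), "AAAAA")
})
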