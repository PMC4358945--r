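# Cleavage-rule engine, complete digestion and pentapeptide enumeration.

test_that("parseFasta handles text input, case and multiple records", {
  expect_equal(parseFasta(">a\nVLSA\n"), c(a = "VLSA"))
  expect_equal(parseFasta(">a\nvlsa\n"), c(a = "VLSA"))
  two <- parseFasta(">x1 desc\nAC\nDE\n>x2\nGH\n")
  expect_equal(two, c(x1 = "ACDE", x2 = "GH"))
  expect_error(parseFasta(">a\n>b\nAC\n"), "empty")
  expect_error(parseFasta(character()), "FASTA")
})

test_that("trypsin rule reproduces the published site logic", {
  expect_equal(cleavageSites("AAKAA", "trypsin"), 3L)
  expect_equal(cleavageSites("AAKPA", "trypsin"), integer())  # proline blocks
  expect_equal(cleavageSites("AAAAA", "trypsin"), integer())
  expect_equal(cleavageSites("AWKPA", "trypsin"), 3L)         # WKP rescue
  expect_equal(cleavageSites("ACKDA", "trypsin"), integer())  # CKD veto
  expect_equal(cleavageSites("ARRHA", "trypsin"), 2L)         # RRH vetoes 2nd R only
})

test_that("digest fragments tile the parent and concatenate to it", {
  expect_equal(digestSequence("AAKAA", "trypsin")$sequence, c("AAK", "AA"))
  d <- digestSequence("AAAAA", "trypsin")
  expect_equal(d$sequence, "AAAAA")
  for (i in 1:40) {
    s <- randomProtein(60, seed = 100 + i)
    for (rule in c("trypsin", "pepsin_ph_gt2")) {
      d <- digestSequence(s, rule)
      expect_equal(paste(d$sequence, collapse = ""), s)
      expect_equal(d$start[-1], head(d$end, -1) + 1)
    }
  }
})

test_that("digestion is idempotent: fragments contain no internal sites", {
  for (i in 1:20) {
    s <- randomProtein(80, seed = 200 + i)
    for (rule in c("trypsin", "pepsin_ph_gt2", "pepsin_ph1.3")) {
      for (f in digestSequence(s, rule)$sequence)
        if (nchar(f) > 1)
          expect_equal(digestSequence(f, rule)$sequence, f)
    }
  }
})

test_that("cleavage sites agree with an independent regex oracle on random 50-mers", {
  for (i in 1:1000) {
    s <- randomProtein(50, seed = i)
    rule <- c("trypsin", "pepsin_ph1.3", "pepsin_ph_gt2")[(i %% 3) + 1]
    expect_identical(cleavageSites(s, rule), oracleSites(s, rule),
                     label = paste(rule, s))
  }
})

test_that("pentapeptide enumeration equals the brute-force oracle", {
  for (i in 1:10) {
    s <- randomProtein(200, seed = 300 + i)
    got <- enumeratePentapeptides(c(p1 = s), list("trypsin"))
    frags <- oracleFragments(s, oracleSites(s, "trypsin"))
    expect_setequal(got$sequence, unique(frags[nchar(frags) == 5]))
  }
  empty <- enumeratePentapeptides(character(), list("trypsin"))
  expect_equal(nrow(empty), 0L)
})

test_that("hemoglobin digestion recovers the published candidate table", {
  for (met in c(TRUE, FALSE)) {
    hb <- hemoglobinSubunits(includeInitiatorMet = met)
    pent <- enumeratePentapeptides(hb, list("pepsin_ph_gt2", "trypsin"))
    expect_equal(nrow(pent), 7L)
    cand <- loadCandidateSet()
    got <- pent[order(pent$sequence), ]
    expect_equal(got$sequence, cand$Sequence)
    expect_equal(sub("_.*$", "", got$protease), cand$Protease)
    expect_equal(got$parent_id, cand$Subunit)
  }
})

test_that("unknown residues are reported with their position", {
  expect_error(cleavageSites("AAXAA", "trypsin"), "position 3")
  expect_error(digestSequence("AAB", "trypsin"), "non-canonical")
})
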