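# Independent oracles used across the suite.  These deliberately take a
# different route than the package implementation (regular expressions with
# lookarounds instead of the window-pattern engine; explicit pair counting
# instead of stats::cor; residue formula sums instead of the SDF parser).

# --- digestion oracles -------------------------------------------------------

regexSites <- function(sequence, pattern) {
  m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  sort(unique(m + attr(m, "match.length") - 1L))
}

oracleSites <- function(sequence, protease) {
  if (protease == "trypsin") {
    base <- regexSites(sequence, "[KR](?=[^P])")
    rescue <- c(regexSites(sequence, "(?<=W)K(?=P)"),
                regexSites(sequence, "(?<=M)R(?=P)"))
    veto <- c(regexSites(sequence, "(?<=[CD])K(?=D)"),
              regexSites(sequence, "(?<=C)K(?=[HY])"),
              regexSites(sequence, "(?<=C)R(?=K)"),
              regexSites(sequence, "(?<=R)R(?=[HR])"))
    return(sort(unique(c(setdiff(base, veto), rescue))))
  }
  if (protease == "pepsin_ph1.3") {
    pat <- "((?<=[^HKR][^P])[^R](?=[FL][^P]))|((?<=[^HKR][^P])[FL](?=\\w[^P]))"
  } else if (protease == "pepsin_ph_gt2") {
    pat <- paste0("((?<=[^HKR][^P])[^R](?=[FL][^P]))",
                  "|((?<=[^HKR][^P])[^HKR](?=[WY][^P]))",
                  "|((?<=[^HKR][^P])[FLWY](?=\\w[^P]))")
  } else stop("no oracle for ", protease)
  regexSites(sequence, pat)
}

oracleFragments <- function(sequence, sites) {
  bounds <- c(0L, sites, nchar(sequence))
  substring(sequence, head(bounds, -1L) + 1L, bounds[-1L])
}

# --- correlation oracles -----------------------------------------------------

kendallOracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  tiesX <- sum(sapply(table(x), choose, k = 2))
  tiesY <- sum(sapply(table(y), choose, k = 2))
  n0 <- choose(n, 2)
  (conc - disc) / sqrt((n0 - tiesX) * (n0 - tiesY))
}

spearmanOracle <- function(x, y) stats::cor(rank(x), rank(y))

# --- molecular formula oracle ------------------------------------------------

RESIDUE_FORMULA <- list(
  A = c(C = 3, H = 5, N = 1, O = 1), R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1), E = c(C = 5, H = 7, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  P = c(C = 5, H = 7, N = 1, O = 1), S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2), W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2), V = c(C = 5, H = 9, N = 1, O = 1))

peptideFormulaOracle <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  tot <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # start from one water
  for (r in res) {
    f <- RESIDUE_FORMULA[[r]]
    tot[names(f)] <- tot[names(f)] + f
  }
  tot[tot > 0]
}

expect_formula_equal <- function(formula, oracle) {
  expect_setequal(names(formula), names(oracle))
  expect_equal(formula[names(oracle)], oracle, ignore_attr = TRUE)
}
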