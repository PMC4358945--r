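# Static residue-level data shared across modules.

#' The twenty canonical one-letter amino-acid codes
#' @export
AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average residue masses (g/mol), i.e. the amino-acid mass minus one water.
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MASS <- 18.0153

# Side-chain SMILES fragments attached at the alpha carbon.  Neutral (uncharged)
# forms; proline is handled specially because its side chain closes a ring onto
# the backbone nitrogen.
AA_SIDECHAIN_SMILES <- c(
  A = "C",            R = "CCCNC(=N)N",   N = "CC(N)=O",     D = "CC(O)=O",
  C = "CS",           E = "CCC(O)=O",     Q = "CCC(N)=O",    G = "",
  H = "Cc1c[nH]cn1",  I = "C(C)CC",       L = "CC(C)C",      K = "CCCCN",
  M = "CCSC",         F = "Cc1ccccc1",    P = NA,            S = "CO",
  T = "C(O)C",        W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1", V = "C(C)C")

# Atomic polarizabilities (A^3), standard atomic values as tabulated in Open
# Babel / CRC; used for the additive apol descriptor in computed mode.
ELEMENT_POLARIZABILITY <- c(H = 0.666793, C = 1.76, N = 1.1, O = 0.802, S = 2.9)

# Van der Waals radii (Angstrom) for the free-sphere total-surface proxy
# behind the fractional PSA.
ELEMENT_VDW_RADIUS <- c(H = 1.1, C = 1.7, N = 1.55, O = 1.52, S = 1.8)

checkSequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop(what, " must be a single non-empty string", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% AA_CODES)
  if (length(bad))
    stop(sprintf("%s contains non-canonical residue '%s' at position %d",
                 what, res[bad[1]], bad[1]), call. = FALSE)
  res
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.  All stochastic operations in the package are
# funneled through this so that a user-visible seed fully determines results.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
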