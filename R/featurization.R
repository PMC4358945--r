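# Descriptor computation and min-max normalization.
#
# Two modes exist throughout the package: "fixture" uses the printed
# descriptor tables (the canonical values for everything that reproduces the
# published analysis), "computed" derives 2-D/topological descriptors from the
# sequence alone for novel peptides.  Computed values come from OpenBabel via
# ChemmineR/ChemmineOB and are NOT expected to match the fixture values
# numerically (those were produced by proprietary software); they are
# validated by rank agreement only.

#' Assemble the SMILES of a linear peptide
#'
#' Standard backbone amides, free N-terminal amine and C-terminal carboxylic
#' acid, neutral forms throughout.
#'
#' @param sequence peptide sequence, canonical one-letter codes.
#' @return single SMILES string.
#' @export
peptideSmiles <- function(sequence) {
  res <- checkSequence(sequence)
  units <- vapply(seq_along(res), function(i) {
    aa <- res[i]
    if (aa == "P") return("N1CCCC1C(=O)")  # ring closure onto the backbone N
    side <- AA_SIDECHAIN_SMILES[[aa]]
    if (aa == "G") "NCC(=O)" else paste0("N", "C(", side, ")", "C(=O)")
  }, "")
  # proline ring labels must not collide with aromatic ring labels (1, 2)
  units <- vapply(seq_along(units), function(i)
    if (res[i] == "P") gsub("1", "8", units[i], fixed = TRUE) else units[i], "")
  paste0(paste(units, collapse = ""), "O")
}

#' Build the molecular graph of a linear peptide
#'
#' Parses the assembled SMILES with OpenBabel (via
#' \code{ChemmineR::smiles2sdf}) into an explicit atom/bond graph, with ring
#' perception (smallest set of smallest rings), aromaticity (five-membered
#' heteroaromatics such as imidazole and indole included), the molecular
#' formula with implicit hydrogens, and the OpenBabel whole-molecule
#' properties (Wildman-Crippen ALogP and molar refractivity, TPSA, H-bond
#' donor/acceptor counts).
#'
#' @inheritParams peptideSmiles
#' @return object of class \code{MolecularGraph}: a list with \code{atoms}
#'   (data.frame: element, aromatic flag), \code{bonds} (data.frame: atom1,
#'   atom2, order, inRing, rotatable), \code{formula} (named integer vector of
#'   element counts incl. hydrogens), \code{rings}, \code{aromaticRings},
#'   \code{props} (OpenBabel property row) and \code{sequence}.
#' @examples
#' g <- buildMolecularGraph("GG")
#' g$formula  # C4 H8 N2 O3
#' @export
buildMolecularGraph <- function(sequence) {
  res <- checkSequence(sequence)
  smi <- peptideSmiles(sequence)
  sdfset <- ChemmineR::smiles2sdf(smi)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  bonds <- data.frame(atom1 = as.integer(bb[, 1]), atom2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  # upper = 6 restricts to the smallest set of smallest rings for peptide
  # chemistry (no ring of interest exceeds benzene; excludes fused envelopes,
  # so indole counts as 2 rings)
  rings <- ChemmineR::rings(sdf, upper = 6, type = "all", arom = TRUE)
  ringList <- lapply(rings$RINGS, function(r) as.integer(gsub("^.*_", "", r)))
  aromatic <- unlist(rings$AROMATIC, use.names = FALSE)
  if (is.null(aromatic)) aromatic <- logical(length(ringList))
  inRingAtom <- unique(unlist(ringList))
  aromAtom <- unique(unlist(ringList[aromatic]))
  pairKey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ringBondKeys <- unlist(lapply(ringList, function(r) {
    nb <- c(r[-1], r[1])
    pairKey(r, nb)
  }))
  bonds$inRing <- pairKey(bonds$atom1, bonds$atom2) %in% ringBondKeys
  heavyDegree <- tabulate(c(bonds$atom1, bonds$atom2), nbins = length(elements))
  # amide C-N bonds: carbon double-bonded to O on one end, nitrogen the other
  carbonylC <- unique(c(bonds$atom1[bonds$order == 2 & elements[bonds$atom2] == "O"],
                        bonds$atom2[bonds$order == 2 & elements[bonds$atom1] == "O"]))
  carbonylC <- carbonylC[elements[carbonylC] == "C"]
  isAmide <- (bonds$order == 1) &
    ((bonds$atom1 %in% carbonylC & elements[bonds$atom2] == "N") |
     (bonds$atom2 %in% carbonylC & elements[bonds$atom1] == "N"))
  bonds$rotatable <- bonds$order == 1 & !bonds$inRing & !isAmide &
    heavyDegree[bonds$atom1] > 1 & heavyDegree[bonds$atom2] > 1
  formula <- parseFormula(as.character(ChemmineR::MF(sdf, addH = TRUE)))
  props <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smi, identity))
  structure(list(
    sequence = sequence,
    atoms = data.frame(element = elements,
                       aromatic = seq_along(elements) %in% aromAtom),
    bonds = bonds,
    rings = ringList,
    aromaticRings = aromatic,
    formula = formula,
    props = props), class = "MolecularGraph")
}

parseFormula <- function(mf) {
  parts <- regmatches(mf, gregexpr("[A-Z][a-z]?[0-9]*", mf))[[1]]
  el <- gsub("[0-9]+", "", parts)
  ct <- as.integer(ifelse(gsub("[A-Za-z]+", "", parts) == "", "1",
                          gsub("[A-Za-z]+", "", parts)))
  stats::setNames(ct, el)
}

#' @export
print.MolecularGraph <- function(x, ...) {
  cat("MolecularGraph of", x$sequence, "-",
      nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds,",
      length(x$rings), "rings\n")
  invisible(x)
}

#' Integer structural descriptors of a peptide graph
#'
#' @param graph a \code{MolecularGraph} from [buildMolecularGraph()].
#' @return named integer vector: \code{Rotbond} (acyclic single bonds between
#'   non-terminal heavy atoms, amide C-N excluded), \code{Ring} (smallest set
#'   of smallest rings, so indole counts 2), \code{AR} (aromatic rings,
#'   five-membered heteroaromatics included), \code{HBA}, \code{HBD}
#'   (OpenBabel conventions).
#' @export
structuralCounts <- function(graph) {
  stopifnot(inherits(graph, "MolecularGraph"))
  c(Rotbond = sum(graph$bonds$rotatable),
    Ring = length(graph$rings),
    AR = sum(graph$aromaticRings),
    HBA = as.integer(graph$props$HBA2),
    HBD = as.integer(graph$props$HBD))
}

#' Thermodynamic / electronic descriptors of a peptide graph
#'
#' ALogP and molar refractivity follow the Wildman-Crippen atom-contribution
#' scheme (OpenBabel implementation).  Apol is the sum of tabulated atomic
#' polarizabilities over all atoms including implicit hydrogens (units A^3 --
#' note the fixture tables carry the source software's own, much larger,
#' unit).  The fractional polar surface area is the topological PSA divided by
#' a free-sphere total-surface proxy (sum of van der Waals sphere areas over
#' all atoms), clipped to [0, 1].
#'
#' @inheritParams structuralCounts
#' @return named numeric vector: \code{ALogP}, \code{MR}, \code{Apol},
#'   \code{PSA}.
#' @export
thermoDescriptors <- function(graph) {
  stopifnot(inherits(graph, "MolecularGraph"))
  counts <- graph$formula
  known <- names(ELEMENT_POLARIZABILITY)
  bad <- setdiff(names(counts), known)
  if (length(bad))
    stop("no polarizability/radius tabulated for atom type ", bad[1], call. = FALSE)
  apol <- sum(ELEMENT_POLARIZABILITY[names(counts)] * counts)
  surf <- sum(4 * pi * ELEMENT_VDW_RADIUS[names(counts)]^2 * counts)
  psa <- min(max(graph$props$TPSA / surf, 0), 1)
  c(ALogP = graph$props$logP, MR = graph$props$MR, Apol = apol, PSA = psa)
}

#' Compute the full ten-descriptor vector from a sequence
#'
#' LogD at pH 7.4 cannot be computed without a pKa model and is imputed as
#' ALogP (with a warning unless \code{quiet = TRUE}); all other descriptors
#' are topological computations, see [structuralCounts()] and
#' [thermoDescriptors()].
#'
#' @inheritParams peptideSmiles
#' @param quiet suppress the LogD imputation warning.
#' @return one-row data.frame with the ten descriptor columns in canonical
#'   order (ALogP, MR, Apol, LogD, Rotbond, Ring, AR, HBA, HBD, PSA).
#' @export
computeDescriptors <- function(sequence, quiet = FALSE) {
  g <- buildMolecularGraph(sequence)
  th <- thermoDescriptors(g)
  st <- structuralCounts(g)
  if (!quiet)
    warning("LogD imputed as ALogP (no pKa model in computed mode)", call. = FALSE)
  out <- data.frame(ALogP = th[["ALogP"]], MR = th[["MR"]], Apol = th[["Apol"]],
                    LogD = th[["ALogP"]], Rotbond = st[["Rotbond"]],
                    Ring = st[["Ring"]], AR = st[["AR"]], HBA = st[["HBA"]],
                    HBD = st[["HBD"]], PSA = th[["PSA"]])
  rownames(out) <- sequence
  out
}

#' Featurize peptides in fixture or computed mode
#'
#' Fixture mode looks sequences up in the bundled reference and candidate
#' descriptor tables (the canonical route for reproducing the published
#' analysis); computed mode derives descriptors from the sequence via
#' [computeDescriptors()].
#'
#' @param sequences character vector of peptide sequences.
#' @param mode \code{"fixture"} or \code{"computed"}.
#' @param quiet passed to [computeDescriptors()].
#' @return data.frame of descriptors, one row per sequence.
#' @export
featurizePeptides <- function(sequences, mode = c("fixture", "computed"),
                              quiet = FALSE) {
  mode <- match.arg(mode)
  if (mode == "computed") {
    out <- do.call(rbind, lapply(sequences, computeDescriptors, quiet = TRUE))
    if (!quiet)
      warning("LogD imputed as ALogP (no pKa model in computed mode)", call. = FALSE)
    return(out)
  }
  ref <- loadReferenceSet()
  cand <- loadCandidateSet()
  tab <- rbind(ref[DESCRIPTOR_COLUMNS], cand[DESCRIPTOR_COLUMNS])
  missing <- setdiff(sequences, rownames(tab))
  if (length(missing))
    stop("no fixture descriptors for sequence(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab[sequences, , drop = FALSE]
}

#' Fit column-wise min-max normalization
#'
#' @param x numeric matrix or data.frame with at least 2 rows.
#' @return a [NormalizationParams-class].
#' @examples
#' ref <- loadReferenceSet()
#' np <- fitNormalization(as.matrix(ref[, "pIC50", drop = FALSE]))
#' @export
fitNormalization <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit normalization", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("normalization input must be finite numeric", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  deg <- maxs == mins
  if (any(deg))
    warning("degenerate column(s) with max == min: ",
            paste(colnames(x)[deg], collapse = ", "), call. = FALSE)
  new("NormalizationParams", mins = mins, maxs = maxs, degenerate = unname(deg))
}

normInput <- function(params, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(params@mins))
    stop("column count does not match normalization parameters", call. = FALSE)
  x
}

#' Apply / invert min-max normalization
#'
#' \code{applyNormalization} maps each column through
#' \code{(x - min) / (max - min)}; values from outside the fitted hull fall
#' outside [0, 1] (deliberately -- candidate peptides may lie outside the
#' training ranges).  Degenerate columns map to constant 0.
#' \code{invertNormalization} is the exact affine inverse on non-degenerate
#' columns; \code{invert(apply(x)) == x} on the fitting data.
#'
#' @param params a [NormalizationParams-class].
#' @param x matrix/data.frame with matching columns.
#' @return numeric matrix of the same shape.
#' @export
applyNormalization <- function(params, x) {
  x <- normInput(params, x)
  out <- sweep(x, 2, params@mins, "-")
  span <- ifelse(params@degenerate, 1, params@maxs - params@mins)
  out <- sweep(out, 2, span, "/")
  out[, params@degenerate] <- 0
  out
}

#' @rdname applyNormalization
#' @export
invertNormalization <- function(params, x) {
  x <- normInput(params, x)
  span <- ifelse(params@degenerate, 0, params@maxs - params@mins)
  sweep(sweep(x, 2, span, "*"), 2, params@mins, "+")
}
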