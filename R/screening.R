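# Output denormalization, candidate ranking, structural-feature statistics
# and molecular weight.

#' Denormalize a network output into pIC50
#'
#' The network is trained on [0, 1] min-max normalized pIC50, so the inverse
#' map is the affine \code{pic50 = pic50Min + out * (pic50Max - pic50Min)},
#' with the extremes taken from the training activity column (the bundled
#' reference set by default).  The predicted IC50 follows as
#' \code{10^(-pic50)} (uM).
#'
#' @param out numeric network output(s).
#' @param pic50Min,pic50Max target extremes; defaults are the reference-set
#'   pIC50 range.
#' @return numeric pIC50 prediction(s).
#' @examples
#' denormalizeOutput(0.8501)             # ~1.281
#' 10^(-denormalizeOutput(0.8501))       # ~0.0524 uM
#' @export
denormalizeOutput <- function(out, pic50Min = NULL, pic50Max = NULL) {
  if (is.null(pic50Min) || is.null(pic50Max)) {
    p <- loadReferenceSet()$pIC50
    if (is.null(pic50Min)) pic50Min <- min(p)
    if (is.null(pic50Max)) pic50Max <- max(p)
  }
  if (pic50Max <= pic50Min) stop("pic50Max must exceed pic50Min", call. = FALSE)
  pic50Min + out * (pic50Max - pic50Min)
}

#' Rank candidate peptides by predicted activity
#'
#' Accepts either a named numeric vector of network outputs (names are the
#' sequences) or a trained [BPNNModel-class] together with a candidate
#' descriptor table.  Outputs are denormalized to pIC50, converted to IC50
#' (uM) and ranked ascending by predicted IC50 (most potent first), with a
#' deterministic lexicographic tie-break on the sequence.
#'
#' @param outputs named numeric vector of network outputs, or NULL when
#'   \code{model} and \code{candidates} are given.
#' @param model a trained [BPNNModel-class] carrying input/target
#'   normalization.
#' @param candidates data.frame of raw candidate descriptors with row names
#'   (or a \code{Sequence} column).
#' @param pic50Min,pic50Max passed to [denormalizeOutput()]; defaults are the
#'   reference-set extremes.
#' @return data.frame: \code{sequence}, \code{bpnnOutput}, \code{pic50Pred},
#'   \code{ic50PredUm}, \code{rank} (a permutation of 1..n).
#' @examples
#' cand <- loadCandidateSet()
#' rankCandidates(setNames(cand$BPNN_output, cand$Sequence))
#' @export
rankCandidates <- function(outputs = NULL, model = NULL, candidates = NULL,
                           pic50Min = NULL, pic50Max = NULL) {
  if (is.null(outputs)) {
    if (is.null(model) || is.null(candidates))
      stop("provide either outputs, or model plus candidates", call. = FALSE)
    seqs <- if ("Sequence" %in% names(candidates)) candidates$Sequence
            else rownames(candidates)
    X <- as.matrix(candidates[intersect(DESCRIPTOR_COLUMNS, colnames(candidates))])
    outputs <- stats::setNames(predict(model, X), seqs)
  }
  if (is.null(names(outputs)) || any(!nzchar(names(outputs))))
    stop("outputs must be named by peptide sequence", call. = FALSE)
  pic <- denormalizeOutput(outputs, pic50Min, pic50Max)
  ic50 <- 10^(-pic)
  ord <- order(ic50, names(outputs))
  out <- data.frame(sequence = names(outputs), bpnnOutput = as.numeric(outputs),
                    pic50Pred = as.numeric(pic), ic50PredUm = as.numeric(ic50),
                    stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Residue classification scheme
#'
#' The hydrophobic/hydrophilic/aromatic residue classes behind the
#' structural-feature statistics.  The default scheme was calibrated so the
#' 24-peptide reference set reproduces the reported composition fractions
#' (75\% with 1-2 hydrophobic residues; 50\% aromatic-or-hydrophobic at the
#' C-terminus; 66.67\% hydrophilic second-from-C-terminus); it is a
#' reverse-engineered convention, not a published table.  Hydrophobic and
#' hydrophilic sets must be disjoint; A, Y and H are deliberately left out of
#' that dichotomy in the default.
#'
#' @param hydrophobic,hydrophilic,aromatic character vectors of one-letter
#'   codes.
#' @return list of class \code{residueScheme}.
#' @export
residueScheme <- function(hydrophobic = c("V", "L", "I", "P", "M", "F", "W"),
                          hydrophilic = c("G", "S", "T", "C", "N", "Q", "D",
                                          "E", "K", "R"),
                          aromatic = c("F", "W", "Y", "H")) {
  all <- c(hydrophobic, hydrophilic, aromatic)
  if (!all(all %in% AA_CODES))
    stop("scheme contains non-canonical residue codes", call. = FALSE)
  if (length(intersect(hydrophobic, hydrophilic)))
    stop("hydrophobic and hydrophilic sets must be disjoint", call. = FALSE)
  structure(list(hydrophobic = hydrophobic, hydrophilic = hydrophilic,
                 aromatic = aromatic), class = "residueScheme")
}

#' Structural-feature composition statistics of pentapeptides
#'
#' Exact fractions over the input set of (i) peptides with 1 or 2 hydrophobic
#' residues, (ii) peptides with an aromatic or hydrophobic C-terminal residue,
#' and (iii) peptides with a hydrophilic residue second from the C-terminus
#' (position counting from the C-terminus).
#'
#' @param peptides character vector of pentapeptide sequences.
#' @param scheme a [residueScheme()].
#' @return named numeric vector: \code{frac1or2Hydrophobic},
#'   \code{fracCtermAromaticOrHydrophobic}, \code{fracPenultHydrophilic}.
#' @examples
#' compositionStats(loadReferenceSet()$Sequence)
#' @export
compositionStats <- function(peptides, scheme = residueScheme()) {
  stopifnot(inherits(scheme, "residueScheme"))
  mats <- lapply(peptides, checkSequence, what = "peptide")
  if (any(lengths(mats) != 5L))
    stop("all peptides must have length 5", call. = FALSE)
  nHydrophobic <- vapply(mats, function(r) sum(r %in% scheme$hydrophobic), 0L)
  cterm <- vapply(mats, `[`, "", 5L)
  penult <- vapply(mats, `[`, "", 4L)
  c(frac1or2Hydrophobic = mean(nHydrophobic %in% c(1L, 2L)),
    fracCtermAromaticOrHydrophobic =
      mean(cterm %in% union(scheme$aromatic, scheme$hydrophobic)),
    fracPenultHydrophilic = mean(penult %in% scheme$hydrophilic))
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water.  The empty sequence returns
#' the mass of water (the formula's degenerate case, documented rather than an
#' error).
#'
#' @param sequence peptide sequence (canonical one-letter codes) or "".
#' @return average mass in g/mol.
#' @examples
#' molecularWeight("WTQRF")  # 736.83
#' @export
molecularWeight <- function(sequence) {
  if (identical(sequence, "")) return(WATER_MASS)
  res <- checkSequence(sequence)
  sum(AA_RESIDUE_MASS[res]) + WATER_MASS
}
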