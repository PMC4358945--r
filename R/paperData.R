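#' Negative log10 activity transform
#'
#' Converts a half-maximal inhibitory concentration in micromolar into
#' pIC50 = -log10(IC50 / uM).  On this (micromolar) scale the bundled
#' 24-pentapeptide reference set spans pIC50 -2.928 (KDERF, 848 uM) to
#' 2.023 (SLPQN, 0.00948 uM).
#'
#' @param ic50Um positive numeric vector, IC50 in micromolar.
#' @return numeric vector of pIC50 values (dimensionless).
#' @examples
#' pic50(c(848, 1, 0.00948))
#' @export
pic50 <- function(ic50Um) {
  if (!is.numeric(ic50Um) || !length(ic50Um))
    stop("ic50Um must be numeric", call. = FALSE)
  if (any(!is.finite(ic50Um)) || any(ic50Um <= 0))
    stop("ic50Um must be strictly positive and finite", call. = FALSE)
  -log10(ic50Um)
}

extdataFile <- function(name) {
  path <- system.file("extdata", name, package = "pentaQSAR")
  if (!nzchar(path) || !file.exists(path))
    stop("bundled fixture '", name, "' is missing or unreadable", call. = FALSE)
  path
}

readFixtureTable <- function(name) {
  utils::read.delim(extdataFile(name), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

DESCRIPTOR_COLUMNS <- c("ALogP", "MR", "Apol", "LogD", "Rotbond",
                        "Ring", "AR", "HBA", "HBD", "PSA")

checkDescriptorInvariants <- function(tab, what) {
  miss <- setdiff(DESCRIPTOR_COLUMNS, names(tab))
  if (length(miss))
    stop(what, ": fixture is missing descriptor column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  counts <- c("Rotbond", "Ring", "AR", "HBA", "HBD")
  for (cc in counts) {
    v <- tab[[cc]]
    if (any(v < 0) || any(v != round(v)))
      stop(what, ": column ", cc, " must hold non-negative integers", call. = FALSE)
  }
  if (any(tab$AR > tab$Ring))
    stop(what, ": aromatic ring count exceeds total ring count", call. = FALSE)
  if (any(tab$PSA < 0 | tab$PSA > 1))
    stop(what, ": fractional PSA must lie in [0, 1]", call. = FALSE)
  invisible(tab)
}

#' Load the 24-pentapeptide reference set
#'
#' Returns the literature training set: 24 unique pentapeptides with measured
#' ACE-inhibitory IC50 (uM), the derived pIC50, and their ten molecular
#' descriptors (computed with Discovery Studio in the source study and
#' transcribed at full printed precision).  Row i of the descriptor block
#' describes peptide i of the activity block; loaders enforce this pairing and
#' reject duplicate sequences to catch transcription errors.
#'
#' @return data.frame with 24 rows and columns \code{No}, \code{Sequence},
#'   \code{IC50_uM}, \code{pIC50}, then \code{ALogP}, \code{MR}, \code{Apol},
#'   \code{LogD}, \code{Rotbond}, \code{Ring}, \code{AR}, \code{HBA},
#'   \code{HBD}, \code{PSA}.
#' @examples
#' ref <- loadReferenceSet()
#' range(ref$pIC50)
#' @export
loadReferenceSet <- function() {
  act <- readFixtureTable("reference_peptides.tsv")
  des <- readFixtureTable("reference_descriptors.tsv")
  if (nrow(act) != 24L || nrow(des) != 24L)
    stop("reference fixtures must each contain exactly 24 rows", call. = FALSE)
  if (!identical(act$No, des$No))
    stop("reference fixtures disagree on peptide numbering", call. = FALSE)
  if (anyDuplicated(act$Sequence))
    stop("duplicate sequence in reference_peptides.tsv", call. = FALSE)
  for (s in act$Sequence) {
    res <- checkSequence(s, "reference peptide")
    if (length(res) != 5L)
      stop("reference peptide ", s, " is not a pentapeptide", call. = FALSE)
  }
  if (any(act$IC50_uM <= 0))
    stop("reference_peptides.tsv: IC50 must be positive", call. = FALSE)
  checkDescriptorInvariants(des, "reference_descriptors.tsv")
  out <- cbind(act[c("No", "Sequence", "IC50_uM")],
               pIC50 = pic50(act$IC50_uM),
               des[DESCRIPTOR_COLUMNS])
  rownames(out) <- out$Sequence
  out
}

#' Load the seven hemoglobin-derived candidate pentapeptides
#'
#' The pentapeptides obtained by simulated pepsin/trypsin digestion of the
#' bovine hemoglobin alpha and beta subunits, with their protease and subunit
#' attribution, descriptors, final-network output and the predicted IC50 (uM)
#' as published.  These printed outputs pin down the denormalization map (see
#' [denormalizeOutput()]).
#'
#' @return data.frame with 7 rows: \code{Sequence}, \code{Protease},
#'   \code{Subunit}, the ten descriptor columns, \code{BPNN_output},
#'   \code{Predicted_IC50_uM}.
#' @examples
#' loadCandidateSet()[, c("Sequence", "Protease", "BPNN_output")]
#' @export
loadCandidateSet <- function() {
  tab <- readFixtureTable("candidate_peptides.tsv")
  if (nrow(tab) != 7L)
    stop("candidate_peptides.tsv must contain exactly 7 rows", call. = FALSE)
  if (anyDuplicated(tab$Sequence))
    stop("duplicate sequence in candidate_peptides.tsv", call. = FALSE)
  for (s in tab$Sequence) {
    res <- checkSequence(s, "candidate peptide")
    if (length(res) != 5L)
      stop("candidate peptide ", s, " is not a pentapeptide", call. = FALSE)
  }
  if (!all(tab$Protease %in% c("pepsin", "trypsin")))
    stop("candidate_peptides.tsv: protease must be pepsin or trypsin", call. = FALSE)
  if (!all(tab$Subunit %in% c("alpha", "beta")))
    stop("candidate_peptides.tsv: subunit must be alpha or beta", call. = FALSE)
  if (any(tab$BPNN_output <= -1 | tab$BPNN_output >= 1))
    stop("candidate_peptides.tsv: network outputs must lie in (-1, 1)", call. = FALSE)
  if (any(tab$Predicted_IC50_uM <= 0))
    stop("candidate_peptides.tsv: predicted IC50 must be positive", call. = FALSE)
  checkDescriptorInvariants(tab, "candidate_peptides.tsv")
  rownames(tab) <- tab$Sequence
  tab[order(tab$Sequence), ]
}

#' Bovine hemoglobin subunit sequences
#'
#' The alpha (UniProt P01966) and beta (P02070) globin chains digested in the
#' screening pipeline, bundled as FASTA.  Sequences are returned as the full
#' precursor including the initiator methionine unless
#' \code{includeInitiatorMet = FALSE}.
#'
#' @param includeInitiatorMet logical; drop the leading Met when FALSE.
#' @return named character vector of length 2 (\code{alpha}, \code{beta}).
#' @export
hemoglobinSubunits <- function(includeInitiatorMet = TRUE) {
  seqs <- parseFasta(extdataFile("bovine_hemoglobin.fasta"))
  out <- c(alpha = unname(seqs[["P01966"]]), beta = unname(seqs[["P02070"]]))
  if (!includeInitiatorMet) out <- vapply(out, substring, "", 2L)
  out
}
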