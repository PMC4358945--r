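#' @import methods
NULL

#' Protease cleavage rule
#'
#' Site specificity of a protease expressed over a local residue window around
#' a candidate scissile bond.  Window positions are named \code{P4, P3, P2, P1}
#' (amino side, \code{P1} immediately N-terminal to the bond) and
#' \code{P1p, P2p} (carboxyl side).  The specificity is a list of branches
#' combined by OR; each branch is a window pattern, i.e. a named list mapping a
#' position to a list with elements \code{residues} (character vector of
#' one-letter codes) and \code{invert} (logical; \code{TRUE} means the position
#' must NOT hold one of the residues).  A position referenced by any pattern
#' element must exist in the sequence: a window position that falls outside the
#' sequence matches no residue-class pattern, so the branch fails.  Exceptions
#' are window patterns with an \code{action}: \code{"veto"} patterns suppress a
#' site matched by the specificity, \code{"rescue"} patterns cut a site the
#' specificity missed.  A bond is cleaved iff
#' (any branch matches AND no veto matches) OR (any rescue matches).
#'
#' @slot name single character, rule identifier.
#' @slot specificity list of window-pattern branches (OR-combined).
#' @slot exceptions list of window patterns, each carrying an \code{action}
#'   field, \code{"veto"} or \code{"rescue"}.
#' @seealso [getCleavageRule()], [cleavageSites()], [digestSequence()]
#' @export
setClass("CleavageRule",
  representation(name = "character", specificity = "list", exceptions = "list"))

validWindowPattern <- function(p, what) {
  ok_pos <- c("P4", "P3", "P2", "P1", "P1p", "P2p")
  if (!length(p)) return(sprintf("%s: empty window pattern", what))
  if (is.null(names(p)) || !all(names(p) %in% c(ok_pos, "action")))
    return(sprintf("%s: window positions must be among %s", what,
                   paste(ok_pos, collapse = ", ")))
  for (nm in setdiff(names(p), "action")) {
    el <- p[[nm]]
    if (!is.list(el) || !all(c("residues", "invert") %in% names(el)))
      return(sprintf("%s: position %s must be list(residues=, invert=)", what, nm))
    if (!all(el$residues %in% AA_CODES))
      return(sprintf("%s: non-canonical residue code at %s", what, nm))
  }
  NULL
}

setValidity("CleavageRule", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a single non-empty string")
  for (i in seq_along(object@specificity)) {
    m <- validWindowPattern(object@specificity[[i]], sprintf("specificity[%d]", i))
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  for (i in seq_along(object@exceptions)) {
    ex <- object@exceptions[[i]]
    if (is.null(ex$action) || !ex$action %in% c("veto", "rescue"))
      msgs <- c(msgs, sprintf("exceptions[%d]: action must be 'veto' or 'rescue'", i))
    m <- validWindowPattern(ex, sprintf("exceptions[%d]", i))
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CleavageRule", function(object) {
  cat("CleavageRule:", object@name, "\n")
  cat(" ", length(object@specificity), "specificity branch(es),",
      length(object@exceptions), "exception(s)\n")
  invisible(object)
})

#' Column-wise min-max normalization parameters
#'
#' Fitted per-column minima and maxima mapping each column onto [0, 1] via
#' \code{(x - min) / (max - min)}.  Columns with \code{max == min} are flagged
#' degenerate and map to the constant 0.
#'
#' @slot mins,maxs named numeric vectors of per-column extremes.
#' @slot degenerate named logical vector flagging columns with max == min.
#' @seealso [fitNormalization()], [applyNormalization()], [invertNormalization()]
#' @export
setClass("NormalizationParams",
  representation(mins = "numeric", maxs = "numeric", degenerate = "logical"))

setValidity("NormalizationParams", function(object) {
  if (length(object@mins) != length(object@maxs) ||
      length(object@mins) != length(object@degenerate))
    return("mins, maxs and degenerate must have equal length")
  if (!identical(names(object@mins), names(object@maxs)))
    return("mins and maxs must carry identical column names")
  if (any(!is.finite(object@mins)) || any(!is.finite(object@maxs)))
    return("normalization extremes must be finite")
  if (any(object@maxs < object@mins))
    return("max must be >= min for every column")
  if (!identical(unname(object@degenerate), unname(object@maxs == object@mins)))
    return("degenerate flags inconsistent with extremes")
  TRUE
})

setMethod("show", "NormalizationParams", function(object) {
  cat("NormalizationParams over", length(object@mins), "column(s)")
  if (any(object@degenerate))
    cat(" (", sum(object@degenerate), " degenerate)", sep = "")
  cat("\n")
  invisible(object)
})

#' Three-layer feedforward network
#'
#' A 10-h-1 style fully connected network with one hidden layer.  The forward
#' map is \code{g(W2 f(W1 x + b1) + b2)} with \code{f}/\code{g} one of the
#' \code{tansig}, \code{logsig}, \code{purelin} transfer functions.  The object
#' optionally carries the min-max normalization parameters for inputs and
#' target so that raw descriptor vectors can be pushed through [predict()] and
#' outputs can be denormalized into pIC50 / IC50.
#'
#' @slot nInput,nHidden,nOutput integer layer sizes.
#' @slot hiddenTransfer,outputTransfer transfer-function names.
#' @slot W1 hidden weights (nHidden x nInput); @slot b1 hidden biases.
#' @slot W2 output weights (nOutput x nHidden); @slot b2 output biases.
#' @slot inputNorm,targetNorm [NormalizationParams-class] or NULL.
#' @seealso [lmTrain()], [trainFinal()], [forwardBPNN()]
#' @export
setClass("BPNNModel",
  representation(nInput = "integer", nHidden = "integer", nOutput = "integer",
                 hiddenTransfer = "character", outputTransfer = "character",
                 W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 inputNorm = "ANY", targetNorm = "ANY"))

setValidity("BPNNModel", function(object) {
  tf <- c("tansig", "logsig", "purelin")
  if (object@nInput < 1L || object@nHidden < 1L || object@nOutput < 1L)
    return("layer sizes must be positive")
  if (!object@hiddenTransfer %in% tf || !object@outputTransfer %in% tf)
    return(sprintf("transfer functions must be among %s", paste(tf, collapse = ", ")))
  if (!identical(dim(object@W1), c(object@nHidden, object@nInput)))
    return("W1 must be nHidden x nInput")
  if (length(object@b1) != object@nHidden) return("b1 must have length nHidden")
  if (!identical(dim(object@W2), c(object@nOutput, object@nHidden)))
    return("W2 must be nOutput x nHidden")
  if (length(object@b2) != object@nOutput) return("b2 must have length nOutput")
  if (!all(is.finite(object@W1)) || !all(is.finite(object@b1)) ||
      !all(is.finite(object@W2)) || !all(is.finite(object@b2)))
    return("all network parameters must be finite")
  for (s in c("inputNorm", "targetNorm")) {
    v <- slot(object, s)
    if (!is.null(v) && !is(v, "NormalizationParams"))
      return(sprintf("%s must be NULL or NormalizationParams", s))
  }
  TRUE
})

setMethod("show", "BPNNModel", function(object) {
  cat(sprintf("BPNNModel %d-%d-%d (%s/%s)\n", object@nInput, object@nHidden,
              object@nOutput, object@hiddenTransfer, object@outputTransfer))
  cat(" ", nParams(object), "free parameters;",
      if (is.null(object@inputNorm)) "no" else "with", "input normalization\n")
  invisible(object)
})

#' @rdname BPNNModel-class
#' @param model a [BPNNModel-class]
#' @export
nParams <- function(model) {
  length(model@W1) + length(model@b1) + length(model@W2) + length(model@b2)
}

#' Accessors for BPNNModel
#'
#' @param model a [BPNNModel-class]
#' @return \code{networkConfig()} returns a list with the layer sizes and
#'   transfer names; \code{networkWeights()} a list of the four parameter
#'   arrays; \code{inputNormalization()} / \code{targetNormalization()} the
#'   attached [NormalizationParams-class] (or NULL).
#' @export
networkConfig <- function(model) {
  list(nInput = model@nInput, nHidden = model@nHidden, nOutput = model@nOutput,
       hiddenTransfer = model@hiddenTransfer, outputTransfer = model@outputTransfer)
}

#' @rdname networkConfig
#' @export
networkWeights <- function(model) {
  list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2)
}

#' @rdname networkConfig
#' @export
inputNormalization <- function(model) model@inputNorm

#' @rdname networkConfig
#' @export
targetNormalization <- function(model) model@targetNorm
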