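# Synthetic data with the statistical structure the analysis assumes, so
# every stage is testable without external downloads: descriptor vectors
# uniform over the reference-table ranges, a smooth nonlinear teacher network
# mapping normalized descriptors to activity plus Gaussian noise, and random
# protein sequences as digestion-oracle fuel.

descriptorRanges <- function() {
  ref <- loadReferenceSet()
  X <- as.matrix(ref[DESCRIPTOR_COLUMNS])
  list(mins = apply(X, 2, min), maxs = apply(X, 2, max))
}

#' Sample synthetic descriptor vectors
#'
#' Each of the ten descriptor columns is drawn uniformly within the range it
#' spans in the bundled 24-peptide reference table; integer count columns are
#' rounded (AR additionally capped at Ring so the descriptor invariants hold)
#' and the fractional PSA is clipped to [0, 1].
#'
#' @param n number of vectors (>= 1).
#' @param seed integer seed; same seed, identical draw.
#' @return data.frame (n x 10) with the canonical descriptor columns.
#' @export
sampleDescriptors <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  rng <- descriptorRanges()
  counts <- c("Rotbond", "Ring", "AR", "HBA", "HBD")
  withSeed(seed, {
    cols <- lapply(DESCRIPTOR_COLUMNS, function(cc) {
      v <- stats::runif(n, rng$mins[[cc]], rng$maxs[[cc]])
      if (cc %in% counts) v <- round(v)
      if (cc == "PSA") v <- pmin(pmax(v, 0), 1)
      v
    })
    out <- as.data.frame(stats::setNames(cols, DESCRIPTOR_COLUMNS))
    out$AR <- pmin(out$AR, out$Ring)
    out
  })
}

#' Teacher specification for synthetic QSAR data
#'
#' A fixed small network of the same family as the trained models serves as
#' the ground-truth descriptor-to-activity function (it stands in for the
#' unknown true structure-activity relationship).  The default teacher is a
#' 10-5-1 tansig/tansig network drawn once from a frozen seed, so recovery
#' bounds are stable across sessions.
#'
#' @param network a [BPNNModel-class]; default: the frozen 10-5-1 teacher.
#' @param sigma Gaussian noise standard deviation (>= 0) on the activity.
#' @param seed seed governing the noise draw in [generateQsarDataset()].
#' @return list of class \code{teacherSpec}.
#' @export
teacherSpec <- function(network = NULL, sigma = 0.1, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(network)) {
    # frozen teacher: moderate weights give a smooth, clearly nonlinear map
    network <- withSeed(970201L, {
      bpnnModel(W1 = matrix(stats::runif(5L * 10L, -1, 1), 5L, 10L),
                b1 = stats::runif(5L, -0.5, 0.5),
                W2 = matrix(stats::runif(5L, -1.5, 1.5), 1L, 5L),
                b2 = stats::runif(1L, -0.2, 0.2))
    })
  }
  structure(list(network = network, sigma = sigma, seed = as.integer(seed)),
            class = "teacherSpec")
}

#' Generate a synthetic QSAR dataset
#'
#' Draws descriptor vectors with [sampleDescriptors()], min-max normalizes
#' them by the reference-table ranges, and produces
#' \code{y = teacher(Xnorm) + N(0, sigma^2)}.
#'
#' @param n number of samples.
#' @param teacher a [teacherSpec()]; its \code{sigma} may be overridden by the
#'   \code{sigma} argument.
#' @param sigma optional noise override.
#' @param seed integer seed for descriptors and noise.
#' @return list: \code{X} raw descriptors, \code{Xnorm} normalized inputs,
#'   \code{y} noisy targets, \code{yTrue} noise-free teacher outputs,
#'   \code{teacher}, \code{inputNorm}.
#' @export
generateQsarDataset <- function(n, teacher = teacherSpec(), sigma = NULL,
                                seed = 1L) {
  stopifnot(inherits(teacher, "teacherSpec"))
  if (is.null(sigma)) sigma <- teacher$sigma
  X <- sampleDescriptors(n, seed = seed)
  rng <- descriptorRanges()
  inputNorm <- new("NormalizationParams", mins = rng$mins, maxs = rng$maxs,
                   degenerate = unname(rng$maxs == rng$mins))
  Xnorm <- applyNormalization(inputNorm, as.matrix(X))
  yTrue <- forwardBPNN(teacher$network, Xnorm)
  noise <- withSeed(seed + 7L, stats::rnorm(n, 0, sigma))
  list(X = X, Xnorm = Xnorm, y = yTrue + noise, yTrue = yTrue,
       teacher = teacher, inputNorm = inputNorm)
}

#' Random protein sequence
#'
#' @param length sequence length (>= 1).
#' @param composition probability weights over the 20 canonical residues,
#'   either unnamed (in \code{AA_CODES} order) or named; default uniform.
#' @param seed integer seed.
#' @return single character string.
#' @examples
#' randomProtein(50, seed = 7)
#' @export
randomProtein <- function(length, composition = NULL, seed = 1L) {
  if (!is.numeric(length) || length < 1L) stop("length must be >= 1", call. = FALSE)
  if (is.null(composition)) composition <- rep(1 / 20, 20)
  if (!is.null(names(composition))) {
    if (!all(names(composition) %in% AA_CODES))
      stop("composition names must be canonical residues", call. = FALSE)
    w <- stats::setNames(rep(0, 20), AA_CODES)
    w[names(composition)] <- composition
    composition <- w
  }
  if (base::length(composition) != 20L || any(composition < 0) || sum(composition) <= 0)
    stop("composition must be 20 non-negative weights with positive sum",
         call. = FALSE)
  withSeed(seed, paste(sample(AA_CODES, length, replace = TRUE,
                              prob = composition / sum(composition)),
                       collapse = ""))
}
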