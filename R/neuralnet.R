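# Three-layer feedforward network with Levenberg-Marquardt training and
# validation-based early stopping.

#' Transfer functions and their derivatives
#'
#' \code{tansig(x) = 2/(1+exp(-2x)) - 1}, \code{logsig(x) = 1/(1+exp(-x))},
#' \code{purelin(x) = x}.  Derivatives are analytic.
#'
#' @param name one of \code{"tansig"}, \code{"logsig"}, \code{"purelin"}.
#' @param x numeric input.
#' @return numeric of the same shape as \code{x}.
#' @examples
#' transferFun("tansig", 0)      # 0
#' transferDeriv("logsig", 0)    # 0.25
#' @export
transferFun <- function(name, x) {
  switch(name,
         tansig = 2 / (1 + exp(-2 * x)) - 1,
         logsig = 1 / (1 + exp(-x)),
         purelin = x,
         stop("unknown transfer function '", name, "'", call. = FALSE))
}

#' @rdname transferFun
#' @export
transferDeriv <- function(name, x) {
  switch(name,
         tansig = { y <- transferFun("tansig", x); 1 - y^2 },
         logsig = { y <- transferFun("logsig", x); y * (1 - y) },
         purelin = x * 0 + 1,
         stop("unknown transfer function '", name, "'", call. = FALSE))
}

#' Construct a BPNN model
#'
#' \code{bpnnModel()} wraps explicit weights; \code{initBPNN()} draws seeded
#' random initial weights, uniform on [-0.5, 0.5] scaled by 1/sqrt(fan-in).
#'
#' @param nInput,nHidden,nOutput layer sizes.
#' @param hiddenTransfer,outputTransfer transfer names.
#' @param W1,b1,W2,b2 parameter arrays (see [BPNNModel-class]).
#' @param inputNorm,targetNorm optional [NormalizationParams-class].
#' @return a [BPNNModel-class].
#' @export
bpnnModel <- function(W1, b1, W2, b2, hiddenTransfer = "tansig",
                      outputTransfer = "tansig", inputNorm = NULL,
                      targetNorm = NULL) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  new("BPNNModel", nInput = ncol(W1), nHidden = nrow(W1), nOutput = nrow(W2),
      hiddenTransfer = hiddenTransfer, outputTransfer = outputTransfer,
      W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2),
      inputNorm = inputNorm, targetNorm = targetNorm)
}

#' @rdname bpnnModel
#' @param seed integer seed for the draw.
#' @export
initBPNN <- function(nInput = 10L, nHidden = 7L, nOutput = 1L,
                     hiddenTransfer = "tansig", outputTransfer = "tansig",
                     seed = 1L) {
  withSeed(seed, {
    W1 <- matrix(stats::runif(nHidden * nInput, -0.5, 0.5) / sqrt(nInput),
                 nHidden, nInput)
    b1 <- stats::runif(nHidden, -0.5, 0.5) / sqrt(nInput)
    W2 <- matrix(stats::runif(nOutput * nHidden, -0.5, 0.5) / sqrt(nHidden),
                 nOutput, nHidden)
    b2 <- stats::runif(nOutput, -0.5, 0.5) / sqrt(nHidden)
    bpnnModel(W1, b1, W2, b2, hiddenTransfer, outputTransfer)
  })
}

#' Forward pass
#'
#' Computes \code{g(W2 f(W1 x + b1) + b2)} for each row of \code{X}.  Inputs
#' are expected on the normalized scale the network was trained on.
#'
#' @param model a [BPNNModel-class].
#' @param X numeric matrix (n x nInput) or vector of length nInput.
#' @return numeric vector of n outputs (nOutput = 1 assumed for the return
#'   simplification; multi-output models return a matrix).
#' @export
forwardBPNN <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model@nInput)
    stop("input has ", ncol(X), " columns; model expects ", model@nInput,
         call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite network input", call. = FALSE)
  A1 <- sweep(X %*% t(model@W1), 2, model@b1, "+")
  Z1 <- transferFun(model@hiddenTransfer, A1)
  A2 <- sweep(Z1 %*% t(model@W2), 2, model@b2, "+")
  Y <- transferFun(model@outputTransfer, A2)
  if (model@nOutput == 1L) as.numeric(Y) else Y
}

#' @describeIn forwardBPNN \code{predict} on raw descriptor rows: applies the
#'   model's input normalization, runs the forward pass and (when
#'   \code{denormalize = TRUE} and a target normalization is attached) maps
#'   the output back to the target scale via [invertNormalization()].
#' @param object a [BPNNModel-class].
#' @param newdata raw descriptor matrix/data.frame.
#' @param denormalize return outputs on the original target scale.
#' @param ... ignored.
#' @export
setMethod("predict", "BPNNModel",
  function(object, newdata, denormalize = FALSE, ...) {
    X <- as.matrix(newdata)
    if (!is.null(object@inputNorm)) X <- applyNormalization(object@inputNorm, X)
    out <- forwardBPNN(object, X)
    if (denormalize) {
      if (is.null(object@targetNorm))
        stop("model carries no target normalization", call. = FALSE)
      out <- as.numeric(invertNormalization(object@targetNorm,
                                            matrix(out, ncol = 1L)))
    }
    out
  })

# --- parameter vector packing -----------------------------------------------

packParams <- function(model)
  c(as.numeric(t(model@W1)), model@b1, as.numeric(t(model@W2)), model@b2)

unpackParams <- function(model, theta) {
  h <- model@nHidden; p <- model@nInput; o <- model@nOutput
  i <- 0L
  model@W1 <- matrix(theta[i + seq_len(h * p)], h, p, byrow = TRUE); i <- i + h * p
  model@b1 <- theta[i + seq_len(h)]; i <- i + h
  model@W2 <- matrix(theta[i + seq_len(o * h)], o, h, byrow = TRUE); i <- i + o * h
  model@b2 <- theta[i + seq_len(o)]
  model
}

# Residuals e = yhat - y and the Jacobian de/dtheta for a single-output
# network, vectorized over samples.  Column order matches packParams().
bpnnJacobian <- function(model, X, y) {
  h <- model@nHidden; p <- model@nInput
  A1 <- sweep(X %*% t(model@W1), 2, model@b1, "+")
  Z1 <- transferFun(model@hiddenTransfer, A1)
  a2 <- as.numeric(Z1 %*% t(model@W2)) + model@b2
  yhat <- transferFun(model@outputTransfer, a2)
  gp <- transferDeriv(model@outputTransfer, a2)
  e <- yhat - y
  D <- (gp * sweep(transferDeriv(model@hiddenTransfer, A1), 2,
                   as.numeric(model@W2), "*"))      # n x h: de/da1
  n <- nrow(X)
  J <- matrix(0, n, h * p + h + h + 1L)
  for (j in seq_len(h))
    J[, (j - 1L) * p + seq_len(p)] <- D[, j] * X
  J[, h * p + seq_len(h)] <- D
  J[, h * p + h + seq_len(h)] <- gp * Z1
  J[, h * p + 2L * h + 1L] <- gp
  list(e = e, J = J, yhat = yhat)
}

#' Levenberg-Marquardt training control
#'
#' Defaults follow the widely documented LM convention: initial damping
#' mu = 1e-3, increase x10 on a rejected step, decrease x0.1 on an accepted
#' one, at most 1000 epochs, gradient tolerance 1e-7, stop after 6 consecutive
#' validation failures, random 70/15/15 train/validation/test split.
#'
#' @param mu0,muInc,muDec,muMax damping schedule (mu0 > 0, muInc > 1,
#'   0 < muDec < 1).
#' @param maxEpochs,gradTol,maxValFail stopping criteria.
#' @param splitFrac length-3 fractions (train, validation, test) summing to 1.
#' @param seed integer; drives the split and any weight initialization.
#' @return list of class \code{trainControl}.
#' @export
trainControl <- function(mu0 = 1e-3, muInc = 10, muDec = 0.1, muMax = 1e10,
                         maxEpochs = 1000L, gradTol = 1e-7, maxValFail = 6L,
                         splitFrac = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(mu0 > 0, muInc > 1, muDec > 0, muDec < 1, maxEpochs >= 1,
            gradTol >= 0, maxValFail >= 1, length(splitFrac) == 3L,
            all(splitFrac >= 0), abs(sum(splitFrac) - 1) < 1e-8)
  structure(list(mu0 = mu0, muInc = muInc, muDec = muDec, muMax = muMax,
                 maxEpochs = as.integer(maxEpochs), gradTol = gradTol,
                 maxValFail = as.integer(maxValFail), splitFrac = splitFrac,
                 seed = as.integer(seed)), class = "trainControl")
}

splitIndices <- function(n, splitFrac, seed) {
  withSeed(seed, {
    idx <- sample.int(n)
    nTrain <- max(1L, round(splitFrac[1] * n))
    nVal <- round(splitFrac[2] * n)
    nVal <- min(nVal, n - nTrain)
    list(train = sort(idx[seq_len(nTrain)]),
         val = sort(idx[nTrain + seq_len(nVal)]),
         test = sort(idx[setdiff(seq_len(n), seq_len(nTrain + nVal))]))
  })
}

#' Train a network by Levenberg-Marquardt with early stopping
#'
#' Damped Gauss-Newton: each epoch solves \code{(J'J + mu I) delta = -J'e} on
#' the training split; an update is accepted only if the training SSE
#' decreases (mu is divided by \code{muDec^-1} on acceptance and multiplied by
#' \code{muInc} on rejection, so the accepted-step training loss is monotone
#' non-increasing).  After every accepted epoch the validation error is
#' monitored; training stops at \code{maxEpochs}, when the gradient
#' infinity-norm falls below \code{gradTol}, when mu exceeds \code{muMax}, or
#' when validation error has risen above its running best for
#' \code{maxValFail} consecutive epochs -- and the parameters with the best
#' validation error are returned.  Fully reproducible given
#' \code{control$seed}.
#'
#' @param X numeric matrix of normalized inputs (n x nInput).
#' @param y numeric vector of normalized targets (length n).
#' @param model a [BPNNModel-class] providing architecture and initial
#'   weights; when NULL a fresh [initBPNN()] of size \code{ncol(X)}-7-1
#'   tansig/tansig is drawn from \code{control$seed}.
#' @param control a [trainControl()] list.
#' @return list with \code{model} (trained [BPNNModel-class]) and
#'   \code{report}: final full-data MSE, Pearson/Kendall/Spearman between
#'   predictions and targets over all rows, epoch count, stop reason,
#'   per-epoch training/validation loss trace and the split membership.
#' @examples
#' d <- generateQsarDataset(60, sigma = 0.05, seed = 3)
#' fit <- lmTrain(d$Xnorm, d$y, control = trainControl(seed = 3, maxEpochs = 50))
#' fit$report$mse
#' @export
lmTrain <- function(X, y, model = NULL, control = trainControl()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("X and y must have aligned rows", call. = FALSE)
  if (n < 3L) stop("need at least 3 samples to split", call. = FALSE)
  if (is.null(model))
    model <- initBPNN(nInput = ncol(X), nHidden = 7L, nOutput = 1L,
                      seed = control$seed)
  if (model@nOutput != 1L) stop("lmTrain supports single-output networks",
                                call. = FALSE)
  sp <- splitIndices(n, control$splitFrac, control$seed)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  hasVal <- length(sp$val) > 0L
  theta <- packParams(model)
  mu <- control$mu0
  valMSE <- function(th) {
    m <- unpackParams(model, th)
    mean((forwardBPNN(m, X[sp$val, , drop = FALSE]) - y[sp$val])^2)
  }
  ej <- bpnnJacobian(unpackParams(model, theta), Xtr, ytr)
  sse <- sum(ej$e^2)
  bestValTheta <- theta
  bestVal <- if (hasVal) valMSE(theta) else Inf
  valFail <- 0L
  trace <- data.frame(epoch = integer(), trainMSE = numeric(), valMSE = numeric())
  stopReason <- "maxEpochs"
  epoch <- 0L
  while (epoch < control$maxEpochs) {
    epoch <- epoch + 1L
    g <- crossprod(ej$J, ej$e)
    if (max(abs(g)) < control$gradTol) { stopReason <- "gradTol"; break }
    JtJ <- crossprod(ej$J)
    accepted <- FALSE
    while (!accepted && mu <= control$muMax) {
      delta <- tryCatch(
        -solve(JtJ + diag(mu, nrow(JtJ)), g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        thetaNew <- theta + as.numeric(delta)
        ejNew <- bpnnJacobian(unpackParams(model, thetaNew), Xtr, ytr)
        sseNew <- sum(ejNew$e^2)
        if (is.finite(sseNew) && sseNew < sse) {
          theta <- thetaNew; ej <- ejNew; sse <- sseNew
          mu <- mu * control$muDec
          accepted <- TRUE
        }
      }
      if (!accepted) mu <- mu * control$muInc
    }
    if (!accepted) { stopReason <- "muMax"; break }
    vm <- if (hasVal) valMSE(theta) else NA_real_
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     trainMSE = sse / length(ytr), valMSE = vm))
    if (hasVal) {
      if (vm < bestVal) {
        bestVal <- vm; bestValTheta <- theta; valFail <- 0L
      } else {
        valFail <- valFail + 1L
        if (valFail >= control$maxValFail) { stopReason <- "earlyStopping"; break }
      }
    }
  }
  finalTheta <- if (hasVal) bestValTheta else theta
  if (any(!is.finite(finalTheta)))
    stop("training diverged to non-finite parameters", call. = FALSE)
  fitted <- unpackParams(model, finalTheta)
  yhat <- forwardBPNN(fitted, X)
  met <- regressionMetrics(y, yhat)
  report <- c(met, list(epochs = epoch, stopReason = stopReason,
                        trace = trace, split = sp,
                        bestValMSE = if (hasVal) bestVal else NA_real_))
  list(model = fitted, report = report)
}

#' Regression metrics between observed and predicted values
#'
#' Mean squared error plus Pearson r, tie-adjusted Kendall tau-b and Spearman
#' rho (midranks), computed with \code{stats::cor}.  When either vector has
#' zero variance the correlations are undefined and reported as NA with a
#' warning.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @return list with \code{mse}, \code{pearson}, \code{kendall},
#'   \code{spearman}.
#' @export
regressionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) < 2L)
    stop("need two aligned vectors of length >= 2", call. = FALSE)
  mse <- mean((yTrue - yPred)^2)
  if (stats::sd(yTrue) == 0 || stats::sd(yPred) == 0) {
    warning("zero variance: correlations undefined", call. = FALSE)
    return(list(mse = mse, pearson = NA_real_, kendall = NA_real_,
                spearman = NA_real_))
  }
  list(mse = mse,
       pearson = stats::cor(yTrue, yPred, method = "pearson"),
       kendall = stats::cor(yTrue, yPred, method = "kendall"),
       spearman = stats::cor(yTrue, yPred, method = "spearman"))
}

# --- plain-text model serialization -----------------------------------------

fmtNum <- function(x) sprintf("%.17g", x)

writeNormBlock <- function(con, prefix, np) {
  if (is.null(np)) { writeLines(paste0(prefix, ".present\tFALSE"), con); return() }
  writeLines(c(paste0(prefix, ".present\tTRUE"),
               paste0(prefix, ".names\t", paste(names(np@mins), collapse = ",")),
               paste0(prefix, ".mins\t", paste(fmtNum(np@mins), collapse = ",")),
               paste0(prefix, ".maxs\t", paste(fmtNum(np@maxs), collapse = ","))),
             con)
}

#' Save / load a BPNN model as plain text
#'
#' A tab-separated key/value format storing the architecture, all weight
#' matrices row-major at full precision (\code{\%.17g}, so load/save
#' round-trips are bit-exact for doubles) and both normalization parameter
#' sets.
#'
#' @param model a [BPNNModel-class].
#' @param path file path.
#' @return \code{readBPNNModel} returns the restored [BPNNModel-class].
#' @export
writeBPNNModel <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("nInput\t", model@nInput),
               paste0("nHidden\t", model@nHidden),
               paste0("nOutput\t", model@nOutput),
               paste0("hiddenTransfer\t", model@hiddenTransfer),
               paste0("outputTransfer\t", model@outputTransfer),
               paste0("W1\t", paste(fmtNum(t(model@W1)), collapse = ",")),
               paste0("b1\t", paste(fmtNum(model@b1), collapse = ",")),
               paste0("W2\t", paste(fmtNum(t(model@W2)), collapse = ",")),
               paste0("b2\t", paste(fmtNum(model@b2), collapse = ","))), con)
  writeNormBlock(con, "inputNorm", model@inputNorm)
  writeNormBlock(con, "targetNorm", model@targetNorm)
  invisible(path)
}

#' @rdname writeBPNNModel
#' @export
readBPNNModel <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2] else "", "")
  get1 <- function(k) vals[match(k, keys)]
  nums <- function(k) as.numeric(strsplit(get1(k), ",", fixed = TRUE)[[1]])
  h <- as.integer(get1("nHidden")); p <- as.integer(get1("nInput"))
  o <- as.integer(get1("nOutput"))
  readNorm <- function(prefix) {
    if (get1(paste0(prefix, ".present")) != "TRUE") return(NULL)
    nm <- strsplit(get1(paste0(prefix, ".names")), ",", fixed = TRUE)[[1]]
    mins <- stats::setNames(nums(paste0(prefix, ".mins")), nm)
    maxs <- stats::setNames(nums(paste0(prefix, ".maxs")), nm)
    new("NormalizationParams", mins = mins, maxs = maxs,
        degenerate = unname(maxs == mins))
  }
  bpnnModel(matrix(nums("W1"), h, p, byrow = TRUE), nums("b1"),
            matrix(nums("W2"), o, h, byrow = TRUE), nums("b2"),
            hiddenTransfer = get1("hiddenTransfer"),
            outputTransfer = get1("outputTransfer"),
            inputNorm = readNorm("inputNorm"),
            targetNorm = readNorm("targetNorm"))
}
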