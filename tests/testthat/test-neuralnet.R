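# Transfer functions, forward pass, Levenberg-Marquardt training, metrics and
# serialization.

test_that("transfer functions hit their landmark values", {
  expect_equal(transferFun("tansig", 0), 0)
  expect_equal(transferFun("logsig", 0), 0.5)
  expect_equal(transferFun("purelin", 3.7), 3.7)
  expect_equal(transferFun("tansig", 100), 1)
  expect_error(transferFun("relu", 1), "unknown")
})

test_that("transfer derivatives match central finite differences", {
  x <- seq(-3, 3, by = 0.37)
  eps <- 1e-6
  for (nm in c("tansig", "logsig", "purelin"))
    expect_equal(transferDeriv(nm, x),
                 (transferFun(nm, x + eps) - transferFun(nm, x - eps)) / (2 * eps),
                 tolerance = 1e-8)
})

test_that("forward pass equals direct matrix algebra for purelin nets", {
  set.seed(5)
  W1 <- matrix(rnorm(12), 3, 4); b1 <- rnorm(3)
  W2 <- matrix(rnorm(3), 1, 3); b2 <- rnorm(1)
  m <- bpnnModel(W1, b1, W2, b2, "purelin", "purelin")
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(forwardBPNN(m, X),
               as.numeric(X %*% t(W1) %*% t(W2) + sum(W2 * b1) + b2))
  z <- bpnnModel(matrix(0, 3, 4), rep(0, 3), matrix(0, 1, 3), 0)
  expect_equal(forwardBPNN(z, X), rep(0, 5))
  expect_error(forwardBPNN(m, matrix(1, 2, 3)), "expects")
})

test_that("analytic Jacobian agrees with central finite differences", {
  for (tf in list(c("tansig", "tansig"), c("logsig", "purelin"))) {
    m <- initBPNN(4, 3, 1, tf[1], tf[2], seed = 9)
    set.seed(10)
    X <- matrix(rnorm(24), 6, 4); y <- rnorm(6)
    ej <- pentaQSAR:::bpnnJacobian(m, X, y)
    th <- pentaQSAR:::packParams(m)
    eps <- 1e-6
    Jnum <- sapply(seq_along(th), function(k) {
      tp <- th; tp[k] <- tp[k] + eps
      tm <- th; tm[k] <- tm[k] - eps
      (pentaQSAR:::bpnnJacobian(pentaQSAR:::unpackParams(m, tp), X, y)$e -
       pentaQSAR:::bpnnJacobian(pentaQSAR:::unpackParams(m, tm), X, y)$e) / (2 * eps)
    })
    expect_equal(Jnum, ej$J, tolerance = 1e-5)
  }
})

test_that("LM training solves linear least squares to the OLS solution", {
  set.seed(42)
  X <- matrix(rnorm(60), 20, 3)
  y <- as.numeric(X %*% c(0.5, -1, 2)) + 0.7
  m0 <- initBPNN(3, 2, 1, "purelin", "purelin", seed = 1)
  fit <- lmTrain(X, y, m0, trainControl(seed = 1, splitFrac = c(1, 0, 0),
                                        maxEpochs = 200))
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(forwardBPNN(fit$model, X), as.numeric(cbind(1, X) %*% ols$coefficients),
               tolerance = 1e-6)
})

test_that("LM cross-checks against minpack.lm on a small nonlinear problem", {
  skip_if_not_installed("minpack.lm")
  set.seed(3)
  X <- matrix(runif(40, -1, 1), 20, 2)
  teacher <- initBPNN(2, 2, 1, seed = 77)
  y <- forwardBPNN(teacher, X)
  m0 <- initBPNN(2, 2, 1, seed = 78)
  fit <- lmTrain(X, y, m0, trainControl(seed = 78, splitFrac = c(1, 0, 0),
                                        maxEpochs = 500, gradTol = 1e-12))
  th0 <- pentaQSAR:::packParams(m0)
  res <- minpack.lm::nls.lm(par = th0, fn = function(p)
    forwardBPNN(pentaQSAR:::unpackParams(m0, p), X) - y,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  sseMine <- mean((forwardBPNN(fit$model, X) - y)^2)
  sseRef <- mean(res$fvec^2)
  expect_lt(sseMine, 1e-6)           # both routes reach the optimum
  expect_lt(abs(sseMine - sseRef), 1e-6)
})

test_that("one-parameter quadratic objective converges in few iterations", {
  # network purelin/purelin with single input weight free: residuals linear in
  # theta, so the LM step solves the quadratic objective essentially at once
  X <- matrix(c(1, 2, 3), 3, 1)
  y <- c(2, 4, 6)
  m0 <- bpnnModel(matrix(0.1, 1, 1), 0, matrix(1, 1, 1), 0,
                  "purelin", "purelin")
  fit <- lmTrain(X, y, m0, trainControl(seed = 1, splitFrac = c(1, 0, 0),
                                        maxEpochs = 5))
  expect_lt(fit$report$mse, 1e-10)
  expect_lte(fit$report$epochs, 5)
})

test_that("training is deterministic given the seed", {
  d <- generateQsarDataset(40, sigma = 0.05, seed = 6)
  f1 <- lmTrain(d$Xnorm, d$y, control = trainControl(seed = 4, maxEpochs = 60))
  f2 <- lmTrain(d$Xnorm, d$y, control = trainControl(seed = 4, maxEpochs = 60))
  expect_identical(f1$report, f2$report)
  expect_identical(networkWeights(f1$model), networkWeights(f2$model))
})

test_that("accepted-step training loss is monotone non-increasing", {
  d <- generateQsarDataset(50, sigma = 0.1, seed = 8)
  f <- lmTrain(d$Xnorm, d$y, control = trainControl(seed = 8, maxEpochs = 80,
                                                    maxValFail = 80))
  expect_true(all(diff(f$report$trace$trainMSE) <= 1e-12))
})

test_that("metrics match brute-force pair-counting and rank oracles", {
  m <- regressionMetrics(1:5, 1:5)
  expect_equal(m, list(mse = 0, pearson = 1, kendall = 1, spearman = 1))
  rev <- regressionMetrics(1:5, 5:1)
  expect_equal(rev$kendall, -1)
  set.seed(13)
  for (i in 1:10) {
    a <- sample(1:8, 20, replace = TRUE)  # replace => ties exercised
    b <- a + rnorm(20, 0, 2)
    m <- regressionMetrics(a, b)
    expect_equal(m$kendall, kendallOracle(a, b))
    expect_equal(m$spearman, spearmanOracle(a, b))
    expect_equal(m$mse, mean((a - b)^2))
  }
  expect_warning(z <- regressionMetrics(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(z$pearson))
})

test_that("model serialization round-trips bit-exactly", {
  dat <- pentaQSAR:::referenceTrainingData()
  fit <- lmTrain(dat$X, dat$y, control = trainControl(seed = 2, maxEpochs = 30))
  fit$model@inputNorm <- dat$inputNorm
  fit$model@targetNorm <- dat$targetNorm
  path <- tempfile(fileext = ".txt")
  writeBPNNModel(fit$model, path)
  back <- readBPNNModel(path)
  expect_identical(networkWeights(back), networkWeights(fit$model))
  expect_identical(back@inputNorm@mins, fit$model@inputNorm@mins)
  expect_identical(back@targetNorm@maxs, fit$model@targetNorm@maxs)
  expect_equal(networkConfig(back), networkConfig(fit$model))
})

test_that("predict on raw descriptors uses the attached normalizations", {
  dat <- pentaQSAR:::referenceTrainingData()
  ref <- loadReferenceSet()
  fit <- lmTrain(dat$X, dat$y, control = trainControl(seed = 3, maxEpochs = 30))
  fit$model@inputNorm <- dat$inputNorm
  fit$model@targetNorm <- dat$targetNorm
  X <- as.matrix(ref[, c("ALogP", "MR", "Apol", "LogD", "Rotbond",
                         "Ring", "AR", "HBA", "HBD", "PSA")])
  outNorm <- predict(fit$model, X)
  expect_equal(outNorm, forwardBPNN(fit$model, dat$X))
  outP <- predict(fit$model, X, denormalize = TRUE)
  expect_equal(outP, denormalizeOutput(outNorm))
})
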