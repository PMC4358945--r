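# Synthetic descriptor sampling, teacher-network datasets and random
# proteins.

test_that("sampled descriptors respect the reference-table ranges", {
  d <- sampleDescriptors(1000, seed = 4)
  ref <- loadReferenceSet()
  expect_true(all(d$MR >= 111.291 & d$MR <= 186.874))
  for (cc in c("ALogP", "Apol", "PSA"))
    expect_true(all(d[[cc]] >= min(ref[[cc]]) & d[[cc]] <= max(ref[[cc]])))
  for (cc in c("Rotbond", "Ring", "AR", "HBA", "HBD"))
    expect_true(all(d[[cc]] == round(d[[cc]])))
  expect_true(all(d$AR <= d$Ring))
  expect_true(all(d$PSA >= 0 & d$PSA <= 1))
  expect_identical(sampleDescriptors(50, seed = 9), sampleDescriptors(50, seed = 9))
  expect_error(sampleDescriptors(0), ">= 1")
})

test_that("teacher datasets carry signal beyond the noise floor", {
  d <- generateQsarDataset(400, sigma = 0.1, seed = 5)
  expect_gt(var(d$y), 0.1^2)
  d2 <- generateQsarDataset(400, sigma = 0.1, seed = 5)
  expect_identical(d$y, d2$y)
})

test_that("trained networks recover the teacher within the locked bounds", {
  # noiseless: a teacher-sized net interpolates the smooth teacher closely
  d0 <- generateQsarDataset(600, sigma = 0, seed = 11)
  idx <- 1:500
  f0 <- suppressWarnings(lmTrain(d0$Xnorm[idx, ], d0$y[idx],
        initBPNN(10, 5, 1, seed = 21), trainControl(seed = 21)))
  rmse0 <- sqrt(mean((forwardBPNN(f0$model, d0$Xnorm[-idx, ]) - d0$y[-idx])^2))
  expect_lt(rmse0, 0.05)
  # sigma = 0.1: held-out RMSE within 1.5 sigma at n = 500
  d1 <- generateQsarDataset(600, sigma = 0.1, seed = 12)
  f1 <- suppressWarnings(lmTrain(d1$Xnorm[idx, ], d1$y[idx],
        initBPNN(10, 7, 1, seed = 22), trainControl(seed = 22)))
  rmse1 <- sqrt(mean((forwardBPNN(f1$model, d1$Xnorm[-idx, ]) - d1$y[-idx])^2))
  expect_lte(rmse1, 1.5 * 0.1)
})

test_that("random proteins are reproducible and respect composition", {
  s1 <- randomProtein(50, seed = 7)
  expect_identical(s1, randomProtein(50, seed = 7))
  expect_equal(nchar(s1), 50L)
  # all-lysine: trypsin cuts every bond except before the terminal position
  kOnly <- randomProtein(20, composition = c(K = 1), seed = 1)
  expect_equal(kOnly, strrep("K", 20))
  frag <- digestSequence(kOnly, "trypsin")$sequence
  expect_true(all(frag == "K"))
  # no specificity residues: both proteases leave one fragment
  comp <- setNames(rep(1, 5), c("A", "G", "S", "T", "V"))
  inert <- randomProtein(60, composition = comp, seed = 3)
  expect_equal(nrow(digestSequence(inert, "trypsin")), 1L)
  expect_equal(nrow(digestSequence(inert, "pepsin_ph_gt2")), 1L)
  expect_error(randomProtein(10, composition = rep(-1, 20)), "non-negative")
})
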