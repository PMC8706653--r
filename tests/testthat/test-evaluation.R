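test_that("confusion matrix tallies hand cases and the identity diagonal", {
  cm <- activityConfusion(1:6, 1:6)
  expect_equal(confusionCounts(cm), diag(1L, 6),
               ignore_attr = TRUE)
  cm2 <- activityConfusion(c(1, 1, 2), c(1, 2, 2))
  counts <- confusionCounts(cm2)
  expect_equal(counts[1, 1], 1L, ignore_attr = TRUE)
  expect_equal(counts[1, 2], 1L, ignore_attr = TRUE)
  expect_equal(counts[2, 2], 1L, ignore_attr = TRUE)
  expect_equal(sum(counts), 3L)
  expect_error(activityConfusion(c(1, 2), 1), "length")
  expect_error(activityConfusion(c(1, 7), c(1, 1)), "1\\.\\.")
})

test_that("metrics match a brute-force one-vs-rest oracle on random pairs", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 500
    yTrue <- sample(1:6, n, replace = TRUE)
    # skewed predictions so some classes may go unpredicted
    yPred <- ifelse(runif(n) < 0.6, yTrue, sample(1:5, n, replace = TRUE))
    cm <- activityConfusion(yTrue, yPred)
    oracle <- oracleBinaryTally(yTrue, yPred)
    got <- binaryCounts(cm)
    expect_equal(got$TP, oracle$TP)
    expect_equal(got$FP, oracle$FP)
    expect_equal(got$FN, oracle$FN)
    expect_equal(got$TN, oracle$TN)
    # every class satisfies TP+FP+FN+TN = total
    expect_true(all(got$TP + got$FP + got$FN + got$TN == n))
    # accuracy: diagonal / total, exactly
    expect_equal(overallAccuracy(cm), 100 * sum(yTrue == yPred) / n)
    # per-class precision/recall from exact integer tallies
    pr <- suppressWarnings(macroPrecisionRecall(cm))
    for (i in 1:6) {
      expP <- if (oracle$TP[i] + oracle$FP[i] > 0)
        100 * oracle$TP[i] / (oracle$TP[i] + oracle$FP[i]) else 0
      expR <- if (oracle$TP[i] + oracle$FN[i] > 0)
        100 * oracle$TP[i] / (oracle$TP[i] + oracle$FN[i]) else 0
      expect_equal(unname(pr$precision[i]), expP)
      expect_equal(unname(pr$recall[i]), expR)
    }
    expect_equal(pr$Pmacro, mean(pr$precision))
    expect_equal(pr$Rmacro, mean(pr$recall))
    expect_true(all(c(pr$precision, pr$recall) >= 0 &
                      c(pr$precision, pr$recall) <= 100))
  }
})

test_that("accuracy handles hand cases and class permutations", {
  # 3-class matrix with diagonal (8, 7, 5) out of 25 -> 80%
  yTrue <- rep(1:3, times = c(10, 9, 6))
  yPred <- c(rep(1, 8), 2, 3,  rep(2, 7), 1, 3,  rep(3, 5), 1)
  cm <- activityConfusion(yTrue, yPred, nClasses = 3)
  expect_equal(overallAccuracy(cm), 80)
  # invariant under simultaneous row/column permutation of class ids
  perm <- c(3, 1, 2)
  cmP <- activityConfusion(perm[yTrue], perm[yPred], nClasses = 3)
  expect_equal(overallAccuracy(cmP), overallAccuracy(cm))
  expect_error(overallAccuracy(activityConfusion(integer(0), integer(0))),
               "empty")
})

test_that("perfect predictions give 100 everywhere; unpredicted classes flag", {
  cm <- activityConfusion(rep(1:6, 10), rep(1:6, 10))
  expect_equal(overallAccuracy(cm), 100)
  pr <- macroPrecisionRecall(cm)
  expect_equal(unname(pr$precision), rep(100, 6))
  expect_equal(unname(pr$recall), rep(100, 6))
  expect_equal(f1FromMacros(pr$Pmacro, pr$Rmacro), 100)

  # class 6 never predicted: precision contributes 0 but macro is defined
  yTrue <- rep(1:6, 5)
  yPred <- yTrue
  yPred[yTrue == 6] <- 1
  expect_warning(pr2 <- macroPrecisionRecall(activityConfusion(yTrue, yPred)),
                 "zero-denominator")
  expect_equal(unname(pr2$precision[6]), 0)
  expect_equal(pr2$flags, 6L)
  expect_true(is.finite(pr2$Pmacro))
})

test_that("F1 from macros follows the printed harmonic-mean formula", {
  expect_equal(f1FromMacros(75, 75), 75)      # F1 = P when P = R
  expect_equal(f1FromMacros(100, 0), 0)
  expect_equal(f1FromMacros(60, 40), 48)      # 2*60*40/100
  # per-class macro-F1 differs from the macro harmonic mean in general
  yTrue <- rep(1:2, times = c(30, 10))
  yPred <- c(rep(1, 25), rep(2, 5), rep(2, 8), rep(1, 2))
  cm <- activityConfusion(yTrue, yPred, nClasses = 2)
  pr <- macroPrecisionRecall(cm)
  expect_false(isTRUE(all.equal(macroF1(cm),
                                f1FromMacros(pr$Pmacro, pr$Rmacro))))
})

test_that("fold assignment partitions near-equally and reproducibly", {
  labs <- rep(1:6, times = c(40, 33, 31, 29, 47, 20))
  f <- makeFolds(labs, k = 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_identical(f, makeFolds(labs, k = 10, seed = 3))
  expect_false(identical(f, makeFolds(labs, k = 10, seed = 4)))
  # 20 items, k = 10: all folds of size 2, disjoint and exhaustive
  f20 <- makeFolds(rep(1:2, 10), k = 10, seed = 1)
  expect_equal(unname(table(f20)), rep(2L, 10), ignore_attr = TRUE)
  # 10,299 items, k = 10: nine folds of 1,030 and one of 1,029
  f10299 <- makeFolds(sample(1:6, 10299, replace = TRUE), k = 10, seed = 2)
  expect_equal(sort(unname(table(f10299))), c(1029L, rep(1030L, 9)),
               ignore_attr = TRUE)
  # property over seeds: every index appears in exactly one fold
  for (s in 1:4) {
    fs <- makeFolds(rep(1:6, 12), k = 7, seed = s)
    expect_length(fs, 72)
    expect_true(all(fs %in% 1:7))
  }
  expect_error(makeFolds(rep(1, 5), k = 6), "exceeds")
})

test_that("k-fold cross-validation tests every window exactly once", {
  ws <- smallSimulatedSet(participants = 2, windowsPer = 5, seed = 13,
                          samplingRate = 10)    # L = 30, 60 windows
  cv <- kFoldCV(ws, tinyModelConfig(L = windowLength(ws)),
                trainConfig(maxEpochs = 2, batchSize = 16,
                            earlyStopPatience = 2),
                k = 3, seed = 5)
  expect_length(cv$folds, nWindows(ws))
  expect_equal(sort(unique(cv$folds)), 1:3)
  expect_length(cv$reports, 3)
  ns <- vapply(cv$reports, `[[`, numeric(1), "n")
  expect_equal(sum(ns), nWindows(ws))
  expect_equal(cv$meanAccuracy, mean(cv$accuracy))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 100))
})
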