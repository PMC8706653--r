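# Shared fixtures, all generated in code.

assaySignal <- function(ws) SummarizedExperiment::assay(ws, "signal")

combineSets <- function(...) harfusion:::combineWindowSets(list(...))

# A small WindowSet with deterministic pseudo-random content.
makeWindowSet <- function(n = 12, L = 10, labels = NULL, seed = 99) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep_len(1:6, n)
  arr <- array(rnorm(L * 6 * n), dim = c(L, 6, n))
  WindowSet(arr, labels = labels, subjects = paste0("s", rep_len(1:3, n)))
}

# A tiny architecture (same topology, small widths) for fast training tests.
tinyModelConfig <- function(L = 20, nClasses = 6) {
  modelConfig(windowLen = L, kernelSizes = c(1, 3, 5), filters = c(4, 6, 8),
              fcWidths = c(16, 24), dropout = 0.3, nClasses = nClasses)
}

# Reduced simulated dataset: nPerClass windows per class.
smallSimulatedSet <- function(participants = 2, windowsPer = 10, seed = 7,
                              samplingRate = 50, windowSeconds = 3) {
  generateDataset(protocolSpec(nParticipants = participants,
                               windowsPerParticipant = windowsPer,
                               samplingRate = samplingRate,
                               windowSeconds = windowSeconds, seed = seed))
}

# Brute-force one-vs-rest tally: the independent metrics oracle.
oracleBinaryTally <- function(yTrue, yPred, nClasses = 6) {
  out <- data.frame(class = 1:nClasses, TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (i in 1:nClasses) {
    for (t in seq_along(yTrue)) {
      isPos <- yTrue[t] == i
      predPos <- yPred[t] == i
      if (isPos && predPos) out$TP[i] <- out$TP[i] + 1L
      else if (!isPos && predPos) out$FP[i] <- out$FP[i] + 1L
      else if (isPos && !predPos) out$FN[i] <- out$FN[i] + 1L
      else out$TN[i] <- out$TN[i] + 1L
    }
  }
  out
}
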