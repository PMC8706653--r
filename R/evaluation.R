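#' @include AllGenerics.R training.R
NULL

#' Build a multiclass confusion matrix
#'
#' `counts[i, j]` is the number of windows with true class i predicted as
#' class j.
#'
#' @param yTrue,yPred equal-length integer label vectors in 1..nClasses.
#' @param nClasses matrix dimension (default 6).
#' @return An \linkS4class{ActivityConfusion}.
#' @export
#' @examples
#' cm <- activityConfusion(c(1, 1, 2), c(1, 2, 2), nClasses = 2)
#' confusionCounts(cm)
activityConfusion <- function(yTrue, yPred, nClasses = 6L) {
  if (length(yTrue) != length(yPred))
    stop("true and predicted label vectors differ in length")
  if (anyNA(yTrue) || anyNA(yPred) ||
      any(c(yTrue, yPred) < 1L) || any(c(yTrue, yPred) > nClasses))
    stop("labels must lie in 1..nClasses")
  cm <- matrix(tabulate((yPred - 1L) * nClasses + yTrue,
                        nbins = nClasses * nClasses),
               nClasses, nClasses)
  nm <- if (nClasses == 6L) activityNames() else as.character(seq_len(nClasses))
  dimnames(cm) <- list(true = nm, predicted = nm)
  new("ActivityConfusion", counts = cm)
}

#' Confusion-matrix accessors
#'
#' `confusionCounts` returns the raw count matrix; `binaryCounts` the
#' per-class one-vs-rest TP/FP/FN/TN tallies (each row sums to the total
#' window count).
#'
#' @param x an \linkS4class{ActivityConfusion}.
#' @name activityConfusion-accessors
#' @rdname activityConfusion
NULL

#' @rdname activityConfusion
#' @export
setMethod("confusionCounts", "ActivityConfusion", function(x) x@counts)

#' @rdname activityConfusion
#' @export
setMethod("binaryCounts", "ActivityConfusion", function(x) {
  cm <- x@counts
  total <- sum(cm)
  tp <- as.integer(diag(cm))
  fp <- as.integer(colSums(cm)) - tp
  fn <- as.integer(rowSums(cm)) - tp
  data.frame(class = seq_len(nrow(cm)), TP = tp, FP = fp, FN = fn,
             TN = as.integer(total) - tp - fp - fn, row.names = rownames(cm))
})

setMethod("show", "ActivityConfusion", function(object) {
  cat(sprintf("ActivityConfusion: %d windows, accuracy %.2f%%\n",
              sum(object@counts), overallAccuracy(object)))
  print(object@counts)
})

#' Overall classification accuracy, in percent
#'
#' The standard multiclass reading of the binary TP/TN formula:
#' `100 * sum(diagonal) / total`. [oneVsRestAccuracy()] exposes the
#' alternative literal one-vs-rest average, which also counts true
#' negatives and is therefore systematically higher.
#'
#' @param cm an \linkS4class{ActivityConfusion}.
#' @return Percent in [0, 100].
#' @export
overallAccuracy <- function(cm) {
  counts <- confusionCounts(cm)
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(counts)) / total
}

#' @rdname overallAccuracy
#' @export
oneVsRestAccuracy <- function(cm) {
  b <- binaryCounts(cm)
  total <- sum(confusionCounts(cm))
  if (total == 0) stop("empty confusion matrix")
  mean(100 * (b$TP + b$TN) / total)
}

#' Per-class and macro-averaged precision and recall, in percent
#'
#' `precision_i = TP_i / (TP_i + FP_i)`, `recall_i = TP_i / (TP_i + FN_i)`,
#' macro values are their unweighted means over classes. A class never
#' predicted (or never present) has an undefined ratio; it contributes 0
#' and is reported in `flags` so degenerate folds stay well-defined.
#'
#' @param cm an \linkS4class{ActivityConfusion}.
#' @return List with `precision`, `recall` (per class), `Pmacro`,
#'   `Rmacro`, and `flags` (classes with a zero denominator).
#' @export
macroPrecisionRecall <- function(cm) {
  b <- binaryCounts(cm)
  precDen <- b$TP + b$FP
  recDen <- b$TP + b$FN
  precision <- ifelse(precDen > 0, 100 * b$TP / precDen, 0)
  recall <- ifelse(recDen > 0, 100 * b$TP / recDen, 0)
  flags <- which(precDen == 0 | recDen == 0)
  if (length(flags))
    warning("zero-denominator class(es): ", paste(flags, collapse = ", "),
            "; contributing 0 to the macro averages")
  list(precision = setNames(precision, rownames(b)),
       recall = setNames(recall, rownames(b)),
       Pmacro = mean(precision), Rmacro = mean(recall), flags = flags)
}

#' F1 score from macro precision and recall, in percent
#'
#' The harmonic mean `2 P R / (P + R)` of the two macro averages, exactly
#' as the headline formula defines it; 0 when both are 0. For the
#' per-class alternative (mean of per-class F1 values) see [macroF1()].
#'
#' @param Pmacro,Rmacro macro precision/recall in percent.
#' @return Percent in [0, 100].
#' @export
#' @examples
#' f1FromMacros(60, 40)  # 48
f1FromMacros <- function(Pmacro, Rmacro) {
  if (Pmacro + Rmacro <= 0) return(0)
  2 * Pmacro * Rmacro / (Pmacro + Rmacro)
}

#' Mean of per-class F1 scores, in percent
#'
#' The conventional macro-F1: harmonic mean per class, then the
#' unweighted mean. Reported alongside [f1FromMacros()] because the two
#' differ whenever per-class precision and recall are unbalanced.
#'
#' @param cm an \linkS4class{ActivityConfusion}.
#' @return Percent in [0, 100].
#' @export
macroF1 <- function(cm) {
  pr <- suppressWarnings(macroPrecisionRecall(cm))
  f1 <- ifelse(pr$precision + pr$recall > 0,
               2 * pr$precision * pr$recall / (pr$precision + pr$recall), 0)
  mean(f1)
}

#' Full metrics report
#'
#' Confusion matrix plus accuracy, per-class and macro precision/recall,
#' and both F1 variants, all in percent.
#'
#' @param yTrue,yPred integer label vectors, or pass a prebuilt `cm`.
#' @param nClasses matrix dimension.
#' @param cm optionally an \linkS4class{ActivityConfusion} instead of
#'   label vectors.
#' @return List with elements `confusion`, `accuracy`,
#'   `accuracy_one_vs_rest`, `precision`, `recall`, `Pmacro`, `Rmacro`,
#'   `F1`, `F1_per_class`, `flags`, `n`.
#' @export
metricsReport <- function(yTrue = NULL, yPred = NULL, nClasses = 6L,
                          cm = NULL) {
  if (is.null(cm)) cm <- activityConfusion(yTrue, yPred, nClasses)
  pr <- suppressWarnings(macroPrecisionRecall(cm))
  list(confusion = cm,
       accuracy = overallAccuracy(cm),
       accuracy_one_vs_rest = oneVsRestAccuracy(cm),
       precision = pr$precision, recall = pr$recall,
       Pmacro = pr$Pmacro, Rmacro = pr$Rmacro,
       F1 = f1FromMacros(pr$Pmacro, pr$Rmacro),
       F1_per_class = macroF1(cm),
       flags = pr$flags, n = sum(confusionCounts(cm)))
}

#' Assign windows to k cross-validation folds
#'
#' Deals shuffled indices cyclically across folds, per class when
#' stratified (the default), continuing the cycle across classes so fold
#' sizes always differ by at most one. Folds are disjoint, exhaustive and
#' seed-reproducible.
#'
#' @param labels integer labels (their length defines the index set).
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified deal per class (default TRUE).
#' @return Integer vector of fold ids in 1..k, one per window.
#' @export
makeFolds <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of windows")
  fold <- integer(n)
  withr_seed(seed, {
    if (stratified) {
      cursor <- 0L
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- (cursor + seq_along(idx) - 1L) %% k + 1L
        cursor <- (cursor + length(idx)) %% k
      }
    } else {
      idx <- sample.int(n)
      fold[idx] <- (seq_len(n) - 1L) %% k + 1L
    }
  })
  fold
}

#' k-fold cross-validation of the fusion classifier
#'
#' Implements the merged-data protocol: the full window collection is
#' divided into k near-equal folds; each fold is tested once by a fresh
#' model trained on the other k-1 folds. Because plateau decay and early
#' stopping need a verification set, a stratified 10% slice of each
#' fold's training part is held out internally for that purpose (and
#' recorded). Min-max normalization is refitted on each fold's training
#' part only.
#'
#' @param ws the merged \linkS4class{WindowSet}.
#' @param modelCfg a [modelConfig()]; `windowLen` must match `ws`.
#' @param trainCfg a [trainConfig()].
#' @param k number of folds (default 10).
#' @param seed seed for fold assignment and per-fold training.
#' @param stratified stratify folds by class (default TRUE).
#' @param verbose print per-fold progress.
#' @return List with `folds` (the assignment), `reports` (per-fold
#'   [metricsReport()]s), `accuracy` (per fold, percent) and
#'   `meanAccuracy`.
#' @export
kFoldCV <- function(ws, modelCfg, trainCfg = trainConfig(), k = 10L,
                    seed = 1L, stratified = TRUE, verbose = FALSE) {
  stopifnot(is(ws, "WindowSet"))
  labs <- activityLabels(ws)
  fold <- makeFolds(labs, k = k, seed = seed, stratified = stratified)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(fold == f)
    poolIdx <- which(fold != f)
    verSel <- withr_seed(deriveSeed(seed, 1000L, f), {
      sel <- logical(length(poolIdx))
      for (cl in unique(labs[poolIdx])) {
        clIdx <- which(labs[poolIdx] == cl)
        nv <- max(1L, as.integer(ceiling(0.1 * length(clIdx))))
        sel[clIdx[sample.int(length(clIdx), nv)]] <- TRUE
      }
      sel
    })
    trainWs <- ws[, poolIdx[!verSel]]
    verWs <- ws[, poolIdx[verSel]]
    testWs <- ws[, testIdx]
    norm <- fitMinMax(trainWs)
    foldTrainCfg <- trainCfg
    foldTrainCfg@seed <- deriveSeed(seed, 2000L, f)
    model <- buildModel(modelCfg, seed = deriveSeed(seed, 3000L, f))
    fit <- trainModel(model, normalizeWindows(trainWs, norm),
                      normalizeWindows(verWs, norm), foldTrainCfg)
    pred <- predictActivities(fit$model, normalizeWindows(testWs, norm))
    reports[[f]] <- metricsReport(activityLabels(testWs), pred,
                                  nClasses = modelCfg@nClasses)
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.2f%% (n=%d)", f, k,
                      reports[[f]]$accuracy, reports[[f]]$n))
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  list(folds = fold, reports = reports, accuracy = acc,
       meanAccuracy = mean(acc))
}
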