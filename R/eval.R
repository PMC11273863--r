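# Evaluation protocol: confusion counts under the first-neuron decision
# rule, the four standard metrics, ROC/AUC, stratified fivefold
# cross-validation, and the leave-one-farm-out robustness protocol.
# Provenance (clip ids and augmentation source ids) is checked on every
# evaluation so no augmented copy of a held-out clip can leak into
# training.

#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integers; positive class =
#'   vocalization.
#' @return a list of class `confusionCounts`.
#' @export
confusionCounts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusionCounts")
}

#' Accuracy, precision, recall, and F1 from confusion counts
#'
#' The four standard formulas applied verbatim:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2*precision*recall/(precision+recall).
#' A zero denominator in precision or recall yields 0 with a warning.
#'
#' @param counts a [confusionCounts()].
#' @return list with `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' metricsFromCounts(confusionCounts(50, 40, 5, 5))
#' @export
metricsFromCounts <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) stop("all-zero confusion counts")
  acc <- (counts$TP + counts$TN) / n
  prec <- if (counts$TP + counts$FP == 0) {
    warning("precision denominator is zero; reporting 0")
    0
  } else counts$TP / (counts$TP + counts$FP)
  rec <- if (counts$TP + counts$FN == 0) {
    warning("recall denominator is zero; reporting 0")
    0
  } else counts$TP / (counts$TP + counts$FN)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

# ROC from vocalization-class scores (threshold swept over the observed
# scores), AUC by the trapezoid rule.
.rocCurve <- function(scores, isPos) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  tpr <- vapply(thr, function(t) if (nPos == 0) 0 else
    sum(scores >= t & isPos) / nPos, 0)
  fpr <- vapply(thr, function(t) if (nNeg == 0) 0 else
    sum(scores >= t & !isPos) / nNeg, 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a trained model on held-out clips
#'
#' Applies the first-neuron decision rule to every clip, tallies the
#' confusion counts (positive class = vocalization), computes the four
#' metrics, and builds the ROC curve from the vocalization-class
#' probability. If `trainIds` is supplied, any overlap between it and
#' the test clips' ids or augmentation sources raises a protocol error.
#'
#' @param fitOrModel a `dcnnFit` (provenance checked automatically) or a
#'   bare `dcnnModel`.
#' @param testSet a labeled [ClipSet].
#' @param method feature method used at training time.
#' @param trainIds optional character vector of training clip ids.
#' @return list of class `evalReport`: `counts`, `accuracy`,
#'   `precision`, `recall`, `f1`, `rocPoints`, `auc`, `n`.
#' @export
evaluateModel <- function(fitOrModel, testSet, method, trainIds = NULL) {
  stopifnot(is(testSet, "ClipSet"))
  if (inherits(fitOrModel, "dcnnFit")) {
    if (is.null(trainIds)) trainIds <- fitOrModel$trainIds
    model <- fitOrModel$model
  } else model <- fitOrModel
  man <- manifest(testSet)
  if (!is.null(trainIds)) {
    leak <- intersect(trainIds, unique(c(man$id, man$source_id)))
    if (length(leak))
      stop("protocol error: test clips overlap the training set (e.g. ",
           leak[1], ")")
  }
  feats <- lapply(clips(testSet), extractFeatures, method = method)
  p <- predictProba(model, feats)
  .reportFromProbs(p, clipLabel(testSet) == "vocalization")
}

# Confusion counts + metrics + ROC from an n x 2 probability matrix
# (column 1 = vocalization) under the first-neuron decision rule.
.reportFromProbs <- function(p, isPos) {
  predPos <- p[, 1] > p[, 2]          # tie -> non-vocalization
  counts <- confusionCounts(
    TP = sum(predPos & isPos), TN = sum(!predPos & !isPos),
    FP = sum(predPos & !isPos), FN = sum(!predPos & isPos))
  roc <- .rocCurve(p[, 1], isPos)
  structure(c(list(counts = counts), metricsFromCounts(counts),
              list(rocPoints = roc$points, auc = roc$auc,
                   n = length(isPos))),
            class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf(
    "evalReport: n=%d  acc=%.4f  prec=%.4f  rec=%.4f  F1=%.4f  AUC=%.4f\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1, x$auc))
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", x$counts$TP, x$counts$TN,
              x$counts$FP, x$counts$FN))
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Partitions a clip set into `k` folds, stratified by label so each
#' fold's class balance is within one clip of 50/50 on a balanced set.
#'
#' @param set a [ClipSet].
#' @param k number of folds (default 5; must be >= 2 and <= clips).
#' @param seed shuffle seed.
#' @return list of class `foldSplit`: `k`, `assignments` (integer fold
#'   per clip, named by id), `stratified`.
#' @export
makeFolds <- function(set, k = 5, seed = 1) {
  stopifnot(is(set, "ClipSet"))
  n <- length(set)
  if (k < 2) stop("k must be at least 2 (one fold must be held out)")
  if (k > n) stop("k exceeds the number of clips")
  man <- manifest(set)
  assign <- integer(n)
  withSeed(seed, {
    for (lab in unique(man$label)) {
      idx <- which(man$label == lab)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  names(assign) <- man$id
  structure(list(k = k, assignments = assign, stratified = TRUE),
            class = "foldSplit")
}

.meanMetrics <- function(reports) {
  ms <- c("accuracy", "precision", "recall", "f1")
  out <- lapply(ms, function(m) mean(vapply(reports, `[[`, 0, m)))
  names(out) <- ms
  out
}

#' Fivefold cross-validation
#'
#' For each fold: train on the other four (optionally expanded with the
#' four augmentation operators), evaluate on the held-out fold with
#' provenance checking, and average the four metrics over folds.
#'
#' @param set a balanced labeled [ClipSet].
#' @param method feature method.
#' @param config a [trainConfig()].
#' @param k folds (5).
#' @param augment expand training folds with [augmentTrainingSet()]
#'   (5x).
#' @param seed seed controlling folds and augmentation draws.
#' @param modelCfg a [modelConfig()].
#' @return list of class `cvReport`: `folds` (per-fold `evalReport`s),
#'   `mean` (averaged metrics), `foldSplit`.
#' @export
crossValidate <- function(set, method, config = trainConfig("desk"),
                          k = 5, augment = FALSE, seed = config$seed,
                          modelCfg = modelConfig()) {
  fs <- makeFolds(set, k, seed = deriveSeed(seed, 10L))
  # features for the un-augmented clips are fold-independent: extract once
  fa <- .featureArray(set, method)
  isPos <- clipLabel(set) == "vocalization"
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- which(fs$assignments != f)
    teIdx <- which(fs$assignments == f)
    foldCfg <- config
    foldCfg$seed <- deriveSeed(seed, 30L + f)
    if (augment) {
      augSet <- augmentTrainingSet(set[trIdx],
                                   seed = deriveSeed(seed, 20L + f))
      faTr <- .featureArray(augSet, method)
      fit <- .trainOnArray(faTr$X, faTr$y, foldCfg, modelCfg)
    } else {
      fit <- .trainOnArray(fa$X[, , trIdx, drop = FALSE], fa$y[trIdx],
                           foldCfg, modelCfg)
    }
    p <- cpp_dcnn_predict(fa$X[, , teIdx, drop = FALSE],
                          fit$model$weights)
    reports[[f]] <- .reportFromProbs(p, isPos[teIdx])
  }
  structure(list(folds = reports, mean = .meanMetrics(reports),
                 foldSplit = fs),
            class = "cvReport")
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("cvReport: %d folds, mean acc=%.4f prec=%.4f rec=%.4f F1=%.4f\n",
              length(x$folds), x$mean$accuracy, x$mean$precision,
              x$mean$recall, x$mean$f1))
  invisible(x)
}

#' Leave-one-farm-out robustness run
#'
#' Trains on the union of two farms' clips (optionally augmented) and
#' evaluates on the third, held-out farm. The held-out farm must not
#' appear among the training farms; provenance is asserted at
#' evaluation.
#'
#' @param farmSets named list of [ClipSet]s, one per farm.
#' @param trainFarms character vector of two farm names.
#' @param testFarm the held-out farm name.
#' @param method feature method.
#' @param config a [trainConfig()].
#' @param augment expand the combined training set 5x (default TRUE,
#'   matching the protocol).
#' @param seed seed for augmentation and training.
#' @param modelCfg a [modelConfig()].
#' @return an `evalReport` with attribute `"trainFarms"`.
#' @export
robustnessRun <- function(farmSets, trainFarms, testFarm, method,
                          config = trainConfig("desk"), augment = TRUE,
                          seed = config$seed, modelCfg = modelConfig()) {
  stopifnot(length(trainFarms) == 2)
  if (testFarm %in% trainFarms)
    stop("protocol error: test farm '", testFarm,
         "' overlaps the training farms")
  if (!all(c(trainFarms, testFarm) %in% names(farmSets)))
    stop("unknown farm name")
  trainSet <- combineClipSets(farmSets[trainFarms])
  if (augment)
    trainSet <- augmentTrainingSet(trainSet, seed = deriveSeed(seed, 40L))
  cfg <- config
  cfg$seed <- deriveSeed(seed, 41L)
  fit <- trainNetwork(trainSet, method, cfg, modelCfg)
  rep <- evaluateModel(fit, farmSets[[testFarm]], method)
  attr(rep, "trainFarms") <- trainFarms
  attr(rep, "testFarm") <- testFarm
  rep
}

# The published train/test pairings for three farms (nias, gimje,
# jeongeup): train (1,2) test 3; train (1,3) test 2; train (2,3) test 1.
.robustnessCombos <- function(nm) {
  stopifnot(length(nm) == 3)
  list(list(train = nm[c(1, 2)], test = nm[3]),
       list(train = nm[c(1, 3)], test = nm[2]),
       list(train = nm[c(2, 3)], test = nm[1]))
}

#' The three-combination robustness protocol
#'
#' Runs the three leave-one-farm-out combinations — train on farms
#' (1,2) test 3, train (1,3) test 2, train (2,3) test 1 — and averages
#' the four metrics.
#'
#' @inheritParams robustnessRun
#' @return list of class `robustnessReport`: `runs` (three
#'   `evalReport`s named by held-out farm), `mean`.
#' @export
robustnessProtocol <- function(farmSets, method,
                               config = trainConfig("desk"),
                               augment = TRUE, seed = config$seed,
                               modelCfg = modelConfig()) {
  stopifnot(length(farmSets) == 3, !is.null(names(farmSets)))
  combos <- .robustnessCombos(names(farmSets))
  runs <- vector("list", 3)
  for (i in 1:3) {
    runs[[i]] <- robustnessRun(farmSets, combos[[i]]$train,
                               combos[[i]]$test,
                               method, config, augment,
                               seed = deriveSeed(seed, 50L + i), modelCfg)
  }
  names(runs) <- vapply(combos, `[[`, "", "test")
  structure(list(runs = runs, mean = .meanMetrics(runs)),
            class = "robustnessReport")
}

#' @export
print.robustnessReport <- function(x, ...) {
  cat("robustnessReport (held-out farm -> accuracy):\n")
  for (nm in names(x$runs))
    cat(sprintf("  %s: %.4f\n", nm, x$runs[[nm]]$accuracy))
  cat(sprintf("  mean acc=%.4f prec=%.4f rec=%.4f F1=%.4f\n",
              x$mean$accuracy, x$mean$precision, x$mean$recall, x$mean$f1))
  invisible(x)
}
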