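# Speech and multi-source fusion classifiers with held-out evaluation.

.classifierReport <- function(truth, pred, levels, meta) {
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  conf <- table(truth = truth, predicted = pred)
  conf <- matrix(as.integer(conf), nrow = length(levels),
                 dimnames = list(truth = levels, predicted = levels))
  acc <- sum(diag(conf)) / sum(conf)
  rec <- diag(conf) / pmax(rowSums(conf), 1L)
  names(rec) <- levels
  new("ClassifierReport", accuracy = acc, confusion = conf,
      perClassRecall = rec, meta = meta)
}

.featureMatrix <- function(features) {
  X <- do.call(rbind, lapply(features, function(f) {
    stopifnot(is(f, "SpectralFeatures"))
    f@vector
  }))
  if (length(unique(vapply(features, function(f) length(f@vector), 1L))) != 1L)
    stop("feature vectors must share one length across the dataset",
         call. = FALSE)
  X
}

#' Train and evaluate the fully-connected speech classifier
#'
#' Fits a fully-connected softmax network (one hidden layer of `size`
#' rectifying units via `nnet`, weight decay regularization) on spectral
#' feature vectors.  Under the default `split = "per-class"` protocol each
#' class contributes `testPerClass` held-out sample(s) and the remainder
#' trains the network -- with 10 samples per class this is the 9 train /
#' 1 test per-class split.  Features are standardized by training-set
#' statistics.  Deterministic given `seed`.
#'
#' @param features list of [SpectralFeatures-class], one per sample.
#' @param labels character/factor vector of class labels, same length.
#' @param seed integer seed controlling the split and the initial weights.
#' @param testPerClass held-out samples per class (default 1).
#' @param minPerClass minimum samples a class must contribute (default 10,
#'   the 9 train / 1 test protocol).
#' @param size hidden-layer width.
#' @param decay weight-decay penalty.
#' @param maxit training iterations.
#' @return list with elements `model` (the fitted `nnet` plus scaling) and
#'   `report` (a [ClassifierReport-class]).
#' @examples
#' \donttest{
#' labs <- rep(speechLabels(), each = 10)
#' feats <- lapply(seq_along(labs), function(i) {
#'   fl <- genSpeechFlow(speechTemplate(labs[i]), seed = i)
#'   voltageSpectrum(simulateResponse(devicePlate(), fluidProperties(),
#'                                    fl, 300.15))
#' })
#' fit <- trainSpeechClassifier(feats, labs, seed = 1)
#' accuracy(fit$report)
#' }
#' @export
trainSpeechClassifier <- function(features, labels, seed = 1L,
                                  testPerClass = 1L, minPerClass = 10L,
                                  size = 32L, decay = 1e-3, maxit = 300L) {
  labels <- as.character(labels)
  if (length(features) != length(labels))
    stop("'features' and 'labels' must have equal length", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < max(minPerClass, testPerClass + 1L)))
    stop("every class needs >= ", max(minPerClass, testPerClass + 1L),
         " samples; the 9/1 protocol needs >= 10 samples per class",
         call. = FALSE)
  X <- .featureMatrix(features)
  .withSeed(seed, {
    testIdx <- unlist(lapply(classes, function(cl) {
      sample(which(labels == cl), testPerClass)
    }))
    trainIdx <- setdiff(seq_along(labels), testIdx)
    mu <- colMeans(X[trainIdx, , drop = FALSE])
    sdv <- apply(X[trainIdx, , drop = FALSE], 2L, sd)
    sdv[sdv < 1e-12] <- 1
    Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
    y <- nnet::class.ind(factor(labels, levels = classes))
    fit <- nnet::nnet(Xs[trainIdx, , drop = FALSE],
                      y[trainIdx, , drop = FALSE],
                      size = size, softmax = TRUE, decay = decay,
                      maxit = maxit, MaxNWts = 50000L, trace = FALSE)
    prob <- predict(fit, Xs[testIdx, , drop = FALSE])
    pred <- classes[max.col(prob, ties.method = "first")]
    report <- .classifierReport(labels[testIdx], pred, classes,
      meta = list(seed = seed, size = size, decay = decay, maxit = maxit,
                  nTrain = length(trainIdx), nTest = length(testIdx)))
    list(model = list(net = fit, center = mu, scale = sdv,
                      classes = classes),
         report = report)
  })
}

# Concatenated spectral features of the two channels of a recording, with
# channel-appropriate framing: the thermally low-passed voltage trace needs
# 1 s frames over the sub-15 Hz band; the PPG trace needs 2 s frames so the
# 0.25-1 Hz beat-rate differences are resolvable, capped at 12 Hz.
.fusionFeatures <- function(rec) {
  stopifnot(is(rec, "LabeledRecording"))
  fsHb <- 1 / diff(rec@hb$time_s[1:2])
  c(featureVector(voltageSpectrum(rec@ted, frameLen = 1, hop = 0.5,
                                  nFreqBins = 12L, nTimeBins = 12L,
                                  maxFreq = 15)),
    featureVector(spectralFeatures(rec@hb$value, fs = fsHb, frameLen = 2,
                                   hop = 0.5, nFreqBins = 24L,
                                   nTimeBins = 12L, maxFreq = 12)))
}

#' Train and evaluate the multi-source fusion classifier
#'
#' Concatenates the spectral feature vectors of the airflow-voltage and
#' heartbeat channels of each recording and trains a gradient-boosted
#' decision-tree ensemble (xgboost, shallow trees) on the fused label, with
#' a stratified hold-out evaluation.  Deterministic given `seed`
#' (single-threaded boosting).
#'
#' @param dataset list of [LabeledRecording-class] objects containing both
#'   fused classes.
#' @param seed integer seed for the split and boosting.
#' @param testFraction stratified hold-out fraction.
#' @param nrounds boosting rounds.
#' @param maxDepth tree depth.
#' @param eta learning rate.
#' @param shuffleLabels permute the labels before training (null control).
#' @return list with `model` (xgboost booster) and `report`
#'   (a [ClassifierReport-class]).
#' @examples
#' \donttest{
#' ds <- genFusionDataset(5, seed = 2)
#' fit <- trainFusionClassifier(ds, seed = 2)
#' accuracy(fit$report)
#' }
#' @export
trainFusionClassifier <- function(dataset, seed = 1L, testFraction = 0.25,
                                  nrounds = 400L, maxDepth = 5L, eta = 0.1,
                                  shuffleLabels = FALSE) {
  labels <- vapply(dataset, fusedLabel, "")
  if (length(unique(labels)) < 2L)
    stop("dataset must contain both fused classes", call. = FALSE)
  X <- do.call(rbind, lapply(dataset, .fusionFeatures))
  .withSeed(seed, {
    if (shuffleLabels) labels <- sample(labels)
    y <- as.integer(labels == "abnormal")
    testIdx <- unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, max(1L, round(testFraction * length(idx))))
    }))
    trainIdx <- setdiff(seq_along(labels), testIdx)
    if (length(unique(y[trainIdx])) < 2L)
      stop("training split lost a class; enlarge the dataset",
           call. = FALSE)
    dtr <- xgboost::xgb.DMatrix(X[trainIdx, , drop = FALSE],
                                label = y[trainIdx])
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = maxDepth,
                    eta = eta, nthread = 1L, seed = seed),
      data = dtr, nrounds = nrounds, verbose = 0)
    prob <- predict(bst, xgboost::xgb.DMatrix(X[testIdx, , drop = FALSE]))
    pred <- ifelse(prob > 0.5, "abnormal", "normal")
    report <- .classifierReport(labels[testIdx], pred,
      c("normal", "abnormal"),
      meta = list(seed = seed, nrounds = nrounds, maxDepth = maxDepth,
                  eta = eta, nTrain = length(trainIdx),
                  nTest = length(testIdx), shuffled = shuffleLabels))
    list(model = bst, report = report)
  })
}
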