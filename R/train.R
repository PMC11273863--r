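# Training loop contract: momentum SGD with a continuous exponential
# learning-rate decay, categorical cross-entropy on the softmax outputs,
# batch size 16. The "paper" profile carries the published settings
# (50 epochs, initial rate 5e-4); the "desk" profile is a scaled-down
# configuration meant to converge on the separable synthetic data within
# minutes on one CPU.

#' Training configuration
#'
#' @param profile `"paper"` (published settings: 50 epochs, initial
#'   learning rate 5e-4) or `"desk"` (scaled-down: 2 epochs, a larger
#'   initial rate for few-step convergence on synthetic data).
#' @param initialLr initial learning rate.
#' @param decaySteps learning-rate decay period in optimizer steps.
#' @param decayRate multiplicative decay per period.
#' @param staircase discrete (TRUE) or continuous (FALSE, default)
#'   decay.
#' @param momentum SGD momentum.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param seed seed for shuffling, weight init, and dropout.
#' @return a list of class `trainConfig`.
#' @export
trainConfig <- function(profile = c("paper", "desk"),
                        initialLr = NULL, decaySteps = 1000,
                        decayRate = 0.9, staircase = FALSE,
                        momentum = 0.9, batchSize = 16, epochs = NULL,
                        seed = 1) {
  profile <- match.arg(profile)
  if (is.null(initialLr)) initialLr <- if (profile == "paper") 5e-4 else 5e-3
  if (is.null(epochs)) epochs <- if (profile == "paper") 50 else 2
  stopifnot(epochs >= 1, initialLr > 0, batchSize >= 1)
  structure(list(profile = profile, optimizer = "sgd",
                 loss = "categorical_crossentropy",
                 initialLr = initialLr, decaySteps = decaySteps,
                 decayRate = decayRate, staircase = staircase,
                 momentum = momentum, batchSize = batchSize,
                 epochs = epochs, seed = seed),
            class = "trainConfig")
}

#' Learning rate at an optimizer step
#'
#' Continuous exponential decay
#' `initialLr * decayRate^(step / decaySteps)` (or the staircase variant
#' with a floored exponent).
#'
#' @param step optimizer step (>= 0).
#' @param config a [trainConfig()].
#' @return the learning rate.
#' @examples
#' lrAtStep(0, trainConfig())     # 5e-4
#' lrAtStep(1000, trainConfig())  # 4.5e-4
#' @export
lrAtStep <- function(step, config = trainConfig()) {
  stopifnot(all(step >= 0))
  expo <- if (config$staircase) floor(step / config$decaySteps)
          else step / config$decaySteps
  config$initialLr * config$decayRate^expo
}

.labelsToInt <- function(labels) {
  if (!all(labels %in% c("vocalization", "non_vocalization")))
    stop("labels must be 'vocalization' or 'non_vocalization'")
  ifelse(labels == "vocalization", 0L, 1L)  # neuron 1 = vocalization
}

# ClipSet -> (H x 130 x N) input array + integer labels. Features are
# extracted one clip at a time to keep the peak memory at one matrix
# beyond the output array.
.featureArray <- function(set, method, params = stftParams()) {
  cl <- clips(set)
  f1 <- extractFeatures(cl[[1]], method, params)
  d <- dim(f1)
  X <- array(0, c(d[1], d[2], length(cl)))
  X[, , 1] <- .networkInput(f1)
  for (i in seq_along(cl)[-1])
    X[, , i] <- .networkInput(extractFeatures(cl[[i]], method, params))
  list(X = X, y = .labelsToInt(clipLabel(set)))
}

#' Train the classifier on a labeled clip set
#'
#' Extracts features for every clip, z-scores each feature matrix, and
#' runs momentum SGD with the configured schedule. Deterministic given
#' `config$seed` (shuffling, dropout, and weight initialization all
#' derive from it).
#'
#' @param set a training [ClipSet] (typically augmented).
#' @param method feature method (`"mfcc"`, `"mel"`, `"chroma"`,
#'   `"tonnetz12"`, `"mixed_mmct"`).
#' @param config a [trainConfig()].
#' @param modelCfg a [modelConfig()].
#' @param model optionally a pre-built `dcnnModel` to continue training.
#' @return a list of class `dcnnFit`: `model` (trained `dcnnModel`),
#'   `history` (per-epoch mean cross-entropy), `steps`, `trainIds`
#'   (provenance of every clip seen in training, including augmentation
#'   sources).
#' @export
trainNetwork <- function(set, method, config = trainConfig("desk"),
                         modelCfg = modelConfig(), model = NULL) {
  stopifnot(is(set, "ClipSet"))
  if (length(set) == 0L) stop("training set is empty")
  fa <- .featureArray(set, method)
  fit <- .trainOnArray(fa$X, fa$y, config, modelCfg, model)
  man <- manifest(set)
  structure(c(fit, list(trainIds = unique(c(man$id, man$source_id)))),
            class = "dcnnFit")
}

# Core SGD driver on a prebuilt (H x W x N) input array; shuffling,
# dropout, and weight init all derive from config$seed.
.trainOnArray <- function(X, y, config, modelCfg = modelConfig(),
                          model = NULL) {
  if (is.null(model))
    model <- buildModel(dim(X)[1:2], modelCfg,
                        seed = deriveSeed(config$seed, 1L))
  n <- dim(X)[3]
  order <- withSeed(deriveSeed(config$seed, 2L), {
    t(vapply(seq_len(config$epochs), function(e) sample.int(n) - 1L,
             integer(n)))
  })
  storage.mode(order) <- "integer"
  fit <- cpp_dcnn_train(X, as.integer(y), model$weights,
                        lr0 = config$initialLr,
                        decayRate = config$decayRate,
                        decaySteps = config$decaySteps,
                        staircase = config$staircase,
                        momentum = config$momentum,
                        batchSize = config$batchSize,
                        epochs = config$epochs,
                        dropoutRate = model$config$dropoutRate,
                        order = order,
                        dropoutSeed = deriveSeed(config$seed, 3L))
  model$weights <- fit$weights
  list(model = model, history = as.numeric(fit$loss), steps = fit$steps)
}

#' @export
print.dcnnFit <- function(x, ...) {
  cat(sprintf("dcnnFit: %d epochs, final loss %.4f, %d clips seen\n",
              length(x$history), x$history[length(x$history)],
              length(x$trainIds)))
  invisible(x)
}
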