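# The fixed three-block convolutional classifier: builder, decision
# rule, and closed-form trainable-parameter / FLOP counters. The
# architecture is conv(32, 5x5, same) -> pool(2x2) -> conv(64) -> pool
# -> conv(128) -> pool -> dropout(0.5) -> dense(1000, ReLU) ->
# dense(2, softmax), with floor rounding in the pooling layers. Output
# neuron 1 is the vocalization class.

#' Network architecture configuration
#'
#' @param convFilters filters per block, fixed at `c(32, 64, 128)`.
#' @param kernel square kernel edge (5).
#' @param pool square pooling edge (2), floor rounding.
#' @param dropoutRate dropout after the third block (0.5).
#' @param fc1Units first dense layer width (1000).
#' @param nClasses output classes (2).
#' @return a list of class `modelConfig`.
#' @export
modelConfig <- function(convFilters = c(32, 64, 128), kernel = 5, pool = 2,
                        dropoutRate = 0.5, fc1Units = 1000, nClasses = 2) {
  stopifnot(length(convFilters) == 3, fc1Units >= 1, nClasses == 2)
  structure(list(convFilters = convFilters, kernel = kernel, pool = pool,
                 dropoutRate = dropoutRate, fc1Units = fc1Units,
                 nClasses = nClasses),
            class = "modelConfig")
}

# Spatial dimensions after the three same-conv + floor-pool blocks.
.shapeChain <- function(rows, cols, config) {
  h <- rows; w <- cols
  chain <- list()
  for (l in 1:3) {
    h <- h %/% config$pool
    w <- w %/% config$pool
    chain[[l]] <- c(h, w)
    if (h < 1 || w < 1)
      stop("input shape (", rows, " x ", cols,
           ") too small for three 2x2 poolings (block ", l,
           " spatial dimension reaches 0)")
  }
  chain
}

#' Build the classifier for a feature input shape
#'
#' Initializes weights (He-scaled Gaussians, seeded) for the fixed
#' architecture on a `rows x cols x 1` input.
#'
#' @param inputShape integer vector `(rows, cols)` or `(rows, cols, 1)`;
#'   e.g. `c(166, 130)` for the fused features.
#' @param config a [modelConfig()].
#' @param seed seed for weight initialization.
#' @return a list of class `dcnnModel` with elements `weights`,
#'   `inputShape`, `config`, `flatSize`.
#' @examples
#' m <- buildModel(c(20, 130))
#' m$flatSize  # 4096
#' @export
buildModel <- function(inputShape, config = modelConfig(), seed = 1) {
  rows <- inputShape[1]
  cols <- if (length(inputShape) >= 2) inputShape[2] else 130
  chain <- .shapeChain(rows, cols, config)
  k2 <- config$kernel^2
  cf <- config$convFilters
  flat <- chain[[3]][1] * chain[[3]][2] * cf[3]
  he <- function(nOut, nIn) matrix(stats::rnorm(nOut * nIn, 0,
                                                sqrt(2 / nIn)), nOut, nIn)
  weights <- withSeed(seed, list(
    W1 = he(cf[1], k2 * 1), b1 = numeric(cf[1]),
    W2 = he(cf[2], k2 * cf[1]), b2 = numeric(cf[2]),
    W3 = he(cf[3], k2 * cf[2]), b3 = numeric(cf[3]),
    W4 = he(config$fc1Units, flat), b4 = numeric(config$fc1Units),
    # near-zero output layer: initial logits ~ 0, so early steps train the
    # features rather than un-doing initialization noise
    W5 = matrix(stats::rnorm(config$nClasses * config$fc1Units, 0, 0.01),
                config$nClasses, config$fc1Units),
    b5 = numeric(config$nClasses)
  ))
  structure(list(weights = weights, inputShape = c(rows, cols, 1),
                 config = config, flatSize = flat, shapeChain = chain),
            class = "dcnnModel")
}

#' @export
print.dcnnModel <- function(x, ...) {
  pc <- countTrainableParams(x$inputShape, x$config)
  cat(sprintf("dcnnModel: input %d x %d x 1, flatten %d, %s trainable params (%.2f M)\n",
              x$inputShape[1], x$inputShape[2], x$flatSize,
              format(pc$total, big.mark = ","), pc$totalMillions))
  invisible(x)
}

# Number of trainable weights actually held by a built model (the
# built-network count the closed form must agree with).
modelWeightCount <- function(model) {
  sum(vapply(model$weights, length, 0L))
}

#' Closed-form trainable-parameter count
#'
#' Per layer: a convolution contributes `k*k*cin*cout + cout`, a dense
#' layer `nin*nout + nout`; pooling and dropout contribute nothing.
#' Matches the built network's weight count exactly.
#'
#' @param inputShape `(rows, cols)` feature shape (cols defaults to 130).
#' @param config a [modelConfig()].
#' @return list with `perLayer` (data.frame layer/count), `total`
#'   (integer), and `totalMillions` (rounded to 2 decimals).
#' @examples
#' countTrainableParams(c(166, 130))$totalMillions  # 41.22
#' @export
countTrainableParams <- function(inputShape, config = modelConfig()) {
  rows <- inputShape[1]
  cols <- if (length(inputShape) >= 2) inputShape[2] else 130
  chain <- .shapeChain(rows, cols, config)
  k2 <- config$kernel^2
  cf <- config$convFilters
  flat <- chain[[3]][1] * chain[[3]][2] * cf[3]
  counts <- c(
    conv1 = k2 * 1 * cf[1] + cf[1],
    conv2 = k2 * cf[1] * cf[2] + cf[2],
    conv3 = k2 * cf[2] * cf[3] + cf[3],
    dense1 = flat * config$fc1Units + config$fc1Units,
    dense2 = config$fc1Units * config$nClasses + config$nClasses
  )
  list(perLayer = data.frame(layer = names(counts), count = as.numeric(counts)),
       total = sum(counts),
       totalMillions = round(sum(counts) / 1e6, 2))
}

#' Closed-form FLOP count for one forward pass
#'
#' Accumulates per-layer multiply-accumulates (convolutions:
#' `H*W*cout*k*k*cin` with size-preserving padding; dense: `nin*nout`)
#' plus bias additions. Under `"mac"` each multiply-accumulate counts
#' once; under `"2xmac"` (default) multiplies and additions are counted
#' separately, i.e. the total is doubled.
#'
#' @inheritParams countTrainableParams
#' @param convention `"2xmac"` or `"mac"`.
#' @return list with `perLayerMacs`, `gflops` (total under the chosen
#'   convention, in units of 1e9).
#' @examples
#' countFlops(c(166, 130))$gflops  # ~1.21
#' @export
countFlops <- function(inputShape, config = modelConfig(),
                       convention = c("2xmac", "mac")) {
  convention <- match.arg(convention)
  rows <- inputShape[1]
  cols <- if (length(inputShape) >= 2) inputShape[2] else 130
  chain <- .shapeChain(rows, cols, config)
  k2 <- config$kernel^2
  cf <- config$convFilters
  flat <- chain[[3]][1] * chain[[3]][2] * cf[3]
  # conv l sees the pooled output of block l-1 as input
  sp <- list(c(rows, cols), chain[[1]], chain[[2]])
  cin <- c(1, cf[1], cf[2])
  macs <- numeric(0)
  adds <- numeric(0)
  for (l in 1:3) {
    hw <- sp[[l]][1] * sp[[l]][2]
    macs[paste0("conv", l)] <- hw * cf[l] * k2 * cin[l]
    adds[paste0("conv", l)] <- hw * cf[l]
  }
  macs["dense1"] <- flat * config$fc1Units
  adds["dense1"] <- config$fc1Units
  macs["dense2"] <- config$fc1Units * config$nClasses
  adds["dense2"] <- config$nClasses
  mult <- if (convention == "2xmac") 2 else 1
  list(perLayerMacs = macs,
       gflops = mult * (sum(macs) + sum(adds)) / 1e9)
}

# Feature matrix -> network input: per-matrix z-scoring so dB-scale and
# unit-scale features train under comparable dynamics.
.networkInput <- function(fm) {
  v <- featureValues(fm)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(v * 0)
  (v - mean(v)) / s
}

#' Class probabilities for feature matrices
#'
#' @param model a `dcnnModel`.
#' @param features a [FeatureMatrix] or list of them, matching the
#'   model's input shape.
#' @return matrix `n x 2` of softmax probabilities; column 1 is the
#'   vocalization class.
#' @export
predictProba <- function(model, features) {
  if (is(features, "FeatureMatrix")) features <- list(features)
  d <- dim(features[[1]])
  if (d[1] != model$inputShape[1] || d[2] != model$inputShape[2])
    stop("feature shape (", d[1], " x ", d[2],
         ") does not match model input (", model$inputShape[1], " x ",
         model$inputShape[2], ")")
  X <- array(0, c(d[1], d[2], length(features)))
  for (i in seq_along(features)) X[, , i] <- .networkInput(features[[i]])
  p <- cpp_dcnn_predict(X, model$weights)
  colnames(p) <- c("vocalization", "non_vocalization")
  p
}

#' Classify a feature matrix
#'
#' Label is `"vocalization"` when the first output neuron strictly
#' exceeds the second; otherwise (including ties) `"non_vocalization"`.
#'
#' @param model a `dcnnModel`.
#' @param feature a [FeatureMatrix].
#' @return list with `label` and `proba` (named length-2 vector).
#' @export
classify <- function(model, feature) {
  p <- predictProba(model, feature)[1, ]
  list(label = .decisionRule(p[1], p[2]), proba = p)
}

# The published decision rule: vocalization iff p1 > p2; the tie goes to
# non-vocalization.
.decisionRule <- function(p1, p2) {
  if (p1 > p2) "vocalization" else "non_vocalization"
}
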