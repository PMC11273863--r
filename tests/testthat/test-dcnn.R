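test_that("closed-form parameter counts match the published table", {
  shapes <- list(mfcc = 20, mel = 128, chroma = 12, tonnetz12 = 12,
                 mixed = 166)
  exact <- c(mfcc = 4356026, mel = 33028026, chroma = 2308026,
             tonnetz12 = 2308026, mixed = 41220026)
  printed <- c(mfcc = 4.36, mel = 33.03, chroma = 2.31,
               tonnetz12 = 2.31, mixed = 41.22)
  for (nm in names(shapes)) {
    pc <- countTrainableParams(c(shapes[[nm]], 130))
    expect_equal(pc$total, exact[[nm]], info = nm)
    expect_equal(pc$totalMillions, printed[[nm]], info = nm)
    expect_equal(sum(pc$perLayer$count), pc$total, info = nm)
  }
  # per-layer closed form for the smallest input
  pl <- countTrainableParams(c(20, 130))$perLayer
  expect_equal(pl$count, c(832, 51264, 204928, 4097000, 2002))
})

test_that("the counter equals the built network's own weight count", {
  for (rows in c(20, 128, 12, 166)) {
    m <- buildModel(c(rows, 130), seed = 1)
    built <- sum(vapply(m$weights, length, 0L))
    expect_identical(built, as.integer(countTrainableParams(
      c(rows, 130))$total), info = paste("rows", rows))
  }
})

test_that("parameter count grows with input rows", {
  totals <- vapply(c(12, 20, 64, 128, 166),
                   function(r) countTrainableParams(c(r, 130))$total, 0)
  expect_true(all(diff(totals) > 0))
})

test_that("shape propagation matches the floor-pooling oracle", {
  expect_equal(buildModel(c(20, 130))$flatSize, 2 * 16 * 128)
  expect_equal(buildModel(c(166, 130))$flatSize, 20 * 16 * 128)
  expect_equal(buildModel(c(12, 130))$flatSize, 1 * 16 * 128)
  # three floor-halvings must stay >= 1: 6 -> 3 -> 1 -> 0 fails
  expect_error(buildModel(c(6, 130)), "too small")
  expect_error(countTrainableParams(c(4, 130)), "too small")
})

test_that("FLOP counting is convention-consistent and matches the table", {
  fl <- countFlops(c(20, 130), convention = "mac")
  expect_equal(unname(fl$perLayerMacs["dense1"]), 4096 * 1000)
  # doubling the dense width doubles exactly the dense term
  cfgWide <- modelConfig(fc1Units = 2000)
  flWide <- countFlops(c(20, 130), cfgWide, convention = "mac")
  expect_equal(unname(flWide$perLayerMacs["dense1"]),
               2 * unname(fl$perLayerMacs["dense1"]))
  # full network under the 2xMAC convention reproduces the printed GFLOPS
  expect_equal(round(countFlops(c(166, 130))$gflops, 2), 1.21)
  expect_equal(round(countFlops(c(20, 130))$gflops, 3), 0.145)
  expect_equal(round(countFlops(c(128, 130))$gflops, 3), 0.939)
  expect_equal(round(countFlops(c(12, 130))$gflops, 3), 0.086)
  # the two conventions differ exactly twofold
  expect_equal(countFlops(c(166, 130), convention = "2xmac")$gflops,
               2 * countFlops(c(166, 130), convention = "mac")$gflops)
})

test_that("the engine's forward pass matches a double-precision reference", {
  withr::with_seed(42, {
    m <- buildModel(c(16, 24), seed = 9)
    X <- array(stats::rnorm(16 * 24 * 3), c(16, 24, 3))
    engine <- pigvoc:::cpp_dcnn_predict(X, m$weights)
    for (i in 1:3) {
      ref <- refForward(m$weights, X[, , i])
      expect_equal(unname(engine[i, ]), ref, tolerance = 1e-5)
    }
    expect_equal(unname(rowSums(engine)), rep(1, 3), tolerance = 1e-6)
  })
})

test_that("analytic gradients agree with numeric gradients of the reference", {
  withr::with_seed(3, {
    m <- buildModel(c(8, 16), seed = 2)
    X <- array(stats::rnorm(8 * 16 * 2), c(8, 16, 2))
    y <- c(0L, 1L)
    lossRef <- function(w) -mean(vapply(1:2, function(i)
      log(refForward(w, X[, , i])[y[i] + 1]), 0))
    lr <- 1e-4
    fit <- pigvoc:::cpp_dcnn_train(X, y, m$weights, lr, 1, 1000, FALSE,
                                   0, 2, 1, 0, matrix(c(0L, 1L), 1, 2), 1)
    for (nm in names(m$weights)) {
      gA <- (m$weights[[nm]] - fit$weights[[nm]]) / lr
      idx <- sample(length(gA), min(4, length(gA)))
      gN <- vapply(idx, function(i) {
        wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + 1e-6
        wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - 1e-6
        (lossRef(wp) - lossRef(wm)) / 2e-6
      }, 0)
      # single-precision engine vs double-precision oracle, relative to
      # the layer's gradient magnitude
      expect_lt(max(abs(gN - gA[idx])) / max(abs(gA), 1e-4), 0.05)
    }
  })
})

test_that("classification follows the first-neuron rule with ties negative", {
  expect_identical(pigvoc:::.decisionRule(0.7, 0.3), "vocalization")
  expect_identical(pigvoc:::.decisionRule(0.5, 0.5), "non_vocalization")
  expect_identical(pigvoc:::.decisionRule(0.3, 0.7), "non_vocalization")

  m <- buildModel(c(20, 130), seed = 4)
  clip <- makeVocalization(builtinFarmProfiles()[[1]], seed = 2)
  out <- classify(m, extractFeatures(clip, "mfcc"))
  expect_true(out$label %in% c("vocalization", "non_vocalization"))
  expect_equal(unname(sum(out$proba)), 1, tolerance = 1e-6)
  expect_identical(out$label == "vocalization",
                   unname(out$proba[1] > out$proba[2]))
  expect_error(predictProba(m, extractFeatures(clip, "mel")),
               "does not match")
})
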