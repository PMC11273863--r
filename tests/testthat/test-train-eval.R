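test_that("the learning-rate schedule decays continuously from 5e-4", {
  cfg <- trainConfig("paper")
  expect_equal(lrAtStep(0, cfg), 5e-4)
  expect_equal(lrAtStep(1000, cfg), 4.5e-4)
  expect_equal(lrAtStep(2000, cfg), 5e-4 * 0.9^2)
  steps <- seq(0, 5000, by = 50)
  lrs <- lrAtStep(steps, cfg)
  expect_true(all(diff(lrs) < 0))
  # continuous (non-staircase): mid-period steps sit between endpoints
  expect_lt(lrAtStep(500, cfg), 5e-4)
  expect_gt(lrAtStep(500, cfg), 4.5e-4)
  stair <- trainConfig("paper", staircase = TRUE)
  expect_equal(lrAtStep(500, stair), 5e-4)
  expect_equal(lrAtStep(1500, stair), 4.5e-4)
})

test_that("the paper profile carries the published training settings", {
  cfg <- trainConfig("paper")
  expect_equal(cfg$initialLr, 5e-4)
  expect_equal(cfg$decaySteps, 1000)
  expect_equal(cfg$decayRate, 0.9)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$batchSize, 16)
  expect_equal(cfg$epochs, 50)
  expect_identical(cfg$optimizer, "sgd")
  expect_identical(cfg$loss, "categorical_crossentropy")
  expect_equal(modelConfig()$dropoutRate, 0.5)
})

test_that("stratified folds partition a balanced set evenly", {
  set <- tinyClipSet(4000, seed = 2)
  fs <- makeFolds(set, 5, seed = 3)
  sizes <- table(fs$assignments)
  expect_equal(unname(as.vector(sizes)), rep(800, 5))
  # training split of any fold is 3200
  expect_equal(sum(fs$assignments != 1), 3200)
  # per-fold class balance within one clip
  man <- manifest(set)
  for (f in 1:5) {
    lab <- man$label[fs$assignments == f]
    expect_lte(abs(sum(lab == "vocalization") -
                   sum(lab == "non_vocalization")), 1)
  }
  # partition: each clip in exactly one fold
  expect_length(fs$assignments, 4000)
  expect_setequal(names(fs$assignments), man$id)
  expect_error(makeFolds(set, 1), "at least 2")
  expect_error(makeFolds(tinyClipSet(4), 5), "exceeds")
})

test_that("metrics follow the four formulas exactly", {
  perfect <- metricsFromCounts(confusionCounts(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  recall = 1, f1 = 1))
  m <- metricsFromCounts(confusionCounts(50, 40, 5, 5))
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$f1, 50 / 55)
  expect_warning(z <- metricsFromCounts(confusionCounts(0, 5, 0, 3)),
                 "precision")
  expect_equal(z$precision, 0)
  expect_error(metricsFromCounts(confusionCounts(0, 0, 0, 0)), "zero")
  expect_error(confusionCounts(-1, 0, 0, 0), "non-negative")
})

test_that("metrics agree with a per-sample tally oracle", {
  withr::with_seed(11, {
    for (rep in 1:200) {
      n <- sample(10:60, 1)
      truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
      pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
      counts <- confusionCounts(sum(pred & truth), sum(!pred & !truth),
                                sum(pred & !truth), sum(!pred & truth))
      got <- suppressWarnings(metricsFromCounts(counts))
      # oracle: direct per-sample tallies
      accO <- mean(pred == truth)
      precO <- if (sum(pred) == 0) 0 else sum(pred & truth) / sum(pred)
      recO <- if (sum(truth) == 0) 0 else sum(pred & truth) / sum(truth)
      expect_equal(got$accuracy, accO)
      expect_equal(got$precision, precO)
      expect_equal(got$recall, recO)
      if (precO + recO > 0)
        expect_equal(got$f1, 2 * precO * recO / (precO + recO),
                     tolerance = 1e-12)
      # identities
      expect_lte(got$f1, max(got$precision, got$recall) + 1e-12)
      expect_identical(got$f1 == 0, counts$TP == 0)
      expect_gte(got$accuracy, 0); expect_lte(got$accuracy, 1)
    }
  })
})

test_that("ROC/AUC behave at the degenerate and null extremes", {
  # all-positive classifier: recall 1, precision = base rate
  p <- cbind(rep(1, 100), rep(0, 100))
  isPos <- c(rep(TRUE, 30), rep(FALSE, 70))
  r <- pigvoc:::.reportFromProbs(p, isPos)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 0.3)
  # perfect separation
  sep <- cbind(c(rep(0.9, 50), rep(0.1, 50)))
  sep <- cbind(sep, 1 - sep)
  rp <- pigvoc:::.reportFromProbs(sep, c(rep(TRUE, 50), rep(FALSE, 50)))
  expect_equal(rp$auc, 1)
  expect_equal(rp$accuracy, 1)
  # random scores on balanced labels: AUC ~ 0.5 (Monte-Carlo null)
  withr::with_seed(5, {
    s <- stats::runif(2000)
    pr <- cbind(s, 1 - s)
    rn <- pigvoc:::.reportFromProbs(pr, rep(c(TRUE, FALSE), 1000))
    expect_lt(abs(rn$auc - 0.5), 0.03)
  })
})

test_that("a smoke-scale training run completes with finite losses", {
  set <- makeFarmDataset(builtinFarmProfiles()[["jeongeup-like"]], 10,
                         seed = 31)
  cfg <- trainConfig("desk", epochs = 2, seed = 8)
  fit <- trainNetwork(set, "mfcc", cfg)
  expect_length(fit$history, 2)
  expect_true(all(is.finite(fit$history)))
  expect_equal(fit$steps, 2 * ceiling(20 / 16))
  test <- makeFarmDataset(builtinFarmProfiles()[["jeongeup-like"]], 5,
                          seed = 77)
  r <- suppressWarnings(evaluateModel(fit, test, "mfcc"))
  expect_equal(r$counts$TP + r$counts$TN + r$counts$FP + r$counts$FN, 10)
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  expect_error(trainNetwork(set[integer(0)], "mfcc", cfg), "empty")
})

test_that("training is reproducible under a fixed seed", {
  set <- makeFarmDataset(builtinFarmProfiles()[["jeongeup-like"]], 6,
                         seed = 31)
  cfg <- trainConfig("desk", epochs = 1, seed = 8)
  f1 <- trainNetwork(set, "mfcc", cfg)
  f2 <- trainNetwork(set, "mfcc", cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$weights$W5, f2$model$weights$W5)
})

test_that("augmented copies of held-out clips are caught as leakage", {
  set <- makeFarmDataset(builtinFarmProfiles()[["nias-like"]], 4, seed = 51)
  aug <- augmentTrainingSet(set, seed = 3)
  cfg <- trainConfig("desk", epochs = 1, seed = 8)
  fit <- trainNetwork(aug, "mfcc", cfg)
  # evaluating on the originals must trip the provenance assertion
  expect_error(evaluateModel(fit, set, "mfcc"), "protocol error")
  # an independently generated set passes
  fresh <- makeFarmDataset(builtinFarmProfiles()[["nias-like"]], 2,
                           seed = 52)
  expect_s3_class(suppressWarnings(evaluateModel(fit, fresh, "mfcc")),
                  "evalReport")
})

test_that("cross-validation averages its fold reports exactly", {
  set <- makeFarmDataset(builtinFarmProfiles()[["jeongeup-like"]], 10,
                         seed = 61)
  cv <- suppressWarnings(
    crossValidate(set, "mfcc", trainConfig("desk", epochs = 1, seed = 2),
                  k = 5))
  expect_length(cv$folds, 5)
  for (metric in c("accuracy", "precision", "recall", "f1")) {
    expect_equal(cv$mean[[metric]],
                 mean(vapply(cv$folds, `[[`, 0, metric)),
                 tolerance = 1e-12)
  }
  # every fold evaluated once, on 1/5 of the data
  expect_true(all(vapply(cv$folds, `[[`, 0, "n") == 4))
})

test_that("the robustness protocol trains on two farms and tests the third", {
  combos <- pigvoc:::.robustnessCombos(c("nias", "gimje", "jeongeup"))
  expect_equal(combos[[1]], list(train = c("nias", "gimje"),
                                 test = "jeongeup"))
  expect_equal(combos[[2]], list(train = c("nias", "jeongeup"),
                                 test = "gimje"))
  expect_equal(combos[[3]], list(train = c("gimje", "jeongeup"),
                                 test = "nias"))

  farms <- makeThreeFarms(3, seed = 71)
  expect_error(robustnessRun(farms, c("nias-like", "gimje-like"),
                             "gimje-like", "mfcc"), "protocol error")
  expect_error(robustnessRun(farms, c("nias-like", "gimje-like"),
                             "elsewhere", "mfcc"), "unknown farm")
  r <- suppressWarnings(
    robustnessRun(farms, c("nias-like", "gimje-like"), "jeongeup-like",
                  "mfcc", trainConfig("desk", epochs = 1, seed = 4),
                  augment = FALSE))
  expect_s3_class(r, "evalReport")
  expect_equal(r$n, 6)
  expect_identical(attr(r, "testFarm"), "jeongeup-like")
})
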