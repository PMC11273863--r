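profiles <- builtinFarmProfiles()

test_that("generation is bit-identical under a fixed seed", {
  p <- profiles[["nias-like"]]
  expect_identical(samples(makeVocalization(p, seed = 7)),
                   samples(makeVocalization(p, seed = 7)))
  expect_identical(samples(makeNonVocalization(p, seed = 7)),
                   samples(makeNonVocalization(p, seed = 7)))
  expect_false(identical(samples(makeVocalization(p, seed = 7)),
                         samples(makeVocalization(p, seed = 8))))
})

test_that("clip loudness stays within 2 dB of the profile target", {
  # loudness contract checked across > 100 seeds spread over profiles
  for (p in profiles) {
    voc <- vapply(1:20, function(s) dbfs(makeVocalization(p, seed = s)), 0)
    non <- vapply(21:40, function(s)
      dbfs(makeNonVocalization(p, seed = s)), 0)
    expect_true(all(abs(voc - p@targetDbfsVoc) <= 2),
                label = paste(p@name, "vocalization loudness"))
    expect_true(all(abs(non - p@targetDbfsNonvoc) <= 2),
                label = paste(p@name, "non-vocalization loudness"))
  }
  # the published per-farm averages are the built-in targets
  expect_equal(profiles[["nias-like"]]@targetDbfsVoc, -24.86)
  expect_equal(profiles[["nias-like"]]@targetDbfsNonvoc, -28.58)
  expect_equal(profiles[["jeongeup-like"]]@targetDbfsVoc, -18.99)
})

test_that("vocalization spectra peak at the fundamental or a harmonic", {
  # narrow f0 interval makes the admissible peak set checkable by FFT
  params <- vocalEventParams(f0Range = c(400, 410), nHarmonics = 8,
                             nBurstsRange = c(1, 2))
  p <- farmProfile("quiet", noiseColor = "white",
                   targetDbfsVoc = -20, targetDbfsNonvoc = -30)
  for (s in 1:50) {
    clip <- makeVocalization(p, params, seed = s)
    peak <- fftPeakHz(samples(clip), sampleRate(clip))
    harmonic <- peak / round(peak / 405)
    expect_true(round(peak / 405) <= 8 && harmonic > 385 && harmonic < 425,
                label = sprintf("seed %d peak %.1f Hz", s, peak))
  }
})

test_that("non-vocalization clips are spectrally flat relative to calls", {
  p <- farmProfile("flatfarm", noiseColor = "white", humHz = 0,
                   targetDbfsVoc = -20, targetDbfsNonvoc = -25,
                   reverbSmearMs = 0)
  for (s in 1:50) {
    fv <- spectralFlatness(samples(makeVocalization(p, seed = s)))
    fn <- spectralFlatness(samples(makeNonVocalization(p, seed = 1000 + s)))
    expect_gt(fn, fv)
  }
})

test_that("farm datasets are balanced, labeled, and seed-reproducible", {
  p <- profiles[["gimje-like"]]
  set <- makeFarmDataset(p, 5, seed = 42)
  expect_length(set, 10)
  expect_equal(sum(clipLabel(set) == "vocalization"), 5)
  expect_equal(sum(clipLabel(set) == "non_vocalization"), 5)
  expect_true(all(clipFarm(set) == "gimje-like"))
  expect_true(all(vapply(clips(set), nSamples, 0L) == 66150L))

  minimal <- makeFarmDataset(p, 1, seed = 1)
  expect_length(minimal, 2)
  expect_setequal(clipLabel(minimal), c("vocalization", "non_vocalization"))

  again <- makeFarmDataset(p, 5, seed = 42)
  expect_identical(samples(clips(set)[[1]]), samples(clips(again)[[1]]))
  other <- makeFarmDataset(p, 5, seed = 43)
  expect_length(other, 10)
  expect_false(identical(samples(clips(set)[[1]]),
                         samples(clips(other)[[1]])))
  expect_error(makeFarmDataset(p, 0, seed = 1), "positive")
})

test_that("the three virtual farms differ in loudness and noise color", {
  farms <- makeThreeFarms(5, seed = 9)
  expect_named(farms, c("nias-like", "gimje-like", "jeongeup-like"))
  expect_true(all(vapply(farms, length, 0L) == 10L))

  avgDbfs <- vapply(farms, function(s) mean(manifest(s)$dbfs), 0)
  expect_true(avgDbfs[["jeongeup-like"]] > avgDbfs[["nias-like"]])
  expect_true(avgDbfs[["jeongeup-like"]] > avgDbfs[["gimje-like"]])

  # spectral-slope oracle on the noise class: white ~ 0 > pink ~ -1 >
  # brown ~ -2 (log-log power slope)
  slopeOf <- function(set) {
    nn <- which(clipLabel(set) == "non_vocalization")
    mean(vapply(nn, function(i)
      spectralSlope(samples(clips(set)[[i]]), 22050), 0))
  }
  sl <- vapply(farms, slopeOf, 0)
  expect_true(sl[["jeongeup-like"]] > sl[["nias-like"]])
  expect_true(sl[["nias-like"]] > sl[["gimje-like"]])
})

test_that("invalid generator parameters are rejected", {
  expect_error(vocalEventParams(f0Range = c(50, 300)), "100")
  expect_error(vocalEventParams(burstDurRange = c(0.5, 3.5)), "3-s")
  expect_error(farmProfile("x", targetDbfsVoc = 5), "negative")
  expect_error(farmProfile("x", noiseColor = "violet"), "white")
})

test_that("clip sets round-trip through WAV + manifest on disk", {
  dir <- withr::local_tempdir()
  set <- makeFarmDataset(profiles[["nias-like"]], 2, seed = 3)
  mp <- writeClipSet(set, dir)
  expect_true(file.exists(mp))
  man <- utils::read.csv(mp)
  expect_named(man, c("clip_path", "label", "farm", "seed", "dbfs"))
  back <- readClipSet(mp)
  expect_length(back, 4)
  expect_setequal(clipLabel(back), clipLabel(set))
  # 16-bit quantization bounds the round-trip error
  expect_lt(max(abs(samples(clips(back)[[1]]) - samples(clips(set)[[1]]))),
            2^-14)
})
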