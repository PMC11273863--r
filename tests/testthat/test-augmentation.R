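clip <- makeVocalization(builtinFarmProfiles()[["nias-like"]], seed = 21)

test_that("null-parameter operators are identities", {
  expect_identical(samples(pitchShift(clip, 0)), samples(clip))
  expect_identical(samples(timeShift(clip, 0)), samples(clip))
  expect_identical(samples(timeStretch(clip, 1)), samples(clip))
  noise <- audioClip(numeric(nSamples(clip)), 22050)
  expect_identical(samples(addBackgroundNoise(clip, noise, 0.7)),
                   samples(clip))
})

test_that("pitch shifting moves tones by the requested ratio, not duration", {
  a4 <- sineClip(440)
  up <- pitchShift(a4, 12)
  expect_identical(nSamples(up), nSamples(a4))
  # FFT-peak oracle, one STFT-bin tolerance (22050/2048 ~ 10.8 Hz)
  expect_lt(abs(fftPeakHz(samples(up), 22050) - 880), 10.8)
  down <- pitchShift(a4, -12)
  expect_lt(abs(fftPeakHz(samples(down), 22050) - 220), 10.8)
  # fractional shift: 4 semitones up
  four <- pitchShift(a4, 4)
  expect_lt(abs(fftPeakHz(samples(four), 22050) - 440 * 2^(4 / 12)), 10.8)
  expect_error(pitchShift(a4, NaN), "finite")
  # every operator output keeps the standardized length
  expect_identical(nSamples(pitchShift(clip, 2.5)), 66150L)
})

test_that("time shifting displaces samples and zero-fills exactly", {
  rate <- sampleRate(clip)
  marker <- audioClip(c(rep(0.5, rate), numeric(2 * rate)), rate)
  fwd <- timeShift(marker, 1)
  expect_identical(samples(fwd)[1:rate], numeric(rate))
  expect_identical(samples(fwd)[(rate + 1):(2 * rate)], rep(0.5, rate))
  expect_identical(samples(fwd)[(2 * rate + 1):(3 * rate)], numeric(rate))

  # the marker occupies the first second, so advancing by 1 s drops it
  expect_identical(samples(timeShift(marker, -1)), numeric(3 * rate))
  # full-duration displacement silences the clip entirely
  expect_identical(samples(timeShift(marker, 3)), numeric(3 * rate))
  expect_identical(nSamples(timeShift(clip, -1.2)), 66150L)
  expect_error(timeShift(clip, 3.5), "duration")
})

test_that("time stretching changes tempo but not pitch", {
  a4 <- sineClip(440)
  fast <- timeStretch(a4, 2)
  expect_identical(nSamples(fast), nSamples(a4))
  # content compressed into the first half; the re-standardized tail is
  # zero padding (pre-standardization length halved, +/- one hop)
  tailPart <- samples(fast)[(33075 + 1024):66150]
  expect_lt(max(abs(tailPart)), 1e-6)
  # energy concentrated in the first half
  expect_gt(sqrt(mean(samples(fast)[1:33075]^2)), 0.2)
  # pitch preserved under slow-down
  slow <- timeStretch(a4, 0.8)
  expect_lt(abs(fftPeakHz(samples(slow), 22050) - 440), 10.8)
  expect_error(timeStretch(a4, 0), "positive")
  expect_error(timeStretch(a4, -2), "positive")
})

test_that("background mixing follows z = x + w*y with safe renormalization", {
  n <- nSamples(clip)
  x <- audioClip(rep(0.5, n), 22050)
  y <- audioClip(rep(0.5, n), 22050)
  expect_identical(samples(addBackgroundNoise(x, y, 0.5)), rep(0.75, n))
  cancel <- addBackgroundNoise(clip,
                               audioClip(-samples(clip), 22050), 1)
  expect_identical(samples(cancel), numeric(n))
  # renormalization only above full scale
  loud <- addBackgroundNoise(x, audioClip(rep(1, n), 22050), 1)
  expect_equal(max(abs(samples(loud))), 1)
  expect_error(addBackgroundNoise(x, audioClip(rep(0.1, 10), 22050), 0.5),
               "equal lengths")
  expect_error(addBackgroundNoise(x, y, 1.5), "\\[0, 1\\]")
  expect_error(addBackgroundNoise(x, y, -0.1), "\\[0, 1\\]")
})

test_that("training-set expansion is exactly fivefold with inherited labels", {
  set <- tinyClipSet(8, seed = 5)
  aug <- augmentTrainingSet(set, seed = 99)
  expect_length(aug, 40)
  man <- manifest(aug)
  expect_equal(sum(man$augmentation == "none"), 8)
  for (tech in c("pitch_shift", "time_shift", "time_stretch",
                 "background_noise"))
    expect_equal(sum(man$augmentation == tech), 8)
  expect_equal(sum(man$label == "vocalization"), 20)
  expect_equal(sum(man$label == "non_vocalization"), 20)
  # augmented rows point at their source clips
  augRows <- man[man$augmentation != "none", ]
  expect_true(all(augRows$source_id %in% manifest(set)$id))
  # single-clip case
  one <- augmentTrainingSet(set[1], seed = 1)
  expect_length(one, 5)
  expect_error(augmentTrainingSet(set[integer(0)], seed = 1), "non-empty")
})

test_that("expansion is deterministic given the seed", {
  set <- tinyClipSet(4, seed = 5)
  a1 <- augmentTrainingSet(set, seed = 123)
  a2 <- augmentTrainingSet(set, seed = 123)
  expect_identical(lapply(clips(a1), samples), lapply(clips(a2), samples))
  a3 <- augmentTrainingSet(set, seed = 124)
  expect_false(identical(lapply(clips(a1), samples),
                         lapply(clips(a3), samples)))
})

test_that("the fixed-factor stretch mode reproduces originals", {
  set <- tinyClipSet(2, seed = 5)
  aug <- augmentTrainingSet(set, seed = 7, stretchMode = "fixed")
  man <- manifest(aug)
  i <- which(man$augmentation == "time_stretch")[1]
  src <- which(man$id == man$source_id[i])
  expect_equal(samples(clips(aug)[[i]]), samples(clips(aug)[[src]]))
})
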