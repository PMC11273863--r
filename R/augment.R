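# The four training-set augmentation operators (pitch-shift, time-shift,
# time-stretch, background noise) and the bookkeeping that expands a
# training fold fivefold. Operators are applied to training folds only;
# provenance (source_id) lets the evaluation protocol verify that no
# augmented copy of a held-out clip ever enters training.

#' Pitch-shift a clip without changing its duration
#'
#' Phase-vocoder time-scale modification followed by band-limited
#' resampling: pitch is scaled by `2^(semitones / binsPerOctave)`, the
#' output is re-standardized to the input length. `semitones = 0` is the
#' identity.
#'
#' @param clip a standardized [AudioClip].
#' @param semitones pitch shift in semitones (training draws use
#'   \[0, 4\]).
#' @param binsPerOctave bins per octave (12).
#' @return an [AudioClip] of identical length.
#' @export
pitchShift <- function(clip, semitones, binsPerOctave = 12) {
  stopifnot(is(clip, "AudioClip"))
  if (length(semitones) != 1L || !is.finite(semitones))
    stop("semitones must be a single finite number")
  if (semitones == 0) return(clip)
  alpha <- 2^(semitones / binsPerOctave)
  x <- samples(clip)
  stretched <- phaseVocoder(x, rate = 1 / alpha)
  y <- .fftResample(stretched, length(x))
  audioClip(pmin(1, pmax(-1, y)), sampleRate(clip),
            label = clipLabel(clip), farm = clipFarm(clip))
}

# Band-limited resampling to m samples by spectrum truncation /
# zero-padding (the phase-vocoded signal is already band-limited, so
# Fourier interpolation is exact up to the periodic-extension edges).
.fftResample <- function(x, m) {
  n <- length(x)
  if (n == m) return(x)
  X <- stats::fft(x)
  keep <- min(n, m) %/% 2
  Y <- complex(m)
  Y[1:(keep + 1)] <- X[1:(keep + 1)]
  if (keep > 1) Y[(m - keep + 2):m] <- X[(n - keep + 2):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Time-shift a clip, zero-filling the vacated region
#'
#' Positive `shiftS` delays the content (zeros fill the start); negative
#' `shiftS` advances it (zeros fill the end). Length is unchanged;
#' `abs(shiftS)` equal to the clip duration yields silence.
#'
#' @param clip an [AudioClip].
#' @param shiftS shift in seconds, `abs(shiftS) <=` clip duration.
#' @return an [AudioClip].
#' @export
timeShift <- function(clip, shiftS) {
  stopifnot(is(clip, "AudioClip"))
  if (abs(shiftS) > duration(clip) + 1e-9)
    stop("abs(shiftS) exceeds the clip duration")
  x <- samples(clip)
  n <- length(x)
  k <- round(abs(shiftS) * sampleRate(clip))
  k <- min(k, n)
  y <- if (k == 0) x
       else if (shiftS > 0) c(numeric(k), x[seq_len(n - k)])
       else c(x[(k + 1):n], numeric(k))
  audioClip(y, sampleRate(clip), label = clipLabel(clip),
            farm = clipFarm(clip))
}

#' Time-stretch a clip without changing its pitch
#'
#' Phase-vocoder tempo scaling: `stretchFactor > 1` speeds up (content
#' shortens), `< 1` slows down. The output is re-standardized to the
#' input duration by end-truncation/zero-padding. `stretchFactor = 1` is
#' the identity.
#'
#' @param clip a standardized [AudioClip].
#' @param stretchFactor positive tempo factor.
#' @return an [AudioClip] of identical length.
#' @export
timeStretch <- function(clip, stretchFactor) {
  stopifnot(is(clip, "AudioClip"))
  if (length(stretchFactor) != 1L || !is.finite(stretchFactor) ||
      stretchFactor <= 0)
    stop("stretchFactor must be a single positive number")
  if (stretchFactor == 1) return(clip)
  x <- samples(clip)
  y <- phaseVocoder(x, rate = stretchFactor)
  y <- .fitLength(y, length(x))
  audioClip(pmin(1, pmax(-1, y)), sampleRate(clip),
            label = clipLabel(clip), farm = clipFarm(clip))
}

#' Mix background noise into a clip
#'
#' Elementwise `z = x + w * y`; the result is peak-renormalized only if
#' it exceeds full scale, so `w = 0` returns `x` exactly.
#'
#' @param clip an [AudioClip] (the signal `x`).
#' @param noiseClip an [AudioClip] of identical length (the background
#'   `y`).
#' @param w mixing weight in \[0, 1\].
#' @return an [AudioClip].
#' @export
addBackgroundNoise <- function(clip, noiseClip, w) {
  stopifnot(is(clip, "AudioClip"), is(noiseClip, "AudioClip"))
  if (nSamples(clip) != nSamples(noiseClip))
    stop("clip and noiseClip must have equal lengths")
  if (length(w) != 1L || !is.finite(w) || w < 0 || w > 1)
    stop("w must lie in [0, 1]")
  z <- samples(clip) + w * samples(noiseClip)
  peak <- max(abs(z))
  if (peak > 1) z <- z / peak
  audioClip(z, sampleRate(clip), label = clipLabel(clip),
            farm = clipFarm(clip))
}

#' Expand a training fold with the four augmentation operators
#'
#' For every original clip, adds exactly one new sample per technique
#' (pitch-shift, time-shift, time-stretch, background noise), so the
#' output holds `5 *` the input clips with labels inherited and
#' `source_id` pointing at the originating clip. Parameter draws:
#' semitones ~ U\[0, 4\] (or an integer draw), shift magnitude ~
#' U\[0, 1.5\] s with random sign, stretch factor ~ U\[0.8, 1.2\] (or
#' the fixed factor 1.0 with `stretchMode = "fixed"`), white noise `y`
#' regenerated per clip at the clip's RMS with weight w ~ U\[0, 1\].
#' Deterministic given `seed`.
#'
#' @param set a training-fold [ClipSet].
#' @param seed integer seed.
#' @param stretchMode `"range"` (factor ~ U\[0.8, 1.2\], default) or
#'   `"fixed"` (the no-op factor 1.0).
#' @param pitchMode `"continuous"` (semitones ~ U\[0, 4\], default) or
#'   `"integer"` (uniform on 0..4).
#' @return a [ClipSet] of `5 * length(set)` clips.
#' @export
augmentTrainingSet <- function(set, seed, stretchMode = c("range", "fixed"),
                               pitchMode = c("continuous", "integer")) {
  stopifnot(is(set, "ClipSet"))
  stretchMode <- match.arg(stretchMode)
  pitchMode <- match.arg(pitchMode)
  n <- length(set)
  if (n == 0L) stop("augmentTrainingSet() requires a non-empty training set")
  man <- manifest(set)
  techniques <- c("pitch_shift", "time_shift", "time_stretch",
                  "background_noise")
  newClips <- vector("list", 4L * n)
  rows <- vector("list", 4L * n)
  for (i in seq_len(n)) {
    cl <- clips(set)[[i]]
    seeds <- deriveSeed(seed, 4L * (i - 1L) + 0:3)
    for (j in seq_along(techniques)) {
      tech <- techniques[j]
      out <- withSeed(seeds[j], {
        switch(tech,
          pitch_shift = {
            s <- if (pitchMode == "continuous") stats::runif(1, 0, 4)
                 else sample(0:4, 1)
            pitchShift(cl, s)
          },
          time_shift = {
            mag <- stats::runif(1, 0, 1.5)
            sgn <- sample(c(-1, 1), 1)
            timeShift(cl, sgn * mag)
          },
          time_stretch = {
            f <- if (stretchMode == "range") stats::runif(1, 0.8, 1.2)
                 else 1.0
            standardizeLength(timeStretch(cl, f),
                              duration(cl))
          },
          background_noise = {
            y <- stats::rnorm(nSamples(cl))
            rms <- sqrt(mean(samples(cl)^2))
            y <- y / sqrt(mean(y^2)) * max(rms, 1e-12)
            addBackgroundNoise(cl, audioClip(pmin(1, pmax(-1, y)),
                                             sampleRate(cl)),
                               stats::runif(1, 0, 1))
          })
      })
      idx <- 4L * (i - 1L) + j
      newClips[[idx]] <- out
      rows[[idx]] <- data.frame(
        id = paste0(man$id[i], "#", tech),
        label = man$label[i], farm = man$farm[i],
        seed = seeds[j], dbfs = dbfs(out),
        source_id = man$id[i], augmentation = tech,
        stringsAsFactors = FALSE)
    }
  }
  clipSet(c(clips(set), newClips), rbind(man, do.call(rbind, rows)))
}
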