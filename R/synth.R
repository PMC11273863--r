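# Synthetic "virtual farm" audio: seeded, balanced two-class 3-s clips
# with per-farm background-noise character and loudness statistics, so
# the full pipeline can be exercised without the private recordings.
# Vocalizations are amplitude-enveloped harmonic-stack bursts over the
# farm's noise bed; non-vocalizations are the noise bed plus sporadic
# broadband transients.

.WORK_RATE <- 22050
.CLIP_S <- 3

#' Construct a FarmProfile
#'
#' @param name farm identifier.
#' @param noiseColor background noise color: `"white"`, `"pink"`, `"brown"`.
#' @param humHz mains/fan hum frequency in Hz (0 = none).
#' @param targetDbfsVoc,targetDbfsNonvoc mean clip loudness per class
#'   (dBFS, negative).
#' @param dbfsRangeVoc,dbfsRangeNonvoc length-2 (min, max) loudness
#'   bounds per class; per-clip loudness targets are truncated to these.
#' @param reverbSmearMs exponential reverberation smear constant (ms).
#' @return a [FarmProfile].
#' @export
farmProfile <- function(name, noiseColor = "white", humHz = 0,
                        targetDbfsVoc = -24, targetDbfsNonvoc = -28,
                        dbfsRangeVoc = c(targetDbfsVoc - 6, targetDbfsVoc + 6),
                        dbfsRangeNonvoc = c(targetDbfsNonvoc - 6,
                                            targetDbfsNonvoc + 6),
                        reverbSmearMs = 0) {
  new("FarmProfile", name = name, noiseColor = noiseColor, humHz = humHz,
      targetDbfsVoc = targetDbfsVoc, targetDbfsNonvoc = targetDbfsNonvoc,
      dbfsRangeVoc = dbfsRangeVoc, dbfsRangeNonvoc = dbfsRangeNonvoc,
      reverbSmearMs = reverbSmearMs)
}

#' Built-in virtual farm profiles
#'
#' Three profiles emulating the per-site character of the study farms:
#' distinct noise colors and hum, and class loudness targets equal to the
#' published per-farm average dBFS, truncated to the published min/max.
#' `"jeongeup-like"` is the loudest site.
#'
#' @return named list of three [FarmProfile] objects (`nias-like`,
#'   `gimje-like`, `jeongeup-like`).
#' @export
builtinFarmProfiles <- function() {
  list(
    "nias-like" = farmProfile("nias-like", noiseColor = "pink", humHz = 120,
      targetDbfsVoc = -24.86, targetDbfsNonvoc = -28.58,
      dbfsRangeVoc = c(-36.56, -6.98), dbfsRangeNonvoc = c(-37.97, -24.01),
      reverbSmearMs = 12),
    "gimje-like" = farmProfile("gimje-like", noiseColor = "brown", humHz = 60,
      targetDbfsVoc = -26.07, targetDbfsNonvoc = -29.30,
      dbfsRangeVoc = c(-35.74, -9.03), dbfsRangeNonvoc = c(-39.26, -21.08),
      reverbSmearMs = 25),
    "jeongeup-like" = farmProfile("jeongeup-like", noiseColor = "white",
      humHz = 0,
      targetDbfsVoc = -18.99, targetDbfsNonvoc = -22.69,
      dbfsRangeVoc = c(-23.60, -5.96), dbfsRangeNonvoc = c(-24.72, -18.98),
      reverbSmearMs = 5)
  )
}

#' Construct VocalEventParams
#'
#' Defaults describe grunt/squeal-like bursts: fundamentals between 200
#' and 1500 Hz, ten harmonics with 1/h amplitude falloff, one to four
#' bursts of 0.3-1.2 s per clip.
#'
#' @param f0Range fundamental frequency interval (Hz), within
#'   \[100, 4000\].
#' @param nHarmonics harmonics per burst.
#' @param harmonicDecay amplitude falloff exponent.
#' @param nBurstsRange integer interval of bursts per clip.
#' @param burstDurRange burst duration interval in seconds (max 3).
#' @return a [VocalEventParams].
#' @export
vocalEventParams <- function(f0Range = c(200, 1500), nHarmonics = 10,
                             harmonicDecay = 1.0, nBurstsRange = c(1, 4),
                             burstDurRange = c(0.3, 1.2)) {
  new("VocalEventParams", f0Range = f0Range, nHarmonics = nHarmonics,
      harmonicDecay = harmonicDecay, nBurstsRange = nBurstsRange,
      burstDurRange = burstDurRange)
}

# Unit-RMS colored noise via FFT spectral shaping: power ~ f^0 (white),
# f^-1 (pink), f^-2 (brown).
.coloredNoise <- function(n, color) {
  w <- stats::rnorm(n)
  if (color == "white") return(w / sqrt(mean(w^2)))
  expo <- switch(color, pink = 0.5, brown = 1.0)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)           # symmetric frequency index
  f[1] <- 1                     # avoid DC blow-up
  X <- X * f^(-expo)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

.scaleToDbfs <- function(x, target) {
  cur <- dbfs(x)
  if (!is.finite(cur)) return(x)
  y <- x * 10^((target - cur) / 20)
  peak <- max(abs(y))
  if (peak > 0.999) y <- y * (0.999 / peak)
  y
}

# Per-clip loudness target: Gaussian around the profile mean, truncated
# to +/-2 dB of the mean and to the profile's (min, max) bounds.
.drawDbfsTarget <- function(mean, range) {
  lo <- max(mean - 2, range[1]); hi <- min(mean + 2, range[2])
  for (i in 1:100) {
    d <- stats::rnorm(1, mean, 1)
    if (d >= lo && d <= hi) return(d)
  }
  min(max(mean, lo), hi)
}

# Direct path plus an exponentially decaying diffuse tail; keeping the
# dry impulse preserves the noise color of the bed (a tail-only kernel
# would lowpass everything at ~1/(2*pi*tau)).
.reverbSmear <- function(x, smearMs, rate, wet = 0.6) {
  if (smearMs <= 0) return(x)
  tau <- smearMs / 1000 * rate
  kLen <- ceiling(5 * tau)
  kern <- c(1, wet * exp(-(1:kLen) / tau) / sqrt(tau))
  kern <- kern / sqrt(sum(kern^2))
  y <- stats::convolve(c(x, numeric(kLen)), rev(kern), type = "open")
  y[seq_along(x) + kLen]
}

# Background bed shared by both classes: colored noise plus optional hum
# (fundamental + weak second harmonic), unit RMS.
.backgroundBed <- function(profile, n, rate) {
  bg <- .coloredNoise(n, profile@noiseColor)
  if (profile@humHz > 0) {
    t <- (0:(n - 1)) / rate
    ph <- stats::runif(2, 0, 2 * pi)
    hum <- sin(2 * pi * profile@humHz * t + ph[1]) +
      0.4 * sin(2 * pi * 2 * profile@humHz * t + ph[2])
    bg <- bg + 0.3 * hum / sqrt(mean(hum^2))
  }
  bg / sqrt(mean(bg^2))
}

.burstEnvelope <- function(n) {
  ramp <- max(2L, round(0.15 * n))
  env <- rep(1, n)
  up <- sin(pi / 2 * seq(0, 1, length.out = ramp))^2
  env[seq_len(ramp)] <- up
  env[(n - ramp + 1):n] <- rev(up)
  env
}

#' Synthesize a vocalization clip
#'
#' A 3-s clip at 22,050 Hz containing one or more amplitude-enveloped
#' harmonic-stack bursts (stacked sinusoids at `f0 * h` with amplitude
#' `h^-harmonicDecay`) mixed about 12 dB above the farm's background
#' bed, smeared by the profile's reverberation constant, and scaled to a
#' per-clip loudness target within +/-2 dB of the profile's vocalization
#' mean. Bit-identical for identical `(profile, params, seed)`.
#'
#' @param profile a [FarmProfile].
#' @param params a [VocalEventParams].
#' @param seed integer seed.
#' @return a labeled [AudioClip] (`label = "vocalization"`).
#' @export
makeVocalization <- function(profile, params = vocalEventParams(), seed) {
  stopifnot(is(profile, "FarmProfile"), is(params, "VocalEventParams"))
  validObject(profile); validObject(params)
  if (params@burstDurRange[2] > .CLIP_S)
    stop("burst durations must fit within the 3-s clip")
  rate <- .WORK_RATE
  n <- .CLIP_S * rate
  withSeed(seed, {
    bg <- .backgroundBed(profile, n, rate)
    sig <- numeric(n)
    nB <- if (params@nBurstsRange[1] == params@nBurstsRange[2])
      params@nBurstsRange[1]
    else sample(params@nBurstsRange[1]:params@nBurstsRange[2], 1)
    for (b in seq_len(nB)) {
      f0 <- stats::runif(1, params@f0Range[1], params@f0Range[2])
      dur <- stats::runif(1, params@burstDurRange[1], params@burstDurRange[2])
      nb <- round(dur * rate)
      onset <- sample.int(n - nb + 1L, 1L) - 1L
      t <- (0:(nb - 1)) / rate
      burst <- numeric(nb)
      for (h in seq_len(params@nHarmonics)) {
        fh <- f0 * h
        if (fh >= rate / 2) break
        burst <- burst + h^(-params@harmonicDecay) *
          sin(2 * pi * fh * t + stats::runif(1, 0, 2 * pi))
      }
      burst <- burst * .burstEnvelope(nb)
      i <- (onset + 1):(onset + nb)
      sig[i] <- sig[i] + burst
    }
    sig <- sig / sqrt(mean(sig^2))
    mix <- 10^(12 / 20) * sig + bg      # ~12 dB burst-over-bed ratio
    mix <- .reverbSmear(mix, profile@reverbSmearMs, rate)
    target <- .drawDbfsTarget(profile@targetDbfsVoc, profile@dbfsRangeVoc)
    audioClip(.scaleToDbfs(mix, target), rate,
              label = "vocalization", farm = profile@name)
  })
}

#' Synthesize a non-vocalization clip
#'
#' A 3-s clip of the farm's background bed (colored noise plus optional
#' hum) with sporadic broadband transients and no harmonic stack, scaled
#' to a per-clip loudness target within +/-2 dB of the profile's
#' non-vocalization mean. Bit-identical for identical `(profile, seed)`.
#'
#' @param profile a [FarmProfile].
#' @param seed integer seed.
#' @return a labeled [AudioClip] (`label = "non_vocalization"`).
#' @export
makeNonVocalization <- function(profile, seed) {
  stopifnot(is(profile, "FarmProfile"))
  validObject(profile)
  rate <- .WORK_RATE
  n <- .CLIP_S * rate
  withSeed(seed, {
    bg <- .backgroundBed(profile, n, rate)
    nT <- sample(0:3, 1)
    for (k in seq_len(nT)) {
      nb <- round(stats::runif(1, 0.02, 0.08) * rate)
      onset <- sample.int(n - nb + 1L, 1L) - 1L
      click <- stats::rnorm(nb) * .burstEnvelope(nb) *
        stats::runif(1, 1, 2)
      i <- (onset + 1):(onset + nb)
      bg[i] <- bg[i] + click
    }
    bg <- .reverbSmear(bg, profile@reverbSmearMs, rate)
    target <- .drawDbfsTarget(profile@targetDbfsNonvoc,
                              profile@dbfsRangeNonvoc)
    audioClip(.scaleToDbfs(bg, target), rate,
              label = "non_vocalization", farm = profile@name)
  })
}

#' Generate a balanced labeled dataset for one virtual farm
#'
#' Exactly `nPerClass` vocalization and `nPerClass` non-vocalization
#' clips. Per-clip seeds are derived from the master seed with a
#' counter-based mix ([deriveSeed()]), so each clip is reproducible
#' independent of generation order.
#'
#' @param profile a [FarmProfile].
#' @param nPerClass clips per class (>= 1).
#' @param seed master seed.
#' @param params a [VocalEventParams] for the vocalization class.
#' @return a [ClipSet] of `2 * nPerClass` clips.
#' @export
makeFarmDataset <- function(profile, nPerClass, seed,
                            params = vocalEventParams()) {
  if (length(nPerClass) != 1L || nPerClass < 1)
    stop("nPerClass must be a positive integer")
  nPerClass <- as.integer(nPerClass)
  seeds <- deriveSeed(seed, 0:(2L * nPerClass - 1L))
  voc <- lapply(seq_len(nPerClass), function(i)
    makeVocalization(profile, params, seeds[i]))
  non <- lapply(seq_len(nPerClass), function(i)
    makeNonVocalization(profile, seeds[nPerClass + i]))
  allClips <- c(voc, non)
  man <- data.frame(
    id = c(sprintf("%s-s%d_voc_%05d", profile@name, seed, seq_len(nPerClass)),
           sprintf("%s-s%d_non_%05d", profile@name, seed, seq_len(nPerClass))),
    label = rep(c("vocalization", "non_vocalization"), each = nPerClass),
    farm = profile@name,
    seed = seeds,
    dbfs = vapply(allClips, dbfs, 0),
    stringsAsFactors = FALSE
  )
  man$source_id <- man$id
  man$augmentation <- "none"
  clipSet(allClips, man)
}

#' Generate datasets for the three built-in virtual farms
#'
#' One balanced [ClipSet] per built-in profile, with disjoint per-farm
#' master seeds derived from `seed`.
#'
#' @param nPerClass clips per class per farm.
#' @param seed master seed.
#' @param params a [VocalEventParams].
#' @return named list of three [ClipSet] objects.
#' @export
makeThreeFarms <- function(nPerClass, seed, params = vocalEventParams()) {
  profiles <- builtinFarmProfiles()
  farmSeeds <- deriveSeed(seed, 1048576L + seq_along(profiles))
  out <- mapply(function(p, s) makeFarmDataset(p, nPerClass, s, params),
                profiles, farmSeeds, SIMPLIFY = FALSE)
  names(out) <- names(profiles)
  out
}

#' Write a ClipSet to disk
#'
#' Writes one WAV per clip plus a `manifest.csv` with columns
#' `clip_path, label, farm, seed, dbfs`.
#'
#' @param set a [ClipSet].
#' @param dir output directory (created if missing).
#' @param bitDepth 16 or 32.
#' @return the manifest path, invisibly.
#' @export
writeClipSet <- function(set, dir, bitDepth = 16) {
  stopifnot(is(set, "ClipSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- manifest(set)
  paths <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", man$id), ".wav"))
  for (i in seq_along(paths)) writeWav(clips(set)[[i]], paths[i], bitDepth)
  out <- data.frame(clip_path = paths, label = man$label, farm = man$farm,
                    seed = man$seed, dbfs = man$dbfs)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(out, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a ClipSet from a manifest
#'
#' @param manifestPath path to a `manifest.csv` written by
#'   [writeClipSet()].
#' @return a [ClipSet].
#' @export
readClipSet <- function(manifestPath) {
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  base <- dirname(manifestPath)
  cl <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$clip_path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    readWav(p, label = man$label[i], farm = man$farm[i])
  })
  df <- data.frame(
    id = tools::file_path_sans_ext(basename(man$clip_path)),
    label = man$label, farm = man$farm,
    seed = if (is.null(man$seed)) NA_integer_ else man$seed,
    dbfs = if (is.null(man$dbfs)) vapply(cl, dbfs, 0) else man$dbfs,
    stringsAsFactors = FALSE)
  df$source_id <- df$id
  df$augmentation <- "none"
  clipSet(cl, df)
}
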