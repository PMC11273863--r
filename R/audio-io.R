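# WAV input/output and waveform preprocessing: mono conversion,
# resampling to the 22,050 Hz working rate, 3-s segmentation, length
# standardization, and dBFS measurement.

#' Read a RIFF WAV file
#'
#' Reads PCM 16-bit or IEEE float32 WAV. Stereo is converted to mono by
#' channel mean; amplitudes are scaled to \[-1, 1\] (16-bit samples are
#' divided by 32768).
#'
#' @param path path to a `.wav` file.
#' @param label,farm optional provenance attached to the returned clip.
#' @return an [AudioClip].
#' @seealso [writeWav()]
#' @export
readWav <- function(path, label = NA_character_, farm = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        nChannels   = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sampleRate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bitsPerSample = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("corrupt WAV (missing chunk): ", path)

  if (fmt$audioFormat == 1L && fmt$bitsPerSample == 16L) {
    x <- readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audioFormat == 3L && fmt$bitsPerSample == 32L) {
    x <- readBin(data, "double", length(data) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audioFormat, ", ",
         fmt$bitsPerSample, " bits)")
  }
  if (fmt$nChannels > 1L) {
    x <- matrix(x, nrow = fmt$nChannels)
    x <- colMeans(x)
  }
  x <- pmin(1, pmax(-1, x))
  audioClip(x, fmt$sampleRate, label = label, farm = farm)
}

#' Write an AudioClip as a RIFF WAV file
#'
#' @param clip an [AudioClip].
#' @param path output path.
#' @param bitDepth 16 (PCM, the recording format) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeWav <- function(clip, path, bitDepth = 16) {
  stopifnot(is(clip, "AudioClip"), bitDepth %in% c(16, 32))
  x <- pmin(1, pmax(-1, samples(clip)))
  sr <- as.integer(sampleRate(clip))
  n <- length(x)
  bytes <- bitDepth / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bitDepth == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(sr, con, 4, endian = "little")
  writeBin(as.integer(sr * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bitDepth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, 4, endian = "little")
  if (bitDepth == 16) {
    q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}

#' Resample a clip to a target rate
#'
#' Band-limited polyphase FIR resampling (via the signal package). The
#' working rate of the pipeline is 22,050 Hz.
#'
#' @param clip an [AudioClip] with rate >= `targetRate`.
#' @param targetRate target sampling rate in Hz (default 22,050).
#' @return the resampled [AudioClip]; identity when rates already match.
#' @export
resampleClip <- function(clip, targetRate = 22050) {
  stopifnot(is(clip, "AudioClip"))
  if (length(targetRate) != 1L || !is.finite(targetRate) || targetRate <= 0)
    stop("targetRate must be a positive number")
  sr <- sampleRate(clip)
  if (sr == targetRate) return(clip)
  if (sr < targetRate) stop("upsampling not supported: clip rate ", sr,
                            " < target ", targetRate)
  g <- .gcd(round(sr), round(targetRate))
  p <- round(targetRate) / g
  q <- round(sr) / g
  y <- signal::resample(samples(clip), p, q)
  nOut <- round(length(samples(clip)) * targetRate / sr)
  y <- .fitLength(y, nOut)
  audioClip(pmin(1, pmax(-1, y)), targetRate,
            label = clipLabel(clip), farm = clipFarm(clip))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.fitLength <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}

#' Cut a recording into consecutive 3-s segments
#'
#' Non-overlapping consecutive windows; a final remainder shorter than
#' the window is dropped (the datasets consist of exact 3-s files). A
#' clip shorter than one window yields an empty list.
#'
#' @param clip an [AudioClip].
#' @param windowS window length in seconds (default 3).
#' @return list of [AudioClip] segments inheriting label/farm.
#' @export
segmentClip <- function(clip, windowS = 3.0) {
  stopifnot(is(clip, "AudioClip"))
  if (windowS <= 0) stop("windowS must be positive")
  w <- round(windowS * sampleRate(clip))
  n <- nSamples(clip)
  k <- n %/% w
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) {
    audioClip(samples(clip)[((i - 1) * w + 1):(i * w)], sampleRate(clip),
              label = clipLabel(clip), farm = clipFarm(clip))
  })
}

#' Standardize a clip to an exact duration
#'
#' Truncates or zero-pads at the end so the clip has exactly
#' `targetS * sampleRate` samples — the fixed network input length.
#'
#' @param clip an [AudioClip].
#' @param targetS target duration in seconds (default 3).
#' @return an [AudioClip] of exact length.
#' @export
standardizeLength <- function(clip, targetS = 3.0) {
  stopifnot(is(clip, "AudioClip"))
  n <- round(targetS * sampleRate(clip))
  x <- .fitLength(samples(clip), n)
  audioClip(x, sampleRate(clip), label = clipLabel(clip),
            farm = clipFarm(clip))
}

#' @rdname dbfs
#' @export
setMethod("dbfs", "AudioClip", function(x) dbfs(samples(x)))
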