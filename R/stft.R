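# Short-time Fourier analysis shared by the feature extractors and the
# phase-vocoder augmentation operators. Conventions: periodic Hann
# window, centered frames (the signal is padded by n_fft/2 on each
# side), so a clip of n samples yields 1 + floor(n / hop) frames.

#' STFT frame count for a centered analysis
#'
#' With centered framing a signal of `nSamplesIn` samples analyzed at hop
#' `hop` yields `1 + floor(nSamplesIn / hop)` frames; the standardized
#' 3-s clip (66,150 samples, hop 512) yields 130.
#'
#' @param nSamplesIn number of samples.
#' @param hop hop length in samples (default 512).
#' @param center logical; centered framing (default TRUE).
#' @param nFft FFT window size (only used when `center = FALSE`).
#' @return integer frame count.
#' @examples
#' nFrames(66150)  # 130
#' @export
nFrames <- function(nSamplesIn, hop = 512, center = TRUE, nFft = 2048) {
  if (hop <= 0) stop("hop must be positive")
  if (nSamplesIn < 1) stop("nSamplesIn must be >= 1")
  if (center) 1L + as.integer(nSamplesIn %/% hop)
  else 1L + as.integer(max(0, nSamplesIn - nFft) %/% hop)
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)  # periodic

# Complex STFT: (1 + nFft/2) x frames.
stftMatrix <- function(x, nFft = 2048, hop = 512, window = .hann(nFft),
                       center = TRUE) {
  if (center) x <- c(numeric(nFft / 2), x, numeric(nFft / 2))
  nF <- if (center) 1L + (length(x) - nFft) %/% hop else
    1L + max(0L, (length(x) - nFft) %/% hop)
  need <- (nF - 1) * hop + nFft
  if (length(x) < need) x <- c(x, numeric(need - length(x)))
  idx <- outer(seq_len(nFft), (seq_len(nF) - 1) * hop, `+`)
  frames <- matrix(x[idx], nrow = nFft) * window
  Sfull <- stats::mvfft(frames)
  Sfull[seq_len(nFft / 2 + 1), , drop = FALSE]
}

# Least-squares inverse STFT (overlap-add with window-square
# normalization); exact inverse of stftMatrix where window coverage is
# complete.
istftMatrix <- function(S, nOut, nFft = 2048, hop = 512,
                        window = .hann(nFft), center = TRUE) {
  nF <- ncol(S)
  full <- rbind(S, Conj(S[(nFft / 2):2, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / nFft
  frames <- frames * window
  total <- (nF - 1) * hop + nFft
  y <- numeric(total)
  wsum <- numeric(total)
  w2 <- window^2
  for (t in seq_len(nF)) {
    i <- ((t - 1) * hop + 1):((t - 1) * hop + nFft)
    y[i] <- y[i] + frames[, t]
    wsum[i] <- wsum[i] + w2
  }
  nz <- wsum > 1e-11
  y[nz] <- y[nz] / wsum[nz]
  if (center) y <- y[-seq_len(nFft / 2)]
  .fitLength(y, nOut)
}

# Phase-vocoder time-scale modification. rate > 1 speeds up (shorter
# output), rate < 1 slows down. Output length ~ n / rate. rate == 1 is
# an exact round trip.
phaseVocoder <- function(x, rate, nFft = 2048, hop = 512) {
  stopifnot(rate > 0)
  D <- stftMatrix(x, nFft, hop)
  nBins <- nrow(D); nT <- ncol(D)
  steps <- seq(0, nT - 1, by = rate)
  phiAdv <- 2 * pi * hop * (0:(nBins - 1)) / nFft
  D <- cbind(D, complex(real = numeric(nBins)))  # pad one zero column
  out <- matrix(complex(real = 0), nBins, length(steps))
  phase <- Arg(D[, 1])
  for (j in seq_along(steps)) {
    t <- steps[j]
    k <- floor(t); frac <- t - k
    c1 <- D[, k + 1]; c2 <- D[, k + 2]
    mag <- (1 - frac) * Mod(c1) + frac * Mod(c2)
    out[, j] <- mag * exp(1i * phase)
    dphi <- Arg(c2) - Arg(c1) - phiAdv
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    phase <- phase + phiAdv + dphi
  }
  istftMatrix(out, nOut = round(length(x) / rate), nFft = nFft, hop = hop)
}
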