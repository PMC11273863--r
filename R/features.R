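# Spectral feature extraction. All methods share the same short-time
# analysis (FFT window 2048, hop 512, centered), so every method on the
# same standardized 3-s clip yields 130 frames; they differ only in the
# frequency-axis projection:
#   mel     : 128-band Slaney-style Mel filterbank on the power
#             spectrogram, log-compressed (dB re max, 80 dB floor)
#   mfcc    : orthonormal DCT-II of the log-Mel energies, first 20 rows
#   chroma  : power folded onto the 12 Western pitch classes (C = row 1),
#             per-frame max-normalized
#   tonnetz : 6-D tonal centroid (fifths, minor thirds, major thirds) of
#             the L1-normalized chroma
#   mixed_mmct : per-block z-scored [mfcc; mel; chroma; tonnetz] stack,
#             166 rows

#' STFT analysis parameters
#'
#' @param nFft FFT window size (2048).
#' @param hop hop length in samples (512).
#' @param center centered framing (TRUE).
#' @return a list of class `stftParams`.
#' @export
stftParams <- function(nFft = 2048, hop = 512, center = TRUE) {
  stopifnot(nFft == 2048, hop == 512)
  structure(list(nFft = nFft, hop = hop, center = center),
            class = "stftParams")
}

# Slaney-style Hz <-> Mel (linear below 1 kHz, log above).
.hzToMel <- function(f) {
  mel <- f / (200 / 3)
  logRegion <- f >= 1000
  mel[logRegion] <- 15 + log(f[logRegion] / 1000) / (log(6.4) / 27)
  mel
}
.melToHz <- function(m) {
  f <- m * (200 / 3)
  logRegion <- m >= 15
  f[logRegion] <- 1000 * exp((m[logRegion] - 15) * (log(6.4) / 27))
  f
}

#' Mel filterbank matrix
#'
#' Triangular, area-normalized filters on the Slaney Mel scale.
#'
#' @param nMels number of bands (128).
#' @param nFft FFT size.
#' @param rate sampling rate (Hz).
#' @param fmin,fmax frequency range (defaults 0 to Nyquist).
#' @return `nMels x (nFft/2 + 1)` weight matrix.
#' @export
melFilterbank <- function(nMels = 128, nFft = 2048, rate = 22050,
                          fmin = 0, fmax = rate / 2) {
  fftFreqs <- seq(0, rate / 2, length.out = nFft / 2 + 1)
  melPts <- .melToHz(seq(.hzToMel(fmin), .hzToMel(fmax),
                         length.out = nMels + 2))
  fb <- matrix(0, nMels, length(fftFreqs))
  for (m in seq_len(nMels)) {
    lo <- melPts[m]; ce <- melPts[m + 1]; hi <- melPts[m + 2]
    up <- (fftFreqs - lo) / (ce - lo)
    down <- (hi - fftFreqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)  # slaney norm
  }
  fb
}

# Mel band center frequencies (used by oracle tests).
melCenterFreqs <- function(nMels = 128, rate = 22050, fmin = 0,
                           fmax = rate / 2) {
  .melToHz(seq(.hzToMel(fmin), .hzToMel(fmax),
               length.out = nMels + 2))[2:(nMels + 1)]
}

.powerSpectrogram <- function(clip, params) {
  S <- stftMatrix(samples(clip), params$nFft, params$hop,
                  center = params$center)
  Mod(S)^2
}

.powerToDb <- function(S, topDb = 80) {
  amin <- 1e-10
  ref <- max(S, amin)
  db <- 10 * log10(pmax(S, amin)) - 10 * log10(ref)
  pmax(db, max(db) - topDb)
}

.fbCache <- new.env(parent = emptyenv())

.melFromS <- function(S, rate, nFft) {
  key <- paste0("fb", nFft, "_", rate)
  fb <- .fbCache[[key]]
  if (is.null(fb)) {
    fb <- melFilterbank(128, nFft, rate)
    .fbCache[[key]] <- fb
  }
  .powerToDb(fb %*% S)
}

#' Log-Mel spectrogram (128 x frames)
#'
#' @param clip an [AudioClip] (standardized 3-s clips give 130 frames).
#' @param params an [stftParams()] list.
#' @return a [FeatureMatrix] with method `"mel"`.
#' @export
extractMel <- function(clip, params = stftParams()) {
  S <- .powerSpectrogram(clip, params)
  featureMatrix(.melFromS(S, sampleRate(clip), params$nFft), "mel")
}

# Orthonormal DCT-II matrix (nCoef x n).
.dctMatrix <- function(nCoef, n) {
  k <- 0:(nCoef - 1)
  m <- outer(k, 0:(n - 1), function(k, j) cos(pi * (j + 0.5) * k / n))
  m * sqrt(2 / n) * ifelse(k == 0, 1 / sqrt(2), 1)
}

#' MFCC (20 x frames)
#'
#' First 20 coefficients of the orthonormal DCT-II applied to the
#' log-Mel energies of each frame.
#'
#' @inheritParams extractMel
#' @return a [FeatureMatrix] with method `"mfcc"`.
#' @export
extractMfcc <- function(clip, params = stftParams()) {
  logMel <- featureValues(extractMel(clip, params))
  featureMatrix(.mfccFromMel(logMel), "mfcc")
}

.mfccFromMel <- function(logMel) {
  key <- paste0("dct20_", nrow(logMel))
  D <- .fbCache[[key]]
  if (is.null(D)) {
    D <- .dctMatrix(20, nrow(logMel))
    .fbCache[[key]] <- D
  }
  D %*% logMel
}

#' Chroma (12 x frames)
#'
#' STFT power folded onto the 12 pitch classes (row 1 = C), each frame
#' normalized by its maximum, so non-silent frames have column maximum 1.
#'
#' @inheritParams extractMel
#' @return a [FeatureMatrix] with method `"chroma"`.
#' @export
extractChroma <- function(clip, params = stftParams()) {
  S <- .powerSpectrogram(clip, params)
  featureMatrix(.chromaFromS(S, sampleRate(clip)), "chroma")
}

.chromaFromS <- function(S, rate) {
  freqs <- seq(0, rate / 2, length.out = nrow(S))
  keep <- freqs >= 27.5           # below A0 there is no pitch class
  cls <- (round(69 + 12 * log2(freqs[keep] / 440)) %% 12) + 1
  C <- matrix(0, 12, ncol(S))
  Sk <- S[keep, , drop = FALSE]
  for (p in 1:12) {
    rows <- cls == p
    if (any(rows)) C[p, ] <- colSums(Sk[rows, , drop = FALSE])
  }
  mx <- apply(C, 2, max)
  nz <- mx > 0
  C[, nz] <- sweep(C[, nz, drop = FALSE], 2, mx[nz], "/")
  C
}

# 6 x 12 tonal-centroid transformation: projections of the 12 pitch
# classes onto the circle of fifths (radius 1), minor thirds (radius 1),
# and major thirds (radius 0.5).
tonnetzBasis <- function() {
  j <- 0:11
  rbind(
    sin(j * 7 * pi / 6), cos(j * 7 * pi / 6),
    sin(j * 3 * pi / 2), cos(j * 3 * pi / 2),
    0.5 * sin(j * 2 * pi / 3), 0.5 * cos(j * 2 * pi / 3)
  )
}

#' Tonnetz tonal centroids (6 x frames)
#'
#' Projects the per-frame L1-normalized chroma vector onto the fifths /
#' minor-third / major-third circles; values lie in \[-1, 1\].
#'
#' @inheritParams extractMel
#' @return a [FeatureMatrix] with method `"tonnetz"`.
#' @export
extractTonnetz <- function(clip, params = stftParams()) {
  C <- featureValues(extractChroma(clip, params))
  featureMatrix(.tonnetzFromChroma(C), "tonnetz")
}

.tonnetzFromChroma <- function(C) {
  l1 <- colSums(abs(C))
  nz <- l1 > 0
  C[, nz] <- sweep(C[, nz, drop = FALSE], 2, l1[nz], "/")
  tonnetzBasis() %*% C
}

#' Tile 6-row tonnetz to the 12-row standalone network input
#'
#' The standalone-Tonnetz network input is 12 x 130; the native tonal
#' centroid has 6 rows. The 12-row input is the 6 rows stacked twice
#' (rows 1-6 == rows 7-12), which preserves both the printed input size
#' and the network parameter count.
#'
#' @param t6 a 6-row [FeatureMatrix] (method `"tonnetz"`).
#' @return a [FeatureMatrix] with method `"tonnetz12"`.
#' @export
tonnetzStandaloneInput <- function(t6) {
  stopifnot(is(t6, "FeatureMatrix"))
  v <- featureValues(t6)
  if (nrow(v) != 6L || featureMethod(t6) != "tonnetz")
    stop("tonnetzStandaloneInput() requires a 6-row tonnetz FeatureMatrix")
  featureMatrix(rbind(v, v), "tonnetz12")
}

.zscoreBlock <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(v * 0)
  (v - mean(v)) / s
}

#' Fused Mixed-MMCT features (166 x frames)
#'
#' Vertical concatenation of the per-block z-scored MFCC (20), log-Mel
#' (128), chroma (12), and tonnetz (6) matrices. Per-block
#' standardization keeps the dB-scale Mel block from dominating the
#' \[-1, 1\]-scale tonnetz block.
#'
#' @inheritParams extractMel
#' @param normalize apply per-block z-scoring before stacking (default
#'   TRUE).
#' @return a [FeatureMatrix] with method `"mixed_mmct"`.
#' @export
extractMixedMmct <- function(clip, params = stftParams(), normalize = TRUE) {
  S <- .powerSpectrogram(clip, params)   # shared by all four blocks
  mel <- .melFromS(S, sampleRate(clip), params$nFft)
  chroma <- .chromaFromS(S, sampleRate(clip))
  blocks <- list(.mfccFromMel(mel), mel, chroma,
                 .tonnetzFromChroma(chroma))
  if (normalize) blocks <- lapply(blocks, .zscoreBlock)
  featureMatrix(do.call(rbind, blocks), "mixed_mmct")
}

#' Extract features by method name
#'
#' @param clip an [AudioClip].
#' @param method `"mfcc"`, `"mel"`, `"chroma"`, `"tonnetz"`,
#'   `"tonnetz12"`, or `"mixed_mmct"` (alias `"mixed"`).
#' @param params an [stftParams()] list.
#' @return a [FeatureMatrix].
#' @examples
#' clip <- makeVocalization(builtinFarmProfiles()[[1]], seed = 1)
#' dim(extractFeatures(clip, "mfcc"))  # 20 x 130
#' @export
extractFeatures <- function(clip, method, params = stftParams()) {
  switch(match.arg(method, c("mfcc", "mel", "chroma", "tonnetz",
                             "tonnetz12", "mixed_mmct", "mixed")),
    mfcc = extractMfcc(clip, params),
    mel = extractMel(clip, params),
    chroma = extractChroma(clip, params),
    tonnetz = extractTonnetz(clip, params),
    tonnetz12 = tonnetzStandaloneInput(extractTonnetz(clip, params)),
    mixed_mmct = ,
    mixed = extractMixedMmct(clip, params)
  )
}
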