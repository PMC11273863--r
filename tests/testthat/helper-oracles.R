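# Independent oracles used across the suite.

# Frequency of the largest FFT magnitude of a waveform (DC excluded).
fftPeakHz <- function(x, rate) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[2:(n %/% 2)]
  freqs <- (1:(n %/% 2 - 1)) * rate / n
  freqs[which.max(mag)]
}

# Spectral flatness (geometric / arithmetic mean of the power spectrum).
spectralFlatness <- function(x) {
  p <- Mod(stats::fft(x))[2:(length(x) %/% 2)]^2
  p <- p[p > 0]
  exp(mean(log(p))) / mean(p)
}

# Log-log spectral slope of the power spectrum between two frequencies:
# ~0 for white, ~-1 for pink, ~-2 for brown noise.
spectralSlope <- function(x, rate, fLo = 200, fHi = 3000) {
  n <- length(x)
  p <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  freqs <- (1:(n %/% 2 - 1)) * rate / n
  keep <- freqs >= fLo & freqs <= fHi
  stats::coef(stats::lm(log(p[keep]) ~ log(freqs[keep])))[2]
}

# Double-precision R reference forward pass for the three-block CNN,
# mirroring the engine's channels-last layout and floor pooling.
refIm2col <- function(A, H, W) {      # A: (HW x C) -> (HW x 25C)
  C <- ncol(A)
  out <- matrix(0, H * W, 25 * C)
  for (c in seq_len(C)) {
    pad <- matrix(0, H + 4, W + 4)
    pad[3:(H + 2), 3:(W + 2)] <- matrix(A[, c], H, W)
    for (dj in -2:2) for (di in -2:2) {
      q <- (dj + 2) * 5 + (di + 2) + 1
      out[, (c - 1) * 25 + q] <-
        as.vector(pad[(1:H) + di + 2, (1:W) + dj + 2])
    }
  }
  out
}

refPool <- function(A, H, W) {        # (HW x C) -> (HpWp x C), floor
  C <- ncol(A); Hp <- H %/% 2; Wp <- W %/% 2
  out <- matrix(0, Hp * Wp, C)
  for (c in seq_len(C)) {
    img <- matrix(A[, c], H, W)
    for (jp in 1:Wp) for (ip in 1:Hp)
      out[ip + (jp - 1) * Hp, c] <-
        max(img[(2 * ip - 1):(2 * ip), (2 * jp - 1):(2 * jp)])
  }
  out
}

refForward <- function(w, x) {        # x: H x W matrix -> probs (2)
  H <- nrow(x); W <- ncol(x)
  A <- matrix(as.vector(x), ncol = 1)
  for (l in 1:3) {
    Wl <- w[[paste0("W", l)]]; bl <- w[[paste0("b", l)]]
    Z <- refIm2col(A, H, W) %*% t(Wl)
    Z <- sweep(Z, 2, bl, "+")
    A <- refPool(pmax(Z, 0), H, W)
    H <- H %/% 2; W <- W %/% 2
  }
  f <- as.vector(A)
  a4 <- pmax(as.vector(w$W4 %*% f + w$b4), 0)
  z5 <- as.vector(w$W5 %*% a4 + w$b5)
  z5 <- z5 - max(z5)
  exp(z5) / sum(exp(z5))
}

# A tiny labeled ClipSet of lightweight waveforms for bookkeeping tests
# (low rate keeps memory small; the augmentation operators are
# rate-agnostic).
tinyClipSet <- function(n, rate = 1000, durS = 1.5, seed = 1,
                        farm = "farmA") {
  stopifnot(n %% 2 == 0)
  half <- n / 2
  clips <- withr::with_seed(seed, lapply(seq_len(n), function(i) {
    audioClip(stats::rnorm(rate * durS) * 0.1, rate,
              label = if (i <= half) "vocalization" else "non_vocalization",
              farm = farm)
  }))
  man <- data.frame(
    id = sprintf("%s_clip_%05d", farm, seq_len(n)),
    label = c(rep("vocalization", half), rep("non_vocalization", half)),
    farm = farm, seed = seq_len(n), dbfs = NA_real_,
    stringsAsFactors = FALSE)
  man$dbfs <- vapply(clips, dbfs, 0)
  man$source_id <- man$id
  man$augmentation <- "none"
  clipSet(clips, man)
}

workRate <- 22050

sineClip <- function(freq, durS = 3, rate = workRate, amp = 0.5,
                     label = NA_character_) {
  audioClip(amp * sin(2 * pi * freq * (0:(durS * rate - 1)) / rate), rate,
            label = label)
}
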