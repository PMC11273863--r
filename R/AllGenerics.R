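#' @import methods
NULL

#' Loudness in decibels relative to full scale
#'
#' RMS loudness of a signal measured against a full-scale amplitude of 1.0:
#' `20 * log10(RMS(x))`. A full-scale square wave (+/-1) is 0 dBFS and a
#' full-scale sine is -3.0103 dBFS. All-zero input returns `-Inf`.
#'
#' @param x an [AudioClip] or a numeric vector of amplitudes in \[-1, 1\].
#' @return loudness in dBFS (a single double; `-Inf` for silence).
#' @examples
#' dbfs(rep(c(1, -1), 100))      # 0
#' dbfs(sin(2 * pi * (0:999) / 100) * sqrt(2) / sqrt(2))  # ~ -3.01
#' @export
setGeneric("dbfs", function(x) standardGeneric("dbfs"))

#' @rdname dbfs
#' @export
setMethod("dbfs", "numeric", function(x) {
  if (length(x) == 0L) stop("dbfs() requires a non-empty signal")
  r <- sqrt(mean(x^2))
  if (r == 0) -Inf else 20 * log10(r)
})

#' Number of samples in a clip
#' @param x an [AudioClip].
#' @return integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Duration of a clip in seconds
#' @param x an [AudioClip].
#' @return duration in seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Sample rate accessor
#' @param x an [AudioClip].
#' @return sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Amplitude samples accessor
#' @param x an [AudioClip].
#' @return numeric vector of amplitudes in \[-1, 1\].
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' Class label accessor
#' @param x an [AudioClip] or [ClipSet].
#' @return `"vocalization"`, `"non_vocalization"`, or `NA`; for a
#'   [ClipSet], the vector of per-clip labels.
#' @export
setGeneric("clipLabel", function(x) standardGeneric("clipLabel"))

#' Farm identifier accessor
#' @param x an [AudioClip] or [ClipSet].
#' @return farm id string (`NA` if unknown); vector for a [ClipSet].
#' @export
setGeneric("clipFarm", function(x) standardGeneric("clipFarm"))

#' Clips accessor
#' @param x a [ClipSet].
#' @return list of [AudioClip] objects.
#' @export
setGeneric("clips", function(x) standardGeneric("clips"))

#' Manifest accessor
#' @param x a [ClipSet].
#' @return data.frame with one row per clip (id, label, farm, seed, dbfs,
#'   source_id, augmentation).
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' Feature-matrix method accessor
#' @param x a [FeatureMatrix].
#' @return the extraction method name.
#' @export
setGeneric("featureMethod", function(x) standardGeneric("featureMethod"))
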