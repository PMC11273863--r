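#' AudioClip: a mono waveform with provenance
#'
#' The basic audio container: a mono sequence of amplitudes in \[-1, 1\]
#' with its sampling rate, and optional class label / farm provenance used
#' by the evaluation protocol to guard against train/test leakage.
#'
#' @slot samples numeric vector of amplitudes in \[-1, 1\].
#' @slot sampleRate sampling rate in Hz (44,100 for raw recordings,
#'   22,050 for the working rate).
#' @slot label `"vocalization"`, `"non_vocalization"`, or `NA_character_`.
#' @slot farm farm identifier or `NA_character_`.
#'
#' @seealso [audioClip()], [readWav()], [makeVocalization()]
#' @export
setClass("AudioClip",
  representation(
    samples = "numeric",
    sampleRate = "numeric",
    label = "character",
    farm = "character"
  ),
  prototype(label = NA_character_, farm = NA_character_)
)

setValidity("AudioClip", function(object) {
  msg <- character()
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@label) != 1L ||
      !(is.na(object@label) ||
        object@label %in% c("vocalization", "non_vocalization")))
    msg <- c(msg, "label must be 'vocalization', 'non_vocalization', or NA")
  if (length(object@farm) != 1L)
    msg <- c(msg, "farm must be a single string or NA")
  if (length(msg)) msg else TRUE
})

#' Construct an AudioClip
#'
#' @param samples numeric amplitudes in \[-1, 1\].
#' @param sampleRate sampling rate in Hz.
#' @param label optional class label (`"vocalization"` /
#'   `"non_vocalization"`).
#' @param farm optional farm identifier.
#' @return an [AudioClip].
#' @examples
#' clip <- audioClip(sin(2 * pi * 440 * (0:22049) / 22050), 22050)
#' duration(clip)
#' @export
audioClip <- function(samples, sampleRate, label = NA_character_,
                      farm = NA_character_) {
  new("AudioClip", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate),
      label = as.character(label), farm = as.character(farm))
}

#' @rdname nSamples
#' @export
setMethod("nSamples", "AudioClip", function(x) length(x@samples))

#' @rdname duration
#' @export
setMethod("duration", "AudioClip", function(x) length(x@samples) / x@sampleRate)

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "AudioClip", function(x) x@sampleRate)

#' @rdname samples
#' @export
setMethod("samples", "AudioClip", function(x) x@samples)

#' @rdname clipLabel
#' @export
setMethod("clipLabel", "AudioClip", function(x) x@label)

#' @rdname clipFarm
#' @export
setMethod("clipFarm", "AudioClip", function(x) x@farm)

setMethod("show", "AudioClip", function(object) {
  cat(sprintf(
    "AudioClip: %d samples @ %g Hz (%.3f s)%s%s\n",
    length(object@samples), object@sampleRate,
    length(object@samples) / object@sampleRate,
    if (!is.na(object@label)) paste0(", label=", object@label) else "",
    if (!is.na(object@farm)) paste0(", farm=", object@farm) else ""
  ))
})

#' ClipSet: a labeled collection of audio clips
#'
#' Holds a list of [AudioClip] objects together with a manifest
#' data.frame carrying one row per clip: `id`, `label`, `farm`, `seed`,
#' `dbfs`, `source_id` (the id of the original clip for augmented
#' copies; equal to `id` for originals), and `augmentation` (`"none"` or
#' the operator name). The manifest is the provenance record used to
#' enforce that augmented copies never cross a train/test boundary.
#'
#' @slot clips list of [AudioClip].
#' @slot manifest data.frame as described above.
#' @seealso [makeFarmDataset()], [augmentTrainingSet()]
#' @export
setClass("ClipSet",
  representation(clips = "list", manifest = "data.frame")
)

setValidity("ClipSet", function(object) {
  msg <- character()
  need <- c("id", "label", "farm", "seed", "dbfs", "source_id", "augmentation")
  if (!all(need %in% names(object@manifest)))
    msg <- c(msg, paste("manifest must have columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@manifest) != length(object@clips))
    msg <- c(msg, "manifest rows must match number of clips")
  if (length(object@clips) &&
      !all(vapply(object@clips, is, logical(1), "AudioClip")))
    msg <- c(msg, "clips must all be AudioClip objects")
  if ("id" %in% names(object@manifest) &&
      anyDuplicated(object@manifest$id))
    msg <- c(msg, "clip ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ClipSet
#'
#' @param clips list of [AudioClip].
#' @param manifest data.frame with columns `id`, `label`, `farm`, `seed`,
#'   `dbfs`, `source_id`, `augmentation`. Missing provenance columns are
#'   filled with defaults.
#' @return a [ClipSet].
#' @export
clipSet <- function(clips, manifest) {
  if (is.null(manifest$source_id)) manifest$source_id <- manifest$id
  if (is.null(manifest$augmentation)) manifest$augmentation <- "none"
  if (is.null(manifest$seed)) manifest$seed <- NA_integer_
  if (is.null(manifest$dbfs))
    manifest$dbfs <- vapply(clips, function(cl) dbfs(samples(cl)), 0)
  rownames(manifest) <- NULL
  new("ClipSet", clips = clips, manifest = manifest)
}

#' @rdname clips
#' @export
setMethod("clips", "ClipSet", function(x) x@clips)

#' @rdname manifest
#' @export
setMethod("manifest", "ClipSet", function(x) x@manifest)

#' @rdname clipLabel
#' @export
setMethod("clipLabel", "ClipSet", function(x) x@manifest$label)

#' @rdname clipFarm
#' @export
setMethod("clipFarm", "ClipSet", function(x) x@manifest$farm)

#' @param x a [ClipSet].
#' @rdname ClipSet-class
#' @export
setMethod("length", "ClipSet", function(x) length(x@clips))

#' @param i index vector.
#' @param j unused.
#' @param drop unused.
#' @param ... unused.
#' @rdname ClipSet-class
#' @export
setMethod("[", "ClipSet", function(x, i, j, ..., drop = FALSE) {
  clipSet(x@clips[i], x@manifest[i, , drop = FALSE])
})

setMethod("show", "ClipSet", function(object) {
  tab <- table(object@manifest$label)
  cat(sprintf("ClipSet: %d clips (%s); farms: %s\n",
              length(object@clips),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              paste(unique(object@manifest$farm), collapse = ", ")))
})

#' Combine ClipSets
#'
#' Concatenates clip collections, keeping provenance. Ids are made unique
#' by prefixing the originating set index when they collide.
#'
#' @param ... [ClipSet] objects.
#' @return a single [ClipSet].
#' @export
combineClipSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "ClipSet"))
    sets <- sets[[1]]
  mans <- lapply(sets, manifest)
  ids <- unlist(lapply(mans, `[[`, "id"))
  if (anyDuplicated(ids)) {
    for (k in seq_along(mans)) {
      mans[[k]]$id <- paste0("s", k, ":", mans[[k]]$id)
      mans[[k]]$source_id <- paste0("s", k, ":", mans[[k]]$source_id)
    }
  }
  clipSet(do.call(c, lapply(sets, clips)), do.call(rbind, mans))
}

#' FarmProfile: acoustic character of a virtual farm
#'
#' Describes the background-noise character and loudness statistics of
#' one recording site: the noise color of the ambient bed, an optional
#' mains/fan hum, target mean loudness for each class (dBFS), the Table-
#' style loudness bounds the per-clip targets are truncated to, and an
#' exponential reverberation smear constant.
#'
#' @slot name farm identifier.
#' @slot noiseColor `"white"`, `"pink"`, or `"brown"`.
#' @slot humHz hum frequency in Hz (0 = none).
#' @slot targetDbfsVoc mean loudness of vocalization clips (dBFS, negative).
#' @slot targetDbfsNonvoc mean loudness of non-vocalization clips (dBFS).
#' @slot dbfsRangeVoc length-2 (min, max) dBFS bounds for vocalization.
#' @slot dbfsRangeNonvoc length-2 (min, max) dBFS bounds for non-vocalization.
#' @slot reverbSmearMs exponential smearing constant (ms, 0 = none).
#' @seealso [farmProfile()], [builtinFarmProfiles()]
#' @export
setClass("FarmProfile",
  representation(
    name = "character",
    noiseColor = "character",
    humHz = "numeric",
    targetDbfsVoc = "numeric",
    targetDbfsNonvoc = "numeric",
    dbfsRangeVoc = "numeric",
    dbfsRangeNonvoc = "numeric",
    reverbSmearMs = "numeric"
  )
)

setValidity("FarmProfile", function(object) {
  msg <- character()
  if (!object@noiseColor %in% c("white", "pink", "brown"))
    msg <- c(msg, "noiseColor must be white, pink, or brown")
  for (s in c("targetDbfsVoc", "targetDbfsNonvoc")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v >= 0)
      msg <- c(msg, paste(s, "must be a single finite negative dBFS value"))
  }
  if (length(object@dbfsRangeVoc) != 2L || diff(object@dbfsRangeVoc) < 0)
    msg <- c(msg, "dbfsRangeVoc must be (min, max)")
  if (length(object@dbfsRangeNonvoc) != 2L || diff(object@dbfsRangeNonvoc) < 0)
    msg <- c(msg, "dbfsRangeNonvoc must be (min, max)")
  if (object@humHz < 0) msg <- c(msg, "humHz must be >= 0")
  if (object@reverbSmearMs < 0) msg <- c(msg, "reverbSmearMs must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FarmProfile", function(object) {
  cat(sprintf(
    "FarmProfile '%s': %s noise, hum %g Hz, voc %.2f dBFS, non-voc %.2f dBFS\n",
    object@name, object@noiseColor, object@humHz,
    object@targetDbfsVoc, object@targetDbfsNonvoc))
})

#' VocalEventParams: parameters of synthetic vocal bursts
#'
#' Controls the harmonic-stack burst model used to synthesize pig-call
#' stand-ins: fundamental frequency range, number of harmonics and their
#' amplitude falloff, and how many bursts of what duration occur per
#' 3-second clip.
#'
#' @slot f0Range length-2 fundamental frequency interval (Hz), within
#'   \[100, 4000\].
#' @slot nHarmonics number of harmonics per burst.
#' @slot harmonicDecay amplitude falloff exponent (harmonic h has
#'   relative amplitude `h^-harmonicDecay`).
#' @slot nBurstsRange length-2 integer interval for bursts per clip.
#' @slot burstDurRange length-2 burst duration interval (s); must fit in
#'   the 3-s clip.
#' @seealso [vocalEventParams()], [makeVocalization()]
#' @export
setClass("VocalEventParams",
  representation(
    f0Range = "numeric",
    nHarmonics = "numeric",
    harmonicDecay = "numeric",
    nBurstsRange = "numeric",
    burstDurRange = "numeric"
  )
)

setValidity("VocalEventParams", function(object) {
  msg <- character()
  if (length(object@f0Range) != 2L || object@f0Range[1] < 100 ||
      object@f0Range[2] > 4000 || diff(object@f0Range) < 0)
    msg <- c(msg, "f0Range must lie within [100, 4000] Hz")
  if (object@nHarmonics < 1) msg <- c(msg, "nHarmonics must be >= 1")
  if (length(object@nBurstsRange) != 2L || object@nBurstsRange[1] < 1 ||
      diff(object@nBurstsRange) < 0)
    msg <- c(msg, "nBurstsRange must be an increasing integer interval >= 1")
  if (length(object@burstDurRange) != 2L || object@burstDurRange[1] <= 0 ||
      diff(object@burstDurRange) < 0)
    msg <- c(msg, "burstDurRange must be a positive increasing interval")
  if (length(object@burstDurRange) == 2L && object@burstDurRange[2] > 3)
    msg <- c(msg, "burst durations must fit within the 3-s clip")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: a 2-D time-frequency feature array
#'
#' A feature-bins x frames matrix tagged with the extraction method that
#' produced it. For a standardized 3-s clip at 22,050 Hz with hop 512 the
#' frame count is always 130; the row count identifies the method
#' (20 mfcc, 128 mel, 12 chroma, 6 tonnetz / 12 tiled, 166 mixed).
#'
#' @slot values numeric matrix (feature bins x frames), all finite.
#' @slot method one of `"mfcc"`, `"mel"`, `"chroma"`, `"tonnetz"`,
#'   `"tonnetz12"`, `"mixed_mmct"`.
#' @seealso [extractFeatures()]
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", method = "character")
)

.featureRows <- c(mfcc = 20L, mel = 128L, chroma = 12L, tonnetz = 6L,
                  tonnetz12 = 12L, mixed_mmct = 166L)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!object@method %in% names(.featureRows))
    msg <- c(msg, paste("unknown method:", object@method))
  else if (nrow(object@values) != .featureRows[[object@method]])
    msg <- c(msg, sprintf("method '%s' requires %d rows, got %d",
                          object@method, .featureRows[[object@method]],
                          nrow(object@values)))
  if (!all(is.finite(object@values)))
    msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

featureMatrix <- function(values, method) {
  new("FeatureMatrix", values = values, method = method)
}

#' @rdname featureMethod
#' @export
setMethod("featureMethod", "FeatureMatrix", function(x) x@method)

#' @param x a [FeatureMatrix].
#' @rdname FeatureMatrix-class
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' Feature values accessor
#' @param x a [FeatureMatrix].
#' @return the numeric matrix (feature bins x frames).
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@values
}

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d bins x %d frames\n",
              object@method, nrow(object@values), ncol(object@values)))
})
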