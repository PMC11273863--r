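# pigvoc

Detecting pig vocalizations in farm audio — an R implementation of a
complete bioacoustic classification pipeline for precision livestock
monitoring.

Continuous barn recordings are the raw material for acoustic welfare
monitoring, but before any call analysis can happen every 3-second
slice must be sorted into *contains a pig call* versus *background
only*. `pigvoc` implements that binary classifier end to end, for
researchers in precision livestock farming and bioacoustics who need a
tested, seedable, CPU-friendly reference pipeline:

* **Preprocessing** — WAV I/O (PCM 16-bit / float32), stereo-to-mono,
  band-limited resampling to 22,050 Hz, 3-s segmentation, dBFS
  loudness (`20·log₁₀ RMS`, full scale = 1).
* **Features** — from one shared STFT (n_fft 2048, hop 512, Hann,
  centered; 130 frames per 3-s clip): 20-coefficient MFCC, 128-band
  log-Mel spectrogram, 12-class chroma, 6-dimensional tonnetz
  (tonal centroids), and the fused **Mixed-MMCT** matrix
  `[MFCC; Mel; Chroma; Tonnetz]` of 166 × 130, with per-block
  z-scoring.
* **Augmentation** — pitch-shift (`2^(s/12)`, s ∈ [0, 4]), time-shift
  with zero-filled vacancy, phase-vocoder time-stretch, and background
  noising `z = x + w·y`, w ~ U[0, 1]; each operator adds one copy per
  training clip (5× expansion), applied to training folds only with
  provenance tracking.
* **Classifier** — a fixed three-block CNN: conv(5×5, same) → ReLU →
  maxpool(2×2, floor) with 32/64/128 filters, dropout 0.5, dense 1000,
  softmax 2 (first neuron = vocalization; ties → non-vocalization).
  Trained with momentum SGD (0.9) under continuous exponential decay
  `lr·0.9^(step/1000)`, batch 16, cross-entropy. Closed-form counters
  reproduce the published complexity table: 4.36 M / 33.03 M / 2.31 M /
  41.22 M trainable parameters and 0.145 / 0.939 / 0.086 / 1.21 GFLOPs
  for the MFCC / Mel / Chroma-Tonnetz / Mixed inputs. The training
  engine is single-precision RcppArmadillo (im2col + BLAS gemm),
  verified in the tests against an independent double-precision R
  reference.
* **Evaluation** — stratified fivefold cross-validation and the
  leave-one-farm-out robustness protocol (train on two farms, test on
  the third), with confusion counts, accuracy/precision/recall/F1,
  ROC/AUC, and a hard provenance check that no augmented copy of a
  held-out clip ever enters training.
* **Virtual farms** — the original three-farm recordings are private,
  so `makeThreeFarms()` generates seeded stand-ins: balanced two-class
  3-s clips with per-farm noise color (pink/brown/white), hum, reverb
  smear, and class loudness matching the published per-farm dBFS
  statistics. Vocalizations are harmonic-stack bursts; every clip is
  bit-reproducible from `(profile, params, seed)`.

## Worked example

```r
library(pigvoc)

profiles <- builtinFarmProfiles()
profiles[["nias-like"]]
#> FarmProfile 'nias-like': pink noise, hum 120 Hz, voc -24.86 dBFS, non-voc -28.58 dBFS

set <- makeFarmDataset(profiles[["nias-like"]], 80, seed = 5)
set
#> ClipSet: 160 clips (non_vocalization=80, vocalization=80); farms: nias-like

clip <- clips(set)[[1]]
clip
#> AudioClip: 66150 samples @ 22050 Hz (3.000 s), label=vocalization, farm=nias-like
round(dbfs(clip), 2)
#> [1] -26.32

extractFeatures(clip, "mixed_mmct")
#> FeatureMatrix [mixed_mmct]: 166 bins x 130 frames

buildModel(c(166, 130))
#> dcnnModel: input 166 x 130 x 1, flatten 40960, 41,220,026 trainable params (41.22 M)

fit <- trainNetwork(set, "mixed_mmct", trainConfig("desk", epochs = 3, seed = 9))
round(fit$history, 4)
#> [1] 1.5342 0.3063 0.0497

test <- makeFarmDataset(profiles[["nias-like"]], 20, seed = 99)
evaluateModel(fit, test, "mixed_mmct")
#> evalReport: n=40  acc=0.9250  prec=1.0000  rec=0.8500  F1=0.9189  AUC=1.0000
#>   TP=17 TN=20 FP=0 FN=3
```

Reading the output: the generator's clip lands within 2 dB of the
farm's −24.86 dBFS vocalization target; the fused feature matrix has
the contracted 166 × 130 shape; the network built for it carries
41.22 M trainable parameters; training cross-entropy falls from 1.53
to 0.05 in three epochs on 160 clips; and on 40 held-out clips the
model reaches 92.5% accuracy with perfect ranking (AUC 1), missing
three quiet calls (FN = 3) and raising no false alarms (FP = 0).

`countTrainableParams(c(166, 130))$perLayer` breaks the 41.22 M down:
832 + 51,264 + 204,928 (convolutions) + 40,961,000 + 2,002 (dense).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/pigvoc.R synth --farm nias --n-per-class 50 --seed 1 --out data/
Rscript inst/cli/pigvoc.R model-describe --input-shape 166,130
Rscript inst/cli/pigvoc.R cv --farm nias --n-per-class 50 --method mixed --seed 1
```

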