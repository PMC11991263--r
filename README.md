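# LIBSnet

Origin authentication of medicinal plant material from laser-induced
breakdown spectroscopy (LIBS). A laser pulse ablates a pressed-powder
tablet into a plasma; the emission spectrum (370–1100 nm, 2048 points)
carries element lines — Ca 616.22 nm, Na 589.14 nm, N 656.26 nm,
K 766.49 nm among others — whose relative intensities differ between
growing regions. `LIBSnet` classifies such spectra end to end:

* **Preprocessing** — per-spectrum min–max normalization to [0, 1],
  Savitzky–Golay smoothing (least-squares weights
  $C = (X^TX)^{-1}X^TY$; polynomial-reproducing edges; default order 5,
  window 7), and ModPoly-style iterative polynomial baseline
  correction (fit, clamp to the pointwise minimum, repeat). SNR-based
  denoiser selection ($10\log_{10}(\sum\hat y^2/\sum(y-\hat y)^2)$) and
  wavelet denoising are included as the selection harness.
* **Classifier** — a dual-stream multi-scale residual network with
  squeeze-and-excitation channel attention, written from first
  principles (forward and backward passes, SGD with momentum; compiled
  convolution kernels). One stream sees the raw spectrum, the other its
  backward difference $(y_k - y_{k-h})/h$; each stream runs parallel
  1/3/5-kernel convolutions, a max-pool, a further convolution, then a
  basic and a downsampling residual block (SE after normalization,
  before activation). The streams share weights — 2 × 3 = six logical
  branches on one parameter set — and fuse into an MLP head with 50%
  dropout. Accuracy is $(TP+TN)/(TP+TN+FP+FN)$.
* **Comparison suite** — KNN, random forest and decision tree under a
  7:3 split with five-fold cross-validation, plus 1-D LeNet, a modified
  AlexNet (batch-norm replacing the first two max-pools) and ResNet-18
  under a 6:2:2 split.
* **Saliency** — 1-D Grad-CAM over wavelength, verifying that the
  classifier attends to genuine emission lines.
* **Synthetic generator** — Gaussian emission lines on a cubic
  continuum with class-dependent line multipliers, tablet-level
  intensity jitter and detector noise, in the grouped design
  2 classes × 20 tablets × 50 shots = 2000 spectra. All tests and
  benchmarks run on generated data; no measured spectra ship with the
  package.

## Worked example

```r
library(LIBSnet)

# two classes: a neutral "reference" and a "marked" origin whose
# O 777.19 nm line is enhanced 2.2x
cfg   <- singleLineConfig(seed = 1, tabletsPerClass = 5L, shotsPerTablet = 10L)
ds    <- generateSpectra(cfg)
ds
#> SpectralSet: 100 spectra x 2048 wavelength points (370.00-1100.00 nm)
#> classes: reference (50), marked (50)
#> tablets: 10

pp    <- preprocessSpectra(ds)          # normalize -> SG(5,7) -> baseline
parts <- splitDataset(pp, c(0.6, 0.2, 0.2), seed = 1)
model <- buildModel(netConfig(), seed = 1)
model
#> <libsModel 'msnet'>
#>   input length 2048, 2 classes
#>   streams: 2 (shared weights) | multiscale: on (kernels 1/3/5, 8 ch/branch)
#>   residual module: 24 -> 32 channels, SE reduction 4
#>   MLP head: 256-64, dropout 0.50
#>   parameters: 46774

trainModel(model, parts$train, parts$val,
           trainConfig(learningRate = 0.02, epochs = 10L,
                       batchSize = 16L, seed = 1))
evaluateModel(model, parts$test)
#> ClassifierEval: accuracy 100.00% on 20 spectra
#>            pred
#> truth       reference marked
#>   reference        10      0
#>   marked            0     10

i <- which(classLabels(parts$test) == "marked")[1]
gradCam1d(model, parts$test[, i], classIndex = 2L)
#> SaliencyMap (rsm_raw, class 2): 2048 points, peak relevance at 774.41 nm
```

The confusion matrix shows every held-out spectrum assigned to its true
origin, and the saliency map for the marked class peaks at the O
777.19 nm line (774.4 nm is 2.8 nm from its center, inside the line's
pooled-feature cell) — the only feature that separates the two
synthetic classes — rather than at the continuum or the shared lines.

A command-line front end wrapping the same functions lives at
`inst/cli/libsnet.R` (subcommands `generate`, `preprocess`, `train`,
`compare`, `explain`, `run`); `runPipeline()` orchestrates the whole
chain from one YAML/JSON config and writes a self-describing run
directory.

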