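# HRFseg

Segmentation of **hyperreflective foci (HRF)** — punctate 20–50 µm lesions
with reflectivity at or above the retinal pigment epithelium — in retinal
OCT B-scans of diabetic retinopathy patients. The HRF count is a clinical
biomarker of disease progression, but the lesions occupy only a few pixels,
which is exactly the regime where a conventional U-Net encoder (whose
receptive field grows as `2^{2(i-1)}·κ` with level *i*) starts missing
them.

HRFseg implements a **dual-branch network**:

* a three-level **U-Net branch** for semantic context,
* a two-level over-complete **Kite-Net branch** whose encoder *upsamples*
  instead of pooling, shrinking receptive fields as `(1/2)^{2(i-1)}·κ` so
  filters specialise in fine detail,
* **cross-attention blocks (CAB)** fusing the branches at spatial resample
  factors 4 and 16: each side's features are gated residually,
  `F ← F + α ⊙ F`, by a sigmoid attention map
  `α = σ(conv₁ₓ₁(ReLU(conv₁ₓ₁(F) + conv₁ₓ₁(resample(F_other)))))`.

Training uses the compound objective
`loss = 0.5 · dice + 0.5 · focal` (soft dice; focal with α = 0.25, γ = 2),
Adam at batch size 1 (lr 1e-4, β₁ = 0.9, β₂ = 0.999), learning-rate
halving after 5 epochs without improvement, and early stopping.
Evaluation is **two-tier**: per-pixel and per-lesion sensitivity (SE),
precision (P) and dice (DSC), where a ground-truth lesion counts as
detected when predictions cover ≥ 60 % of its pixels.

Because clinical HRF datasets are private, the package ships a **synthetic
OCT phantom generator** (layered retinal bands, multiplicative gamma
speckle, bright punctate foci without back-shadow, exudate-like
confounders *with* back-shadow) so that every pipeline stage is testable.
All network layers and their reverse-mode gradients are implemented in
compiled code within the package — there is no deep-learning framework
dependency.

## Worked example

```r
library(HRFseg)

## a small phantom corpus (3 retinal bands, speckle, 2-4 px foci)
cfg <- PhantomConfig(height = 32L, width = 64L, nLayers = 3L,
                     layerIntensities = c(0.2, 0.5, 0.3),
                     surfaceCurvature = 2, fociCountMean = 4,
                     fociDiameterRange = c(2, 4), confounderRate = 0.3)
raw <- generateDataset(cfg, nPatients = 24, slicesPerPatient = 1, seed = 1)
samples <- lapply(raw, function(s) {
  im <- denoiseBilateral(scanArray(s), 2, 0.15)   # speckle suppression
  PhantomSample(BScan(im, patientId(s), sliceId(s)), s@mask)
})

## 8:1:1 split and a short training run
split <- splitDataset(vapply(samples, sampleId, ""), seed = 1)
fit <- fitModel(ModelConfig(), samples, split,
                TrainConfig(lr = 1e-3, epochs = 10L, monitor = "val_dsc",
                            seed = 1L),
                augmentPolicy = AugmentPolicy())

## two-tier evaluation on the held-out images
test <- samples[match(split@test, vapply(samples, sampleId, ""))]
preds <- predictMasks(fit$model, lapply(test, scanArray))
evaluateDataset(lapply(preds, maskArray), lapply(test, maskArray))
#> MetricsReport over 2 images (tau=0.60, 8-connectivity)
#>   pixel : SE 0.4831  P 0.6111  DSC 0.5385
#>   lesion: SE 0.2917  P 0.4167  DSC 0.3429
```

Read: on the two held-out phantoms, 48 % of true HRF pixels were
recovered, 61 % of predicted HRF pixels were correct, and under the 60 %
coverage rule roughly a third of the individual foci counted as detected —
typical numbers for a deliberately short CPU training run on noisy
phantoms (longer schedules and larger corpora improve them; see the
methods vignette for the scaling rationale).

The pixel tier scores every pixel; the lesion tier counts whole foci under
the 60 % coverage rule — on punctate lesions the lesion tier is the
clinically meaningful one (each focus is a countable biomarker), while the
pixel tier is sensitive to single-pixel boundary disagreements.

Other entry points: `crossAttentionBlock()` (the fusion unit on raw
feature arrays), `receptiveFieldU()` / `receptiveFieldKite()` (closed-form
receptive fields), `countParameters()` vs
`referenceUNetParameterCount()` (the parameter-economy comparison),
`connectedComponents()`, `lesionMatch()`, and `runStage()` — a
config-driven driver for the `phantom → preprocess → train → predict →
evaluate` pipeline, also exposed as the thin command-line script
`inst/scripts/hrfseg`.

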