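---
title: "Segmenting hyperreflective foci in OCT with a dual-branch over-complete network"
author: "HRFseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting hyperreflective foci in OCT with a dual-branch over-complete network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hyperreflective foci (HRF) are punctate lesions of roughly 20-50 µm seen in
OCT B-scans of diabetic retinopathy patients: bright dots with reflectivity
at or above the retinal pigment epithelium and, unlike hard exudates, no
back-shadow.  Their count tracks disease severity, so segmenting them
automatically is clinically useful — and hard, because a typical focus
occupies only a handful of pixels after resampling to a working resolution.

A conventional U-Net encoder pools at every level.  If a level-1 filter
sees a receptive field of $\kappa \times \kappa$ pixels, level $i$ sees
$2^{2(i-1)}\kappa$ — growth that is exactly wrong for lesions a few pixels
across.  The over-complete ("Kite-Net") encoder replaces pooling with
factor-2 bilinear **up**sampling, so the receptive field *shrinks* as
$(1/2)^{2(i-1)}\kappa$ and deep filters specialise in fine detail.
`receptiveFieldU()` and `receptiveFieldKite()` expose these closed forms.

## The network

`ModelConfig()` describes a dual-branch architecture:

* a **three-level U-Net branch** (default channels 8/16/32) providing
  semantic context; standard blocks of two 3×3 convolutions with optional
  per-channel normalisation and ReLU; 2×2 max-pooling between levels;
  decoder with bilinear upsampling and encoder skip concatenation;
* a **two-level Kite-Net branch** (default channels 16/32) whose encoder
  upsamples ×2 per level (features at 2× and 4× input resolution) and
  whose decoder pools back down, with the level-1 skip;
* **cross-attention blocks (CAB)** at the pairings (kite 1, U 2) and
  (kite 2, U 3) — spatial resample factors 4 and 16.  One side's map
  $F_{ki}$ is resampled to the other side's grid, both are projected by
  1×1 convolutions that halve the channel count, summed, passed through
  ReLU, projected to one channel and squashed by a sigmoid into an
  attention map $\alpha \in (0,1)$; the output is the residual gating
  $F \leftarrow F + \alpha \odot F$.  Zero projection weights therefore
  give $\alpha = 1/2$ and output $1.5F$ — a property the test suite pins
  down exactly.
* the **head**: each branch ends in its own 1×1 convolution to a single
  logit map and the two are summed before the sigmoid.  This makes the
  dual model's parameter set the exact disjoint union of the two ablation
  modes (`u_only`, `kite_only`) plus the CABs, which the tests verify by
  counting.

Design choices the architecture description leaves open, decided here:
channel widths (chosen so that paired CAB levels carry equal channels —
with the pairings above this forces kite widths to equal U widths at
levels 2 and 3; widths are halved relative to a typical GPU configuration
to keep CPU training tractable); two-convolution blocks; bilinear
resampling inside CABs; encoder→decoder concatenation skips;
Kaiming-uniform initialisation with a seed held in the model object; and a
prior-probability initialisation of the head biases
($\mathrm{logit}(0.01)$, split between the two heads) so that the initial
output matches the ~1% foreground prevalence instead of 50%, a standard
measure for extreme class imbalance.

The whole network — convolutions, pooling, bilinear resampling,
normalisation and their reverse-mode gradients — is implemented in
compiled code inside the package (single-precision im2col + BLAS for the
convolutions), with a small tape in R orchestrating the backward pass.
Gradients were validated against central finite differences and each
kernel against a direct dense oracle.

## The objective

`combinedLoss()` is the equally weighted sum of

* **soft dice loss** $1 - (2\sum p t + \varepsilon)/(\sum p + \sum t +
  \varepsilon)$, which on binary inputs reduces to $1 - 2TP/(2TP+FP+FN)$,
  and
* **focal loss** $-w (1-p_t)^\gamma \log p_t$ averaged over pixels, with
  $p_t$ the probability of the true class and $w = \alpha$ on foreground,
  $1-\alpha$ on background.

Defaults $\alpha = 0.25$, $\gamma = 2$ are the standard focal settings;
$\varepsilon = 10^{-6}$; probabilities are clamped to $[10^{-7},
1-10^{-7}]$ and the analytic gradient is zeroed at the clamp.  The dice
term is computed per image and averaged, not pooled over the batch — the
batch size is 1 in the reference schedule anyway.

## Training schedule

`TrainConfig()` defaults encode the reference schedule: Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$), initial learning rate $10^{-4}$,
batch size 1, at most 150 epochs, learning rate halved after 5 epochs
without improvement of the monitored loss, and early stopping (patience
15, our choice; the original only states that early stopping was used).
Which loss the plateau rule watches is not specified; `monitor` accepts
`val_loss` (default), `train_loss`, or `val_dsc`, and the weights returned
are those of the best monitored epoch.  Splitting is by image at 8:1:1
with the validation set taking the odd remainder — for 173 slices this
gives 138/18/17 — with an optional patient-grouped mode that keeps all
slices of a patient in one subset (recommended when patient leakage
matters, but not the default, which mirrors the by-image protocol).

## Evaluation

`pixelMetrics()` reports sensitivity $TP/(TP+FN)$, precision $TP/(TP+FP)$
and dice $2TP/(2TP+FP+FN)$.  `lesionMatch()` implements the lesion tier: a
ground-truth component counts as detected when predictions cover at least
$\tau = 0.6$ of its pixels; undetected components are lesion-FNs; a
predicted component is a lesion-FP iff it contributes no pixel to any
detected component (the rule for partially-overlapping-but-unmatched
predictions is not fixed by the protocol's text; counting them as FPs
keeps $TP + FN$ anchored to the ground-truth count while penalising
spurious blobs).  Components use 8-connectivity by default because
anti-aliased punctate blobs fragment under 4-connectivity.  Dataset values
are unweighted per-image means (macro averaging, matching "the average
value of the evaluation index of all image segmentation results"); images
with empty truth and empty prediction score 1.  Zero denominators with a
nonempty counterpart score 0.

## The phantom generator

No public dataset with HRF masks exists at the time of writing, so
`generatePhantom()` synthesises B-scans with the statistical structure the
method assumes:

* `nLayers` horizontal bands with configurable mean intensities, deformed
  by a smooth low-frequency curve (`surfaceCurvature`, pixels) — the
  retinal layer stack;
* unit-mean multiplicative gamma speckle (`speckleShape`; smaller =
  noisier), the standard model of OCT speckle;
* Poisson-many bright elliptical foci (axis ratio 0.7-1, diameters
  uniform in `fociDiameterRange`, default 2-6 px ≈ 20-50 µm at typical
  Heidelberg lateral resolution) placed strictly inside the banded
  region, non-overlapping, with additive contrast `fociContrast` and *no*
  shadow — the HRF analogue; the truth mask is exactly their rendered
  footprint;
* optionally, larger exudate-like blobs that *do* cast a darkened column
  below them (`confounderRate`), excluded from the mask — emulating the
  hard-exudate confusion mode.

`generateDataset()` shares the band geometry across slices of a patient
(so grouped splitting is testable) and can thin, e.g., 50 patients × 4
slices to a 173-slice corpus.  Configurations whose expected focus area
exceeds 25% of the banded region are rejected: the generator models
punctate lesions only.

What the phantom does **not** model: wave-optics speckle correlation,
vessel shadows, motion artefacts, pathology other than the two lesion
types, and annotation noise.  Passing the recovery experiment below
therefore shows that the pipeline can learn and localise small bright
lesions under speckle and confounders — not that it reaches any particular
accuracy on clinical scans.

## Problem sizes used by the tests and the acceptance script

The experiments are scaled to desk-top CPU sizes, chosen once:

* phantoms of 32 × 64 pixels with 3 bands, foci 2-4 px, speckle shape 4,
  confounder rate 0.3, denoised with the bilateral filter (σ_spatial = 2,
  σ_range = 0.15) before training — the pipeline's standard order;
* recovery experiment: 48 training, 8 validation, 16 held-out test
  phantoms, 24-36 epochs at learning rate $10^{-3}$.  The reference
  schedule ($10^{-4}$, 150 epochs, 138 images) performs ~20,000 Adam
  updates; the scaled runs preserve the product (steps × learning rate)
  rather than the raw epoch count, which is the quantity that governs
  total parameter displacement under Adam's unit-scaled steps;
* overfit sanity check: one phantom, 200 updates at learning rate
  $10^{-2}$ (again the displacement-preserving equivalent of a few
  thousand small-step updates).

## Numerical choices and degenerate inputs

Bilinear resampling uses the half-pixel-centre convention at both train
and test time; max-pooling breaks ties toward the first element in scan
order; component labelling is deterministic in column-major scan order;
rotation fills exposed image corners with the background median and mask
corners with 0; masks are re-binarised after every geometric transform;
`standardize()` short-circuits when the input is already at the target
size.  Inputs whose sides are not divisible by 4 are rejected by default
(`inputPolicy = "resize"` resamples instead and resizes the probability
map back).  All generators and the trainer draw from private RNG streams
seeded explicitly, so every artefact is reproducible from its recorded
seeds.

## Known limitations

Pixel dice on lesions a few pixels across is intrinsically brittle — a
one-pixel boundary disagreement on a five-pixel lesion costs ~0.2 dice —
which is exactly why the lesion tier with its 60% coverage rule is
reported alongside.  Training on a CPU in R is two orders of magnitude
slower than a GPU framework, so the shipped experiments are small; the
architecture and losses themselves put no constraint on image size beyond
divisibility by 4.  The plateau schedule watches a noisy small-sample
validation loss in the scaled experiments; with large validation sets its
behaviour approaches the reference schedule's.
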