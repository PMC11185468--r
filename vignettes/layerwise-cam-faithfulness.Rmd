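---
title: "Layer-wise CAMs and the per-layer ROAD faithfulness series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-wise CAMs and the per-layer ROAD faithfulness series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(camroad)
```

## The model of an explanation

A class activation map (CAM) explains the score $y^c$ a classifier
$f(\cdot)$ assigns to class $c$ on image $x$ as a weighted combination of
the channel activation maps $A^l_k = f^l(x)_k$ at a layer $l$:

$$L^c(A^l) \;=\; \mathrm{ReLU}\Big(\sum_k \alpha^c_k\, A^l_k\Big),$$

rectified because negative evidence is not displayed, then bilinearly
upsampled to input resolution. The package computes this map for *every*
layer with a genuinely two-dimensional output, in forward execution order,
under eleven weighting rules, and treats the resulting ordered sequence —
not a single hand-picked layer — as the unit of explanation. Two views of
that sequence are supported:

* **Local normalization** rescales each frame by its own min/max and
  answers *"what matters at this layer?"*
* **Global normalization** rescales every frame by the min/max over all
  frames and answers *"which layer matters most overall?"* — a weakly
  activated layer correctly appears as an attenuated frame instead of being
  silently stretched to full contrast.

Both are affine rescalings, so they preserve the pixel ranking within a
frame; global normalization also preserves it across frames. Global
normalization is computed in two passes (first the raw maps and their
global extrema, then the rescaling); at the 64–224 px scales this package
targets, the frames are simply held in memory between the passes.

### Weighting schemes

The scheme definitions are pinned explicitly so implementations agree
(`eps = 1e-8`, softmax temperature 1):

| scheme | weights |
|---|---|
| `gradcam` | $\alpha_k$ = spatial mean of $G_k = \partial y^c / \partial A_k$ |
| `gradcampp` | $\alpha_k = \sum_{ij} w_{kij}\,\mathrm{ReLU}(G_{kij})$, $w = G^2 / (2G^2 + \sum_{ab} A G^3 + \varepsilon)$ |
| `xgradcam` | $\alpha_k = \sum_{ij} \big(A_{kij}/(\sum_{ab} A_{kab} + \varepsilon)\big) G_{kij}$ |
| `hirescam` | map $= \sum_k G_k \odot A_k$ (no spatial averaging) |
| `gradcam_elementwise` | map $= \sum_k \mathrm{ReLU}(G_k \odot A_k)$ |
| `layercam` | map $= \sum_k \mathrm{ReLU}(G_k) \odot A_k$ |
| `eigencam` | first right singular vector of the $k \times HW$ activation matrix, sign chosen so the map sums $\ge 0$; class-agnostic |
| `eigengradcam` | eigencam applied to $G \odot A$ |
| `scorecam` | $\alpha$ = softmax over channels of the target score on the image masked by each channel's min–max-normalized upsampled activation |
| `ablationcam` | $\alpha_k = (y^c - y^c_{k\text{-ablated}}) / (\lvert y^c\rvert + \varepsilon)$ |
| `randomcam` | $\alpha_k \sim \mathrm{Uniform}(-1, 1)$, seeded — a calibration null |

Design choices worth stating: gradients are taken of the **pre-softmax
logit** (standard in this literature; softmax gradients saturate), the
ReLU is applied **before** upsampling (the map is rectified at layer
resolution; the difference from rectifying after interpolation is minor
but has to be pinned), and the target class is resolved **once** from the
unperturbed image and held fixed across layers and perturbations.
Upsampling is corner-aligned bilinear interpolation: corners are
preserved, constant maps stay constant, and resampling at the same shape
is the identity.

### Which layers are mapped

A layer qualifies if its output is a numeric tensor with at least two
trailing spatial axes of extent above one (`spatial2d`). Rank-2 outputs
and spatial outputs collapsed to $1\times1$ (`vector1d`) would merely draw
a 1-D vector as stripes, so they are filtered from rendering and scoring
but still reported in the frame index and in the skipped-layer table.
Rank-3 token sequences are recognized as such; rendering them requires a
token-to-grid rule the user must supply, and is otherwise skipped. The
global extrema are taken over rendered (spatial) frames only — excluded
layers never contribute, since they are never shown.

## The faithfulness series

Each frame is scored with the combined Remove-and-Debias (ROAD) metric.
For perturbation fractions $p \in \{0.2, 0.4, 0.6, 0.8\}$ the
most-relevant (MRP) or least-relevant (LRP) $round(p \cdot HW)$ pixels
(ties broken by ascending flat index) are replaced by **noisy linear
imputation**: each imputed pixel equals the mean of its 4-neighbors —
unmasked neighbors enter as constants, borders shrink the stencil — which
yields a sparse linear system solved per channel, followed by seeded
Gaussian noise ($\sigma = 0.01$ on unit-scaled intensities) on the imputed
pixels only. Imputation (rather than blacking out or blurring) prevents
the mask shape itself from leaking class information. With
$C = p_\text{softmax}(c \mid \text{imputed}) - p_\text{softmax}(c \mid x)$:

$$\mathrm{ROAD}(L^c(A^l)) \;=\; \underset{p}{\mathrm{mean}}\;
  \frac{C_{\mathrm{LRP},p} - C_{\mathrm{MRP},p}}{2} \in [-1, 1].$$

The **mean** over fractions (not the sum) is the default aggregate so the
score stays bounded per fraction and comparable across configurations with
different numbers of fractions; `aggregate = "sum"` is available. $C$ is
defined as a *change* from the unperturbed confidence; post-softmax
probabilities are used here (the gradient pass, above, uses logits). The
4-neighborhood is weighted uniformly — a deliberate dialect pinned for
testability against a dense linear-algebra oracle, which the test suite
exercises to $10^{-8}$ on 8×8 instances. Noise seeds derive from
(seed, fraction) only, so exchanging the LRP/MRP labels negates the
combined score *exactly*, an antisymmetry the tests assert as an identity.
ROAD is computed on the locally normalized map; only the pixel ranking
enters, and ranking is invariant to affine normalization.

The ordered per-layer scores form the series **ybROAD**, with its mean
(overall end-to-end faithfulness), max, and argmax layer — the most
faithful explanatory layer, a measured alternative to picking the last
convolution by convention. The series covers scorable (`spatial2d`) layers
only, and is labelled as such.

## The synthetic study

No real imagery ships with the package. The fixture emulates a two-class
lesion-detection task: 64×64 single-channel images, a speckled background
(`base` 0.3) built from Gaussian-smoothed multiplicative noise
(`noise_level` 0.15, kernel sd 1.5 px — visually ultrasound-like and fully
parameterized), and for class 1 a filled ellipse (random center, axes
12–25 % of the image side, random orientation) whose intensity exceeds the
background by `contrast` 0.4 before speckle. At `noise_level = 0` lesion
pixels sit exactly at background + contrast, which the tests exploit. The
stock study conditions are n = 400 samples, class-balanced, split
80–10–10, classified by a three-block CNN (conv 3×3 + batch-norm + ReLU +
max-pool at 8/16/32 channels, global average pooling, 2-class linear head;
14 leaf layers, 6,066 parameters) trained for 10 epochs with Adam at
lr 0.01, batch 32. Images are 64 px rather than 224 px so the whole suite
runs in minutes; one smoke test confirms the pipeline accepts 224 px
inputs unchanged. No augmentations are applied.

Because short runs leave batch-norm's exponential running statistics
lagging the rapidly changing weights, training ends with a standard
recalibration pass: the running statistics are replaced by the cumulative
average of batch statistics over the training set under the final weights.
Without it, inference-mode accuracy can sit near chance while batch-mode
accuracy is perfect.

What the fixture shows — and what it cannot. Passing tests demonstrate the
mechanics end to end: a trained model reaches ≥ 0.9 test accuracy, its
final-block GradCAM maps overlap the true lesion (IoU ≥ 0.25 at threshold
0.5 on ≥ 8/10 lesion images), trained models dominate random-weight
controls in mean ybROAD, and the rectified block outputs lose spatial
entropy from the first to the last block (diffuse early, focused late) —
measured at the block activation outputs, because the *signed* first-conv
response is sparse after the CAM ReLU and not representative of what the
block passes forward. None of this certifies behavior on real ultrasound
data: real lesions are not ellipses, real speckle is not stationary, and
real classifiers are far deeper, so the fixture validates the metrics and
plumbing, not clinical utility.

## Numerical and degenerate-input conventions

* Constant (degenerate) CAM frames normalize to all-zero with a warning;
  an all-constant stack likewise.
* A fully masked image makes the imputation system ill-posed; the channel
  mean is used, with a warning.
* ScoreCAM channels with constant activation get weight 0 (no division
  blow-up); if every channel is constant all weights are 0.
* Max-pool gradient ties route to the first matching window position;
  pixel-selection ties break by ascending flat index — both fixed for
  determinism.
* Class indices are 1-based throughout the R API; `"argmax"` resolves once
  against the unperturbed image.

## Known limitations

* RandomCAM on this fixture averages a mean ybROAD of about +0.11 rather
  than 0. On a trained single-subject classifier every channel's
  activation concentrates on the lesion, so even a random channel mix
  ranks lesion pixels above background after rectification. The genuinely
  uninformative controls do sit at zero (normal-class images ≈ 0;
  random-weight models ≈ 0.005). Near-zero RandomCAM behavior belongs to
  multi-object scenes, which a single-lesion generator cannot produce.
* The benchmark architecture profiles (AlexNet … MaxViT-T) are parameter
  censuses generated from the published architecture definitions; they
  profile exactly but do not execute, so CAMs cannot be computed for them
  here.
* The engine covers plain feed-forward topologies; residual/branching
  graphs, recurrent models and detectors are out of scope.
* MP4 encoding requires an external `ffmpeg`; otherwise the package's
  native GIF89a writer (252-color fixed palette) provides the animation
  container.
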