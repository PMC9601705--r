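---
title: "Segmenting dental surface meshes with multiple geometric feature learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting dental surface meshes with multiple geometric feature learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentalseg)
```

## The problem

Virtual orthodontic planning starts from an intraoral surface scan: a
triangular mesh of the dental arch, typically stored as STL. The planning
software needs every triangle assigned to one of 15 semantic classes —
the gingiva (class 0) plus the 14 teeth of one arch. Assigning classes to
*faces* rather than vertices avoids a basic ambiguity: a vertex on a
tooth–gum boundary is shared by triangles of both classes, whereas a face
centroid belongs to exactly one face. `dentalseg` implements a per-face
segmentation network built on that observation, together with everything
around it: mesh I/O, preprocessing, a synthetic dental-arch generator,
training, evaluation and a command-line interface.

## The model

Each face contributes a 15-dimensional input row: its three vertices (9),
its centroid (3, the mean of the vertices), and its unit normal (3, the
normalized cross product of two edge vectors — the winding order defines
the outward side). The network maps the `N x 15` feature matrix to an
`N x C` matrix of class probabilities:

1. **T-Net alignment.** A small tower (pointwise layers of widths 64, 128,
   512, a global max pool, then fully connected layers 256, 128, 225)
   emits a 15 x 15 matrix that is added to the identity and multiplied
   against the input features. It starts numerically at the identity
   (the final layer is initialized near zero) and learns a global feature
   alignment.
2. **Dual-branch multiple geometric feature learning (MGFL).** For every
   face, its K nearest faces by centroid distance (self included) are
   encoded twice: the *centroid branch* concatenates
   `(p_i, p_ik, p_i - p_ik, ||p_i - p_ik||)` and the *normal branch*
   `(n_i, n_ik, n_i - n_ik, cos(n_i, n_ik))` — 10 channels each. A shared
   pointwise MLP lifts the 20 encoding channels; the result is
   concatenated with the (separately lifted) features of the neighbour
   face. A per-channel attention score, normalized by a softmax over the K
   neighbours, weights the slots, which are then summed — attention-based
   aggregation rather than plain max/mean pooling. The whole block is
   residual: a projected shortcut of the block input is added before the
   ReLU. Two receptive fields run in parallel (K = 3 and K = 20) and their
   outputs are summed; two such stages emit widths 128 then 512.
3. **Fusion head with efficient channel attention (ECA).** The stage-2
   output is max-pooled into one 512-vector of global context, tiled back
   to all faces, and concatenated with the aligned input features and the
   per-face stage-2 features (15 + 512 + 512 = 1039 channels). Two
   pointwise layers (256, 128) each followed by ECA, dropout, a final
   linear layer to C and a row softmax produce the probabilities. ECA
   mean-pools the faces into a channel descriptor, convolves it with an
   adaptive odd kernel of size `k = |log2(C)/gamma + b/gamma|_odd`
   (gamma = 2, b = 1; even values are bumped up to the next odd), applies
   a sigmoid and rescales each channel.

Training minimizes the generalized Dice loss
`1 - 2 * sum_l w_l sum_n r_nl p_nl / (sum_l w_l sum_n (r_nl + p_nl) + eps)`
with `w_l = 1/(sum_n r_nl + eps)^2` and `eps = 1e-6`, using Adam
(lr 0.001), reduce-on-plateau decay (factor 0.5), dropout 0.5 on the head
and, at full scale, 200 epochs with batch size 4. Evaluation reports
overall accuracy (OA, the fraction of correctly labeled faces) and mean
intersection-over-union (mIoU) averaged over all C classes from the
confusion matrix.

## What the synthetic generator emulates — and what it does not

No public dental-scan corpus ships with this package, so every experiment
runs on synthetic arches from `generate_arch()`: a gingival band swept
along a parabolic arch (widths sized like an adult jaw, in millimetres)
carrying up to 14 smooth convex caps placed at equal arc-length spacing,
with Gaussian vertex jitter at scanner-noise scale (sd 0.05 mm), then
quadric-edge-collapse decimation to the requested face count with
nearest-centroid label transfer. A crowding preset contracts the spacing
until adjacent caps touch, mirroring malocclusion, and `make_dataset()`
mixes roughly 30% crowded models into each dataset.

The caps are geometrically separable regions with tooth-like normals and
positions — exactly what the neighbourhood encodings consume — but they
are *not* anatomical crowns: no occlusal fissures, no interproximal
undercuts, no gingival margin detail, no scan holes. Passing tests
therefore demonstrate that the implementation learns and generalizes on
arch-shaped geometry; they do not certify clinical accuracy on real
intraoral scans.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `target_faces` | 10000 | faces after decimation (reference protocol) |
| `K_small`, `K_large` | 3, 20 | neighbourhood sizes of the two MGFL branches |
| `mgfl_dims` | 128, 512 | stage output widths |
| `head_dims` | 256, 128 | fusion-head widths |
| `eca_gamma`, `eca_b` | 2, 1 | ECA kernel-size rule |
| `dropout` | 0.5 | head dropout during training |
| `lr` | 0.001 | Adam initial learning rate |
| `epochs`, `batch_size` | 200, 4 | full-scale training protocol |

All lengths are millimetres; `tooth_radius` (2.4–3.1) and `tooth_height`
(4–6.5) give caps in the size range of premolar/molar crowns relative to a
55 x 35 mm arch.

## Desk-scale experiment profile

The shipped tests and the reproduction script run two experiments sized
for a single CPU core:

* an **overfit probe** — one 2000-face arch, 150 optimization steps at the
  default learning rate, dropout disabled (memorization is the point of
  the probe). Memorizing in so few steps needs capacity — narrow variants
  converge erratically because the generalized Dice weights make the
  dominant gingiva class the slowest to fit — so the probe keeps the full
  stage-1 and head widths and halves only stage 2: MGFL 128/256, head
  256/128;
* a **held-out experiment** — 8 training arches, 2 test arches, 2000
  faces, 30 epochs, batch size 1, dropout 0.5, on a lighter quarter-scale
  profile (MGFL 64/128, head 128/64): with eight arches of training signal
  the smaller network generalizes comfortably and runs twice as fast.

These are runtime/capacity profiles for CPU execution; the architecture,
encodings, loss and optimizer are identical to the full configuration,
which remains the default of `network_config()`.

## Numerical and design notes

* **Batch norm placement.** Shared (pointwise) MLPs use linear + batch
  norm + ReLU over the faces. The T-Net fully connected layers act on a
  single 1 x 512 global descriptor per mesh; batch statistics over one row
  are degenerate when meshes are processed one at a time, so those layers
  use plain biases instead.
* **T-Net initialization.** The final fully connected layer is initialized
  with sd 1e-5 weights: the transform starts numerically at the identity
  while gradient reaches the whole tower from the first step (an exactly
  zero initialization would leave the tower without gradient for one
  step).
* **Attention normalization.** The per-channel attention scores are
  softmax-normalized over the K neighbours before the weighted sum.
* **Fusion contents.** The head concatenates the T-Net-aligned input, the
  stage-2 features and the tiled global vector; concatenating stage-1
  features as well is available behind `include_stage1` (off by default).
* **Degenerate faces.** Zero-area faces get a zero normal, are reported
  (not fatal), and their cosine similarity with anything is defined as 0.
* **Welding.** STL facet soup is welded with per-axis tolerance 1e-6 mm
  (below scanner precision, above float32 storage noise) using staggered
  grids + union-find, so merging is exact for any pair within tolerance.
  Welding never changes the face count; faces degenerated by merging are
  flagged.
* **Decimation.** Garland–Heckbert quadric error metrics with
  endpoint/midpoint placement, a link-condition guard against pinching,
  and penalty quadrics on boundary edges so open arch rims survive.
  Labels transfer to the nearest input-face centroid, so decimation can
  run before or after labeling.
* **Ties.** K-NN ties break toward the smaller face index; argmax ties in
  prediction toward the smaller class index. Both make runs bit-stable.
* **Batching unequal meshes.** Gradients are accumulated one mesh at a
  time, so differing face counts need no padding; when `batch_size > 1`
  and counts differ, every mesh is randomly cropped once
  (label-preservingly) to the smallest count, keeping batch semantics.
* **mIoU conventions.** A class absent from both truth and prediction
  contributes IoU 1; absent from truth but predicted contributes 0. With
  all classes present, mIoU <= OA.
* **Reproducibility.** Every artifact embeds the seeds and configuration
  that produced it; two runs with the same seed are bitwise identical.

## Known limitations

* The network is trained and validated on synthetic caps, not anatomical
  crowns; transfer to real scans requires real training data.
* The 15 x 15 transform multiplies all feature columns, including the
  normal columns — a general linear map does not preserve normal
  semantics. The design applies it to all 15 dimensions, and we
  follow it; the oddity is noted.
* ECA's global pooling is implemented as a mean over faces (the usual
  GAP-style reading); max pooling is the other defensible choice.
* Exact K-NN is brute force (O(N^2) per mesh) — fine at 10^4 faces,
  not intended for raw 350k-face scans, which should be decimated first.
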