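---
title: "Classifying short-axis slice levels with a cascaded CNN-RNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying short-axis slice levels with a cascaded CNN-RNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxlevel)
```

## The problem

Short-axis cardiac cine MRI covers the left ventricle with a stack of 8--25
slices ordered from apex to base. Many analyses (segmentation quality control,
regional function, reporting) need to know the anatomical level of every
slice. The package implements a five-level taxonomy driven purely by visible
morphology:

| ordinal | token | definition |
|---|---|---|
| 0 | `oap` | out-of-apical: no LV blood pool visible |
| 1 | `ap`  | apical: myocardial ring around a small pool, no papillary muscle |
| 2 | `mid` | mid: papillary muscles visible inside the pool |
| 3 | `bs`  | basal: larger ring, no papillary muscle |
| 4 | `obs` | out-of-basal: crescent of basal lateral myocardium, no discernible pool |

A single slice can be ambiguous — a strongly contracted basal cavity in
systole can look exactly like a diastolic apical cavity — but the stack order
is strongly informative: levels are non-decreasing from apex to base. The
core claim the package operationalises is that a per-image classifier makes
*ordinal-skipping* mistakes (e.g. predicting `obs` for an `ap` slice) that a
sequence model over the whole stack largely avoids.

## The model

Each slice image is mapped by a frozen convolutional backbone to a
global-average-pooled feature vector $x_i$ (transfer learning in the
fixed-feature-extractor setting; the backbone is never updated). A stack of
$N \le 25$ slices becomes a padded sequence $(x_1,\dots,x_N,0,\dots,0)$ of 25
time steps with a validity mask. Four many-to-many recurrent heads are
implemented, all with 128 units per layer/direction and a shared
per-time-step classifier (dense 256 + ReLU + dropout 0.5 + dense 5 +
softmax):

* `2-lstm`, `2-gru`: two stacked unidirectional layers;
* `bi-lstm`, `bi-gru`: one bidirectional layer, 128 units per direction.

The `cnn` baseline applies the same dense head to each feature vector
independently. Training minimises categorical cross-entropy averaged over
valid steps only, with Adam at its conventional defaults
($\alpha=10^{-3},\beta_1=0.9,\beta_2=0.999$), batch size 32 for the per-image
head and 2 for sequence models, for a fixed epoch budget (default 50); the
reporting epoch is the argmin of validation loss, ties broken toward the
earliest epoch. The layers and backpropagation-through-time are implemented
in base R matrix algebra and are validated against central finite differences
in the test suite (relative error below $10^{-5}$ on every parameter probed).

### Masking and padding

Stacks shorter than 25 slices are post-padded (valid steps first) with
all-zero rows. Two mechanisms make padding inert: inputs are multiplied by
the validity mask before the first recurrent layer, and the loss and all
metrics average over valid steps only. The first matters for the
*bidirectional* variants, whose reverse pass would otherwise traverse padded
rows before reaching valid steps; with input masking, perturbing padded rows
provably changes nothing downstream, which the tests assert to $10^{-6}$.

### Capacity parity and the TinyTest feature dimension

The bidirectional and two-layer arrangements of the same cell differ in RNN
parameters by $4H(D-H)$ (LSTM) and in head parameters by $256H$ (the
bidirectional head sees $2H$ inputs). With $H=128$ these cancel exactly at
$D=64$, so the built-in `TinyTest` backbone uses a 64-dimensional feature
vector: Bi-LSTM and 2-LSTM then have *identical* trainable-parameter counts,
and the GRU pair differs by about 4%. This makes the SOTD comparison between
arrangements a comparison of structure, not capacity. For wide pretrained
feature vectors ($D \ge 1024$) the same arrangements diverge in capacity;
the parity property is asserted at the dimension the package actually
trains at.

### Backbones

Four ImageNet backbones are described by name with their published
penultimate feature widths (EfficientNetB0 1280, MobileNet 1024, NASNetMobile
1056, ResNet50V2 2048, inputs declared 224×224 with the usual $[0,1]$ or
$[-1,1]$ input scaling). Their pretrained weights are not distributed with
the package; requesting them is an explicit error, and they can instead be
instantiated with deterministic random convolution kernels, which preserves
every structural contract (feature width, determinism, frozenness).
`TinyTest` (64×64 input, three convolution layers, 64 features) is the
backbone the package trains with routinely; random convolutional features
are a classical, surprisingly serviceable representation for morphology as
coarse as pool/ring/blob geometry.

## The synthetic phantom generator

Real labelled cine MRI cannot ship with the package, so every stage is
exercised on synthetic phantoms that encode *only* the label-defining
morphology: textured background (`oap`); dark myocardial annulus around a
bright pool, small (`ap`) or large (`bs`); the same with 1--3 dark papillary
blobs inside the pool (`mid`); a dark partial annulus with no pool (`obs`).
The renderer also returns its own region masks (pool, blobs, myocardium) as
a side channel, so tests can verify morphology with an independent
connected-component oracle rather than trusting intensities.

Study conditions encoded in the defaults: 8--25 contiguous slices per
subject, two cardiac phases (diastole, systole) sharing one ground-truth
label sequence, label sequences monotone apex→base
(`oap* ap* mid* bs* obs*`) with the three in-ventricle levels always present
and out-of-level runs appearing with nonzero probability at both ends.
Geometry ranges (fractions of the image side): cavity radius `ap`
0.05--0.08, `mid` 0.09--0.13, `bs` 0.13--0.17; wall 0.04--0.06; blob radius
0.015--0.03; systolic cavity scale 0.55--0.80; crescent arc 120--220°;
additive Gaussian noise (sd 6) over a smoothed-noise texture, clipped to
[0, 255]. The systolic scale was chosen so that systolic basal cavities
overlap diastolic apical/mid sizes — single slices are then genuinely
ambiguous without context, which is precisely the phenomenon that motivates
the cascade. What the phantoms do *not* emulate: MRI physics and artefacts,
anatomical shape variability, through-plane effects, inter-observer label
noise, or non-monotone label sequences. Passing tests on phantoms
demonstrate the pipeline's correctness and the direction of the
sequence-context effect, not clinical performance.

Monotonicity is a generator *choice*: real stacks are ordered apex to base,
but nothing guarantees a labeller never saw, say, a basal slice below a mid
slice; the manifest records the direction and the shared-labels convention
explicitly.

## Curation rules

Three exclusion rules, checked per subject: duplicate identifiers,
inconsistent slice counts across phases, non-contiguous slice indices.
"Identifier" is read as the (subject, phase, slice index) key, with the
index parsed as the leading integer of the file name. Contiguity means the
sorted distinct indices are exactly $0..n-1$. The violation planter used in
tests corrupts a subject with exactly one rule: a duplicate file for an
existing index; removal of the last systolic slice; or removal of a middle
index from *both* phases (one phase alone would also trip the count rule).
Intensity rescaling to 8 bits is per-image linear min--max with round-half-
to-even; a constant image maps to zero. Subject-wise splitting uses
largest-remainder rounding of the requested fractions (ties by partition
order), which makes the 974-subject split with fractions
(0.591, 0.220, 0.189) come out at exactly (576, 214, 184). Full cine phase
selection is out of the curation core; `select_phase_frames()` is a clearly
documented stand-in heuristic.

## Evaluation

All valid test slices are pooled into one 5×5 confusion matrix (rows true,
columns predicted). From it: one-vs-rest precision/recall/F1 per class
(zero-denominator cases return 0 with a warning), accuracy (trace/total),
support-weighted one-vs-rest AUC (rank-statistic per class; classes absent
from the truth are excluded with a warning; a single-class truth is an
error), and SOTD — the sum of entries outside the tridiagonal band
$|i-j|\le 1$, i.e. the count of predictions that skip at least one adjacent
level. Merging `ap`, `mid`, `bs` into one `in` class gives a 3×3 matrix
whose error rate is never larger than the five-class one (confusions can
only vanish under merging). Argmax ties in prediction resolve to the lowest
ordinal.

## Problem sizes and runtime choices

The packaged experiments run on one CPU: the comparison harness defaults to
60 phantom subjects (subject-wise split ≈ 36/13/11), the TinyTest backbone
and 15 epochs, which trains all five variants in a few minutes; the test
suite additionally repeats the comparison over three seeds and averages
before asserting that every recurrent variant's SOTD is at or below the
per-image head's. Unit tests use smaller images (64 px) and tiny hidden
sizes for the gradient checks (those dimensions only need to exercise the
algebra).

## Known limitations

* Random-weight backbones are weaker features than pretrained ones; absolute
  accuracies on phantoms are far below what pretrained backbones reach on
  real data, and only the *relative* CNN vs CNN-RNN comparison is meaningful.
* The generator's monotone labels make the task easier for sequence models
  than real, possibly noisy, label sequences would be.
* Dropout is the only regulariser; there is no data augmentation (stack-wise
  synchronised transforms would be required) and no backbone fine-tuning.
* Training is single-threaded; the sequence batch size of 2 follows the
  study protocol rather than throughput considerations.
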