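---
title: "Image-based QSAR from multi-angle molecular snapshots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based QSAR from multi-angle molecular snapshots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Quantitative structure–activity relationship (QSAR) models predict a
biological activity from chemical structure. `snapqsar` implements an
image-based variant: instead of hand-crafted descriptors or molecular
graphs, each compound is embedded as a single 3D conformer, drawn as a
ball-and-stick model, photographed from a grid of rotations, and the
resulting 2D snapshots are classified by a convolutional network. The
premise is that a CNN can extract stereochemical features — substituent
bulk, halogen placement, overall shape — directly from rendered pixels,
and that showing the same molecule from many viewpoints both augments the
training set and exposes geometry a single projection hides.

The pipeline is one sequential unit:

1. **Assay preparation.** Raw reporter-gene well readings are normalized to
   percent activity, `100 * (Vcompound - Vdmso) / (Vpos - Vdmso)`, where
   the controls are the median DMSO-only and positive-control wells.
   Scores fall in three bands — exactly 0 (inactive), above 0 and below 40
   (inconclusive), 40–100 (active) — and the binary label is
   `score >= 40`. Duplicate structures are collapsed by canonical isomeric
   SMILES. Molecules are partitioned into train/validation/test splits by
   largest-remainder apportionment of integer ratios (1:1:1, 3:1:2, 4:2:3,
   5:1:3, 5:3:4, 7:1:4 are the ratios the method was characterized with),
   optionally after carving out a permanently fixed foldout set.
2. **Conformer embedding.** One explicit-hydrogen 3D conformer per
   molecule via seeded distance geometry (ETKDG) followed by MMFF94
   minimization (UFF fallback), exchanged as SDF V2000.
3. **Snapshot rendering.** For per-axis angle increments
   `(θx, θy, θz)` the viewpoint grid is `{k·θ : k ≥ 0, k·θ < 360}` per
   axis, so the image count is `∏ ceiling(360/θ)`; e.g. 195° gives 2
   angles per axis and 8 images, 176° gives 3 and 27, 95° gives 4 and 64.
   Each viewpoint is rasterized deterministically at 256×256 RGB with a
   configurable background color.
4. **Learning.** A small CNN is trained with Adam on 2-class
   cross-entropy for at most 30 epochs; the checkpoint with the minimum
   validation loss is kept (early stopping). Per-image probabilities are
   pooled per molecule, a Youden-index cutoff fixes the confusion table,
   and the full metric suite is reported: sensitivity, specificity,
   balanced accuracy `(sens + spec)/2`, accuracy, precision, F-measure,
   Matthews correlation coefficient, ROC AUC, PR AUC and the losses.
   Metrics are averaged over `N = 3` seeded replicate runs.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `theta` | (195, 195, 195) | degrees | 8 snapshots/molecule; the characterization sweeps span (95°…350°), i.e. 64 down to 8 images |
| `image_size` | 256 | px | the native snapshot resolution of the method |
| `background` | white | — | named palette entries carry the exact published RGB triples (e.g. aquamarine 0.5,1,1; tv_orange 1,0.55,0.15) |
| `learning_rate` | 1e-3 | — | within the characterized 1e-5…4e-3 band; suits Adam on the small desk CNN |
| `batch_size` | 16 | images | inside the characterized 2–70 band |
| `max_epochs` | 30 | epochs | the early-stopping budget; the minimum-validation-loss epoch is selected |
| `replicate_count` | 3 | runs | replicate averaging to reduce seed variance |
| `input_size` | 32 | px | snapshots are area-averaged down before entering the desk-scale CNN (see below) |
| `foldout_fraction` | 0 | — | size of the permanently fixed external set; a free parameter (its construction is not specified upstream) |

## Numerical and design choices

**MCC denominator.** The printed definition of the normalizer `k` omits
the radical; without the square root MCC escapes [−1, 1], so the standard
Matthews definition with `sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` is used.
Any 0/0 rate is reported as 0 and flagged `degenerate` rather than NaN.

**ROC AUC.** Computed by the Mann–Whitney formulation (ties count ½),
identical to the trapezoidal area under the empirical ROC. The Youden
cutoff maximizes `J = sensitivity + specificity − 1` over midpoints
between consecutive sorted unique probabilities plus sentinels, ties
broken toward the smallest cutoff; prediction at the cutoff itself is
positive (`>=`). PR AUC uses the average-precision (right-continuous
precision) convention. Single-class evaluation sets return ROC AUC 0.5
and PR AUC equal to prevalence, flagged — mirroring how an uninformative
model on a maximally imbalanced assay is reported upstream.

**Angle grid at exact divisors.** The published angle/count pairs never
include a θ that divides 360 exactly, so both `ceiling(360/θ)` and
`floor(360/θ)+1` fit them. The half-open grid `k·θ < 360` was chosen
because a 360° rotation duplicates the identity view; at θ = 120° this
yields 3 angles per axis, not 4.

**Rotation and projection.** Rotations compose as `Rz·Ry·Rx` about the
atom centroid (the composition order is not specified upstream; it is
fixed and documented here). Projection is orthographic with z-buffer
occlusion; atoms are Lambert-shaded spheres with CPK-like element colors,
bonds are half-sticks colored by their end atoms. Pixel determinism is
contracted at the 8-bit quantized array level — identical inputs give
identical pixel arrays, and the array written equals the array read back —
rather than byte-identical PNG streams across encoder versions.

**Split apportionment.** Largest-remainder (Hamilton) apportionment, ties
in fractional remainders broken in split order (train, valid, test).
Stratification on the binary label is on by default: the real screens are
highly imbalanced (≈5 % actives on average) and plain random splits at
small n would not hold per-split prevalence near the global value. The
global split sizes are apportioned first; active counts are apportioned
by the same rule and inactive counts make up the difference, so split
sizes are exact and per-split prevalence is within rounding of global.
The foldout set is governed by its own seed, deliberately independent of
the train/valid/test seed, so re-seeding the inner split can never move a
molecule across the foldout boundary.

**Duplicate policy.** When two records share a canonical SMILES the
maximum activity score is kept (conservative toward activity); the
upstream description only says duplicates were eliminated.

**Raw-score clamping.** Percent activity computed from wells may fall
outside [0,100]; it is clamped for classification and the unclamped value
kept in `raw_score` for provenance.

**Image→molecule pooling.** How 8–64 snapshot probabilities become one
molecule decision is unspecified upstream; the default is the arithmetic
mean, switchable to median or max.

**Cutoff policy.** Whether the Youden cutoff is chosen on the evaluated
split or transferred from validation is likewise unspecified; both are
supported (`cutoff_policy = "self"` default, or `"valid"`).

**The classifier.** No deep-learning framework exists in this R stack, so
the network is implemented natively: 3×3 convolutions via im2col and BLAS
matrix products, 2×2 max-pooling with deterministic first-maximum tie
routing, a dense softmax head, Adam, and seeded weight initialization and
batch order. The default `small_cnn` has three conv blocks (8/16/32
channels); `googlenet_like` is a wider four-block stand-in for the
original large architecture, not a replica — the method's value lies in
the pipeline, not the weights. Inputs are area-averaged to
`input_size = 32` px and centered at zero; at desk scale this retains the
marker chemistry (a halogenated substituent several pixels wide) while
keeping a full 60-molecule, 480-image training run in minutes on one CPU.

## What the synthetic generator emulates — and what it does not

`generate_toy_assay()` emits CSV-shaped assays (SMILES + 0–100 scores)
from a template grammar of alkyl chains, phenyl and cyclohexyl scaffolds.
Exactly `round(n · prevalence)` records are active, and every active
carries a dibromoaryl substituent: two heavy bromine spheres that are
geometrically salient in the rendered image, so the learnable signal
lives in the pixel channel — the same channel the snapshot method claims
to exploit — not in trivial file metadata. The default prevalence is
0.25, chosen a priori for desk-scale statistical sanity: at n = 60 with
1:1:1 splits, the real screens' ≈5 % imbalance would leave about one
active per split and make split-level ROC/BAC ill-defined. Setting
`prevalence = 0.05` reproduces the imbalanced regime.

The generator does **not** emulate realistic chemistry-space coverage,
activity cliffs, assay noise, or the scale of a 10K screening library.
Consequently a green end-to-end test establishes that the pipeline is
wired correctly and that the network can learn a geometry-visible
structural signal from rendered snapshots and beat its label-permuted
null control — it does not establish the predictive performance reported
for the real nuclear-receptor assays, which would require the external
screening data and GPU-scale training and are out of scope here.

## Known limitations

- SMILES parsing and 3D embedding are delegated to RDKit through the
  system Python; without an RDKit-capable `python` on the PATH the
  conformer stage (and anything downstream of it) is unavailable.
- The renderer is a deterministic rasterizer, not a PyMOL replica:
  lighting, sphere/stick proportions and anti-aliasing differ from the
  original imagery; only determinism, centering, palette semantics and
  the background contract are promised.
- Bond order is recorded but drawn as a single stick.
- Training is single-threaded CPU R; it is sized for desk-scale
  experiments (tens of molecules, thousands of images), not for 10K
  compound screens.
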