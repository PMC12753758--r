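---
title: "Similarity-guided swarm-of-models semi-supervised segmentation: methods and design"
author: "SwarmSeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SwarmSeg methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SwarmSeg)
```

## The problem and the method

Pixel-precise annotation of whole-slide histology images (WSIs) is so
laborious that most segmentation projects have a handful of annotated
slides and a large pool of unannotated ones. Pseudo-label-based
semi-supervised learning (SSL) expands the training set by letting a
model trained on the annotated slides label the rest — but a single
pooled model generalizes poorly to tumor morphologies it has barely
seen, and pseudo-label quality is the bottleneck.

SwarmSeg implements a similarity-guided *swarm of models* (S-o-M)
alternative. Every annotated case trains its own segmentation model, a
"morphology expert" specialized in that case's tumor appearance. For
each unlabeled slide the framework measures slide-level similarity to
every annotated case and lets the most similar expert generate the
pseudo-labels for the two hardest classes, tumor and tumor stroma; a
pooled supervised model supplies the remaining classes, which vary
little across cases. The final model then trains on the union of
labeled and pseudo-labeled patches.

Slide similarity is computed from tumor morphology alone:

1. Tessellate the tumor region into patches (224 px at the 10x working
   magnification, configurable). On annotated slides patches are chosen
   by the ground-truth mask; on unlabeled slides by a dedicated 3-class
   tumor / non-tumor / background locator model. Only patches with
   **strictly more than 60 %** tumor content are kept.
2. Embed each retained patch with a feature encoder (the adapter
   contract accepts any foundation encoder; a deterministic
   histogram/gradient encoder ships with the package).
3. Summarize each slide by the k = 5 embeddings closest to the K-means
   centroids of its patch embeddings (each representative is an exact
   member of the patch set).
4. Score a slide pair by the mean of all 5 x 5 = 25 pairwise cosine
   similarities between their representative sets. Negated L1/L2
   distances are available as alternate metrics; "most similar" is
   always arg-max.

Pseudo-label fusion is deliberately simple: per pixel, if the matched
expert predicts tumor or tumor stroma, its code wins; otherwise the
supervised model's code is taken. No confidence threshold is applied to
any prediction, so method comparisons are not confounded by threshold
choices. Externally supplied artifact masks blank pixels to the ignore
code, which carries no loss and no score.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `tumorContentThreshold` | 0.60 | strict lower bound on patch tumor fraction; trades tumor purity against patch count |
| `kRepresentatives` | 5 | K-means clusters / exemplars per slide; 25 comparisons per slide pair |
| `metric` | cosine | slide similarity metric; distances are negated |
| `patchSize` / overlap | 512 / 128 px | training tiles; annotated slides overlap, unlabeled do not |
| `similarityPatchSize` | 224 px | tessellation for the similarity stage and locator |
| `epochs` | 36 | no early stopping; best-validation checkpoint is kept |
| `lrStepSize`, `lrGamma` | 10, 0.1 | step-decay learning-rate schedule |
| `valFraction` | 0.10 | per-case 90/10 train/validation split |
| target `mpp` | 1.0 | 10x working magnification (40x scans at about 0.25 um/px are downscaled 4x) |

Class weights for the cross-entropy objective are inverse-frequency,
`w_i = N / (K n_i)` over the K observed classes — the conventional
normalization that gives weight 1 everywhere under a uniform histogram.
The weighting formula, the checkpoint-selection metric (mean foreground
Dice), and the step-decay factor 0.1 are this package's choices where
the training convention leaves them open.

## Design decisions in the open points

**Tumor definition for patch harvesting.** The locator maps only the
tumor class itself to "tumor"; tumor stroma counts as non-tumor
(`includeStroma = TRUE` reverses this). The pipeline applies the same
strict definition on the annotated side so both sides of the similarity
matrix are computed over comparable patch populations. Fusion and
evaluation always treat tumor and tumor stroma together as the
expert-precedence set.

**K-means determinism and ties.** Representative selection uses
k-means++ seeding with 10 restarts under a fixed seed and keeps the
restart with the lowest within-cluster SSE (Hartigan-Wong iterations,
which escape the local optima plain Lloyd steps can stall in). With
fewer than k distinct vectors, `k_eff = min(k, #distinct)` collapses
the clustering instead of erroring — slides with almost no tumor
produce fewer representatives and a log-visible degradation rather
than a hard failure. Centroid-distance ties resolve to the lowest row
index; expert-matching ties resolve to the lexicographically smallest
annotated slide id. Exact SSE ties between different optimal
partitions are genuinely ambiguous; any optimal partition is accepted.

**Fusion edge case.** The per-pixel rule takes the supervised code
verbatim wherever the expert predicts non-tumor. The supervised
channel's role is to supply the non-tumor classes; if it is allowed to
emit tumor codes they pass through at those pixels. The per-pixel
formulation is equivalent to patch-boundary precedence on no-overlap
tilings and well defined everywhere else.

**Mean-similarity and metric ordering.** The full |a| x |b| grid is
averaged (duplicate representatives count as often as they appear).
Cosine similarity is scale-invariant, so embeddings are not normalized
at encoding time. Per comparison pair, cosine is monotone in negated
L2 distance on the unit sphere, so single-representative matching is
metric-invariant for normalized embeddings; averaging 25 pairs is a
nonlinear aggregation, so the equivalence is not guaranteed for full
sets.

**Paired testing.** The paired t-test compares per-unit combined
tumor + tumor-stroma Dice between two paradigms over the same
evaluation units. Undefined Dice values (class absent from both
prediction and reference) are skipped, never imputed — imputing 1.0
would inflate rare-class means.

## Toy backends and what the tests show

The segmentation backend is pluggable. Two deterministic toy backends
ship with the package so that every pipeline property is testable
without GPU training or downloaded weights:

* `proto` — a nearest-prototype colour classifier. Per class, the
  prototypes are K-means centroids of that class's training pixels in
  RGB space; prediction assigns each pixel its nearest prototype's
  class. The number of prototypes per class is the model-capacity
  knob. The fit is closed form, so the backend converges after one
  epoch.
* `mlp` — a tiny single-hidden-layer pixel classifier (logistic hidden
  units, softmax output, class-weighted examples) trained iteratively,
  exercising the per-epoch validation / best-checkpoint contract for
  real.

A full encoder-decoder network is a backend configuration, not a test
dependency; `registerBackend()` accepts any implementation of the
init / fitEpoch / predictPixels contract.

## The synthetic cohort generator

`generateCohort()` renders seeded slide cohorts in which every pipeline
stage has controlled ground truth. Each slide has a background border,
a benign-mucosa strip, a smooth-muscle strip and a tumor core wrapped
in tumor stroma; the tumor core covers well over a quarter of the
tissue, so the 60 % filter always retains patches. Inter-case tumor
heterogeneity is emulated by per-case *styles*: a tumor base colour
plus an oriented sinusoidal texture and colour jitter. The default
four styles are separated by at least 64 intensity units pairwise, so
the built-in encoder separates them cleanly (within-style cosine
similarity about 0.96, cross-style about 0.44 on the default cohort).

Two generator switches exercise failure modes:

* `mixedStyleSlides` blends two styles half-and-half in one tumor
  core, producing the mid-range similarity scores where expert
  assignment is least reliable.
* `confusable` moves the smooth-muscle colour to 50 intensity units
  from the third style's tumor colour, displaced orthogonally to the
  gray axis so the stripe texture cannot re-separate them. A pooled
  single-prototype model places its tumor prototype at the centroid of
  all four styles and therefore hands that style's tumor pixels to the
  smooth-muscle class; the per-case expert, whose tumor prototype sits
  on the style itself, is unaffected. This reproduces, in a fully
  controlled setting, the regime where pooled pseudo-labeling breaks
  down but expert-matched pseudo-labeling does not — and because the
  mislabeling flows into the final model's training set, the
  traditional-SSL final model loses tumor Dice that the S-o-M final
  model keeps.

In the paradigm-comparison experiments the pseudo-labeling models
(supervised, experts, locator) use one prototype per class — one case,
one morphology — while both paradigms' final models use four,
reflecting that the consolidation model must absorb cohort-wide
heterogeneity. The two compared paradigms use identical architectures
at every stage, so the comparison isolates the pseudo-label source.

What the synthetic cohorts do *not* emulate: staining variation,
scanner differences, nuclear texture, spatially correlated noise, or
ambiguous class boundaries. Passing tests demonstrate that the
similarity engine, matching, fusion and evaluation machinery behave as
specified and that the expert-matching advantage materializes when
morphology is case-specific; they do not certify segmentation accuracy
on real tissue.

## Problem sizes and numerical choices

The shipped experiments use 192-px slides (sized so every slide's tumor
core holds comfortably more than k = 5 patches above the 60 % filter at
the toy tessellation), 32-px training patches
(8-px overlap on annotated slides), 32-px similarity patches, four
styles, cohorts of 4 annotated + 16-20 unlabeled slides, 8 held-out
slides and 3 replicate seeds — sizes chosen so the whole suite runs on
one CPU core in minutes while every pipeline stage still operates on
genuinely multi-patch, multi-slide inputs. All randomness flows from
explicit seeds (cohort seed, k-means seed, split seed, per-slide
derived seeds), never from wall-clock state; reruns are bit-identical
with the deterministic backend. K-means uses restart tolerance 1e-6;
Dice and similarity computations are exact arithmetic on integer pixel
sets.

## Limitations

* The built-in encoder is a colour/gradient histogram: sufficient to
  separate synthetic styles, far too weak for real histology, where a
  foundation encoder should be plugged in through
  `externalEncoderAdapter()`.
* One pseudo-label pass only; no self-training iterations.
* Pseudo-labeled and labeled patches are weighted equally in the final
  training set.
* The artifact mask is an input; no artifact detection is performed.
* Proprietary pyramidal WSI containers are out of scope; slides enter
  as raster images with resolution metadata.
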