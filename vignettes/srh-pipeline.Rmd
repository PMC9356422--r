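---
title: "Whole-slide tumor detection on stimulated Raman histology: model, pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide tumor detection on stimulated Raman histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Stimulated Raman histology (SRH) produces digital H&E-like images of fresh,
unprocessed tissue within minutes, directly in the operating room. Two
grayscale acquisitions are made at Raman shifts 2845 cm⁻¹ (CH₂, lipids) and
2940 cm⁻¹ (CH₃, proteins and nucleic acids); their difference carries the
nuclear signal that hematoxylin would stain, and the lipid channel plays the
role of eosin. The intraoperative question this package addresses is
*qualitative*: does a slide show tumor, non-tumor tissue, or is the
acquisition of too low quality to call — independent of entity or grade.

`SRHdetect` implements the complete semi-automated pipeline: virtual-slide
formation, patch-based classification by a residual CNN into
tumor / non-tumor / low-quality, whole-slide probability aggregation with
low-quality exclusion, color-coded probability heatmaps, and the full
multi-rater reliability analysis (ICC, Cohen's κ, Cronbach's α, ROC-AUC,
Kendall's W). Because clinical SRH data are not freely redistributable, the
package ships a synthetic SRH simulator so that every stage is testable end
to end without a microscope.

## Virtual H&E formation

A slide is the pair $(I_{2845}, I_{2940})$ of channel intensities in
$[0,1]$. The nuclear signal is the clipped subtraction
$N = \max(I_{2940} - I_{2845},\, 0)$ and the lipid signal $L = I_{2845}$.
The rendered image is the linear virtual-H&E map

$$\mathrm{rgb} = 1 - g_h\, N\, \mathbf{h} - g_e\, L\, \mathbf{e},$$

clipped to $[0,1]$, with hematoxylin/eosin color vectors
$\mathbf{h} = (0.65, 0.70, 0.29)$ and $\mathbf{e} = (0.07, 0.99, 0.11)$
(the standard stain-separation directions of digital pathology) and unit
gains by default. Vendor color pipelines are proprietary and unspecified;
this is the simplest map consistent with "digital H&E-like": linear,
monotone (more stain, darker pixel) and invertible up to clipping. Negative
subtraction values are clipped at zero because the protein signal is an
intensity. Internally everything is float in $[0,1]$; 8-bit (PNG) and
16-bit (TIFF channel pairs) apply only at file boundaries.

## Patch geometry

Classification operates on 300 × 300 px windows. Training uses a sliding
window with step 100 px in both directions (overlapping patches);
whole-slide inference uses step 300 px, so windows are pairwise disjoint and
tile the slide. Window counts per axis follow
$\lfloor (\text{size} - 300)/\text{step} \rfloor + 1$; right/bottom
remainders smaller than one window are discarded, matching the exact
3600/300 and 3900/300 divisions of the clinical full-frame geometry
(a 12 × 13 test grid). Patches inherit the slide-level annotation — whole
images are what raters annotate; per-patch ground truth exists only
synthetically via the region mask and is used for diagnostics.

Class imbalance is handled by inverse-class-frequency weights on the
categorical cross-entropy, $w_c \propto N/n_c$, normalized to mean 1 so the
loss scale is comparable to the unweighted case.

The train/validation split (90/10) is at slide level, stratified by class:
patches of one slide overlap heavily at step 100, so a patch-level split
would leak near-duplicates into validation.

## The classifier

The model family is a pre-activation residual network: each block applies
BN → ReLU → conv (3 × 3) twice and adds an identity shortcut, with a 1 × 1
projection where shape changes; the head is BN → ReLU → global average
pooling → dense → softmax over the three classes. Training is minibatch
RMSProp (a momentum-free adaptive optimizer) on the weighted cross-entropy.
Optimizer, learning rate (10⁻³) and batch size (64) are defaults chosen
here, not reported values.

Training stops at the first epoch where validation accuracy exceeds 95%
**and** validation loss is below 0.10 — a conjunction; a safety cap
(`max_epochs`) exists because the criterion need never trigger on hard
data. "Loss" is read as the weighted validation loss, the single loss the
network optimizes. Validation accuracy is patch-weighted (each validation
patch counts once); a class-balanced alternative is not used because the
stopping rule is a convergence gate, not an evaluation metric. For the
reliability analysis the network is retrained from three distinct seeds on
identical data; all stochastic elements (initialization, shuffling) derive
from the seed, so every trained model is bit-reproducible.

**Desk profile.** The package's default profile is sized for a single CPU:
patches are mean-pooled 300 → 25 px (an exact 12 × 12 block average) and the
network has two stages of widths (8, 16), one basic block each — roughly ten
weight layers. The synthetic classes are separable from color and texture
statistics at this resolution, so the stopping criterion is reachable in
minutes; with three training seeds, a 60-slide cohort and the full
statistics suite, the default experiment completes in about 3–4 minutes.
A bottleneck block type, configurable stem and per-stage block counts allow
the full-scale topology (stage widths 256/512/1024/2048, blocks 3/4/6/3,
300 px inputs) to be constructed; the original stem pooling is folded into
a strided stem convolution. Training at full clinical scale (hundreds of
slides, ~10⁶ patches) is out of scope.

The network itself is implemented in R: convolutions are evaluated as
im2col + GEMM so the arithmetic runs in BLAS, and every layer has an
explicit, tested backward pass. This keeps the package free of external
deep-learning runtimes and makes training bit-reproducible from seeds.

## Whole-slide aggregation

Each test patch yields a probability triple. Patches whose top-1 class is
low-quality are excluded; the remaining triples are averaged and
renormalized to the simplex ("renormalized summation" — reconciling
"averaged" and "after summing" descriptions of the same operation). If
*every* patch is excluded, the slide is reported as
$P = (0, 0, 1)$, final class low-quality — mirroring the clinical workflow,
where a fully low-quality area triggers a re-scan of another specimen area
rather than an error.

Binarization takes the argmax of $P$. Ties break by the fixed priority
tumor > non-tumor > low-quality: the clinically conservative direction
(favoring a tumor flag) where the operation is otherwise underdetermined.

## Probability heatmaps

Each class channel of the patch grid is interpolated independently to full
resolution and the three channels are renormalized pixel-wise. The
interpolation kernel is unspecified in the clinical description; bilinear
is the default (nearest-neighbor is available as a config alternative).
Patch values are anchored at the integer patch-center pixel
$(i-1)\,\text{step} + \lfloor \text{window}/2 \rfloor$ (0-based) and edges
are extended by clamping, so patch-center pixels reproduce their grid
values exactly and the center of a 2 × 2 grid cell is the exact mean of its
four anchors — both are tested closed forms. The overlay is the linear
blend $(1-\alpha)\,\text{image} + \alpha\,\text{heatmap}$ with
red = tumor, green = non-tumor, blue = low-quality.

`heatmapRegionAccuracy()` scores a heatmap against a synthetic region mask,
excluding pixels within half a patch (150 px Euclidean) of a region
boundary: inside that band the interpolation necessarily blends classes and
no hard assignment is meaningful.

## The synthetic simulator

The simulator emulates what the classifier actually exploits — cellular and
nuclear morphology — not Raman physics:

* **Tumor**: hypercellular fields of pleomorphic nuclei. Nuclei are
  dark-center ellipses with elevated protein-channel rims (a minimal
  chromatin model); size pleomorphism is log-normal.
* **Non-tumor**: sparse nuclei (about a tenth of the tumor density) over
  oriented low-frequency fiber texture in the lipid channel, with a higher
  lipid baseline (white matter is lipid-rich).
* **Low-quality**: two sub-modes sampled 50/50 — an acellular, near-blank
  field, and a structureless noise/artifact field.

Densities are expressed per 300 × 300 px patch area; pixels are treated as
unitless because the published physical patch size (µm) and the pixel
geometry cannot be reconciled exactly. Defaults: tumor ≈ 150 nuclei per
patch area, radius 6 px; non-tumor ≈ 15; backgrounds
(lipid, protein) = (0.15, 0.30) for tumor, (0.35, 0.25) for non-tumor;
additive Gaussian noise σ = 0.02. Easy mode jitters these narrowly per
specimen (8% log-jitter on densities); hard mode widens the distributions
and pulls the class means together until pixel statistics overlap.

Cohorts follow the clinical structure: each specimen is scanned as three
random areas (A, B, C) sharing a single texture-parameter draw and
differing only in rendering seeds — the structure behind the Cronbach's-α
internal-consistency analysis. Specimen labels follow the clinical
ground-truth prior (78% tumor, 19% non-tumor, 3% low-quality) by
largest-remainder allocation with a floor of one specimen per
nonzero-prior class; the floor keeps every class represented in small
cohorts (the clinical cohort contains all three), which a plain multinomial
draw would fail to do about half the time at 20 specimens with a 3% class.
The default evaluation cohort is 20 specimens × 3 areas = 60 slides of
1200 × 1200 px (a 4 × 4 test grid); the training set is a separate,
class-balanced 18 slides of 600 × 600 px, i.e. 288 training patches — sizes
chosen so a full run stays in the minutes range on one CPU.

**What passing tests do and do not show.** The simulator's easy mode is
linearly separable from per-slide channel statistics by construction (a
tested invariant); the end-to-end thresholds (accuracy ≥ 95%, ICC ≥ 0.90,
AUC ≥ 0.95, α ≥ 0.90) therefore validate the *pipeline machinery* — that
training converges under the stated stopping rule, that aggregation,
exclusion and the statistics are wired correctly — as qualitative analogs
of the clinical results, not as evidence about real tissue. Real SRH images
carry entity-specific histomorphology, acquisition striping, and
out-of-focus gradients that the simulator does not model.

## The reliability suite

All statistics operate on complete subjects × raters tables.

* **ICC**: two-way model, absolute agreement, single measure,
  $\mathrm{ICC} = (MS_R - MS_E)\,/\,(MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E))$.
  The mixed-effects label shares this point estimate with the two-way
  random model; the distinction affects interpretation, not arithmetic.
  Mean squares come from `stats::aov`; the test suite recomputes them by
  direct sums-of-squares arithmetic as an independent oracle. Confidence
  limits use the F-distribution method with Satterthwaite degrees of
  freedom (the SPSS convention; verified externally against an independent
  implementation), default level 99%.
* **Cohen's κ** from the 3 × 3 confusion table; the degenerate case
  $p_e = 1$ (both raters constant and identical) is defined as 1 and
  flagged.
* **Cronbach's α** across the three areas of each specimen, with sample
  variances.
* **ROC-AUC** per class, one-vs-rest, scored by the slide's aggregated
  class probability (the only continuous per-class score the pipeline
  produces); computed by the Mann–Whitney identity with midranks, interval
  by Hanley–McNeil, deliberately *not* truncated at 1 — clinical packages
  print such limits (e.g. upper bounds above 1) and truncation would
  misrepresent the method.
* **Kendall's W** with tie correction and the χ² approximation on
  $n-1$ degrees of freedom, flagged as unreliable for $n < 3$.

Percentages in agreement reports are computed exactly and rendered
half-up at one decimal. The published clinical counts are built in
(`publishedAgreementCheck()`) and their percentages recomputed; one
published cell (model 3, tumor: printed 95.0% for 305/326 = 93.6%) is
internally inconsistent and is flagged rather than imitated. The published
overall agreement of model 1 (86.5% for 348/402 = 86.57%) likewise differs
from its counts by one final-digit rounding; comparisons are therefore made
at the printed one-decimal precision.

## Numerical choices and degenerate inputs

* Probabilities are clamped at $10^{-12}$ inside the loss; it is never
  infinite.
* Zero-variance ratings tables: ICC returns 1 with a `degenerate` flag
  (perfect but uninformative agreement); α returns `NA` flagged.
* Batch normalization uses running moments (momentum 0.9) at evaluation,
  so batched and single-patch inference agree exactly.
* Divergent training (non-finite loss) aborts at the last finite state and
  is flagged, never silently retried.
* All generators and training loops restore the caller's RNG state; every
  random quantity derives from an explicit seed argument.

## Reproducing the desk-scale experiment

```{r}
library(SRHdetect)
cfg <- experimentConfig(out_dir = "srh-run")
exp <- runExperiment(cfg)
print(exp)
```

`scripts/acceptance.R` (repository root) wraps exactly this: it recomputes
the published-count agreement arithmetic and runs the seeded desk-scale
experiment, writing all headline numbers to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Known limitations

* The simulator does not model Raman physics, scanner striping, stitching
  seams, or entity-specific morphology; hard mode approximates difficulty
  only through parameter overlap.
* The full-scale topology is constructible and runs forward/backward, but
  training it at clinical scale is far outside a CPU budget and untested.
* The ICC is reported under the two-way random-effects computation that the
  mixed-effects label shares; rater-population inference is not attempted.
* Agreement statistics assume a single reference rater, as in the clinical
  design; multi-reference adjudication is out of scope.
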