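# SRHdetect

Qualitative intraoperative tumor detection on stimulated Raman histology
(SRH) virtual slides: an R implementation of the full semi-automated
pipeline — virtual H&E formation, patch-based residual-CNN classification
into **tumor / non-tumor / low-quality**, whole-slide probability
aggregation with low-quality exclusion, RGB probability heatmaps, and the
complete inter-rater reliability analysis — plus a seeded synthetic SRH
simulator so everything is testable without a microscope.

## Who it is for

Computational pathology and neurosurgical imaging groups who want a
transparent, dependency-light reference implementation of the
SRH tumor-detection workflow: every stage is a documented, tested function,
and the statistics that validate it (ICC, Cohen's κ, Cronbach's α, ROC-AUC,
Kendall's W) are implemented from first principles with independent test
oracles.

## The method in brief

An SRH slide is acquired at two Raman shifts, 2845 cm⁻¹ (CH₂/lipid, *L*)
and 2940 cm⁻¹ (CH₃/protein, giving the nuclear signal
*N* = max(*I*₂₉₄₀ − *I*₂₈₄₅, 0)). The virtual H&E image is the linear map
`rgb = 1 − N·h − L·e` with standard hematoxylin/eosin color vectors.
Whole slides are cut into 300 × 300 px patches (step 100 px for training,
step 300 px — disjoint tiles — for testing; a 3600 × 3900 px slide gives a
12 × 13 grid). A pre-activation residual CNN with class-weighted categorical
cross-entropy (weights ∝ inverse class frequencies) classifies each patch;
training stops when validation accuracy exceeds 95% **and** validation loss
drops below 0.10, and is repeated from three random seeds for the
reliability analysis. For a whole slide, patches whose top-1 class is
low-quality are excluded and the remaining probability triples are averaged
and renormalized; the argmax (tie priority tumor > non-tumor > low-quality)
is the final call. Patch-grid probabilities are bilinearly interpolated into
per-pixel heatmaps, overlaid red = tumor, green = non-tumor,
blue = low-quality.

## Worked example

The default desk-scale experiment simulates a 60-slide cohort
(20 specimens × 3 scan areas, class prior 78/19/3%), trains three CNN seeds
on a separate balanced training set, classifies every slide with each
model, and computes the reliability report:

```r
library(SRHdetect)
exp <- runExperiment(experimentConfig(out_dir = "srh-run"))
print(exp)
#> SRH desk-scale experiment (config af42465f)
#>   models stopped by criterion: TRUE
#>   slide accuracy: 1.000 / 1.000 / 1.000
#>   ICC (tumor / non-tumor / low quality): 0.991 / 0.996 / 0.990
#>   Cronbach alpha across areas (cnn1): 1.000
```

All three models reached the stopping rule (here in 8–10 epochs); every
slide was classified correctly by all three seeds; the three-model
intraclass correlation of the per-slide class probabilities is ≥ 0.99 for
each output class; and the predictions of the three scan areas of each
specimen are internally consistent (α ≈ 1.0). These are the desk-scale
analogs of the clinical validation quantities: on easy synthetic data they
certify the machinery, not tissue-level performance.

Single-slide use:

```r
slide <- generateSlide("tumor", width_px = 1200, height_px = 1200, seed = 1)
img   <- buildSRH(slide)
res   <- classifySlide(exp$models[[1]], img)
res$prediction
#> SlidePrediction: tumor  [P = 0.877 / 0.053 / 0.070; 0/16 low-quality patches excluded]
hm <- probabilityHeatmap(res$patches, dim(srhRGB(img))[1:2], res$grid)
writeSlide(overlayHeatmap(img, hm, alpha = 0.5), "overlay.png")
```

A thin command-line front end is installed with the package
(`inst/scripts/srh-detect.R`) with subcommands `simulate`, `train`,
`classify`, `validate`, `run` and `agreement-check`.

## Package layout

| Area | Functions |
| --- | --- |
| Simulator | `generateSlide`, `generateMixedSlide`, `generateCohort`, `writeCohort` |
| Image core | `ramanPair`, `buildSRH`, `readSlide`, `writeSlide`, `readChannelPair` |
| Patching | `patchGrid`, `extractPatches`, `patchTensor`, `classWeights`, `splitTrainVal` |
| CNN | `modelConfig`, `buildModel`, `trainCNN`, `retrainEnsemble`, `predictPatch(es)`, `weightedCrossEntropy`, `stopCriterion` |
| Slide inference | `classifySlide`, `aggregateSlide`, `binarizeSlide`, `probabilityHeatmap`, `overlayHeatmap`, `heatmapRegionAccuracy` |
| Reliability | `iccSingleAbsolute`, `cohensKappa`, `cronbachAlpha`, `rocAuc`, `kendallsW`, `agreementReport` |
| Orchestration | `experimentConfig`, `runExperiment`, `publishedAgreementCheck` |

See the vignette (`vignettes/srh-pipeline.Rmd`) for the full account of the
model, the simulator's assumptions, numerical choices and limitations.
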