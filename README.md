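# asploss

Adaptive Sample-level Prioritizing (ASP) losses for binary mass segmentation
in mammography, as a tested, reusable R library.

## Why

Masses occupy anywhere from under 1% to about a third of a whole-view
mammogram, so the severity of pixel class imbalance varies wildly between
samples, and a hybrid loss with *static* term weights treats a tiny and a
huge mass identically. The ASP family instead sets the weights of the hybrid
per sample, from metadata every mammography exam already carries:

- **R-ASP** (ratio-driven): with mass ratio group `p ∈ {0, 1}` (small/large),

  `L = (I_Dice + (1 − p)^γ_d) · L_Dice + (I_BCE + p^γ_b) · L_BCE`

  Dice is prioritized for small masses (it ignores true negatives, so it
  survives extreme imbalance), BCE for large ones. The group divider is
  fitted on the training ratios: median (**QR-ASP**), mean (**VR-ASP**) or
  exact 1-D 2-means centers (**CR-ASP**); **LR-ASP** learns the two weights
  with a small subnetwork reading the ground-truth mask.
- **D-ASP** (density-driven): `L = d·θᵀ · (η·L_RMI + τ·L_SSIM) + (α·L_Dice +
  β·L_BCE)` where `d` one-hot encodes the ACR density category (1–4) and
  `θ` is a prioritizing vector — region-level structure (structural
  similarity, regional mutual information) gets more weight where denser
  tissue makes masses harder to tell apart from their surroundings.
- **SR-ASP / SD-ASP**: focal loss `−(1 − Ŷ_t)^υ log Ŷ_t` whose focusing
  parameter `υ` is looked up per sample from its size group or density
  category.

The package provides all constituent losses with analytic gradients, the
grouping models, segmentation metrics (DSC, relative area difference ΔA,
sensitivity, accuracy), a synthetic mammogram-phantom generator with
controlled mass ratio and density, a small encoder–decoder training harness
that exercises every loss end to end on a CPU, and a command-line interface
(`exec/asploss`) with `synth`, `fit-grouping`, `compute-loss`, `train` and
`evaluate` subcommands. See the vignette (`vignettes/asp-losses.Rmd`) for
the model details and design decisions.

## Worked example

Generate 120 phantoms, fit the cluster grouping on their mass ratios, train
the harness under the cluster-based ratio-adaptive loss and evaluate on
held-out phantoms:

```r
library(asploss)
spec <- phantomSpec(imageSize = c(64, 64), seed = 1)
ds <- generateDataset(spec, 120)
md <- syntheticMetadata(ds)

gm <- fitGrouping(md$ratio, "cluster")
gm
#> GroupingModel (strategy: cluster )
#>   centers: 0.0310250, 0.0980632
#>   fitted on: 120 ratios

fit <- trainModel(ds[1:100], trainConfig("cr_asp", epochs = 3, seed = 7),
                  groupingModel = gm, raspCfg = lossPresets("inbreast")$rasp)
trainingHistory(fit$record)
#>   epoch trainLoss valDsc
#> 1     1 1.1421153     NA
#> 2     2 1.0009072     NA
#> 3     3 0.8159315     NA

evaluateModel(fit$model, ds[101:120])
#> MetricReport (20 images, macro aggregation, threshold 0.50)
#>   DSC 66.68 | DeltaA 215.74 | Sensitivity 78.85 | Accuracy 96.90 (x100)
```

The two cluster centers are the small- and large-mass modes the loss weighs
against each other. The training loss falls epoch over epoch; after three
epochs the model already finds most mass pixels (sensitivity 78.85) with a
mean held-out DSC of 66.68, while the still-large ΔA (over-segmentation)
reflects how short this demonstration run is — the shipped tests train for 5
epochs and reach a training-set DSC above 0.7. Loss values themselves are
computed per sample: `makeLoss("d_asp")(...)`, for instance, weighs the
region term by `θ[category]`, so a category-4 sample with the INbreast-style
preset multiplies it by 0.95.

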