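---
title: "Adaptive sample-level prioritizing losses for mass segmentation"
author: "asploss maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive sample-level prioritizing losses for mass segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asploss)
```

## The problem

Whole-view mammograms are dominated by background: a mass may occupy anything
from under 1% to roughly a third of the image. A pixel-wise loss such as
binary cross-entropy (BCE) therefore sees a heavily imbalanced classification
problem whose severity varies *per image*, and a single static weighting of
loss terms cannot be right for both a tiny and a large mass. A second,
independent difficulty signal is the ACR breast-density category (1–4):
denser tissue hides masses, and pixel-independent losses lose exactly the
neighborhood structure that helps there.

The adaptive sample-level prioritizing (ASP) family addresses both by making
the *weights* of a hybrid loss a function of per-sample metadata:

- **Ratio-driven hybrid.** With $r_i$ the mass-to-image ratio and $p_i \in
  \{0,1\}$ the sample's size group (0 = small, 1 = large),
  $$L_i = \bigl(I_{Dice} + (1-p_i)^{\gamma_d}\bigr)\,L_{Dice}
        + \bigl(I_{BCE} + p_i^{\gamma_b}\bigr)\,L_{BCE},$$
  so dice — which ignores true negatives and tolerates extreme imbalance —
  is prioritized for small masses, BCE for large ones. The group comes from
  a divider fitted on the *training* ratios: the median (quantile split),
  the mean (value split), or the nearer of two exact 1-D k-means centers
  (cluster split). A learned variant replaces the rule by a small
  subnetwork that maps the ground-truth mask to the two weights.
- **Density-driven hybrid.** A region-level term (structural similarity
  plus regional mutual information) is scaled by $d_i\theta^T$, the one-hot
  density encoding dotted with a prioritizing vector $\theta$, and added to
  the pixel-level hybrid: denser categories receive larger $\theta$ entries.
- **Adaptive focal.** The focal focusing parameter $\upsilon$ in
  $-(1-\hat{Y_t})^{\upsilon}\log \hat{Y_t}$ is looked up per sample from its
  size group or density category, so easy pixels in easy samples are
  down-weighted hardest.

## Constituent losses and numerical choices

**Soft dice.** The package's default dialect follows the printed form of the
loss it implements, $1-(\sum \hat y y+\epsilon)/(\sum\hat y+\sum y+\epsilon)$,
whose numerator lacks the conventional factor 2; the `"standard"` dialect
with the $2\times$ numerator is a config switch, and the metric DSC always
uses the conventional definition. Smoothing defaults to $\epsilon = 1$.

**Reductions.** BCE and focal are means over pixels (the source sums without
stating a reduction); the mean keeps loss magnitudes comparable across image
sizes so that $\alpha,\beta,I$ weights transfer. Dice is one global quotient,
not a per-pixel mean. Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$
before logarithms, identically in BCE and focal; gradients are defined as 0
in the clamped region.

**SSIM loss.** Mean over valid window positions of $1-\mathrm{SSIM}$ with
the original SSIM convention: 11×11 Gaussian window, $\sigma = 1.5$,
$C_1=(0.01L)^2$, $C_2=(0.03L)^2$, dynamic range $L=1$ for probability masks.
A uniform window is provided because it admits a transparent per-window
loop oracle in the tests. Binary ground truth enters as real 0/1 values
without smoothing.

**RMI loss.** The ideal regional mutual information integral is intractable;
the package implements the covariance lower-bound surrogate of the cited
regional-MI method. Neighborhoods of side 3 (after 2× average pooling)
become 9-dimensional points; with $\Sigma_{Y|\hat Y} = \Sigma_Y -
\Sigma_{Y\hat Y}(\Sigma_{\hat Y}+\epsilon I)^{-1}\Sigma_{\hat Y Y}$ the loss
is the negative per-dimension Gaussian MI bound
$$L_{RMI} = \tfrac{1}{2d}\bigl[\log\det(\Sigma_{Y|\hat Y}+\epsilon I)
 - \log\det(\Sigma_Y+\epsilon I)\bigr],$$
which is 0 for independent (or constant) masks and increasingly negative as
the prediction becomes informative about the ground truth. The ridge
$\epsilon$ is relative to the mean ground-truth variance (5e-4 of it, plus a
1e-8 absolute floor), so it is well-posed on constant masks and — because it
depends on the ground truth only — gradients never flow through the
regularizer. Covariances and determinants are accumulated in double
precision; near-binary masks make the quotient ill-conditioned otherwise.

**Gradients.** Every loss has a hand-derived analytic gradient with respect
to the prediction (`gradient = TRUE`), verified against central finite
differences in the test suite; the learned-weight subnetwork additionally
exposes the Jacobian of its two outputs with respect to its parameters.

## Design choices where the design was open

- **$\gamma$ is inert for binary $p$** (since $0^\gamma = 0$, $1^\gamma = 1$):
  the formula is implemented verbatim, an explicit regression test documents
  the inertness, and `pMode = "continuous"` exposes the evident intent by
  feeding a normalized ratio (relative position between the group centers,
  or ratio over twice the threshold, clipped to $[0,1]$) where the exponents
  are active. Binary remains the default.
- **Quantile split = median split.** The quantile rule is described through
  its first quantile yet explained as a median division into two groups; the
  two-group structure of the loss forces a binary split, so the median is
  used. A ratio exactly at a quantile/value threshold goes to the small
  group; a cluster tie goes to the small center — deterministic, documented
  tie-breaks.
- **Exact 1-D 2-means.** For one dimension and two clusters the optimum is a
  split point of the sorted sample, so it is found by enumeration rather
  than Lloyd iterations; the seed argument exists only for API symmetry.
  Only $k=2$ is supported because the group indicator is binary (and the
  reference ablation selected 2 clusters over 3).
- **Learned-weight degeneracy.** Jointly minimizing the learned-weight loss
  over the subnetwork drives both weights to 0. The default therefore
  softmax-normalizes the two outputs to sum to 2 — a zeroed output layer
  yields the neutral weights (1, 1) — preserving relative prioritization
  while preventing collapse; an unnormalized softplus mode exists for
  experimentation. The subnetwork itself (4× average-pooled mask, one ReLU
  hidden layer of 8, linear 2-output head) fills in an architecture the
  source leaves unspecified.
- **Initial weights $I_{Dice}, I_{BCE}$.** The sentence pairing "0.125 and
  0.25" with the two datasets is ambiguous; both readings ship as presets
  (`lossPresets("inbreast")` applies 0.125 to both weights,
  `lossPresets("cbis")` 0.25), and nothing is guessed beyond that. Likewise
  $\alpha = 1$ vs $\alpha \in \{2, 2.5\}$ is a documented contradiction in
  the source; the presets carry the density-adaptive experimental values and
  the plain hybrid defaults to $\alpha=\beta=1$. The per-term $\gamma$
  values are only reported as the interval $[0.25, 0.35]$; the presets use
  its endpoints (0.25 dice, 0.35 BCE), flagged as a choice.
- **Metric conventions.** With an empty ground truth and empty prediction,
  DSC and sensitivity are 1 and the relative area difference 0; with an
  empty ground truth but a nonempty prediction, DSC is 0 and the other two
  are undefined and excluded from their means. Aggregation is the unweighted
  per-image mean (macro), consistent with the per-sample loss framing;
  pooled-pixel micro aggregation is available. Binarization threshold 0.5.

## The phantom generator

`generateDataset()` emulates the two properties of the real mammography
datasets that the ASP losses key on, without any download:

- the mass ratio is drawn from a truncated log-normal
  ($\mu = -3.5$, $\sigma = 0.8$, truncated to $[0.002, 0.35]$), giving a
  median near 0.03 and a long right tail — qualitatively the reported
  right-skewed violin shapes, not a calibration to the real datasets;
- the density category (mix 0.35/0.35/0.2/0.1, most samples in the lower
  categories) is realized *operationally*: higher categories get more
  correlated background texture and a smaller mass/background intensity gap
  (0.45 down to 0.22), making segmentation harder — a proxy, not a
  radiological model.

One mass per image, because the loss formulation defines a single ratio per
sample. Masses are rendered as rotated ellipses (axis ratio up to 3, capped
so the minor semi-axis stays above ~1.2 px and the mass fits the canvas)
with smooth radial harmonic boundary perturbation; axes are iteratively
rescaled until the rasterized pixel count is within 2% of the target area,
and the metadata ratio is always recomputed from the rendered mask. Phantoms
are star-shaped, hence single connected components. What passing tests on
phantoms shows is that the losses, grouping, metrics and harness are wired
correctly and optimizable; it says nothing about clinical segmentation
accuracy on real mammograms.

## The training harness

A deliberately small encoder–decoder ("unet3-16": 3 resolution levels, 16
base channels, one 3×3 convolution per stage, max pooling, nearest-neighbor
upsampling with skip concatenation, sigmoid 1×1 head) exists so every loss
can be exercised end to end on a CPU. Inputs are z-score standardized inside
the forward pass, mirroring the normalization the reference pipeline applies
to its images. Convolutions run through im2col + GEMM in compiled code, and
the backward pass is hand-derived and finite-difference-tested. Training
uses Adam — the source does not name its optimizer; Adam is the de-facto
default for this architecture family — at the reference learning rate 1e-4
and batch size 4, averaging per-sample losses (each with its own metadata)
over the batch. Grouping models are fitted on the training split only and
frozen. When a validation set is supplied, the model with the best
validation DSC is kept; a 5-fold cross-validation helper mirrors the
small-dataset protocol of the reference study.

Problem sizes used in the shipped checks: 200 phantoms of 64×64, 5 epochs —
small enough for a desk CPU, large enough that the hybrid loss reliably
segments the training set (mean DSC well above 0.6) while every registered
loss demonstrably descends. The RMI independence checks use 32×32 masks,
where the finite-sample bias of the covariance estimate (which scales with
dimension over the number of regional points) is comfortably below the 0.05
tolerance.

## Limitations

- The phantoms are not photorealistic; no calcifications, architectural
  distortion, multi-view geometry, or annotation noise.
- The harness is a stand-in at desk scale: it is not the attention U-Net
  baseline of the reference study, and benchmark numbers on the restricted
  mammography datasets are out of scope by design.
- The learned-weight subnetwork architecture and the continuous-$p$
  relaxation are this package's concretizations of under-specified parts of
  the method; both are configurable and documented above.

```{r example}
spec <- phantomSpec(imageSize = c(64, 64), seed = 1)
ds <- generateDataset(spec, 8)
ratios <- vapply(ds, function(s) s@meta@ratio, 0)
gm <- fitGrouping(ratios, "cluster")
gm
lossFn <- makeLoss("cr_asp", groupingModel = gm,
                   raspCfg = lossPresets("inbreast")$rasp)
s <- ds[[1]]
lossFn(matrix(0.5, 64, 64), s@mask, s@meta)
```
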