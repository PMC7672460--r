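---
title: "Methods: cross-modal expression prediction for imaging flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal expression prediction for imaging flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifcseq)
```

## The problem and the modelling assumption

Imaging flow cytometry (IFC) measures, for every cell, a small panel of
fluorescent surface markers plus a 32x32-pixel brightfield image. It does
not measure gene expression. Single-cell transcriptomics (SCT) measures the
full expression profile, and CITE-seq-style protocols additionally record
antibody-derived surface-protein counts (ADT) for the same markers a flow
panel would use. `ifcseq` links the two modalities through those shared
markers: if an IFC cell sits close to a group of SCT cells in marker space,
its expression profile is estimated from theirs.

Everything downstream rests on that single assumption. It holds well when
the populations of interest occupy distinct regions of marker space and
degrades for populations squeezed into a narrow band (an intermediate
progenitor between two committed lineages is the canonical hard case, and
the synthetic generator reproduces it deliberately).

The package operates in two modes that differ only in where the IFC marker
values come from:

* **standard** — the measured fluorescence intensities are used directly;
* **label-free** — the marker values are first regressed from the
  brightfield image by a convolutional network, so no staining is needed.

## SCT preprocessing

The preprocessing cascade is fixed, in this order:

1. *Species selection* (datasets with mixed-species spike-ins): a cell is
   kept when it expresses strictly more genes of the kept species than of
   the spike-in species, where "expresses" means a non-zero count. Ties
   are dropped: a cell with equally many genes of both species is most
   plausibly a cross-species doublet, and keeping it would contaminate
   both downstream populations. The spike-in species' gene rows are
   removed and the species prefix is stripped from gene names.
2. *Cell filter*: cells expressing fewer than `min_genes_per_cell` genes
   (200 in the human configuration) are discarded.
3. *Highly variable genes* (human configuration): see below.
4. *Gene filter*: genes expressed in fewer than `min_cells_per_gene`
   cells (default 20) are excluded. A gene seen in exactly the threshold
   number of cells is kept.
5. *Log transform*: `x -> ln(1 + x)`. The `+1` makes the transform total
   on counts (zero maps to zero); plain `ln` is undefined at zero, so
   every practical "natural logarithm" step on count data is `log1p`, and
   that is what the package implements — stated here prominently because
   it changes every downstream number.
6. *Gating and marker ranking*: populations are labelled by rectangular
   gates on the normalized markers, and per population the top
   `n_top_markers` (default 100) one-vs-rest differentially expressed
   genes are ranked. Gating is used only for validation and for the
   profile heat maps, never as a model input.

### The dispersion filter

The highly-variable-gene step follows the 20-bin dispersion recipe that
the classic single-cell toolchains popularised. With cells optionally
scaled to the median library size (`hvg_normalize`, default on), compute
per gene the mean `m` and dispersion `d = var / mean` of the scaled
counts; take `log(d)` and `log1p(m)`; cut the log-means into 20
equal-width bins; z-score the log-dispersions within each bin (unbiased
sd); and keep genes with `min_mean < log1p(m) < max_mean` and normalized
dispersion above `min_disp`. The defaults (0.0125, 3, -0.15) are the
published human-dataset thresholds. Bins containing a single gene (or
zero spread) cannot be z-scored; their genes are scored as
`log(d) / log(d)` = 1, matching the established convention, so lone
extreme-mean genes survive the dispersion gate and are controlled by the
mean gates instead. Whether library-size scaling preceded the published
dispersion filtering is not recorded anywhere; it is exposed as a toggle,
with scaling on as the default because dispersion estimated on unscaled
counts confounds sequencing depth with biology.

### Marker-gene ranking

The default one-vs-rest statistic is the Welch *t* on log expression —
the historical default of the toolchain function the pipeline names — with
a tie-corrected Wilcoxon rank-sum *z* available via
`de_method = "wilcoxon"`. Equal statistics break by gene id so rankings
are deterministic. Genes with zero variance in both groups score 0; zero
variance with unequal means scores infinite, which is the correct limit
(perfect separation) and sorts first.

## Co-registration and gating

Each marker is min-max normalized to [0, 1] *independently within each
modality*: the SCT ADT scale and the IFC fluorescence scale are unrelated,
and the normalization is exactly what makes them comparable. The fitted
min/max are stored on the returned table and in the run manifest so the
mapping is invertible and auditable. Normalization requires at least two
distinct values per marker; a constant marker is a configuration error,
not something to silently pass through.

Gates are axis-aligned rectangles on the normalized markers. Intervals
are half-open `[lo, hi)` with one exception: an upper bound of 1 is
closed, otherwise the top edge of marker space would be ungateable. The
boundary convention is a package decision (no convention is published);
half-openness guarantees that two gates sharing an edge never
double-assign a cell. Overlapping gates are resolved by an explicit
precedence order. Cells in no gate get the reserved label `"other"`.
Gate coordinates are configuration data, not code: the published mouse
gates follow an external reference without printed coordinates, so
coordinates must always be supplied by the user (or by
`truth_gates()` for synthetic data).

Whether the IFC marker normalization should use all exported cells or
only post-gating populations is ambiguous in the published description;
the package normalizes over all exported cells, which is the only choice
that does not make normalization depend on the gates it feeds.

## The expression model

Expression prediction is multi-output regression: one model maps the two
(or more) marker values to all targets jointly. The regressor is a random
forest with the published configuration — 50 trees, splits minimizing the
summed absolute deviation around the per-target median, `sqrt(p)`
candidate features per split, bootstrap resampling — and per-target
median leaf values, the estimator associated with the absolute-error
criterion. The forest prediction is the mean over trees, and the
per-tree predictions remain accessible because the spread of per-tree
correlations is the published uncertainty measure. The split scan uses
streaming two-heap medians, so a node costs `O(n log n)` per target per
candidate feature; with two input markers this is fast at any realistic
target count.

The human configuration appends the ADT surface-CD4 column (log1p by
default, toggleable — the published treatment of ADT targets before
regression is unstated) to the target matrix, so surface CD4 is predicted
alongside gene expression.

A multivariate ordinary-least-squares model is the baseline. On the SCT
test split the two are expected to be close — near-parity is itself a
published observation (the bottleneck is the two-marker input, not
non-linearity) and is asserted as an acceptance property.

The SCT experiment is split 70/30 into train/test by simple random
sampling; whether the published split was stratified by population is
unstated, so the default is unstratified. No validation set exists because
no hyperparameter is tuned. Out-of-range IFC markers (possible because
the modalities are normalized independently) trigger a warning but are
never clipped before prediction — trees are piecewise constant and
extrapolate safely, whereas silent clipping would hide a data problem.

## The label-free CNN

The image model is a residual network regressing the normalized marker
values from the 32x32 brightfield frame:

* stem: 3x3 convolution (1 -> w1), batch norm, ReLU, 2x2 max pool;
* stage 1: two residual blocks at width `w1` on 16x16;
* 2x2 average pool; stage 2: three blocks at `w2` on 8x8;
* 2x2 average pool; stage 3: three blocks at `w3` on 4x4;
* global average pooling and a dense sigmoid head.

A block is conv-BN-ReLU-conv-BN plus an identity skip, then ReLU; when
the width grows across a block the skip is zero-padded in channels
(parameter-free). That gives exactly 17 convolutional layers
(1 + 4 + 6 + 6), every convolution zero-padded so spatial size changes
only at pooling, and batch normalization before every activation except
the final sigmoid. The default widths (32, 64, 96) were chosen so the
trainable parameter count (712,354) lands at the published ~700,000 while
keeping the block structure; they are recorded in the model object.
Published details end there, so the remaining choices are the package's:
the final activation is a sigmoid because the outputs must lie in [0, 1];
the loss is mean squared error, the conventional regression default; the
Adam learning rate defaults to 1e-3; pixels are scaled by 1/65535 with
per-image standardization off. The forward/backward pass is implemented
in compiled code (im2col + BLAS GEMM per layer); the gradients are
verified against central finite differences in the test suite, which is
the strongest correctness check a hand-written backward pass can have.

Training follows the published protocol: Adam, batch 64, up to 50 epochs,
a random 10% validation split, best-validation-loss checkpointing, early
stopping with patience 5, and augmentation by vertical/horizontal/both
flips. Augmentation is applied on the fly per epoch rather than as a
static 4x expansion — equivalent in expectation and four times cheaper.
Whether the validation split was stratified by population is unstated;
it is simple random here.

## Evaluation statistics

* **Per-cell metrics**: Pearson, Spearman (average ranks on ties) and
  RMSE between true and predicted values across a gene subset, with the
  median over cells as the headline number. Cells whose true or predicted
  vector is constant have no defined correlation; they are excluded from
  the median and counted, never coerced to zero (coercion would bias the
  median toward zero in exactly the sparse regimes where it matters).
* **Per-gene correlations** across cells, same conventions.
* **Per-tree uncertainty**: for each gene, the correlation of each tree's
  prediction with truth, then the standard deviation over the ensemble in
  population form (denominator = number of trees; the ensemble is the
  whole population of interest, not a sample from a larger one).
* **Population profiles and similarity**: per-population mean expression
  over the union of top marker genes, and pairwise Pearson between
  profile rows. Confidence intervals use the Fisher transformation,
  `tanh(atanh(r) -+ z / sqrt(n - 3))`. The effective `n` for a profile
  correlation is taken to be the number of genes in the profile vectors —
  the published analysis does not state its `n`, so it is configurable.
  The comparison helper declares A-B significantly more similar than A-C
  exactly when `low(A,B) > high(A,C)`, the criterion used in the
  published human analysis.
* **Bootstrap error bars**: the correlation's standard deviation over
  10,000 resamples of cell indices (the published protocol), population
  form, with degenerate resamples skipped and counted.

One published ambiguity deserves a note: the headline "median Pearson"
numbers sit next to figures describing both per-cell and per-gene
correlation axes. Both axes are implemented and reported side by side;
which one feeds a given summary line is an explicit argument, not a
guess buried in code.

## The synthetic generator

`generate_sct()` / `generate_ifc()` produce paired experiments with known
ground truth: three populations in [0, 1]^2 marker space — two separated
extremes and a narrower intermediate population, mimicking the
progenitor geometry that makes the intermediate population hard — with
Gaussian marker jitter clipped to the unit square; negative-binomial
counts (size 2) whose log-mean is baseline + a planted population effect
(default +2.5 log units for 10 marker genes per population) + a linear
link to the marker coordinates for designated marker-coding genes; and
16-bit 32x32 images in which a centred disk of radius
`4 + 8 * marker1` pixels sits on Gaussian background noise with interior
speckle laid down with probability `0.5 * marker2`. Negative-binomial
(not Poisson) counts give the sparsity the min-cells and dispersion
filters need to act on; the image encoding gives the CNN a morphology
signal (size and granularity) qualitatively like the one real
brightfield data carries.

What the generator does **not** emulate: batch effects within or across
modalities, ambient RNA, doublets, segmentation artefacts, focus drift,
or any nonlinear marker-expression coupling beyond the planted links.
Passing tests on synthetic data therefore demonstrate that the machinery
is correct and that the method recovers planted structure under its own
assumptions — they do not certify performance on any real dataset, where
the published headline correlations (around 0.46 human / 0.32 mouse on
marker genes) set realistic expectations.

## Problem sizes, seeds, determinism

The test and acceptance workloads run at desk scale, chosen so the whole
suite completes in minutes on one core while every property remains
discriminating: 2000 SCT cells x 120 genes for pipeline-level checks,
2000 training images (+500 held out) and at most 10 epochs for the
label-free feasibility check, brute-force oracles at or below 100x100.
These sizes are the package's own test design; nothing in the
implementation depends on them.

Every stochastic step takes a seed. The pipeline fans a single global
seed out to per-stage seeds by hashing the stage name (`stage_seed()`),
so any stage can be reproduced in isolation. Forest fitting and CNN
training are deterministic for a fixed seed in a fixed environment
(single-threaded compiled code; BLAS kernels are deterministic for a
fixed thread count). Artifact-writing runs record seeds, marker bounds,
configuration and package version in a JSON manifest next to the
predictions.

## Known limitations

* Two markers carry limited information; genes not associated with the
  gated populations are not predicted well — this is a property of the
  problem, and the per-gene metrics make it visible rather than hiding it.
* Batch effects are out of scope by design; normalization to [0, 1] is
  the only cross-modality harmonization performed.
* The label-free mode requires the populations to differ morphologically;
  the package cannot detect from images alone that they do not.
* Rectangular gates only; polygonal or data-driven gating is out of scope.
* The dispersion filter reproduces one specific published recipe; other
  HVG definitions (e.g. variance-stabilizing fits) are deliberately not
  offered to keep the preprocessing faithful.
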