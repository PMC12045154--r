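---
title: "DSCT: models, parameters and design choices"
author: "DSCT maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DSCT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DSCT)
```

# The problem

Spatial transcriptomics measures expression in place but without labels;
annotated sc/snRNA-seq atlases have labels but no coordinates. DSCT
transfers the atlas labels onto the spatial observations. The package
treats both inputs as `ExpressionDataset` objects — genes × observations
matrices on a `SummarizedExperiment` backbone, with cell types and (x, y)
coordinates in `colData`. Every observation is classified independently:
no spatial smoothing or neighbourhood operator is applied anywhere, so
coordinates are carried as metadata only. This keeps the method honest —
spatial structure in the output can only come from expression, never from
a spatial prior — at the cost of ignoring information a graph-based model
could exploit.

# Preprocessing

Both data sets are restricted to their shared genes
(`intersectGenes()`), in the *reference's* gene order, because the
trained network's input layout is defined by the reference panel. Counts
are then library-size normalized to a common per-observation total
(default `targetSum = 1e4`) and `log1p`-transformed
(`normalizeDataset()`). This is the field-standard scheme; the classifier
only requires that reference and spatial data share one scheme, which the
pipeline enforces by construction. All-zero observations cannot be
scaled and are left at zero with a warning rather than dropped, so
observation sets never change silently. Duplicated gene names in input
files are resolved deterministically (keep first, warn).

# ACOSG marker selection

## Penalized cosine score

For gene $g$ and type $k$, $\lambda_{gk}$ is the cosine between the
gene's expression vector over all reference cells and the 0/1 indicator
of type $k$; an all-zero gene gets $\lambda = 0$. The penalized score is

$$ s_{gk} = \mathrm{sign}(\lambda_{gk})\,
   \frac{\lambda_{gk}^2}{\lambda_{gk}^2 + \mu \sum_{i \neq k}
   \lambda_{gi}^2}, \qquad \mu \ge 0 ,$$

defined as 0 when the denominator vanishes. $\mu$ (default 1) balances
specificity against expression: at $\mu = 0$ every gene with nonzero
$\lambda$ scores $\pm 1$ and the ranking collapses to the plain cosine;
large $\mu$ strongly penalizes genes shared across types. The sign is
preserved so anti-markers (genes depleted in a type) rank last rather
than being confused with positive markers. Because $\lambda$ is
scale-free, the score is invariant to positive rescaling of any gene,
and because it is computed from whole-column statistics it is invariant
to reordering of cells.

## Attention weights

The attention network is deliberately small: each gene's standardized
expression is multiplied by a learned per-gene gate
($\mathrm{softplus}$ of a scalar, initialized so the gate equals 1),
followed by one 64-unit ReLU layer and a softmax classifier, trained for
30 epochs with Adagrad at learning rate 0.01 (mini-batches of 128).
The per-gene importance is the softmax over genes of the learned gate
activations $\mathrm{softplus}(g_g)$, giving non-negative weights that
sum to one.

Two design points deserve explanation:

* **Inputs are standardized per gene** (zero mean, unit variance) before
  the gate. Without this, highly expressed genes dominate regardless of
  their discriminative value and the gate must undo the scale
  differences before it can express importance.
* **The importance is the gate itself, not the gated data.** An
  alternative — averaging $|\mathrm{softplus}(g_g)\,x_{ig}|$ over cells
  — mixes the learned gate with each gene's distribution *shape*: after
  standardization, a bimodal marker gene has a smaller mean absolute
  value than unimodal noise (the mass sits nearer the mean), so the
  shape factor can outvote the gate and demote exactly the genes the
  gate learned to amplify. In controlled two-type experiments with a
  single separating gene, the gate ranks that gene first while the
  gated-data average ranks it last; the package therefore reads
  importance directly off the gate.
* **Initialization is tied to gene identity.** First-layer weights are
  drawn in canonical (sorted gene name) order and then mapped onto the
  actual column order. This makes the whole procedure exactly
  equivariant: permuting the input genes permutes the attention weights
  identically at a fixed seed, which positional i.i.d. initialization
  would only satisfy approximately.

## Fusion and panel selection

The fused score is $s_{gk} \cdot a_g / \max_g a_g$; max-normalizing the
attention makes uniform weights the exact identity, so with
uninformative attention ACOSG reduces to pure COSG ranking — a property
the test suite asserts exactly. By default the top `nTop = 50` genes per
type are unioned (ties broken by lexicographic gene name, panel reported
in reference gene order); a global top-`nTop` mode is available. A
multiplicative fusion was chosen over additive blends because it
preserves the zeros of both orderings: a gene scored zero by either
component cannot enter the panel ahead of genes supported by both.

# The classifier

`buildNetwork()` defaults to five hidden layers of widths
(256, 128, 64, 128, 256), ReLU activations and dropout 0.1. The
symmetric bottleneck exists so the residual connection — hidden layer
1's activations added to hidden layer 5's pre-activations — joins equal
widths, realizing an initial-to-terminal skip path that keeps gradients
flowing through the narrow middle. Inputs are the normalized
log-expression of the panel genes, standardized per gene with *reference*
statistics that are stored in the model and re-applied to spatial data,
removing platform scale differences between the two data sets.

Training (`trainClassifier()`) uses mini-batch Adagrad (learning rate
0.01, batch 128, 100 epochs) on cross-entropy loss with a stratified
10% validation split; the parameters with the best validation loss are
retained and training stops early after 10 epochs without improvement
(`earlyStopPatience = 0` disables early stopping; `epochs = 0` returns
the untrained initialization). Every stochastic element —
initialization, split, batch order, dropout — draws from one seeded RNG
stream, so identical configurations reproduce results bit for bit on one
machine. Probabilities are clipped at $10^{-12}$ inside the loss; a
non-finite loss aborts with the epoch and batch named rather than
training on silently.

Prediction applies the stored standardization and a dropout-free forward
pass; each output row is a softmax, so rows sum to 1 within $10^{-6}$.
Hard labels take the row argmax with ties resolved to the lowest
vocabulary index (vocabularies are ordered by first appearance in the
reference).

# Evaluation system

All map metrics compare one cell type's predicted column against the
matching reference-map column, then average over types unweighted:

* **COS** — cosine similarity; all-zero pairs give 0.
* **PPMC** — Pearson correlation; a zero-variance vector gives 0 with a
  warning instead of NA, so degenerate columns cannot poison an
  aggregate.
* **SSIM** — the global (single-window) structural similarity with both
  vectors max-scaled to $[0,1]$, $L = 1$, $C_1 = 0.01^2$,
  $C_2 = 0.03^2$, population (1/n) moments. Windowed SSIM presumes a
  raster; spatial observations are an unordered point set, so the global
  form is the appropriate convention here.
* **KL** — $\mathrm{KL}(r \,\|\, p)$ in nats after adding
  $\varepsilon = 10^{-12}$ and renormalizing both vectors to the
  simplex; the direction reads as the information lost when the
  prediction stands in for the reference.
* **JS** — the symmetrized divergence, bounded by $\ln 2$.

The **Acc Score** ranks methods per metric with the best method
receiving rank $M$ (higher-is-better for COS/PPMC/SSIM, lower for
KL/JS), average ranks for ties, and reports the mean rank divided by
$M$: a method dominating every metric scores exactly 1, and the score is
invariant under any strictly monotone transform of a metric column. By
default the four metrics COS, PPMC, SSIM and KL enter the score; JS is
always computed and reported but excluded from ranking, with
`scoreMetrics` as the switch. Confusion matrices are row-normalized over
the annotated classes, and composition checks compare predicted type
proportions (probability means or hard-label frequencies) to a reference
vector by PPMC and COS.

Reference maps for evaluation come in three flavours: one-hot prior
annotations, per-type sums of the top 20 type-specific marker genes
(max-scaled per type), or the exact proportions of a simulation.

# The synthetic generator

`simulationConfig()` defines the study conditions: `K = 5` types over
`G = 500` genes, a disjoint block of `markersPerType = 40` markers per
type elevated `foldChange = 4`-fold above a negative-binomial baseline
(`baseMean = 1`, dispersion 0.5, i.e. NB size 2 — clearly overdispersed,
as raw sc/spatial counts are), 200 reference cells per type and 1000
spatial observations. Disjoint marker blocks make the expected COSG
ranking known a priori, so marker selection is testable without a model
in the loop. The spatial layout places observations uniformly in the
unit square with types in `K` horizontal bands, mimicking laminar
tissue. At single-cell resolution the band determines the label exactly.
Multi-cell spots (`cellsPerSpot > 1`) draw each constituent cell's type
from a Gaussian kernel over band centers with
$\sigma = 1/(4K)$ — a quarter band width, chosen once as a plausible
boundary-mixing scale — and sum the counts; the realized mixing
fractions are recorded as ground truth.

What the simulation does *not* emulate: platform noise (optical
crowding, segmentation error, lateral diffusion), batch effects between
reference and spatial data, correlated gene modules, or continuous
cell-state gradients. Passing the end-to-end tests therefore
demonstrates that the pipeline recovers labels when the reference
faithfully describes the spatial data's types; it does not certify
performance under reference/spatial mismatch, which real applications
must assess with their own annotations.

# Numerical choices and degenerate inputs

* Standardization divisors are floored at $10^{-8}$; constant genes
  become all-zero inputs rather than NaN.
* Cosines are clamped to $[-1, 1]$ against floating-point overshoot.
* Gene-ranking ties break lexicographically by gene name; argmax ties
  break to the lowest index — both total orders, so selection is
  deterministic.
* `nTop` beyond the gene count clamps with a warning; an empty gene
  intersection, a single labelled class, or a missing panel gene are
  errors that name the offending objects.
* Raw-layer matrices must be non-negative integers; readers tag
  non-integer inputs as already normalized (with a warning) instead of
  guessing a count transform.

# Problem sizes in the test suite

Unit tests run on toy fixtures (tens of genes and cells) with
brute-force oracles; the end-to-end checks use the study conditions
above (5 types / 500 genes / 1000 reference cells / 1000 spatial
observations, and the 5-cell-spot variant), sizes at which the full
pipeline completes in well under a minute on one CPU while leaving the
classification problem non-trivial. The monotonicity-in-fold-change and
distribution-exchangeability properties use reduced grids (three fold
changes, 20 seeds) to keep the suite brisk.

# Known limitations

* No spatial regularization: noisy boundaries between territories are
  classified cell by cell.
* Probabilities are softmax outputs and tend to saturate; they track
  spot mixing proportions well in rank and correlation but are not
  calibrated deconvolution fractions.
* The attention network reports a single importance per gene, not per
  (gene, type); genes important for only one rare type can rank lower
  than broadly informative ones.
* h5ad support covers the common core of the format (dense or CSR/CSC
  `X`, categorical or string obs columns, `obsm/spatial`); exotic
  encodings should be converted upstream.
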