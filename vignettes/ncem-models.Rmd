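---
title: "Node-centric expression models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-centric expression models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncemr)
```

## The modeling problem

Segmented spatial molecular profiling assays yield, per tissue image, a
cells × genes expression matrix together with each cell's position, type
label and image identity. A node-centric expression model (NCEM) asks how
much of a cell's expression is explained by its *niche* — the set of
cells within a radius δ_max (the **resolution**, in µm) in the same
image — beyond what its own type and batch explain. Because the models
score all genes, they generate cell-communication hypotheses that are not
limited to annotated ligand–receptor pairs.

A useful orientation statistic is the variance decomposition
(`variance_decomposition()`): the total sum of squares around the grand
mean splits exactly into a gene term (gene means vs grand mean), an
inter-cell-type term (type-gene means vs gene means) and an
intra-cell-type term (cells vs their type-gene mean). Only the
intra-type share is available for niche effects to explain, which is why
test-set gains of spatial over nonspatial models (ΔR²) are expected to be
small relative to baseline R².

## Spatial graph

`build_graph()` connects cells `a, b` of the same image when
`d(a, b) ≤ δ_max` (inclusive threshold, matching the defining
inequality). The diagonal is zero — a cell is never its own neighbour, so
sender presence never reflects the index cell itself — and edges never
cross image boundaries, since images are physically independent tissues.
For graph convolutions the adjacency is row-normalized (`Ā = D⁻¹A`);
isolated cells keep an all-zero row. `resolution_grid()` produces a
screening grid whose mean node degrees span from near-isolation up to a
configurable maximum (default 10), always including the 10 µm reference;
the exact grid is a user choice because only the covered degree range
matters.

## Linear NCEM and inference

The interaction design is `X^D = (X^l, X^TS, X^c)` with
`X^S = 1(A X^l > 0)` and `X^TS` the row-wise outer product of the
receiver one-hot with `X^S`, laid out receiver-major. There is no global
intercept: the complete `X^l` block plays that role. Because the full
`X^l` and `X^c` one-hot blocks are jointly collinear (both sum to one),
`fit_ols()` uses the minimum-norm SVD solution and flags every column
that participates in an exact collinearity as non-estimable; interaction
columns that are all-zero (never-observed sender–receiver combinations)
are likewise excluded from testing and reported as unobservable
couplings. Standard errors use the gene-wise residual variance
(denominator N − rank) times the diagonal of the generalized inverse of
`X^DᵀX^D`; the likelihood `sigma` is the maximum-likelihood residual SD
(denominator N) because the Gaussian log-likelihood is a training
objective. Wald statistics `β/SE` are referred to a t distribution on
N − rank degrees of freedom (the reference distribution is our choice; at
the sample sizes involved it is indistinguishable from the normal), with
Benjamini–Hochberg correction pooled across all interaction × gene
hypotheses of one fit.

Model evaluation uses the per-cell coefficient of determination
`R²_i = 1 − Σ_j (y_ij − ŷ_ij)² / Σ_j (y_ij − ȳ_j)²` with gene means
`ȳ_j` computed on training cells only; we read the centering term as
per-gene training means (an interpretation — the defining expression is
ambiguous about the index). Cells with zero denominator are excluded with
a warning. `resolution_screen()` refits spatial and baseline models on
the same splits per resolution and compares the best spatial model
against the baseline with a two-sided paired t-test across
cross-validation seeds. Splits are cell-level (10% test, then 10% of the
remainder as validation, round-half-up), pooled across images, with a
recorded seed.

## Spot NCEM

For deconvoluted spot transcriptomics, every present (spot, type)
expression vector is an observation and the spot's inferred type
abundance vector is its niche: the design row is
`[one-hot(type) | outer(one-hot(type), composition) | covariates]`.
Composition is used as provided (deconvolution outputs abundances);
`normalize_composition = TRUE` converts to proportions. Absent
(spot, type) rows are dropped, not zero-imputed. Cross-validation splits
at the spot level so all rows of a spot share a fold. With one cell per
spot and one-hot compositions the spot design coincides with the
single-cell interaction design on self-niches, which ties the two model
families together. `coefficient_stability()` compares interaction
coefficient vectors over genes between a reference and a comparison fit
(e.g. after subsampling spots) with a coefficient of determination, so
anticorrelated estimates can score below zero.

## Nonlinear models

The deterministic nonlinear NCEM is implemented as one fully connected
stack over the concatenated features rather than a literal
encoder/decoder pair: for deterministic models the decoder's
re-concatenation of the conditions is a skip connection, and composing
two MLPs yields an MLP, so the single stack is the same function class
with fewer moving parts. Aggregators:

* **indicator** — the interaction features `(X^l, X^TS, X^c)`. With zero
  hidden layers the network is exactly the linear NCEM design, which
  makes the linear model a strict special case (verified in the tests as
  a < 0.01 pooled-R² gap after training).
* **gcn** — a learned one-layer graph convolution
  `softmax(ReLU(Ā X^l W))`. The softmax is applied across the embedding
  features of each cell (the defining expression is dimension-ambiguous;
  per-cell normalization keeps embeddings comparable between cells), so
  isolated cells receive the uniform embedding `1/H`.
* **none** — the nonspatial neural baseline `(X^l, X^c)`, whose
  performance is resolution-invariant by construction.

All neural models share one schedule: Adam; learning rates screened over
{0.5, 0.05, 0.005}; a reduce-on-plateau scheduler on the validation loss
(patience 20 epochs, factor 0.5); early stopping (patience 100); batches
drawing a fixed number of nodes per image (default 128; the exact count
is not pinned down by the model definition, and `Inf` gives full-batch
training). Gene-wise standard deviations are `exp` of free parameters.
The grid member with the best validation R² is selected, mirroring
validation-R²-based model selection throughout. Training is fully
deterministic given the seed. Two numerical choices stabilize the
hand-written trainer and change no model definition: output biases and
log-sigmas start at training gene means/SDs, and encoder expression
inputs are standardized with training statistics.

## Ligand–receptor kernel

`lr_kernel()` embeds each cell into a K-dimensional receptor-activity
space: `z_ik = Σ_{m∈N(i)} f_R(Y_{i,r(k)}) · f_L(Y_{m,l(k)})` — receptor
expression on the index cell times ligand expression summed over its
neighbours. (The defining formula as printed repeats the receptor index
inside the neighbour term; we follow the accompanying description, which
says ligand expression on neighbours.) `f_R` and `f_L` default to the
identity since their functional forms are not specified; an optional
learned variant multiplies each pair's activity by a softplus scalar.
All neighbours within δ_max weigh equally, consistent with the binary
adjacency used elsewhere. The decoder predicts all genes from
`(z, X^c)`; the baseline replaces `z` with the index cell's own receptor
expression — an intracellular model with the same decoder shape, not
nested in the LR model. `differential_receptor_activity()` ranks latent
units by Welch t-tests between receiver cells with and without a chosen
sender type in the niche, BH-corrected.

## Conditional VAE

`fit_cvae()` models cell-intrinsic latent states: the encoder maps
expression plus conditions (cell type, indicator niche embedding,
domain) to a diagonal Gaussian posterior; the decoder reconstructs
expression from the sampled latent and the same conditions. The loss is
the negative mean Gaussian log-likelihood plus the closed-form KL to the
standard-normal prior, the KL averaged with the same `1/(N·J)` convention
so both terms share a scale; the KL weight (default 1) and latent
dimension are exposed because no canonical values exist. Evaluation and
style transfer use posterior means (sampling is available behind a
seeded flag). Restricting training to a single receiver type
(`target_cell_type`) removes the non-identifiability between type
conditions and latent variables. Style transfer decodes a source cell's
latent under a target cell's conditions, probing whether the model uses
its conditions; a known caveat is that a conditional VAE may represent
niche information in the latent variables instead, so a spatial-minus-
nonspatial CVAE gap is *not* asserted anywhere — only reconstruction
quality is.

## Simulators

The generators define the package's study conditions:

* `simulate_null()` — one cell type, gene means uniform on (0, 10),
  Gaussian noise (SD 1 by default), cells placed uniformly in a square
  sized to a target mean degree (default 6) at the interaction radius
  (default 50 µm). Used for type-I calibration.
* `simulate_dependency()` — two types; for 50% of genes an additive
  effect drawn uniformly from (4, 6) is added whenever the respective
  other type is present in the niche. Effects are drawn per
  (gene, direction); `directions = "a_to_b"` plants a one-way effect for
  directionality analyses. Type assignment is uniform at random (the
  spatial arrangement of types is otherwise unspecified; a zoned variant
  can be emulated by supplying coordinates). The noise law is Gaussian,
  matching the fitting likelihood, since no count model is prescribed
  for the simulation design.
* `simulate_segmentation_error()` — re-assigns a fraction of each
  selected cell's whole expression vector (default 0.5; the fractions of
  corrupted cells studied are 10% and 50%) to one uniformly chosen
  neighbour. Transfers are computed from the original matrix and applied
  simultaneously, so per-image totals are conserved exactly; isolated
  selected cells are skipped and reported.
* `simulate_spots()` — bins a simulated tissue into square spots and
  emits the deconvolution-shaped view (per-spot type counts,
  within-spot type-mean expression). The spot benchmark uses a sparse
  tissue (3,000 cells, mean degree 2, 100 µm spots): at higher densities
  the binary presence effect saturates — nearly every cell has an
  other-type neighbour — and spot compositions carry no usable variance,
  so sparsity is the regime in which the spot design is identifiable.
* `simulate_lr()` — plants ligand–receptor structure: one
  sender-type-restricted ligand, broadly expressed receptors, decoy
  pairs with uniformly expressed ligands, and ten target genes driven
  linearly by the true pair's standardized kernel activity.
* Intrinsic latent factors (`n_latent_factors`, default 0) add
  niche-independent gene covariation within cells. They are switched on
  (4 factors, unit loading scale) for the CVAE reconstruction benchmark:
  with purely iid residual noise nothing is compressible, posterior
  collapse is the optimum and the CVAE merely ties the deterministic
  model, whereas reconstruction of intrinsic structure is the task the
  CVAE exists for.

All generators are deterministic given their seed and return ground
truth sufficient to score recovery without re-simulation. What the
simulations do **not** emulate: count noise (expression is Gaussian, not
negative binomial), segmentation geometry, spatially zoned type
arrangements, and real niche-effect sparsity patterns — so passing tests
demonstrate correctness of the estimators under the stated generative
law, not performance on any particular real assay.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale instances chosen to keep the
full validation suite in the low minutes on one CPU while leaving all
statistical margins wide: 2,000 cells × 500 genes for type-I
calibration, 2,000 × 100 for power and coefficient recovery, 1,200-cell
tissues for the resolution screen (grid 15–130 µm around the true
50 µm), 800 × 40 for the neural benchmarks, 20 replicates of 500 cells
for ligand–receptor ranking. Rank decisions in the OLS use the standard
`max(dim) * eps * d_max` singular-value cutoff; collinearity flags use
the null-space support of the design's SVD. Ties in hierarchical
clustering follow `hclust`'s average-linkage conventions on
1 − correlation distances, with constant coefficient vectors masked.
Degenerate Fisher tables (an empty margin) report p = 1 with a flag.

## Limitations

Radius graphs are the only supported neighbourhood definition (no kNN or
Delaunay variants), graphs are 2-D, the likelihood is Gaussian (no
Poisson/negative-binomial variant), graph convolutions are one layer
deep, and the CVAE uses diagonal Gaussian posteriors. Deconvolution
itself is out of scope: the spot model consumes deconvolution output.
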