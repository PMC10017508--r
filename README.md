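# ncemr — node-centric expression models for spatial omics

Cells in a tissue do not transcribe in isolation: their expression state
depends on which cell types sit in their spatial neighbourhood (their
*niche*). `ncemr` implements **node-centric expression models (NCEMs)**
for segmented spatial molecular profiling data (MERFISH, CODEX, MIBI-TOF,
chip cytometry, ...): models that predict a cell's gene expression vector
from its own cell type, the composition of its niche on a spatial graph
of cells, and batch covariates, and then turn fitted coefficients into
testable cell-type coupling hypotheses. It is aimed at computational
biologists who want unbiased, whole-transcriptome cell-communication
inference constrained by physical proximity rather than ligand–receptor
co-expression alone.

## The model

Given expression `Y ∈ R^{N×J}`, one-hot cell types `X^l ∈ {0,1}^{N×L}`
and domain (image/batch) indicators `X^c ∈ {0,1}^{N×C}`, a radius graph
`A` connects cells of the same image whose Euclidean distance is at most
the *resolution* δ_max (µm). The core linear NCEM is

    X^S  = 1(A X^l > 0)                    binary sender presence in the niche
    X^TS = rowwise outer(X^l, X^S)         receiver × sender interactions
    Ŷ    = (X^l, X^TS, X^c) β,             β ∈ R^{(L+L²+C)×J}

fit gene-wise by OLS; interaction coefficients are tested with Wald
t-tests and Benjamini–Hochberg FDR correction, and summarized per
(sender, receiver) pair as *type couplings* (significant-gene counts and
L1 norms). The nonspatial baseline drops `X^TS`, so the test-set ΔR²
between the two, screened over resolutions, locates the length scale of
cell–cell dependency. The family extends to deconvoluted Visium spots
(the spot composition is the niche), nonlinear models with indicator or
graph-convolution niche encoders, a ligand–receptor graph kernel
`z_ik = Σ_{m∈N(i)} f_R(Y_{i,r(k)}) · f_L(Y_{m,l(k)})`, and a conditional
VAE over cell-intrinsic latent states with style transfer. Simulators
generate tissues with planted niche effects so that every model is
validated against known ground truth. See `vignettes/ncem-models.Rmd`
for the full methods description.

## Worked example

```r
library(ncemr)

# a 1,200-cell two-type tissue with mutual niche effects (U(4,6) on half
# the genes) acting at a 50 um radius
sim <- simulate_dependency(simulation_config(n_cells = 1200, n_genes = 40,
                                             seed = 11))
sim$graph
#> cell_graph: 1200 cells, 3366 edges, resolution 50.0 um, mean degree 5.61

fit <- wald_test(fit_ols(build_design(sim$dataset, sim$graph, "interaction"),
                         sim$dataset$expression))
fit
#> ncem_fit (interaction): 7 coefficients x 40 genes, rank 6, df 1194
#>   Wald test: 160 interaction x gene hypotheses, 42 at q < 0.05

type_coupling(fit, alpha = 0.05, min_genes = 10)
#>   sender receiver testable n_significant l1_norm  plot
#> 1 type_A   type_A     TRUE             1   0.423 FALSE
#> 2 type_B   type_A     TRUE            20 103.800  TRUE
#> 3 type_A   type_B     TRUE            20  99.259  TRUE
#> 4 type_B   type_B     TRUE             1   0.465 FALSE

resolution_screen(sim$dataset, c(15, 30, 50, 80, 130), seeds = 1:3)
#> resolution screen (pooled test R2):
#>  resolution    mean_r2      delta_r2
#>          15 0.03389127 -5.315611e-03
#>          30 0.03987684  6.699592e-04
#>          50 0.23410935  1.949025e-01
#>          80 0.03918170 -2.517997e-05
#>         130 0.03920688 -3.330669e-16
#> baseline R2 0.0392; best resolution 50.0 um; paired t-test p = 0.155
```

The coupling table recovers exactly the two planted sender→receiver
edges (20 of 20 dependent genes each, large L1 norms) while the
same-type pairs stay at noise level, and the resolution screen peaks at
the true 50 µm interaction radius while the graph-blind baseline is flat
across resolutions.

## Command line

A thin CLI wraps the same functions:

```sh
exec/ncem simulate --design dependency --seed 3 --out sim/
exec/ncem fit-linear --expr sim/expression.tsv --meta sim/metadata.tsv \
    --resolution 50 --out fit/
exec/ncem couplings --expr sim/expression.tsv --meta sim/metadata.tsv \
    --resolution 50 --out couplings/
```

Subcommands: `simulate`, `fit-linear`, `screen`, `couplings`, `fit-spot`,
`fit-nl`, `fit-lr`, `diff-receptor`, `fit-cvae`, `style-transfer`; every
run writes a `manifest.json` with the config snapshot, seeds, input
checksums and timings.

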