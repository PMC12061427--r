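# spatmap

Spatial reconstruction of single cells by density-ratio transfer.

Single-cell RNA-seq (scRNA-seq) profiles whole transcriptomes but loses the
cells' positions; spatial transcriptomics (ST) keeps positions but with
coarser resolution or fewer genes. `spatmap` transfers spatial information
from one or more ST reference slices onto an scRNA-seq query. It is written
for computational biologists who have a dissociated single-cell dataset and
at least one spatially resolved slice of comparable tissue, and who want
single-cell-resolution positions, the genes that organize them, and tissue
growth directions.

## The model

Let `x` be preprocessed expression, `z = h(x)` a latent co-embedding fitted
on the reference, and `y` a 2-D tissue coordinate. Assuming the conditional
law `p(y | z)` is shared between query and reference while the marginals
differ, the query-population risk of a regressor `g` equals a reference
expectation reweighted by the density ratio `w(z) = p_sc(z) / p_st(z)`.
`spatmap` estimates `w` by KLIEP — a non-negative Gaussian-basis expansion
maximizing the query log-likelihood under the constraint
`(1/m) Σ_j ŵ(z_st_j) = 1` — and fits `g` (a small ReLU network) by the
importance-weighted least-squares objective

    argmin_g  (1/m) Σ_j  ŵ(z_st_j) · || g(z_st_j) − y_st_j ||²  +  Ω(g)

Prediction composes the pieces: `ŷ = g(h(x))`. On top of the fitted map:

* **SOG index** — `I_g = E{ ½ Σ_p |∂y_p/∂x_g| }`, the mean absolute
  Jacobian per gene; the top-ranked genes are the spatial-organizing genes.
* **In-silico knockout** — a gene's input is replaced by its zero-count
  value under the stored preprocessing and positions are re-predicted.
* **Spatial RNA velocity** — `v_st = f(x + v_rna) − f(x)` projects an
  externally estimated RNA-velocity step into the tissue plane.
* **Metrics** — permutation-null accuracy, per-layer reconstruction
  indicators, and Moran's I spatial autocorrelation.
* **Simulators** — coarse-grained spot references, gene-wise noise, a
  ten-gene toy tissue with known coordinate-determining genes, and a
  laminar (cortex-like) fixture; every test input is generated in code.

## A worked example

The ten-gene toy tissue separates two gene roles: genes 1–4 determine the
coordinates (weakly autocorrelated themselves), genes 5–10 are spatially
smoothed noise — highly autocorrelated but causally inert.

```r
library(spatmap)

toy <- simulate_toy(n = 500, seed = 1)    # 500 cells, 10 genes
fit <- spatmap(spatial_slice(toy$X, toy$coords), toy$X,
               normalize = FALSE, scale = FALSE, n_hvg = NULL, seed = 1)
print(fit)
#> Spatial reconstruction model (density-ratio-weighted neural mapping)
#>   reference: 1 slice(s), 500 spots; query: 500 cells; 10 genes
#>   co-embedding K = 10; slice weights: 1.000
#>   final weighted training loss: 0.004661

head(sog_index(fit$mapper, fit$sc_scaled), 4)
#>     gene         I rank
#> 1 gene02 0.6303056    1
#> 2 gene04 0.4174652    2
#> 3 gene01 0.1973563    3
#> 4 gene03 0.1236851    4

round(vapply(colnames(toy$X), function(g)
  morans_i(unclass(toy$X)[, g], toy$coords), numeric(1)), 2)
#> gene01 gene02 gene03 gene04 gene05 gene06 gene07 gene08 gene09 gene10
#>   0.20   0.86   0.03   0.87   0.94   0.96   0.89   0.88   0.94   0.96
```

The sensitivity ranking recovers the four coordinate-determining genes even
though every one of genes 5–10 has higher spatial autocorrelation — the two
notions of "spatial gene" dissociate, which is the method's point.

The fitted object answers the usual generics: `predict(fit, newdata)` for
new cells (raw counts are preprocessed with the stored statistics),
`fitted()`, `residuals()` (reference-spot residuals), `summary()` (slice
weights, KLIEP objective, weight quantiles), and `plot()` (predicted cells
beside the reference). `save_spatmap()` / `load_spatmap()` archive a model
as a single JSON file.

A thin command-line wrapper over the same functions ships in
`inst/cli/spatmap-cli.R` with subcommands `simulate`, `preprocess`, `train`
(YAML config), `predict`, `sog`, `knockout`, `velocity`, and `evaluate`.

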