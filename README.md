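# hrspls

Hypergraph-regularized sparse partial least squares for discovering
**co-modules** — joint sets of features from two omics blocks plus the
samples that support them — in paired data such as gene expression and
DNA methylation measured on the same patients.

## Who this is for

Anyone integrating two feature-rich omics matrices over shared samples
who wants interpretable, sparse, mutually correlated feature sets
rather than dense latent factors: e.g. expression + methylation,
expression + drug response, or any paired assay where a subset of
features in each block co-varies across a subset of samples.

## The model

Given column-standardized $X \in \mathbb{R}^{n\times p}$ and
$Y \in \mathbb{R}^{n\times q}$, each component solves

$$
\min_{g,d}\; -c\,g^\top X^\top Y d
 + \beta_1\, g^\top L_1 g + \beta_2\, d^\top L_2 d
 + \lambda_1\|g\|_1 + \lambda_2\|d\|_1
 \quad \text{s.t. } g^\top g = d^\top d = 1,
$$

where $L_1, L_2$ are normalized Laplacians of k-nearest-neighbour
hypergraphs built over each block's features ($L = I -
D_v^{-1/2} H W D_e^{-1} H^\top D_v^{-1/2}$). The lasso terms select
features; the hypergraph terms smooth weights over neighbourhoods of
correlated features, which stabilizes support recovery when the signal
is weak. The solver alternates soft-threshold sweeps for $g$ and $d$
(with projection to the unit sphere) from a plain-PLS initialization.
Each fitted component becomes a module by z-score thresholding
($|z| > T$, default $T = 1$) of the weights and of the combined latent
scores $u^* + v^*$; the rank-one signal is then deflated and the next
module extracted ($K = 20$ by default). Setting $\beta = 0$ gives
sparse PLS, $\lambda = \beta = 0$ plain PLS, and a simple-graph
Laplacian the SNPLS-style baseline — all through the same solver.

## Worked example

```r
library(hrspls)

sim <- simulate_paired_omics(n_samples = 100, p_features = 300, q_features = 250,
                             n_modules = 2, support_x = 15, support_y = 15,
                             snr = 2, seed = 1)
cfg <- solver_config(seed = 1, n_modules = 3)   # lambda = beta = 0.5 defaults
fit <- extract_modules(sim$X, sim$Y, cfg)
print(fit)
#> 3 extracted co-module(s) (hypergraph graph penalty)
#>  module_index n_x_features n_y_features n_samples      pcc module_error
#>             1           15           15        35 0.966338     155615.9
#>             2           15           15        35 0.969681     148028.2
#>             3            0            0         0       NA           NA
#>  objective converged
#>  0.6713827      TRUE
#>  0.6917754      TRUE
#>         NA        NA

ev <- evaluate_recovery(fit, sim$truth)
cat("mean F1:", ev$mean_f1, " mean latent correlation:", round(ev$mean_latent_cor, 4), "\n")
#> mean F1: 1  mean latent correlation: 0.9839
```

Modules 1 and 2 recover the two planted 15+15-feature co-modules
exactly (support F1 = 1): each selects the planted features of both
blocks, its 35 member samples, and a latent-score correlation
`pcc` ≈ 0.97 between the expression and methylation sides. Module 3 is
*empty*: after both planted signals are deflated only noise remains,
the lasso shrinks every weight to zero, and the degenerate component is
reported as an empty module rather than a spurious one. On real data
`read_omics_matrix()` / `run_pipeline()` read TSV/CSV matrices, align
shared samples, and write `modules.tsv`, `samples.tsv`, `summary.tsv`
and `run_metadata.json`; `grid_search()` tunes the four penalties over
the default grid `{0.01, 0.05, 0.1, 0.5, 1}` by mean module
correlation, and `compare_methods()` tabulates PLS / sparse PLS /
graph-regularized baselines.

A command-line wrapper with `fit`, `gridsearch`, `simulate`,
`evaluate` and `compare` subcommands is installed at
`system.file("cli", "hrspls.R", package = "hrspls")`.

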