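# mtgrn — multi-task gene regulatory network inference on cell lineages

`mtgrn` infers cell type-specific gene regulatory networks (GRNs) for cell
types related by a lineage tree, from per-cell-type single-cell expression
matrices. It is aimed at computational biologists studying how regulatory
programs are conserved and rewired across a differentiation or
reprogramming process: rather than fitting each cell type's network in
isolation, the fits share information along the lineage, so an edge with
solid support in a parent cell type needs less evidence to be kept in its
children.

## The model

Each cell type's GRN is a **dependency network**: every gene
$X_i$ is modeled by a conditional Gaussian given its regulators,
$P(X_i \mid \mathbf{R}_i) = \mathcal{N}(\mu_{i|R_i}, \sigma^2_{i|R_i})$,
and the per-cell-type fit is scored by the log pseudo-likelihood
$\sum_i \log P(X_i \mid \mathbf{R}_i)$. The maximised objective is

$$P(\mathbf{G}, \Theta \mid \mathbf{D}) \propto
  P(\mathbf{D} \mid \mathbf{G}, \Theta)\, P(\Theta \mid \mathbf{G})\,
  P(\mathbf{G}),$$

where the structure prior $P(\mathbf{G})$ has two parts: a logistic edge
prior $P(I_{uv}^{(d)} = 1) = \mathrm{logit}^{-1}(\beta_0 + \beta_1
m_{uv}^{(d)})$ with sparsity penalty $\beta_0 < 0$ and
accessibility/motif-derived prior weights $m_{uv}^{(d)}$, and a per-edge
Markov chain over the lineage tree with root probability $p_r$, gain
probability $p_g$ and maintenance probability $p_m$. Search is greedy
forward selection, coordinated across cell types; `mode = "independent"`
drops the lineage coupling (the single-task ablation). Edge confidences
come from stability selection: repeated inference on random cell
subsamples, each edge scored by the fraction of runs containing it.

Alongside the fitter the package ships the complete surrounding workflow:
construction of prior networks from motif instances, accessibility peaks
and TSS windows (±5000 bp, maximum motif scores, top-20% percentile
filter); a seeded lineage simulator (edge evolution by the same chain, a
linear-Gaussian expression generator, uniform dropout sparsification);
evaluation metrics (AUPR with Davis–Goadrich interpolation, F-score@K,
hypergeometric "predictable TF" tests); and rewiring analyses (k-means
edge clustering with silhouette-selected k, LDA topic networks over
TF-per-cell-type documents, MST lineage reconstruction, gene-set
enrichment). See the vignette in `vignettes/multitask-grn-inference.Rmd`
for the methods account.

## A worked example

Simulate a three-cell-type lineage (5 regulators, 20 genes, 200 cells,
30% dropout), fit the multitask model, and score edge confidences by
stability selection:

```r
library(mtgrn)

sim <- simulate_lineage_data(simulation_config(
  n_regulators = 5, n_genes = 20, n_cells = 200, sparsity = 0.3, seed = 1))

fit <- mtgrn(sim$expression, sim$tree, sim$regulators,
             beta0 = -2, p_root = 0.5, p_gain = 0.4, p_maintain = 0.7)
summary(fit)
#> Multi-task GRN fit (multitask mode), total accepted score 2229.7
#>  cell_type n_edges n_regulators n_targets mean_in_degree
#>         C1      52            5        19       2.736842
#>         C2      58            5        19       3.052632
#>         C3      52            5        19       2.736842

head(coef(fit), 3)
#>   cell_type regulator target coefficient
#> 1        C1       R02    R01   0.4407476
#> 2        C1       R05    R01   0.2153911
#> 3        C1       R03    R01   0.1651692

cfg <- inference_config(sim$regulators, sim$tree,
                       prior_config(beta0 = -2, p_root = 0.5,
                                    p_gain = 0.4, p_maintain = 0.7))
conf <- grn_stability(sim$expression, cfg, n_subsamples = 20,
                      fraction = 0.5, seed = 1)
sapply(sim$tree$nodes, function(d) {
  e <- attr(conf, "edges")
  pred <- data.frame(regulator = e$regulator, target = e$target,
                     confidence = conf[, d])
  aupr(pred[pred$confidence > 0, ], sim$networks[[d]])
})
#>    C1    C2    C3
#> 0.764 0.585 0.766
```

The summary lists one row per cell type with the number of inferred edges
and regulators; `coef()` returns the standardized regression coefficient
of each edge from its target's conditional Gaussian. The final numbers are
areas under the precision-recall curve of the stability-ranked edges
against each cell type's simulated ground-truth network (network densities
here are 0.48–0.56, so 0.59–0.77 reflects genuine signal at 30% dropout;
recovery degrades as dropout approaches the 80% of real single-cell data).

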