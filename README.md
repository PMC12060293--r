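# nichetraj

Niche trajectory inference for single-cell resolution spatial omics data.

Tissues often change continuously in space — cortical layers, zonated
liver lobules, tumor-to-stroma interfaces — and that change is visible in
the local *cell-type composition* long before it is visible in any single
cell. `nichetraj` takes only a cell table (coordinates + cell-type labels,
no gene expression needed) and orders the tissue microenvironment along a
one-dimensional **niche trajectory (NT)**, assigning every niche and every
cell a continuous NT score in [0, 1]. It is aimed at analysts of MERFISH,
Xenium, stereo-seq and similar single-cell resolution spatial datasets.

## Method

1. **Niche network.** Each cell anchors a niche containing its *k* nearest
   neighbours (default *k* = 50). Niches are connected when their anchors
   are mutual kNN. Cell *i*'s association with niche *j* is
   `w_ij = exp(-d_ij^2 / sigma_j^2)`, with `sigma_j` the anchor's distance
   to its 20th neighbour; each niche gets a row-stochastic composition
   vector `v_jm = sum_i w_ij I_im / sum_i w_ij` over the M cell types.
2. **Graph encoder.** A two-layer GCN,
   `X_t = SeLU((Ã + I) X_{t-1} W_t)` with `Ã = D^{-1/2} A D^{-1/2}`,
   embeds compositions into 4 dimensions while respecting the spatial
   graph.
3. **Pooling.** A softmax head `C = softmax(beta X_2 W_C)` softly assigns
   niches to K clusters (default 6). Training minimises
   `0.3·L_m + 300·L_p + 0.1·L_r` (modularity + purity +
   collapse-regularization) with Adam (lr 0.03, up to 1000 epochs),
   jointly over all samples so scores are comparable across samples.
4. **Trajectory.** The niche graph is pooled to a K×K cluster network
   `E = C' A C`, normalized, and ordered by the exact maximum-connectivity
   Hamiltonian path. Cluster scores `(k-1)/(K-1)` propagate to niches
   (`s_j = sum_k c_jk s(k)`) and cells
   (`s̃_i = sum_j w_ij s_j / sum_j w_ij`).

The backprop for the tiny GCN + pooling head is implemented directly on
sparse/dense matrix algebra and verified against finite differences in the
test suite.

## Worked example

```r
library(nichetraj)

# circular benchmark: 1000 cells, types A-G on growing circles, H-J random
sim <- simulate_niche_pattern("circular", seed = 1)
res <- run_pipeline(sim$cells, output_dir = "out", seed = 1)

res$fit
#> Trained pooling model: K = 6 clusters, hidden = 4, 1000 epochs
#> final losses: total 0.95227 (modularity -0.41494, purity 0.00334,
#>   collapse 0.76003)
res$trajectory
#> Niche trajectory over 6 clusters
#> ordering: 1 -> 6 -> 5 -> 4 -> 3 -> 2
#> 1000 cells scored across 1 sample(s); orientation +1

spearman_vs_truth(res$scores$cell_NT_score, sim$ground_truth)
#> [1] 0.9928
```

The trajectory recovers the radial ground truth almost perfectly
(orientation-invariant Spearman 0.99); `out/` contains per-niche and
per-cell score CSVs, the soft cluster assignments, the cluster
connectivity matrices, the ordering and a JSON manifest for exact
re-execution.

A command-line interface wrapping the same functions ships in
`inst/cli/nichetraj`:

```sh
Rscript inst/cli/nichetraj simulate --dataset 1 --seed 0 --out sim/
Rscript inst/cli/nichetraj run --input sim/cells.csv --out run/
Rscript inst/cli/nichetraj evaluate --scores run/cell_NT_scores.csv \
    --truth sim/ground_truth.csv
```

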