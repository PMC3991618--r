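# tsnba

Three-step network-based discovery of disease molecular signatures and key
transcriptional regulators from a protein–protein interaction (PPI) network
and condition-contrast expression data, together with the five standard
prioritization baselines, a hypergeometric enrichment-evaluation harness,
and a seeded synthetic benchmark with planted ground truth.

## Who this is for

Computational biologists who have (a) an undirected PPI network as an edge
list, (b) a normalized gene-level expression matrix with control and
treated samples, (c) a benchmark pathology gene set and a transcription
factor (TF) catalogue — and want a ranked candidate list, a compact
co-expression signature, and a short list of candidate master regulators,
with every stage testable on synthetic data before touching real inputs.

## The method

**Step 1 — interaction activity ranking.** Each PPI edge is weighted by the
log2 fold changes of its endpoints through two bivariate logistic terms
(`s` the logistic function):

    A(f_i, f_j) = C·s(K·f_i)·s(K·f_j) + C·s(−K·f_i)·s(−K·f_j) − T

with defaults `C = 1`, `K = 5`, `T = 0.5`, so co-activated and
co-suppressed pairs score high, a pair of unresponsive genes scores exactly
0, and discordant pairs score negatively. Genes are ranked by total
received activity `P_i = Σ_t A(i,t)`.

**Step 2 — co-expression signature.** Pearson correlations among the top
300 ranked genes are thresholded on the grid 0.600–0.945 (step 0.005); the
largest threshold whose retained-edge network still covers at least 50
genes defines the molecular signature.

**Step 3 — regulator screening.** Mutual information
`MI = −½·ln(1 − ρ²)` feeds a context-likelihood-of-relatedness (CLR)
background correction, `z = sqrt(z_tf² + z_target²)` with rectified
per-gene z-components. TFs are retained as key regulators when their
`z ≥ 3` targets include more than 3 benchmark genes at a benchmark
fraction above 60%.

Baselines sharing the same ranked-list contract: fold change, degree,
neighborhood scoring, interconnectivity, and network propagation
(`F_t = α·A_norm·F_{t−1} + (1−α)·F_0`, `α = 0.1`, L1 tolerance `1e-6`).

## Worked example

```r
library(tsnba)

params <- simulation_params()          # 2000 genes, 200 planted pathology genes
ds <- simulate_dataset(params, seed = 42)
res <- run_tsnba(ds$network, ds$expression,
                 contrast = list(control = ds$control, treated = ds$treated),
                 tf_genes = ds$truth$tf_genes,
                 benchmark = ds$truth$pathology_genes)

universe <- network_genes(ds$network)
bench <- ds$truth$pathology_genes
enrichment_ratio(res$top_genes[1:50], bench, universe)   # step 1, top 50
#> <enrichment_result> 33/50 = 66.0% (background 200/2000), p = 1.81e-22
res$signature                                            # step 2
#> <signature_result> threshold 0.945: 135 genes, 594 co-expression edges
enrichment_ratio(res$signature$signature, bench, universe)
#> <enrichment_result> 110/135 = 81.5% (background 200/2000), p = 2.8e-99
res$regulators                                           # step 3
#> [1] "g00001" "g00002" "g00824"
ds$truth$regulators                                      # planted truth
#> [1] "g00002" "g00001" "g00289" "g00824"
```

Reading the numbers: the background rate of pathology genes is 10%
(200/2000). Step 1 concentrates them to 66% of the top-50; the
co-expression filter raises the signature to 81.5% at the selected
threshold 0.945; and the regulator screen recovers 3 of the 4 planted
module regulators with no false TF. Seeds make every number reproducible.

File-based workflows use the same functions via `read_network()`,
`read_expression()`, `read_gene_set()`, and `read_contrasts()`; a thin
command-line wrapper with `simulate`, `rank`, `signature`, `regulators`,
and `prioritize` subcommands ships in `inst/cli/tsnba.R`.

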