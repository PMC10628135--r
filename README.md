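# attnsurv

Biology-aware self-attention survival analysis of tumor mutation profiles.

## What it does and for whom

Panel sequencing of a tumor yields a sparse binary vector — which of a few
hundred cancer genes carry a somatic mutation. Predicting survival under
immune checkpoint inhibitor (ICI) therapy from such vectors is hard: binary
features are weak individually, and classical survival models ignore the
known structure among genes. `attnsurv` is for computational oncologists
and methodologists who want a mutation-based survival model that
incorporates that structure explicitly and remains interpretable.

The core model embeds each gene as a fixed `d_k`-dimensional vector
(wildtype genes are zero vectors) and scores a patient through one
self-attention layer whose genes-by-genes attention map is biased by three
priors computed from a directed gene-interaction graph:

    map = FC1(x) FC2(x)' / sqrt(d_k)
          + k1 * pathway + k2 * connection + k3 * padding

* `pathway(i,j)` = 1 / (shortest directed path length i→j), 0 if
  unreachable;
* `connection(i,j)` = closeness centrality of i plus closeness of j
  (Wasserman–Faust convention on the directed, possibly disconnected
  graph);
* `padding(i,j)` = −1 for unreachable ordered pairs, else 0;
* `k1, k2, k3` are learnable scalars.

Training maximises the concordance index (c-index) under right censoring
through its sigmoid smoothing:

    loss = 1 − smooth_cindex + 0.01 * Σ parameter²

evaluated full-batch with Adam. Evaluation follows a pretraining plus
repeated cross-validation protocol (10 folds × 5 repeats → 50 test values,
5 folds for cohorts under 50 patients). The attention map is then mined for
biomarkers: per-gene aggregate attention weights (row + column + diagonal),
optional mutation-frequency normalisation, top-10 ranking, gene-ablation
retraining with an ANOVA comparison, Kaplan–Meier/log-rank reporting, and
response-rate-based patient stratification.

A synthetic-cohort generator (`simulate_cohort()`) produces all four input
files — binary mutation matrix, cBioPortal-style clinical table, directed
edge list, embedding table — from an exponential proportional-hazards model
with planted gene and gene-pair effects, so the whole pipeline is testable
end to end with known ground truth.

## Worked example

```r
library(attnsurv)

b      <- simulate_cohort(strong_signal_config(seed = 11))  # planted pair G001-G002
coh    <- cohort(b$mutations, b$survival)
priors <- graph_priors(b$graph)
emb    <- cohort_embedding(coh$mutations, b$embeddings)

cv <- run_protocol(coh, priors, emb, folds = 2, repeats = 1, seed = 11)
print(cv)
#> Cross-validated c-index: 0.563 +/- 0.001 (SE) over 2 values (2 folds x 1 repeats)

cindex(-b$truth$risk, b$survival$time, b$survival$event)   # generative oracle
#> [1] 0.6918468

ens <- train_discovery_ensemble(coh, priors, emb, seed = 11)
rk  <- discover_biomarkers(ens, coh$mutations, emb, k = 10)
rk$gene
#>  [1] "G036" "G003" "G045" "G043" "G024" "G001" "G002" "G034" "G033" "G050"
```

The protocol's mean test c-index (0.563) sits above the 0.5 of an
uninformative score and below the oracle concordance of the true generative
risk (0.692) — the gap is estimation error at 300 patients with 50 genes
and censoring. Both planted genes appear in the top-10 attention ranking
(positions 6 and 7 here; recovery of both is not guaranteed on every cohort
draw — the vignette quantifies this). `ablate_and_rerun()` then confirms
that removing them lowers the achievable test c-index.

Real data enter through `read_mutation_matrix()` (binary matrix or
MAF-style calls), `read_survival()` (cBioPortal `PATIENT_ID` /
`OS_MONTHS` / `OS_STATUS` dialect), `read_edge_list()` and
`load_embedding_table()`; `filter_rare_genes()` applies the 1%-of-cohort
rarity filter. A thin command-line front end over the same functions ships
in `inst/cli/attnsurv.R` (commands: simulate, preprocess, priors, train,
biomarkers, ablate, stratify).

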