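# Interpretation of a trained model: attention averaging, biomarker ranking
# with mutation-frequency normalisation, gene-ablation retraining,
# Kaplan-Meier / log-rank reporting, mismatch-repair grouping, score-based
# stratification and map downsampling for display.

#' Average attention maps across patients
#'
#' @param maps per-patient genes x genes matrices: a list of matrices or a
#'   3-d array (patients, genes, genes), e.g. the `normalized` component of
#'   [model_forward()].
#' @return genes x genes matrix, the elementwise mean.
#' @export
average_attention <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3) {
    if (dim(maps)[1] < 1) stop("no attention maps supplied")
    out <- apply(maps, c(2, 3), mean)
    return(out)
  }
  if (!is.list(maps) || !length(maps)) stop("no attention maps supplied")
  Reduce(`+`, maps) / length(maps)
}

#' Per-gene aggregate attention weight
#'
#' For gene i, sums the downstream interactions (row i off-diagonal), the
#' upstream interactions (column i off-diagonal) and the self-attention
#' (diagonal): `weight(i) = rowSum_i + colSum_i - att(i,i)`.
#'
#' @param att square genes x genes attention matrix.
#' @return named numeric vector of raw weights.
#' @export
gene_weights <- function(att) {
  att <- as.matrix(att)
  if (nrow(att) != ncol(att)) stop("attention matrix must be square")
  w <- rowSums(att) + colSums(att) - diag(att)
  names(w) <- rownames(att)
  w
}

#' Rank biomarkers by frequency-normalised attention
#'
#' Aggregate per-gene attention weights are divided by each gene's mutation
#' frequency (proportion of patients mutated), so rarely mutated genes with
#' high attention can compete with common ones; genes never mutated in the
#' cohort are excluded with a message. Ties break by gene name.
#'
#' @param att genes x genes attention matrix (e.g. a patient-averaged map
#'   from [model_forward()] or [raw_attention_map()]).
#' @param m the cohort [mutation_matrix], gene order matching `att`.
#' @param k number of top genes to return (default 10).
#' @param normalize rank by the frequency-normalised weight (default) or by
#'   the raw aggregate weight; both columns are always reported.
#' @return data.frame with columns `gene`, `raw_weight`,
#'   `mutation_frequency`, `normalized_weight`, `rank` (top `k` rows).
#' @export
rank_biomarkers <- function(att, m, k = 10, normalize = TRUE) {
  check_gene_order(colnames(att) %||% colnames(m), colnames(m),
                   "attention matrix and mutation matrix")
  if (nrow(att) != ncol(m)) stop("attention matrix does not match gene count")
  w <- gene_weights(att)
  freq <- colMeans(m)
  if (all(freq == 0)) stop("degenerate cohort: no gene is ever mutated")
  if (any(freq == 0))
    message(sum(freq == 0), " never-mutated gene(s) excluded from ranking")
  keep <- freq > 0
  tab <- data.frame(gene = colnames(m)[keep],
                    raw_weight = unname(w[keep]),
                    mutation_frequency = unname(freq[keep]),
                    stringsAsFactors = FALSE)
  tab$normalized_weight <- tab$raw_weight / tab$mutation_frequency
  key <- if (normalize) tab$normalized_weight else tab$raw_weight
  ord <- order(-key, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  utils::head(tab, k)
}

#' Patient-averaged raw attention map
#'
#' The prior bias terms of the attention map are identical for every
#' patient; the patient-specific, learned part is the raw attention term.
#' Because a patient's input rows are the embedding rows masked by their
#' mutation profile, its patient average has the closed form
#' `S * comutation`, where `S` is the gene-level raw-attention kernel
#' (embeddings through the two projections) and `comutation(i,j)` the
#' fraction of patients in whom genes i and j are both mutated.
#'
#' @param model an `attnsurv_model` (or list of models, averaged as an
#'   ensemble before masking).
#' @param mut the cohort [mutation_matrix].
#' @param emb cohort-aligned embedding matrix.
#' @return genes x genes matrix (signed); take `abs()` for importance
#'   ranking.
#' @export
raw_attention_map <- function(model, mut, emb) {
  models <- if (inherits(model, "attnsurv_model")) list(model) else model
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, TRUE, "attnsurv_model")))
  S <- 0
  for (m in models)
    S <- S + (emb %*% m$Wq) %*% t(emb %*% m$Wk) / sqrt(m$d_k)
  S <- S / length(models)
  comut <- crossprod(unclass(mut)) / nrow(mut)
  out <- S * comut
  dimnames(out) <- list(colnames(mut), colnames(mut))
  out
}

#' Discover biomarkers from trained models
#'
#' Builds the magnitude of the ensemble-averaged raw attention map (see
#' [raw_attention_map()]) and ranks genes by their aggregate attention
#' weight. Averaging the attention kernel over several independently trained
#' models (e.g. the fold checkpoints of [run_protocol()]) suppresses
#' initialisation noise. Frequency normalisation is exposed but off by
#' default here: at desk-scale cohort sizes the attention magnitudes of
#' rarely mutated genes are estimated from a handful of patients, and
#' dividing by frequency amplifies that noise past the signal (see the
#' methods vignette).
#'
#' @param models an `attnsurv_model` or list of them (e.g. `cv$models` from
#'   [run_protocol()] with `keep_models = TRUE`).
#' @param mut the cohort [mutation_matrix].
#' @param emb cohort-aligned embedding matrix.
#' @param k number of top genes (default 10).
#' @param normalize divide weights by mutation frequency before ranking.
#' @return a biomarker ranking data.frame, see [rank_biomarkers()].
#' @export
discover_biomarkers <- function(models, mut, emb, k = 10, normalize = FALSE) {
  map <- abs(raw_attention_map(models, mut, emb))
  rank_biomarkers(map, mut, k = k, normalize = normalize)
}

#' Ablate genes and re-run the evaluation protocol
#'
#' Removes the given genes from the cohort, recomputes graph priors on the
#' induced subgraph, re-runs the full cross-validated protocol, and compares
#' the with/without c-index distributions by one-way ANOVA.
#'
#' @param coh an `attnsurv_cohort`.
#' @param graph the full interaction igraph (priors are re-derived on the
#'   induced subgraph, since paths through removed genes disappear).
#' @param emb_table full embedding table (genes x d_k, rownames = genes).
#' @param genes_to_remove character vector, subset of the cohort genes.
#' @param ... protocol arguments passed to [run_protocol()] (folds, repeats,
#'   epochs, lr, seed, ...).
#' @return list with `full` and `ablated` `cv_result`s and `p_value` from a
#'   one-way ANOVA on the per-cell test c-indices.
#' @export
ablate_and_rerun <- function(coh, graph, emb_table, genes_to_remove, ...) {
  genes <- colnames(coh$mutations)
  missing <- setdiff(genes_to_remove, genes)
  if (length(missing))
    stop("gene(s) not in cohort: ", paste(missing, collapse = ", "))
  keep <- setdiff(genes, genes_to_remove)
  if (!length(keep)) stop("ablation removes every gene")
  priors_full <- subset_priors(graph, genes)
  full <- run_protocol(coh, priors_full,
                       cohort_embedding(coh$mutations, emb_table), ...)
  m2 <- mutation_matrix(unclass(coh$mutations)[, keep, drop = FALSE])
  coh2 <- cohort(m2, coh$survival, name = coh$name)
  priors_abl <- subset_priors(graph, keep)
  ablated <- run_protocol(coh2, priors_abl,
                          cohort_embedding(coh2$mutations, emb_table), ...)
  vals <- c(full$results$cindex, ablated$results$cindex)
  grp <- factor(rep(c("full", "ablated"),
                    c(nrow(full$results), nrow(ablated$results))))
  p <- stats::anova(stats::lm(vals ~ grp))[["Pr(>F)"]][1]
  list(full = full, ablated = ablated, p_value = p)
}

#' Kaplan-Meier curves by mutation status of one gene
#'
#' @param surv survival data.frame (`patient_id`, `time`, `event`).
#' @param m the [mutation_matrix], rows covering the survival patients.
#' @param gene gene symbol.
#' @return list with `fit` (a [survival::survfit] object over the two
#'   groups), `p_value` (log-rank), and the per-patient `group` factor.
#' @export
km_by_mutation <- function(surv, m, gene) {
  gene <- toupper(gene)
  if (!gene %in% colnames(m)) stop("gene not in mutation matrix: ", gene)
  status <- m[surv$patient_id, gene]
  group <- factor(ifelse(status == 1, "Mut", "Wt"), levels = c("Mut", "Wt"))
  if (length(unique(group)) < 2)
    stop("all patients fall in one group for gene ", gene)
  df <- data.frame(time = surv$time, event = surv$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  list(fit = fit, p_value = p, group = group)
}

#' Stratify patients into responders and non-responders
#'
#' Labels the top `response_rate` fraction of predictive scores as
#' responders (the clinical response rate of the cancer type supplies the
#' threshold the model itself cannot know). When a survival table is given,
#' the two groups are compared by a log-rank test.
#'
#' @param scores named numeric vector of predictive scores (names = patient
#'   ids).
#' @param response_rate fraction in (0, 1), e.g. 0.17 for breast cancer.
#' @param surv optional survival data.frame for the log-rank comparison.
#' @return list with `labels` (factor `responder`/`non-responder` named by
#'   patient), `threshold`, `response_rate`, and when `surv` is given
#'   `logrank_chisq` and `p_value`.
#' @export
stratify <- function(scores, response_rate, surv = NULL) {
  stopifnot(response_rate > 0, response_rate < 1)
  n <- length(scores)
  ids <- names(scores) %||% as.character(seq_len(n))
  if (length(unique(scores)) == 1)
    warning("all scores tied; stratifying by stable patient-id order")
  n_resp <- max(1L, min(n - 1L, round(response_rate * n)))
  ord <- order(-scores, ids)
  lab <- rep("non-responder", n)
  lab[ord[seq_len(n_resp)]] <- "responder"
  labels <- factor(lab, levels = c("responder", "non-responder"))
  names(labels) <- ids
  out <- list(labels = labels,
              threshold = min(scores[ord[seq_len(n_resp)]]),
              response_rate = response_rate)
  if (!is.null(surv)) {
    keep <- match(ids, surv$patient_id)
    if (anyNA(keep)) stop("scores name patients absent from survival table")
    df <- data.frame(time = surv$time[keep], event = surv$event[keep],
                     group = labels)
    lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    out$logrank_chisq <- lr$chisq
    out$p_value <- stats::pchisq(lr$chisq, df = length(lr$n) - 1,
                                 lower.tail = FALSE)
  }
  out
}

#' Mismatch-repair mutation status
#'
#' A patient is labelled `Mut` when at least one of MLH1, MSH2, MSH3, MSH6,
#' PMS2 is mutated, else `Wt`. Genes missing from the panel count as
#' wildtype with a warning. This mutation-based proxy does not coincide with
#' the clinical dMMR/MSI definition.
#'
#' @param m a [mutation_matrix].
#' @return named factor (`Mut`/`Wt`) per patient.
#' @export
infer_mmr_status <- function(m) {
  mmr <- c("MLH1", "MSH2", "MSH3", "MSH6", "PMS2")
  present <- intersect(mmr, colnames(m))
  if (length(present) < length(mmr))
    warning("MMR gene(s) absent from panel, treated as wildtype: ",
            paste(setdiff(mmr, present), collapse = ", "))
  hit <- if (length(present)) {
    rowSums(unclass(m)[, present, drop = FALSE]) > 0
  } else rep(FALSE, nrow(m))
  out <- factor(ifelse(hit, "Mut", "Wt"), levels = c("Mut", "Wt"))
  names(out) <- rownames(m)
  out
}

#' Rank correlation of scores with a clinical covariate
#'
#' Spearman correlation, used e.g. to relate predictive scores to tumor
#' mutation burden when a TMB column is available.
#'
#' @param scores predictive scores.
#' @param covariate paired numeric covariate values.
#' @return list with `rho` and `p_value`.
#' @export
score_vs_covariate <- function(scores, covariate) {
  stopifnot(length(scores) == length(covariate), length(scores) >= 3,
            all(is.finite(scores)), all(is.finite(covariate)))
  if (length(unique(covariate)) == 1)
    stop("constant covariate: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(scores, covariate,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Downsample an attention map for display
#'
#' Block-mean pooling over contiguous gene blocks (blocks as equal-sized as
#' possible), e.g. a 296 x 296 map displayed as 30 x 30.
#'
#' @param att genes x genes matrix.
#' @param out_size output dimension, at most the number of genes.
#' @return out_size x out_size matrix of block means.
#' @export
downsample_map <- function(att, out_size = 30) {
  g <- nrow(att)
  if (out_size > g) stop("out_size exceeds the number of genes")
  bounds <- round(seq(0, g, length.out = out_size + 1))
  blocks <- lapply(seq_len(out_size),
                   function(b) (bounds[b] + 1):bounds[b + 1])
  out <- matrix(0, out_size, out_size)
  for (i in seq_len(out_size))
    for (j in seq_len(out_size))
      out[i, j] <- mean(att[blocks[[i]], blocks[[j]], drop = FALSE])
  out
}
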