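# Gene embeddings: map binary mutation rows to per-patient gene x d_k
# matrices. Embeddings are fixed inputs, never trained.

#' Load a gene embedding table
#'
#' TSV with one row per gene: gene symbol followed by `d_k` numeric columns.
#' No header is required; `#`-prefixed lines are skipped. The embedding
#' dimension is inferred from the file, not hard-coded.
#'
#' @param path path to the embedding TSV.
#' @return numeric matrix (genes x d_k) with gene symbols as row names.
#' @export
load_embedding_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty embedding table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged embedding table: rows with ", paste(unique(widths) - 1L,
         collapse = " vs "), " values")
  d_k <- widths[1] - 1L
  if (d_k < 1) stop("embedding table has no numeric columns")
  genes <- toupper(vapply(fields, `[[`, "", 1L))
  vecs <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(d_k)))
  if (anyNA(vecs) || any(!is.finite(vecs)))
    stop("non-finite embedding value in ", path)
  if (anyDuplicated(genes)) stop("duplicate gene in embedding table")
  rownames(vecs) <- genes
  vecs
}

#' Embed patients as gene x d_k matrices
#'
#' Each mutated gene is replaced by its embedding vector; wildtype genes
#' become zero vectors. Returns a 3-d array of shape
#' (patients, genes, d_k).
#'
#' @param m a [mutation_matrix].
#' @param table embedding matrix from [load_embedding_table()] or
#'   [synth_embeddings()].
#' @param missing_policy what to do when a cohort gene is absent from the
#'   table: `"error"` stops naming the gene; `"zero"` embeds it as the zero
#'   vector (even when mutated) with a warning.
#' @return numeric array (n_patients, n_genes, d_k) with dimnames.
#' @export
embed_patients <- function(m, table, missing_policy = c("error", "zero")) {
  missing_policy <- match.arg(missing_policy)
  genes <- colnames(m)
  absent <- setdiff(genes, rownames(table))
  if (length(absent)) {
    if (missing_policy == "error")
      stop("gene(s) absent from embedding table: ",
           paste(absent, collapse = ", "))
    warning(length(absent), " gene(s) absent from embedding table embed as zeros: ",
            paste(absent, collapse = ", "))
  }
  d_k <- ncol(table)
  emb <- matrix(0, length(genes), d_k, dimnames = list(genes, NULL))
  present <- intersect(genes, rownames(table))
  emb[present, ] <- table[present, , drop = FALSE]
  n <- nrow(m)
  out <- array(0, dim = c(n, length(genes), d_k),
               dimnames = list(rownames(m), genes, NULL))
  for (i in seq_len(n)) out[i, , ] <- m[i, ] * emb
  out
}

#' Cohort-aligned embedding matrix
#'
#' Returns the genes x d_k matrix aligned to the columns of `m`, with zero
#' rows for genes absent from the table. This factorised form (mutation mask
#' times embedding matrix) is what the trainer consumes.
#'
#' @inheritParams embed_patients
#' @return numeric matrix (n_genes, d_k) in the gene order of `m`.
#' @export
cohort_embedding <- function(m, table, missing_policy = c("error", "zero")) {
  missing_policy <- match.arg(missing_policy)
  genes <- colnames(m)
  absent <- setdiff(genes, rownames(table))
  if (length(absent) && missing_policy == "error")
    stop("gene(s) absent from embedding table: ",
         paste(absent, collapse = ", "))
  emb <- matrix(0, length(genes), ncol(table), dimnames = list(genes, NULL))
  present <- intersect(genes, rownames(table))
  emb[present, ] <- table[present, , drop = FALSE]
  emb
}

#' Generate synthetic gene embeddings
#'
#' Standard-normal vectors scaled to unit Euclidean norm, reproducible by
#' seed. When an interaction graph and a `min_cosine` target are supplied,
#' genes of the same weakly connected component share a common direction so
#' that any two of them have cosine similarity at least `min_cosine` --
#' a crude stand-in for the co-expression structure that pretrained
#' embeddings carry.
#'
#' @param gene_names character vector of gene symbols.
#' @param d_k embedding dimension (default 50).
#' @param seed integer seed.
#' @param graph optional igraph object over (a superset of) `gene_names`.
#' @param min_cosine lower bound for the cosine similarity of graph-connected
#'   genes, in `[0, 1)`; 0 disables the blending.
#' @return numeric matrix (genes x d_k), unit-norm rows.
#' @export
synth_embeddings <- function(gene_names, d_k = 50, seed = 1L,
                             graph = NULL, min_cosine = 0) {
  stopifnot(d_k >= 1, min_cosine >= 0, min_cosine < 1)
  gene_names <- toupper(gene_names)
  set.seed(seed)
  vecs <- matrix(stats::rnorm(length(gene_names) * d_k),
                 length(gene_names), d_k,
                 dimnames = list(gene_names, NULL))
  vecs <- vecs / sqrt(rowSums(vecs^2))
  if (!is.null(graph) && min_cosine > 0) {
    comp <- igraph::components(graph, mode = "weak")
    memb <- comp$membership[gene_names]
    cc <- sqrt((1 + min_cosine) / 2)  # shared-component weight: worst-case
                                      # pairwise cosine is 2*cc^2 - 1
    for (k in unique(memb[!is.na(memb)])) {
      idx <- which(memb == k)
      if (length(idx) < 2) next
      u <- stats::rnorm(d_k); u <- u / sqrt(sum(u^2))
      for (i in idx) {
        v <- vecs[i, ] - sum(vecs[i, ] * u) * u
        nv <- sqrt(sum(v^2))
        v <- if (nv > 1e-12) v / nv else rep(0, d_k)
        vecs[i, ] <- cc * u + sqrt(1 - cc^2) * v
      }
    }
    vecs <- vecs / sqrt(rowSums(vecs^2))
  }
  vecs
}
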