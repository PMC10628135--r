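# Directed gene-interaction graph and the three biology-prior matrices that
# bias the attention map: reciprocal shortest-path length ("pathway"),
# summed closeness centrality ("connection") and a reachability penalty
# ("padding").

#' Read a two-column edge list
#'
#' @param path TSV with columns source gene, target gene; `#` comments and a
#'   header line are tolerated (a header is any first line whose tokens
#'   repeat nowhere as both source and target -- in practice we simply treat
#'   every row as an edge, so provide headerless files).
#' @return data.frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("edge list needs two columns: ", path)
  data.frame(from = toupper(as.character(tab[[1]])),
             to = toupper(as.character(tab[[2]])),
             stringsAsFactors = FALSE)
}

#' Build the cohort interaction graph
#'
#' Keeps only edges whose endpoints are both cohort genes, adds every cohort
#' gene as a node (isolated if unreferenced), and collapses duplicate edges
#' and self-loops. Edges are directed: source acts upon target, so mutations
#' propagate downstream.
#'
#' @param edges data.frame with columns `from`, `to` (gene symbols), or a
#'   two-column matrix.
#' @param cohort_genes character vector of gene symbols fixing the node set.
#' @return a directed `igraph` object whose vertex order is `cohort_genes`.
#' @export
build_graph <- function(edges, cohort_genes) {
  if (!length(cohort_genes)) stop("cohort gene list is empty")
  cohort_genes <- toupper(cohort_genes)
  if (anyDuplicated(cohort_genes)) stop("duplicate cohort genes")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  from <- toupper(as.character(edges[[1]]))
  to <- toupper(as.character(edges[[2]]))
  keep <- from %in% cohort_genes & to %in% cohort_genes & from != to
  el <- unique(data.frame(from = from[keep], to = to[keep],
                          stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = cohort_genes, stringsAsFactors = FALSE))
  g
}

#' Reciprocal shortest-path matrix
#'
#' Entry (i, j), i != j, is 1 / L where L is the directed shortest-path
#' length (in hops) from gene i to gene j, or 0 when j is unreachable from
#' i. The diagonal is 1 by convention: a gene is maximally close to itself,
#' which keeps self-attention meaningful.
#'
#' @param g igraph object from [build_graph()].
#' @param mode `"out"` (directed reachability, default) or `"all"`
#'   (undirected).
#' @return numeric genes x genes matrix with entries in `{0} U {1/k}`.
#' @export
pathway_matrix <- function(g, mode = c("out", "all")) {
  mode <- match.arg(mode)
  d <- igraph::distances(g, mode = mode, algorithm = "unweighted")
  p <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(p) <- 1
  dimnames(p) <- dimnames(d)
  p
}

#' Closeness-centrality sum matrix
#'
#' Entry (i, j) is centrality_i + centrality_j. The default centrality is
#' closeness under the Wasserman-Faust correction for disconnected directed
#' graphs: for node v with r_v nodes reachable (excluding itself) at total
#' distance s_v, closeness(v) = (r_v / (n - 1)) * (r_v / s_v); an isolated
#' node scores 0. Distances are taken over outgoing edges, reflecting
#' downstream influence. `centrality = "degree"` uses total degree / (n-1)
#' instead.
#'
#' @param g igraph object.
#' @param centrality `"closeness"` (default) or `"degree"`.
#' @param mode distance direction for closeness.
#' @return symmetric numeric genes x genes matrix.
#' @export
connection_matrix <- function(g, centrality = c("closeness", "degree"),
                              mode = c("out", "all")) {
  centrality <- match.arg(centrality)
  mode <- match.arg(mode)
  n <- igraph::vcount(g)
  if (centrality == "closeness") {
    d <- igraph::distances(g, mode = mode, algorithm = "unweighted")
    diag(d) <- Inf
    reach <- rowSums(is.finite(d))
    tot <- rowSums(ifelse(is.finite(d), d, 0))
    cen <- ifelse(reach > 0 & n > 1, (reach / (n - 1)) * (reach / tot), 0)
  } else {
    cen <- if (n > 1) igraph::degree(g, mode = "all") / (n - 1) else 0
  }
  m <- outer(cen, cen, `+`)
  dimnames(m) <- list(igraph::V(g)$name, igraph::V(g)$name)
  m
}

#' Reachability penalty matrix
#'
#' Entry (i, j) is 0 when a directed path i -> j exists and -1 otherwise;
#' the diagonal is 0, so self-attention is never penalised.
#'
#' @inheritParams pathway_matrix
#' @return numeric genes x genes matrix with entries in `{0, -1}`.
#' @export
padding_matrix <- function(g, mode = c("out", "all")) {
  mode <- match.arg(mode)
  d <- igraph::distances(g, mode = mode, algorithm = "unweighted")
  p <- ifelse(is.finite(d), 0, -1)
  diag(p) <- 0
  dimnames(p) <- dimnames(d)
  p
}

#' Compute all three graph priors
#'
#' @inheritParams connection_matrix
#' @return object of class `graph_priors`: list with `gene_names`,
#'   `pathway`, `connection`, `padding`.
#' @export
graph_priors <- function(g, centrality = c("closeness", "degree"),
                         mode = c("out", "all")) {
  centrality <- match.arg(centrality)
  mode <- match.arg(mode)
  out <- list(gene_names = igraph::V(g)$name,
              pathway = pathway_matrix(g, mode = mode),
              connection = connection_matrix(g, centrality = centrality,
                                             mode = mode),
              padding = padding_matrix(g, mode = mode))
  class(out) <- "graph_priors"
  out
}

#' Subset graph priors to a gene set
#'
#' Used by ablation: restricting the attention model to fewer genes requires
#' priors recomputed on the induced subgraph (paths through removed genes
#' disappear), so this re-derives them from the graph rather than slicing
#' matrices.
#'
#' @param g the full igraph object.
#' @param genes genes to keep.
#' @inheritParams connection_matrix
#' @return `graph_priors` on the induced subgraph.
#' @export
subset_priors <- function(g, genes, centrality = c("closeness", "degree"),
                          mode = c("out", "all")) {
  sub <- igraph::induced_subgraph(g, vids = genes)
  # induced_subgraph may reorder; restore requested order
  perm <- match(genes, igraph::V(sub)$name)
  sub <- igraph::permute(sub, order(perm))
  graph_priors(sub, centrality = match.arg(centrality), mode = match.arg(mode))
}

#' Persist / restore graph priors
#'
#' Prior matrices are computed once per cohort (graph construction is the
#' scaling bottleneck) and cached.
#'
#' @param priors a `graph_priors` object.
#' @param path file path for the cache.
#' @return `read_graph_priors` returns the `graph_priors` object.
#' @export
write_graph_priors <- function(priors, path) {
  stopifnot(inherits(priors, "graph_priors"))
  saveRDS(priors, path)
  invisible(path)
}

#' @rdname write_graph_priors
#' @export
read_graph_priors <- function(path) {
  priors <- readRDS(path)
  if (!inherits(priors, "graph_priors")) stop("not a graph_priors cache: ", path)
  priors
}

check_gene_order <- function(a, b, what = "inputs") {
  if (length(a) != length(b) || any(a != b))
    stop("gene order mismatch between ", what,
         "; align inputs before calling")
  invisible(TRUE)
}
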