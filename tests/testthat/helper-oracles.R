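# Independent brute-force oracles used to check the package implementations.
# These are deliberately naive (triple loops, exhaustive enumeration) and
# share no code with the package.

# All-pairs shortest directed path lengths by Floyd-Warshall on an adjacency
# matrix; Inf = unreachable, 0 on the diagonal.
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1 & row(adj) != col(adj)] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_pathway <- function(adj) {
  d <- oracle_shortest_paths(adj)
  p <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(p) <- 1
  p
}

oracle_padding <- function(adj) {
  d <- oracle_shortest_paths(adj)
  p <- ifelse(is.finite(d), 0, -1)
  diag(p) <- 0
  p
}

# Wasserman-Faust closeness over outgoing breadth-first-search distances.
oracle_closeness <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    dist <- rep(Inf, n)
    dist[v] <- 0
    frontier <- v
    step <- 0
    while (length(frontier)) {
      step <- step + 1
      nxt <- integer(0)
      for (u in frontier)
        nxt <- union(nxt, which(adj[u, ] == 1 & is.infinite(dist)))
      nxt <- setdiff(nxt, v)
      dist[nxt] <- step
      frontier <- nxt
    }
    reach <- sum(is.finite(dist)) - 1
    tot <- sum(dist[is.finite(dist)])
    if (reach > 0 && n > 1) (reach / (n - 1)) * (reach / tot) else 0
  }, numeric(1))
}

oracle_connection <- function(adj) {
  cen <- oracle_closeness(adj)
  outer(cen, cen, `+`)
}

# Exhaustive double-loop concordance index: ordered pairs (i, j) with i the
# shorter-surviving comparable patient, each unordered pair counted once.
oracle_cindex <- function(scores, times, events) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comp <- (times[i] < times[j] && events[i] == 1) ||
      (times[i] == times[j] && events[i] == 1 && events[j] == 0)
    if (!comp) next
    den <- den + 1
    if (scores[j] > scores[i]) num <- num + 1
    else if (scores[j] == scores[i]) num <- num + 0.5
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Random directed graph as adjacency matrix + the matching igraph object.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(rbinom(n * n, 1, p), n, n)
  diag(adj) <- 0
  genes <- sprintf("G%02d", seq_len(n))
  dimnames(adj) <- list(genes, genes)
  idx <- which(adj == 1, arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                      stringsAsFactors = FALSE)
  list(adj = adj, graph = build_graph(edges, genes), genes = genes)
}

# Small random censored survival dataset.
random_survival <- function(n, seed) {
  set.seed(seed)
  list(times = round(rexp(n, 0.1), 2),
       events = rbinom(n, 1, 0.6),
       scores = rnorm(n))
}

# Tiny deterministic cohort for training plumbing tests: a handful of genes,
# one of which carries a strong survival effect.
toy_cohort <- function(n = 60, n_genes = 8, seed = 1) {
  cfg <- simulation_config(n_patients = n, n_genes = n_genes,
                           mutation_freqs = rep(0.3, n_genes),
                           d_k = 4, beta = c(G001 = 1.5),
                           graph_param = 0.3, seed = seed)
  b <- simulate_cohort(cfg)
  list(bundle = b,
       coh = cohort(b$mutations, b$survival),
       priors = graph_priors(b$graph),
       emb = cohort_embedding(b$mutations, b$embeddings))
}
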