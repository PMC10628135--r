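# Synthetic cohorts with the statistical structure the method assumes:
# Bernoulli mutation matrices with per-gene frequencies, a directed random
# interaction graph, unit-norm Gaussian embeddings, and survival times from
# an exponential proportional-hazards model with planted per-gene and
# gene-pair log-hazard effects plus independent exponential censoring.
# Planted effects are recorded so recovery can be tested end to end.

#' Simulation configuration
#'
#' @param n_patients cohort size (default 300).
#' @param n_genes panel size (default 50).
#' @param mutation_freqs optional per-gene Bernoulli rates (named or in gene
#'   order); when NULL, rates are drawn log-uniformly from `freq_range`,
#'   emulating the sparse frequency spectrum of panel-sequencing cohorts.
#' @param freq_range range for drawn mutation frequencies.
#' @param graph_model `"erdos_renyi"` (parameter = edge probability) or
#'   `"scale_free"` (parameter = out-edges per node, preferential
#'   attachment).
#' @param graph_param parameter of the graph model; the default edge
#'   probability 0.07 matches the edge density of a 296-gene interaction
#'   panel with ~6000 directed edges.
#' @param d_k embedding dimension (default 50).
#' @param beta named numeric vector of per-gene log-hazard effects (sparse;
#'   unnamed genes have effect 0).
#' @param gamma data.frame with columns `from`, `to`, `effect`: gene-pair
#'   interaction log-hazard effects, planted on graph edges (missing edges
#'   are added so the interaction is graph-visible).
#' @param baseline_rate exponential baseline hazard per month (default 0.05,
#'   median survival ~14 months at null).
#' @param censor_rate independent exponential censoring rate per month
#'   (default 0.02; 0 disables censoring).
#' @param embedding_min_cosine cosine-similarity floor for graph-adjacent
#'   genes in the synthetic embeddings (0 = independent embeddings).
#' @param seed integer seed; fully determines every generated object.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 300, n_genes = 50,
                              mutation_freqs = NULL,
                              freq_range = c(0.02, 0.4),
                              graph_model = c("erdos_renyi", "scale_free"),
                              graph_param = 0.07, d_k = 50,
                              beta = NULL, gamma = NULL,
                              baseline_rate = 0.05, censor_rate = 0.02,
                              embedding_min_cosine = 0, seed = 1L) {
  graph_model <- match.arg(graph_model)
  stopifnot(n_patients >= 2, n_genes >= 2, d_k >= 1,
            baseline_rate > 0, censor_rate >= 0,
            freq_range[1] > 0, freq_range[2] < 1,
            freq_range[1] <= freq_range[2])
  if (!is.null(mutation_freqs))
    stopifnot(all(mutation_freqs > 0), all(mutation_freqs < 1))
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (!is.null(beta)) {
    stopifnot(!is.null(names(beta)), all(names(beta) %in% genes))
  }
  if (!is.null(gamma)) {
    gamma <- as.data.frame(gamma)
    stopifnot(all(c("from", "to", "effect") %in% names(gamma)),
              all(gamma$from %in% genes), all(gamma$to %in% genes))
  }
  out <- list(n_patients = n_patients, n_genes = n_genes,
              gene_names = genes, mutation_freqs = mutation_freqs,
              freq_range = freq_range, graph_model = graph_model,
              graph_param = graph_param, d_k = d_k, beta = beta,
              gamma = gamma, baseline_rate = baseline_rate,
              censor_rate = censor_rate,
              embedding_min_cosine = embedding_min_cosine,
              seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

#' Null configuration: no planted effects
#'
#' @param seed integer seed.
#' @param n_patients,n_genes cohort dimensions.
#' @param ... further arguments to [simulation_config()].
#' @return `sim_config` with beta = gamma = NULL.
#' @export
null_config <- function(seed, n_patients = 200, n_genes = 30, ...) {
  simulation_config(n_patients = n_patients, n_genes = n_genes,
                    beta = NULL, gamma = NULL, seed = seed, ...)
}

#' Strong-signal configuration: one planted connected gene pair
#'
#' Two genes at mutation frequency 0.3 carry per-gene log-hazard effects of
#' 1.0 each plus an interaction effect of 1.0 on their connecting edge;
#' 300 patients, 50 genes.
#'
#' @param seed integer seed.
#' @param effect log-hazard effect size for both genes and their pair.
#' @param ... further arguments to [simulation_config()].
#' @return `sim_config`.
#' @export
strong_signal_config <- function(seed, effect = 1.0, ...) {
  cfg <- simulation_config(
    n_patients = 300, n_genes = 50,
    beta = c(G001 = effect, G002 = effect),
    gamma = data.frame(from = "G001", to = "G002", effect = effect),
    seed = seed, ...)
  cfg$mutation_freqs <- NULL
  cfg$planted_freq <- 0.3
  cfg
}

#' Simulate the interaction graph
#'
#' @param config a `sim_config`.
#' @return directed igraph over the configured gene names; any planted
#'   interaction pair absent from the random draw is added as an edge.
#' @export
simulate_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- switch(config$graph_model,
    erdos_renyi = {
      stopifnot(config$graph_param >= 0, config$graph_param <= 1)
      igraph::sample_gnp(config$n_genes, config$graph_param, directed = TRUE)
    },
    scale_free = {
      stopifnot(config$graph_param >= 1)
      igraph::sample_pa(config$n_genes, m = config$graph_param,
                        directed = TRUE)
    })
  igraph::V(g)$name <- config$gene_names
  if (!is.null(config$gamma)) {
    for (r in seq_len(nrow(config$gamma))) {
      a <- config$gamma$from[r]; b <- config$gamma$to[r]
      if (!igraph::are_adjacent(g, a, b)) g <- igraph::add_edges(g, c(a, b))
    }
  }
  g
}

resolve_freqs <- function(config) {
  set.seed(config$seed + 1L)
  freqs <- if (is.null(config$mutation_freqs)) {
    exp(stats::runif(config$n_genes, log(config$freq_range[1]),
                     log(config$freq_range[2])))
  } else rep_len(config$mutation_freqs, config$n_genes)
  names(freqs) <- config$gene_names
  if (!is.null(config$planted_freq)) {
    planted <- unique(c(names(config$beta), config$gamma$from,
                        config$gamma$to))
    freqs[planted] <- config$planted_freq
  }
  freqs
}

#' Simulate a binary mutation matrix
#'
#' Independent Bernoulli draws per (patient, gene) at that gene's rate.
#'
#' @param config a `sim_config`.
#' @return a [mutation_matrix].
#' @export
simulate_mutations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- resolve_freqs(config)
  set.seed(config$seed + 2L)
  vals <- matrix(
    stats::rbinom(config$n_patients * config$n_genes, 1,
                  rep(freqs, each = config$n_patients)),
    config$n_patients, config$n_genes,
    dimnames = list(sprintf("P%04d", seq_len(config$n_patients)),
                    config$gene_names))
  mutation_matrix(vals)
}

planted_risk <- function(m, config) {
  lp <- rep(0, nrow(m))
  if (!is.null(config$beta))
    lp <- lp + as.numeric(unclass(m)[, names(config$beta), drop = FALSE] %*%
                            config$beta)
  if (!is.null(config$gamma))
    for (r in seq_len(nrow(config$gamma)))
      lp <- lp + config$gamma$effect[r] *
        m[, config$gamma$from[r]] * m[, config$gamma$to[r]]
  lp
}

#' Simulate survival times under proportional hazards
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(sum(beta_i x_i) + sum(gamma_ij x_i x_j))`; censoring
#' times are independent exponential at `censor_rate`. The observed time is
#' the minimum; the event indicator records whether death preceded
#' censoring.
#'
#' @param m a [mutation_matrix].
#' @param config a `sim_config`.
#' @return survival data.frame (`patient_id`, `time`, `event`).
#' @export
simulate_survival <- function(m, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(m)
  lp <- planted_risk(m, config)
  set.seed(config$seed + 3L)
  t_event <- stats::rexp(n, rate = config$baseline_rate * exp(lp))
  t_cens <- if (config$censor_rate > 0) {
    stats::rexp(n, rate = config$censor_rate)
  } else rep(Inf, n)
  data.frame(patient_id = rownames(m),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort bundle
#'
#' Generates graph, mutations, embeddings and survival, plus a truth record
#' of the planted effects and the generative risk score (whose negative is
#' the oracle predictor). When `dir` is given, the four standard input files
#' (mutation matrix, clinical table, edge list, embedding table) and a truth
#' TSV are written there, so the file-reading path is exercised exactly as
#' with real data.
#'
#' @param config a `sim_config`.
#' @param dir optional output directory.
#' @return list with `mutations`, `survival`, `graph`, `embeddings`,
#'   `truth` (list: beta, gamma, risk, genes) and `paths` when written.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  graph <- simulate_graph(config)
  m <- simulate_mutations(config)
  surv <- simulate_survival(m, config)
  embeddings <- synth_embeddings(config$gene_names, d_k = config$d_k,
                                 seed = config$seed + 4L, graph = graph,
                                 min_cosine = config$embedding_min_cosine)
  truth <- list(beta = config$beta, gamma = config$gamma,
                risk = stats::setNames(planted_risk(m, config), rownames(m)),
                genes = unique(c(names(config$beta), config$gamma$from,
                                 config$gamma$to)))
  out <- list(mutations = m, survival = surv, graph = graph,
              embeddings = embeddings, truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(mutations = file.path(dir, "mutations.tsv"),
                  clinical = file.path(dir, "clinical.tsv"),
                  edges = file.path(dir, "edges.tsv"),
                  embeddings = file.path(dir, "embeddings.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    utils::write.table(
      data.frame(PATIENT_ID = rownames(m), unclass(m), check.names = FALSE),
      paths$mutations, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(PATIENT_ID = surv$patient_id,
                 OS_MONTHS = surv$time,
                 OS_STATUS = ifelse(surv$event == 1, "1:DECEASED",
                                    "0:LIVING")),
      paths$clinical, sep = "\t", quote = FALSE, row.names = FALSE)
    el <- igraph::as_edgelist(graph)
    utils::write.table(el, paths$edges, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(
      cbind(rownames(embeddings), format(embeddings, digits = 17)),
      paths$embeddings, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(patient_id = names(truth$risk), risk = truth$risk),
      paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}
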