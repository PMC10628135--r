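# The biology-aware self-attention network. One attention layer, one head:
# raw attention from two offset-free projections, biased by the three graph
# priors through learnable scalars k1..k3, then row-softmax, a value
# projection, mean pooling over genes and a single linear read-out. Offsets
# are omitted from the projections so that wildtype genes (zero embedding
# rows) contribute exactly zero raw attention and the graph priors alone
# govern those positions.

#' Initialise an attention model
#'
#' Projections are drawn from a small-variance Gaussian (sd `init_sd`); the
#' prior mixers start at k1 = k2 = k3 = 1 so biological priors act from the
#' first epoch.
#'
#' @param d_k embedding dimension.
#' @param seed optional integer seed for reproducible initialisation.
#' @param init_sd standard deviation of the Gaussian initialiser.
#' @return object of class `attnsurv_model`.
#' @export
init_attention_model <- function(d_k, seed = NULL, init_sd = 0.02) {
  stopifnot(d_k >= 1)
  if (!is.null(seed)) set.seed(seed)
  rmat <- function() matrix(stats::rnorm(d_k * d_k, sd = init_sd), d_k, d_k)
  model <- list(
    Wq = rmat(), Wk = rmat(), Wv = rmat(),
    w_head = stats::rnorm(d_k, sd = init_sd), b_head = 0,
    k1 = 1, k2 = 1, k3 = 1,
    d_k = d_k
  )
  class(model) <- "attnsurv_model"
  model
}

param_names <- c("Wq", "Wk", "Wv", "w_head", "b_head", "k1", "k2", "k3")

#' Flatten learnable parameters
#'
#' @param model an `attnsurv_model`.
#' @return numeric vector of all learnable parameters (projections, head,
#'   and the three prior mixers).
#' @export
model_parameters <- function(model) {
  unlist(lapply(param_names, function(nm) as.numeric(model[[nm]])),
         use.names = FALSE)
}

#' Sum of squared model parameters (the L2 penalty term)
#' @param model an `attnsurv_model`.
#' @return scalar.
#' @export
param_sumsq <- function(model) sum(model_parameters(model)^2)

#' Raw (biology-unaware) attention for one patient
#'
#' `proj_q(x) %*% t(proj_k(x)) / sqrt(d_k)` for a single patient's
#' genes x d_k embedding matrix.
#'
#' @param x numeric genes x d_k matrix.
#' @param model an `attnsurv_model`.
#' @return genes x genes matrix.
#' @export
raw_attention <- function(x, model) {
  x <- as.matrix(x)
  if (ncol(x) != model$d_k)
    stop("input has ", ncol(x), " columns but model d_k is ", model$d_k)
  (x %*% model$Wq) %*% t(x %*% model$Wk) / sqrt(model$d_k)
}

#' Prior-weighted attention map
#'
#' Adds the three graph priors to a raw attention matrix:
#' `raw + k1 * pathway + k2 * connection + k3 * padding`, elementwise.
#' Gene order is verified against the priors when the raw matrix carries
#' dimnames.
#'
#' @param raw genes x genes raw attention matrix.
#' @param priors a `graph_priors` object.
#' @param k1,k2,k3 scalar mixers.
#' @return genes x genes matrix.
#' @export
weighted_attention <- function(raw, priors, k1, k2, k3) {
  stopifnot(inherits(priors, "graph_priors"))
  if (nrow(raw) != length(priors$gene_names) || ncol(raw) != nrow(raw))
    stop("raw attention matrix does not match prior dimension")
  if (!is.null(rownames(raw)))
    check_gene_order(rownames(raw), priors$gene_names,
                     "attention matrix and priors")
  raw + k1 * priors$pathway + k2 * priors$connection + k3 * priors$padding
}

row_softmax <- function(w) {
  m <- w[cbind(seq_len(nrow(w)), max.col(w, ties.method = "first"))]
  e <- exp(w - m)
  e / rowSums(e)
}

#' Forward pass: predictive scores and attention maps
#'
#' For each patient: weighted attention map (raw attention plus priors), its
#' row-wise softmax, context = softmax %*% value projection, mean pooling
#' over the gene axis, and a linear head producing a scalar score. Higher
#' scores predict better survival. Deterministic given parameters and input.
#'
#' @param model an `attnsurv_model`.
#' @param x per-patient embedding input: a 3-d array (patients, genes, d_k)
#'   from [embed_patients()], or a single genes x d_k matrix.
#' @param priors a `graph_priors` object in the same gene order as `x`.
#' @param return_maps if TRUE, also return per-patient weighted (pre-softmax)
#'   and normalised (post-softmax) maps as 3-d arrays.
#' @return list with `scores` (named numeric vector) and, when requested,
#'   `weighted` and `normalized` arrays (patients, genes, genes).
#' @export
model_forward <- function(model, x, priors, return_maps = FALSE) {
  stopifnot(inherits(model, "attnsurv_model"), inherits(priors, "graph_priors"))
  if (is.matrix(x)) x <- array(x, dim = c(1L, nrow(x), ncol(x)),
                               dimnames = list(NULL, rownames(x), NULL))
  ng <- dim(x)[2]
  if (ng != length(priors$gene_names))
    stop("input gene dimension does not match priors")
  if (!is.null(dimnames(x)[[2]]))
    check_gene_order(dimnames(x)[[2]], priors$gene_names, "input and priors")
  bias <- model$k1 * priors$pathway + model$k2 * priors$connection +
    model$k3 * priors$padding
  n <- dim(x)[1]
  scores <- numeric(n)
  if (return_maps) {
    wmaps <- array(0, dim = c(n, ng, ng))
    nmaps <- array(0, dim = c(n, ng, ng))
  }
  for (i in seq_len(n)) {
    xi <- matrix(x[i, , ], ng, model$d_k)
    w <- raw_attention(xi, model) + bias
    if (any(!is.finite(w)))
      stop("non-finite attention map for patient ",
           dimnames(x)[[1]][i] %||% i)
    a <- row_softmax(w)
    context <- a %*% (xi %*% model$Wv)
    pooled <- colMeans(context)
    scores[i] <- sum(pooled * model$w_head) + model$b_head
    if (return_maps) { wmaps[i, , ] <- w; nmaps[i, , ] <- a }
  }
  names(scores) <- dimnames(x)[[1]]
  out <- list(scores = scores)
  if (return_maps) {
    dimnames(wmaps) <- dimnames(nmaps) <-
      list(dimnames(x)[[1]], priors$gene_names, priors$gene_names)
    out$weighted <- wmaps
    out$normalized <- nmaps
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the gene order it was trained under and refuses to
#' load against a different one.
#'
#' @param model an `attnsurv_model`.
#' @param path checkpoint file path.
#' @param gene_names gene order the model was trained with.
#' @return `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path, gene_names) {
  stopifnot(inherits(model, "attnsurv_model"))
  saveRDS(list(model = model, gene_names = gene_names, d_k = model$d_k), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, gene_names) {
  ck <- readRDS(path)
  check_gene_order(ck$gene_names, gene_names, "checkpoint and cohort")
  ck$model
}
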