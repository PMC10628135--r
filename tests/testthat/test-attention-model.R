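toy_priors <- function(genes) {
  n <- length(genes)
  out <- list(gene_names = genes,
              pathway = diag(n),
              connection = matrix(0, n, n),
              padding = matrix(0, n, n))
  dimnames(out$pathway) <- dimnames(out$connection) <-
    dimnames(out$padding) <- list(genes, genes)
  class(out) <- "graph_priors"
  out
}

test_that("raw attention is the scaled bilinear form of the projections", {
  # d_k = 1 with identity projections: outer product / sqrt(1)
  model <- init_attention_model(1, seed = 1)
  model$Wq <- model$Wk <- matrix(1, 1, 1)
  x <- matrix(c(1, 2), 2, 1)
  expect_equal(unname(raw_attention(x, model)),
               matrix(c(1, 2, 2, 4), 2, 2), tolerance = 1e-12)
  # offset-free projections: zero input gives exactly zero attention
  model2 <- init_attention_model(6, seed = 2)
  expect_equal(raw_attention(matrix(0, 4, 6), model2), matrix(0, 4, 4))
  # bilinearity: scaling the input by c scales the map by c^2
  x6 <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(raw_attention(3 * x6, model2), 9 * raw_attention(x6, model2),
               tolerance = 1e-12)
  expect_error(raw_attention(matrix(0, 4, 5), model2), "d_k")
})

test_that("weighted attention mixes the priors elementwise", {
  genes <- c("A", "B")
  pri <- toy_priors(genes)
  pri$pathway <- matrix(c(1, 0.5, 0, 1), 2, 2, byrow = TRUE,
                        dimnames = list(genes, genes))
  pri$connection <- matrix(c(0.2, 0.4, 0.4, 0.6), 2, 2,
                           dimnames = list(genes, genes))
  pri$padding <- matrix(c(0, 0, -1, 0), 2, 2, byrow = TRUE,
                        dimnames = list(genes, genes))
  raw <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(genes, genes))
  expect_equal(weighted_attention(raw, pri, 0, 0, 0), raw)
  zero <- raw * 0
  expect_equal(weighted_attention(zero, pri, 1, 0, 0), pri$pathway)
  expect_equal(weighted_attention(raw, pri, 1, 1, 1),
               raw + pri$pathway + pri$connection + pri$padding)
  bad <- raw
  rownames(bad) <- colnames(bad) <- c("B", "A")
  expect_error(weighted_attention(bad, pri, 1, 1, 1), "mismatch")
})

test_that("the forward pass is deterministic and row-normalised", {
  genes <- sprintf("G%d", 1:4)
  pri <- toy_priors(genes)
  tab <- synth_embeddings(genes, d_k = 5, seed = 3)
  vals <- matrix(c(1, 0, 1, 0,
                   1, 0, 1, 0,
                   0, 1, 0, 0), 3, 4, byrow = TRUE,
                 dimnames = list(c("P1", "P2", "P3"), genes))
  x <- embed_patients(mutation_matrix(vals), tab)
  model <- init_attention_model(5, seed = 4)
  out <- model_forward(model, x, pri, return_maps = TRUE)
  expect_equal(out$scores[["P1"]], out$scores[["P2"]])  # identical patients
  expect_equal(out$weighted[1, , ], out$weighted[2, , ])
  expect_equal(unname(rowSums(out$normalized[3, , ])), rep(1, 4),
               tolerance = 1e-6)
})

test_that("scores are invariant under a consistent gene permutation", {
  set.seed(9)
  genes <- sprintf("G%d", 1:5)
  rd <- random_digraph(5, 0.4, seed = 21)
  pri <- graph_priors(rd$graph)
  pri$gene_names <- genes
  dimnames(pri$pathway) <- dimnames(pri$connection) <-
    dimnames(pri$padding) <- list(genes, genes)
  tab <- synth_embeddings(genes, d_k = 4, seed = 5)
  vals <- matrix(rbinom(3 * 5, 1, 0.5), 3, 5,
                 dimnames = list(c("P1", "P2", "P3"), genes))
  x <- embed_patients(mutation_matrix(vals), tab)
  model <- init_attention_model(4, seed = 6)
  base <- model_forward(model, x, pri)$scores
  for (rep in 1:3) {
    perm <- sample(5)
    pri_p <- pri
    pri_p$gene_names <- genes[perm]
    for (nm in c("pathway", "connection", "padding"))
      pri_p[[nm]] <- pri[[nm]][perm, perm]
    x_p <- x[, perm, , drop = FALSE]
    expect_equal(model_forward(model, x_p, pri_p)$scores, base,
                 tolerance = 1e-12)
  }
})

test_that("a large padding mixer drives attention off disconnected pairs", {
  genes <- c("A", "B", "C")
  g <- build_graph(data.frame(from = "A", to = "B"), genes)
  pri <- graph_priors(g)
  tab <- synth_embeddings(genes, d_k = 3, seed = 7)
  vals <- matrix(1L, 1, 3, dimnames = list("P1", genes))
  x <- embed_patients(mutation_matrix(vals), tab)
  model <- init_attention_model(3, seed = 8)
  model$k1 <- 0; model$k2 <- 0; model$k3 <- 50
  nm <- model_forward(model, x, pri, return_maps = TRUE)$normalized[1, , ]
  # row A: B is reachable, C is not
  expect_lt(nm["A", "C"], nm["A", "B"])
  expect_lt(nm["A", "C"], 1e-6)
})

test_that("with zeroed priors and mixers the model is plain self-attention", {
  genes <- sprintf("G%d", 1:4)
  pri_zero <- toy_priors(genes)
  pri_zero$pathway <- pri_zero$pathway * 0
  rd <- random_digraph(4, 0.5, seed = 31)
  pri_real <- graph_priors(rd$graph)
  pri_real$gene_names <- genes
  dimnames(pri_real$pathway) <- dimnames(pri_real$connection) <-
    dimnames(pri_real$padding) <- list(genes, genes)
  tab <- synth_embeddings(genes, d_k = 4, seed = 32)
  vals <- matrix(rbinom(8, 1, 0.6), 2, 4,
                 dimnames = list(c("P1", "P2"), genes))
  x <- embed_patients(mutation_matrix(vals), tab)
  model <- init_attention_model(4, seed = 33)
  model$k1 <- model$k2 <- model$k3 <- 0
  expect_equal(model_forward(model, x, pri_real)$scores,
               model_forward(model, x, pri_zero)$scores, tolerance = 1e-12)
})

test_that("the batched trainer forward agrees with the literal per-patient pass", {
  set.seed(44)
  genes <- sprintf("G%02d", 1:12)
  rd <- random_digraph(12, 0.2, seed = 44)
  pri <- graph_priors(rd$graph)
  tab <- synth_embeddings(rd$genes, d_k = 7, seed = 45)
  vals <- matrix(rbinom(20 * 12, 1, 0.3), 20, 12,
                 dimnames = list(sprintf("P%02d", 1:20), rd$genes))
  m <- mutation_matrix(vals)
  emb <- cohort_embedding(m, tab)
  model <- init_attention_model(7, seed = 46)
  fast <- predict_scores(model, m, emb, pri)
  slow <- model_forward(model, embed_patients(m, tab), pri)$scores
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(55)
  rd <- random_digraph(8, 0.3, seed = 55)
  tab <- synth_embeddings(rd$genes, d_k = 5, seed = 56)
  vals <- matrix(rbinom(25 * 8, 1, 0.35), 25, 8,
                 dimnames = list(sprintf("P%02d", 1:25), rd$genes))
  m <- mutation_matrix(vals)
  pri <- graph_priors(rd$graph)
  emb <- cohort_embedding(m, tab)
  times <- round(rexp(25, 0.1), 2)
  events <- rbinom(25, 1, 0.7)
  model <- init_attention_model(5, seed = 57)
  lg <- attnsurv:::fit_loss_grad(model, m, emb, pri, times, events)
  fd <- function(setter) {
    eps <- 1e-6
    lo <- setter(model, -eps); hi <- setter(model, eps)
    l <- function(mo) 1 - smooth_cindex(predict_scores(mo, m, emb, pri),
                                        times, events) +
      0.01 * param_sumsq(mo)
    (l(hi) - l(lo)) / (2 * eps)
  }
  checks <- list(
    k1 = list(lg$grads$k1, fd(function(mo, e) { mo$k1 <- mo$k1 + e; mo })),
    k2 = list(lg$grads$k2, fd(function(mo, e) { mo$k2 <- mo$k2 + e; mo })),
    k3 = list(lg$grads$k3, fd(function(mo, e) { mo$k3 <- mo$k3 + e; mo })),
    Wq = list(lg$grads$Wq[2, 3],
              fd(function(mo, e) { mo$Wq[2, 3] <- mo$Wq[2, 3] + e; mo })),
    Wv = list(lg$grads$Wv[1, 4],
              fd(function(mo, e) { mo$Wv[1, 4] <- mo$Wv[1, 4] + e; mo })),
    w_head = list(lg$grads$w_head[2],
                  fd(function(mo, e) { mo$w_head[2] <- mo$w_head[2] + e; mo })))
  for (nm in names(checks)) {
    got <- checks[[nm]][[1]]; want <- checks[[nm]][[2]]
    expect_lt(abs(got - want) / max(abs(want), 1e-8), 1e-4)
  }
})

test_that("checkpoints round-trip and refuse mismatched gene orders", {
  model <- init_attention_model(4, seed = 61)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f, gene_names = c("A", "B"))
  expect_equal(load_checkpoint(f, c("A", "B")), model)
  expect_error(load_checkpoint(f, c("B", "A")), "mismatch")
})
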