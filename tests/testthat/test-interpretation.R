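test_that("attention averaging is the elementwise mean", {
  set.seed(2)
  m1 <- matrix(rnorm(16), 4)
  m2 <- matrix(rnorm(16), 4)
  expect_equal(average_attention(list(m1)), m1)
  expect_equal(average_attention(list(m1, -m1)), matrix(0, 4, 4))
  arr <- array(0, dim = c(2, 4, 4))
  arr[1, , ] <- m1; arr[2, , ] <- m2
  expect_equal(average_attention(arr), (m1 + m2) / 2, tolerance = 1e-12)
  expect_error(average_attention(list()), "no attention")
})

test_that("gene weights follow the down/up/self decomposition", {
  expect_equal(unname(gene_weights(diag(3))), rep(1, 3))
  n <- 6
  expect_equal(unname(gene_weights(matrix(1, n, n))), rep(2 * (n - 1) + 1, n))
  a <- matrix(0, 3, 3)
  a[1, 2] <- 0.7
  expect_equal(unname(gene_weights(a)), c(0.7, 0.7, 0))
  expect_error(gene_weights(matrix(0, 2, 3)), "square")
})

test_that("total gene weight double-counts off-diagonal attention once", {
  for (s in 1:10) {
    set.seed(s)
    a <- matrix(rnorm(49), 7)
    expect_equal(sum(gene_weights(a)),
                 2 * (sum(a) - sum(diag(a))) + sum(diag(a)),
                 tolerance = 1e-12)
  }
})

test_that("frequency normalisation promotes rarer genes at equal raw weight", {
  genes <- c("A", "B")
  att <- matrix(c(1, 0, 0, 1), 2, dimnames = list(genes, genes))
  vals <- matrix(0L, 4, 2, dimnames = list(sprintf("P%d", 1:4), genes))
  vals[1:2, "A"] <- 1L   # frequency 0.5
  vals[1, "B"] <- 1L     # frequency 0.25
  rk <- rank_biomarkers(att, mutation_matrix(vals), k = 2)
  expect_equal(rk$gene[1], "B")
  expect_equal(rk$normalized_weight, rk$raw_weight / rk$mutation_frequency)
  rk_raw <- rank_biomarkers(att, mutation_matrix(vals), k = 2,
                            normalize = FALSE)
  expect_equal(rk_raw$gene[1], "A")  # ties break alphabetically
})

test_that("rankings agree with an independent sort and handle edge cases", {
  set.seed(12)
  genes <- sprintf("G%d", 1:6)
  att <- matrix(abs(rnorm(36)), 6, dimnames = list(genes, genes))
  vals <- matrix(rbinom(60, 1, 0.5), 10, 6,
                 dimnames = list(sprintf("P%02d", 1:10), genes))
  vals[, 6] <- 0L   # never mutated
  m <- mutation_matrix(vals)
  expect_message(rk <- rank_biomarkers(att, m, k = 6), "excluded")
  expect_equal(nrow(rk), 5)
  w <- gene_weights(att)[1:5] / colMeans(m)[1:5]
  expect_equal(rk$gene, names(sort(w, decreasing = TRUE)))
  expect_equal(rk$rank, 1:5)
  all0 <- mutation_matrix(matrix(0L, 3, 2,
                                 dimnames = list(c("a", "b", "c"),
                                                 c("X", "Y"))))
  expect_error(rank_biomarkers(matrix(1, 2, 2), all0), "degenerate")
})

test_that("the averaged raw attention map equals kernel times comutation", {
  tc <- toy_cohort(n = 30, seed = 21)
  model <- init_attention_model(4, seed = 22)
  map <- raw_attention_map(model, tc$coh$mutations, tc$emb)
  # literal check: average the per-patient raw attention matrices
  tens <- embed_patients(tc$coh$mutations, tc$bundle$embeddings)
  mats <- lapply(seq_len(dim(tens)[1]),
                 function(i) raw_attention(matrix(tens[i, , ],
                                                  ncol = 4), model))
  expect_equal(unname(map), unname(average_attention(mats)),
               tolerance = 1e-12)
})

test_that("no-op ablation reproduces the reference protocol at matched seeds", {
  tc <- toy_cohort(n = 50, seed = 23)
  ab <- ablate_and_rerun(tc$coh, tc$bundle$graph, tc$bundle$embeddings,
                         genes_to_remove = character(0), folds = 2,
                         repeats = 1, epochs = 2, seed = 6)
  expect_equal(ab$full$results$cindex, ab$ablated$results$cindex)
  expect_error(
    ablate_and_rerun(tc$coh, tc$bundle$graph, tc$bundle$embeddings,
                     genes_to_remove = "NOT_A_GENE", folds = 2,
                     repeats = 1, epochs = 1, seed = 1),
    "not in cohort")
})

test_that("Kaplan-Meier grouping by mutation status behaves at the boundaries", {
  set.seed(31)
  genes <- c("A", "B")
  vals <- matrix(0L, 40, 2, dimnames = list(sprintf("P%02d", 1:40), genes))
  vals[1:20, "A"] <- 1L
  m <- mutation_matrix(vals)
  # identical survival in both groups: p near 1
  surv <- data.frame(patient_id = rownames(m),
                     time = rep(c(5, 10, 15, 20), 10),
                     event = rep(c(1L, 0L), 20), stringsAsFactors = FALSE)
  km <- km_by_mutation(surv, m, "A")
  expect_gt(km$p_value, 0.9)
  # survival estimate starts at one
  expect_true(all(summary(km$fit, times = 0)$surv == 1))
  expect_error(km_by_mutation(surv, m, "B"), "one group")
  expect_error(km_by_mutation(surv, m, "ZZZ"), "not in mutation matrix")
})

test_that("a strongly planted gene separates Kaplan-Meier curves", {
  cfg <- simulation_config(n_patients = 300, n_genes = 10,
                           mutation_freqs = rep(0.3, 10), d_k = 4,
                           beta = c(G001 = 1.5), seed = 41)
  b <- simulate_cohort(cfg)
  km <- km_by_mutation(b$survival, b$mutations, "G001")
  expect_lt(km$p_value, 0.05)
})

test_that("stratification labels the configured top fraction as responders", {
  set.seed(51)
  sc <- setNames(rnorm(100), sprintf("P%03d", 1:100))
  st <- stratify(sc, 0.17)
  expect_equal(sum(st$labels == "responder"), 17)
  expect_gte(min(sc[st$labels == "responder"]),
             max(sc[st$labels == "non-responder"]))
  sc10 <- setNames(1:10, sprintf("P%02d", 1:10))
  st10 <- stratify(sc10, 0.5)
  expect_setequal(names(st10$labels)[st10$labels == "responder"],
                  sprintf("P%02d", 6:10))
  expect_warning(stratify(setNames(rep(1, 5), letters[1:5]), 0.4), "tied")
})

test_that("stratification reports a log-rank comparison when survival is given", {
  tc <- toy_cohort(n = 60, seed = 52)
  sc <- setNames(rnorm(60), tc$coh$survival$patient_id)
  st <- stratify(sc, 0.25, surv = tc$coh$survival)
  expect_true(is.finite(st$p_value))
  expect_true(st$p_value >= 0 && st$p_value <= 1)
})

test_that("mismatch-repair status requires one mutated MMR gene", {
  genes <- c("MLH1", "MSH2", "MSH3", "MSH6", "PMS2", "TP53")
  vals <- matrix(0L, 3, 6, dimnames = list(c("P1", "P2", "P3"), genes))
  vals["P1", "MSH6"] <- 1L
  vals["P3", "TP53"] <- 1L
  st <- infer_mmr_status(mutation_matrix(vals))
  expect_equal(unname(st), factor(c("Mut", "Wt", "Wt"),
                                  levels = c("Mut", "Wt")))
  # a panel without the MMR genes is all wildtype, with a warning
  vals2 <- matrix(1L, 2, 2, dimnames = list(c("P1", "P2"), c("TP53", "KRAS")))
  expect_warning(st2 <- infer_mmr_status(mutation_matrix(vals2)), "absent")
  expect_true(all(st2 == "Wt"))
})

test_that("score-covariate correlation is a Spearman rank test", {
  sc <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(score_vs_covariate(sc, sc)$rho, 1)
  expect_equal(score_vs_covariate(sc, -sc)$rho, -1)
  expect_error(score_vs_covariate(sc, rep(2, 6)), "constant")
  set.seed(61)
  rhos <- replicate(50, score_vs_covariate(rnorm(30), rnorm(30))$rho)
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(50) + 0.05)
})

test_that("map downsampling is block-mean pooling", {
  a <- matrix(1:16, 4, 4)
  expect_equal(downsample_map(a, 4), a)
  expect_equal(downsample_map(matrix(7, 5, 5), 2), matrix(7, 2, 2))
  d <- downsample_map(a, 2)
  expect_equal(d[1, 1], mean(a[1:2, 1:2]))
  expect_equal(d[2, 1], mean(a[3:4, 1:2]))
  expect_equal(d[1, 2], mean(a[1:2, 3:4]))
  expect_equal(d[2, 2], mean(a[3:4, 3:4]))
  expect_error(downsample_map(a, 5), "exceeds")
})
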