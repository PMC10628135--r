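# Training: full-batch Adam on the smoothed c-index loss, pan-cancer
# pretraining, repeated stratified cross-validation and aggregation.
#
# The trainer exploits the lookup structure of the embedding layer: patient
# i's input matrix is diag(m_i) %*% E, where m_i is the binary mutation row
# and E the shared gene-embedding matrix. Raw attention therefore factorises
# as (E Wq Wk' E' / sqrt(d)) masked by outer(m_i, m_i), which lets the
# forward and backward passes run as a handful of stacked matrix operations
# over all patients at once instead of a per-patient loop. Equivalence with
# the literal per-patient forward pass (model_forward) is asserted in the
# test suite.

#' Bundle a cohort
#'
#' Joins a mutation matrix and survival table on their shared patients.
#'
#' @param mutations a [mutation_matrix].
#' @param survival a survival data.frame (`patient_id`, `time`, `event`).
#' @param name optional cohort label (e.g. the cancer type).
#' @return object of class `attnsurv_cohort`.
#' @export
cohort <- function(mutations, survival, name = "cohort") {
  j <- join_cohort(mutations, survival)
  out <- list(mutations = j$mutations, survival = j$survival, name = name)
  class(out) <- "attnsurv_cohort"
  out
}

prior_bias <- function(model, priors) {
  model$k1 * priors$pathway + model$k2 * priors$connection +
    model$k3 * priors$padding
}

# Precompute the sparse row-stacking of a binary cohort matrix. Attention
# rows of wildtype genes carry no raw-attention signal (their input row is
# the zero vector), so they collapse to one shared softmax of the prior
# bias; only mutated (patient, gene) rows need per-patient treatment.
fit_batch <- function(mut) {
  mut <- unclass(mut)
  storage.mode(mut) <- "double"
  nz <- which(mut == 1, arr.ind = TRUE)
  list(mut = mut, n = nrow(mut), G = ncol(mut),
       mi = nz[, 1], gi = nz[, 2],
       Mstack = mut[nz[, 1], , drop = FALSE])
}

# Vectorised forward pass over the whole cohort.
# batch: from fit_batch() (or a raw n x G binary matrix); emb: G x d_k
# cohort-aligned embedding matrix. Returns scores and, when keep = TRUE,
# the intermediates the backward pass needs.
fit_forward <- function(model, batch, emb, priors, keep = FALSE) {
  if (is.matrix(batch) || inherits(batch, "mutation_matrix"))
    batch <- fit_batch(batch)
  n <- batch$n; G <- batch$G; d <- model$d_k
  check_gene_order(colnames(batch$mut), priors$gene_names,
                   "mutations and priors")
  EQ <- emb %*% model$Wq
  EK <- emb %*% model$Wk
  EV <- emb %*% model$Wv
  S <- EQ %*% t(EK) / sqrt(d)
  B <- prior_bias(model, priors)
  A0 <- row_softmax(B)                      # shared wildtype attention rows
  nnz <- length(batch$mi)
  AmSum <- matrix(0, n, G)
  if (nnz) {
    Wm <- S[batch$gi, , drop = FALSE] * batch$Mstack +
      B[batch$gi, , drop = FALSE]
    Am <- row_softmax(Wm)
    rs <- rowsum(Am, batch$mi)
    AmSum[as.integer(rownames(rs)), ] <- rs
  } else Am <- Wm <- NULL
  # per-patient column sums of the full attention matrix:
  # all-wildtype rows, minus the A0 rows of mutated genes, plus their
  # patient-specific rows
  acs <- matrix(colSums(A0), n, G, byrow = TRUE) -
    batch$mut %*% A0 + AmSum
  U <- batch$mut * acs
  H <- (U %*% EV) / G                        # pooled context per patient
  scores <- as.numeric(H %*% model$w_head) + model$b_head
  if (any(!is.finite(scores))) stop("non-finite score in forward pass")
  names(scores) <- rownames(batch$mut)
  if (!keep) return(list(scores = scores))
  list(scores = scores, EQ = EQ, EK = EK, EV = EV, A0 = A0, Am = Am,
       U = U, H = H, batch = batch)
}

#' Predict scores for a cohort
#'
#' @param model an `attnsurv_model`.
#' @param mut binary mutation matrix (patients x genes).
#' @param emb cohort-aligned embedding matrix from [cohort_embedding()].
#' @param priors a `graph_priors` object in the same gene order.
#' @return named numeric vector of predictive scores.
#' @export
predict_scores <- function(model, mut, emb, priors) {
  fit_forward(model, mut, emb, priors)$scores
}

# Loss and analytic gradients for a full batch.
fit_loss_grad <- function(model, batch, emb, priors, times, events,
                          l2_coeff = 0.01, steepness = 1, pairs = NULL) {
  if (is.matrix(batch) || inherits(batch, "mutation_matrix"))
    batch <- fit_batch(batch)
  fw <- fit_forward(model, batch, emb, priors, keep = TRUE)
  if (is.null(pairs)) pairs <- comparable_pairs(times, events)
  n <- batch$n; G <- batch$G; d <- model$d_k
  p <- stats::plogis(steepness * (fw$scores[pairs$longer] -
                                    fw$scores[pairs$shorter]))
  loss <- 1 - mean(p) + l2_coeff * param_sumsq(model)
  gs <- cindex_score_grad(fw$scores, times, events, steepness, pairs = pairs)

  db <- sum(gs)
  dw <- as.numeric(t(fw$H) %*% gs)
  dH <- outer(gs, model$w_head)
  dU <- (dH %*% t(fw$EV)) / G
  dEV <- (t(fw$U) %*% dH) / G
  da <- dU * batch$mut                       # gradient on per-patient
                                             # attention column sums
  # wildtype rows: gene g's shared softmax row A0[g, ] receives the summed
  # da of every patient in whom g is wildtype
  Dsum <- colSums(da)
  Dmut <- t(batch$mut) %*% da
  WtS <- matrix(Dsum, G, G, byrow = TRUE) - Dmut
  dB <- fw$A0 * (WtS - rowSums(fw$A0 * WtS))
  dSmask <- matrix(0, G, G)
  if (length(batch$mi)) {
    dAm <- da[batch$mi, , drop = FALSE]
    dWm <- fw$Am * (dAm - rowSums(dAm * fw$Am))
    rs <- rowsum(dWm, batch$gi)
    gidx <- as.integer(rownames(rs))
    dB[gidx, ] <- dB[gidx, ] + rs
    rs2 <- rowsum(dWm * batch$Mstack, batch$gi)
    dSmask[gidx, ] <- rs2
  }
  dEQ <- (dSmask %*% fw$EK) / sqrt(d)
  dEK <- (t(dSmask) %*% fw$EQ) / sqrt(d)
  grads <- list(
    Wq = t(emb) %*% dEQ, Wk = t(emb) %*% dEK, Wv = t(emb) %*% dEV,
    w_head = dw, b_head = db,
    k1 = sum(dB * priors$pathway),
    k2 = sum(dB * priors$connection),
    k3 = sum(dB * priors$padding)
  )
  for (nm in param_names)
    grads[[nm]] <- grads[[nm]] + 2 * l2_coeff * model[[nm]]
  list(loss = loss, grads = grads, scores = fw$scores)
}

adam_init <- function(model) {
  list(m = lapply(model[param_names], function(p) p * 0),
       v = lapply(model[param_names], function(p) p * 0),
       t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in param_names) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    model[[nm]] <- model[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(model = model, state = state)
}

#' Train a single model with validation-based checkpoint selection
#'
#' Full-batch Adam on the smoothed c-index loss. After every epoch the exact
#' concordance index on the validation split is computed; the parameters
#' with the highest validation c-index are returned (earliest epoch wins
#' ties).
#'
#' @param model initial `attnsurv_model` (e.g. a pretrained checkpoint).
#' @param train,validation lists with elements `mutations` (patients x genes
#'   binary matrix), `times`, `events`; patient sets must be disjoint.
#' @param priors a `graph_priors` object.
#' @param emb cohort-aligned embedding matrix.
#' @param epochs number of epochs (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param l2_coeff L2 coefficient of the loss (default 0.01).
#' @param steepness sigmoid steepness of the smoothed c-index (default 1).
#' @return list with `model` (best checkpoint), `trace` (validation c-index
#'   per epoch), `loss_trace`, and `best_epoch`.
#' @export
train_single <- function(model, train, validation, priors, emb,
                         epochs = 200, lr = 1e-3, l2_coeff = 0.01,
                         steepness = 1) {
  if (length(intersect(rownames(train$mutations),
                       rownames(validation$mutations))))
    stop("train and validation splits overlap")
  pairs_tr <- comparable_pairs(train$times, train$events)
  if (!nrow(pairs_tr)) stop("no comparable pairs in the training split")
  pairs_va <- comparable_pairs(validation$times, validation$events)
  if (!nrow(pairs_va))
    stop("no comparable pairs in the validation split; re-draw the split")
  batch_tr <- fit_batch(train$mutations)
  batch_va <- fit_batch(validation$mutations)
  state <- adam_init(model)
  trace <- numeric(epochs)
  loss_trace <- numeric(epochs)
  best <- model; best_ci <- -Inf; best_epoch <- 0L
  for (ep in seq_len(epochs)) {
    lg <- fit_loss_grad(model, batch_tr, emb, priors,
                        train$times, train$events, l2_coeff, steepness,
                        pairs = pairs_tr)
    loss_trace[ep] <- lg$loss
    upd <- adam_step(model, lg$grads, state, lr)
    model <- upd$model; state <- upd$state
    val_scores <- fit_forward(model, batch_va, emb, priors)$scores
    trace[ep] <- cindex(val_scores, validation$times, validation$events)
    if (trace[ep] > best_ci) {
      best_ci <- trace[ep]; best <- model; best_epoch <- ep
    }
  }
  list(model = best, trace = trace, loss_trace = loss_trace,
       best_epoch = best_epoch)
}

#' Build a repeated cross-validation split plan
#'
#' Per repeat, patients are partitioned into `folds` test sets (~1/folds of
#' the cohort each); the remaining patients of every fold are split 80/20
#' into training and validation. With 10 folds this yields the 10% test /
#' 72% train / 18% validation layout. Cohorts below `small_threshold`
#' patients default to 5 folds.
#'
#' @param patient_ids character vector of patient identifiers.
#' @param folds number of folds, or NULL to choose 10 (5 for small cohorts).
#' @param repeats number of repeats (default 5).
#' @param seed integer seed; repeat r uses `seed + r - 1`.
#' @param small_threshold cohort size below which 5 folds are used.
#' @param val_fraction validation share of the non-test patients.
#' @param strata optional per-patient grouping (e.g. the event indicator)
#'   named by or ordered as `patient_ids`; when given, fold assignment is
#'   stratified so each fold receives a proportional share of every stratum.
#'   Off by default: plain random splits are the reference protocol.
#' @return object of class `split_plan`.
#' @export
make_splits <- function(patient_ids, folds = NULL, repeats = 5, seed = 1,
                        small_threshold = 50, val_fraction = 0.2,
                        strata = NULL) {
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids")
  if (is.null(folds)) folds <- if (n < small_threshold) 5L else 10L
  if (folds > n) stop("more folds than patients")
  if (folds < 2) stop("need at least two folds")
  if (!is.null(strata)) {
    stopifnot(length(strata) == n)
    names(strata) <- patient_ids
  }
  plan <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1)
    perm <- sample(patient_ids)
    if (!is.null(strata))   # group the shuffle by stratum: round-robin fold
      perm <- perm[order(strata[perm])]  # assignment then balances strata
    # shuffled patients assigned round-robin to folds
    fold_of <- rep(seq_len(folds), length.out = n)
    cells <- vector("list", folds)
    for (f in seq_len(folds)) {
      test <- perm[fold_of == f]
      rest <- perm[fold_of != f]
      rest <- sample(rest)
      n_val <- max(1L, round(val_fraction * length(rest)))
      cells[[f]] <- list(test = test,
                         validation = rest[seq_len(n_val)],
                         train = rest[-seq_len(n_val)])
    }
    plan[[r]] <- cells
  }
  out <- list(plan = plan, folds = folds, repeats = repeats, seed = seed,
              patient_ids = patient_ids)
  class(out) <- "split_plan"
  out
}

subset_split <- function(coh, ids) {
  keep <- match(ids, coh$survival$patient_id)
  list(mutations = unclass(coh$mutations)[ids, , drop = FALSE],
       times = coh$survival$time[keep],
       events = coh$survival$event[keep])
}

#' Pan-cancer pretraining
#'
#' Pools every cohort except the target, splits the pool 80/20 into train
#' and validation, and trains from a fresh initialisation with the same
#' loss. Errors if any target patient leaks into the pool.
#'
#' @param cohorts named list of `attnsurv_cohort` objects sharing one gene
#'   panel.
#' @param target name of the held-out target cohort.
#' @param priors,emb shared graph priors and embedding matrix.
#' @param epochs,lr,l2_coeff,steepness training hyper-parameters.
#' @param seed integer seed (initialisation and the 80/20 split).
#' @return a pretrained `attnsurv_model`.
#' @export
pretrain <- function(cohorts, target, priors, emb, epochs = 200, lr = 1e-3,
                     l2_coeff = 0.01, steepness = 1, seed = 1) {
  if (!target %in% names(cohorts)) stop("target cohort not found: ", target)
  pool <- cohorts[setdiff(names(cohorts), target)]
  if (!length(pool)) stop("no non-target cohorts to pretrain on")
  target_ids <- rownames(cohorts[[target]]$mutations)
  for (ch in pool) {
    check_gene_order(colnames(ch$mutations), priors$gene_names,
                     "pooled cohort and priors")
    leak <- intersect(rownames(ch$mutations), target_ids)
    if (length(leak))
      stop("target patient(s) present in the pretraining pool: ",
           paste(leak, collapse = ", "))
  }
  mut <- do.call(rbind, lapply(pool, function(ch) unclass(ch$mutations)))
  times <- unlist(lapply(pool, function(ch) ch$survival$time),
                  use.names = FALSE)
  events <- unlist(lapply(pool, function(ch) ch$survival$event),
                   use.names = FALSE)
  set.seed(seed)
  ids <- rownames(mut)
  val <- sample(ids, max(1L, round(0.2 * length(ids))))
  tr <- setdiff(ids, val)
  pick <- function(sel) list(mutations = mut[sel, , drop = FALSE],
                             times = times[match(sel, ids)],
                             events = events[match(sel, ids)])
  model <- init_attention_model(ncol(emb), seed = seed)
  train_single(model, pick(tr), pick(val), priors, emb,
               epochs = epochs, lr = lr, l2_coeff = l2_coeff,
               steepness = steepness)$model
}

#' Repeated cross-validated evaluation
#'
#' For every repeat x fold of the split plan, initialises from the supplied
#' checkpoint (or a fresh seeded initialisation), trains with
#' validation-based checkpoint selection, and evaluates the exact
#' concordance index on the held-out test patients. With 10 folds and 5
#' repeats this produces 50 test values, summarised by their mean and
#' standard error.
#'
#' @param coh an `attnsurv_cohort`.
#' @param priors a `graph_priors` object in the cohort gene order.
#' @param emb cohort-aligned embedding matrix.
#' @param folds,repeats cross-validation layout (NULL folds = automatic).
#' @param epochs,lr,l2_coeff,steepness training hyper-parameters.
#' @param seed base seed; per-cell seeds are derived from it.
#' @param init_model optional pretrained `attnsurv_model` used to initialise
#'   every fold.
#' @param small_threshold cohort size below which 5 folds are used.
#' @param keep_models if TRUE, the best checkpoint of every fold is returned
#'   (used for ensemble attention averaging in biomarker discovery).
#' @return object of class `cv_result`: list with `results` (data.frame of
#'   per-cell test c-indices), `mean`, `se`, the configuration, and
#'   optionally `models`.
#' @export
run_protocol <- function(coh, priors, emb, folds = NULL, repeats = 5,
                         epochs = 200, lr = 1e-3, l2_coeff = 0.01,
                         steepness = 1, seed = 1, init_model = NULL,
                         small_threshold = 50, keep_models = FALSE) {
  stopifnot(inherits(coh, "attnsurv_cohort"))
  check_gene_order(colnames(coh$mutations), priors$gene_names,
                   "cohort and priors")
  sp <- make_splits(coh$survival$patient_id, folds = folds,
                    repeats = repeats, seed = seed,
                    small_threshold = small_threshold)
  res <- vector("list", sp$repeats * sp$folds)
  models <- if (keep_models) vector("list", sp$repeats * sp$folds)
  cell <- 0L
  for (r in seq_len(sp$repeats)) {
    for (f in seq_len(sp$folds)) {
      cell <- cell + 1L
      sets <- sp$plan[[r]][[f]]
      model0 <- if (is.null(init_model)) {
        init_attention_model(ncol(emb), seed = seed + 131L * r + f)
      } else init_model
      fit <- train_single(model0,
                          subset_split(coh, sets$train),
                          subset_split(coh, sets$validation),
                          priors, emb, epochs = epochs, lr = lr,
                          l2_coeff = l2_coeff, steepness = steepness)
      te <- subset_split(coh, sets$test)
      sc <- fit_forward(fit$model, te$mutations, emb, priors)$scores
      res[[cell]] <- data.frame(repeat_ = r, fold = f,
                                cindex = cindex(sc, te$times, te$events))
      if (keep_models) models[[cell]] <- fit$model
    }
  }
  results <- do.call(rbind, res)
  out <- list(results = results,
              mean = mean(results$cindex),
              se = stats::sd(results$cindex) / sqrt(nrow(results)),
              folds = sp$folds, repeats = sp$repeats,
              config = list(epochs = epochs, lr = lr, l2_coeff = l2_coeff,
                            steepness = steepness, seed = seed))
  if (keep_models) out$models <- models
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validated c-index: %.3f +/- %.3f (SE) over %d values (%d folds x %d repeats)\n",
              x$mean, x$se, nrow(x$results), x$folds, x$repeats))
  invisible(x)
}

#' Train an ensemble of full-cohort models for interpretation
#'
#' Trains `n_models` models on the whole cohort (no validation split:
#' interpretation does not require held-out checkpoint selection, and the
#' extra patients sharpen the learned attention kernel), differing only in
#' their random initialisation. The resulting list feeds
#' [discover_biomarkers()], which averages the attention kernels to
#' suppress initialisation noise.
#'
#' @inheritParams run_protocol
#' @param n_models ensemble size (default 10).
#' @return list of `attnsurv_model` objects.
#' @export
train_discovery_ensemble <- function(coh, priors, emb, n_models = 10,
                                     epochs = 200, lr = 1e-3,
                                     l2_coeff = 0.01, steepness = 1,
                                     seed = 1) {
  stopifnot(inherits(coh, "attnsurv_cohort"), n_models >= 1)
  check_gene_order(colnames(coh$mutations), priors$gene_names,
                   "cohort and priors")
  batch <- fit_batch(coh$mutations)
  pairs <- comparable_pairs(coh$survival$time, coh$survival$event)
  if (!nrow(pairs)) stop("no comparable pairs in the cohort")
  lapply(seq_len(n_models), function(e) {
    model <- init_attention_model(ncol(emb), seed = seed + 37L * e)
    state <- adam_init(model)
    for (ep in seq_len(epochs)) {
      lg <- fit_loss_grad(model, batch, emb, priors, coh$survival$time,
                          coh$survival$event, l2_coeff, steepness,
                          pairs = pairs)
      upd <- adam_step(model, lg$grads, state, lr)
      model <- upd$model; state <- upd$state
    }
    model
  })
}

#' Train one model on a full cohort (80/20 split)
#'
#' Convenience wrapper used for interpretation: splits the cohort 80/20,
#' trains with validation-based selection, and returns the model together
#' with scores and post-softmax attention maps for all patients.
#'
#' @inheritParams run_protocol
#' @param return_maps also return per-patient attention maps.
#' @return list with `model`, `scores`, and (optionally) `normalized` /
#'   `weighted` map arrays.
#' @export
train_cohort_model <- function(coh, priors, emb, epochs = 200, lr = 1e-3,
                               l2_coeff = 0.01, steepness = 1, seed = 1,
                               init_model = NULL, return_maps = TRUE) {
  set.seed(seed)
  ids <- coh$survival$patient_id
  val <- sample(ids, max(1L, round(0.2 * length(ids))))
  tr <- setdiff(ids, val)
  model0 <- if (is.null(init_model)) {
    init_attention_model(ncol(emb), seed = seed)
  } else init_model
  fit <- train_single(model0, subset_split(coh, tr), subset_split(coh, val),
                      priors, emb, epochs = epochs, lr = lr,
                      l2_coeff = l2_coeff, steepness = steepness)
  tensor <- array(0, dim = c(nrow(coh$mutations), ncol(coh$mutations),
                             ncol(emb)),
                  dimnames = list(rownames(coh$mutations),
                                  colnames(coh$mutations), NULL))
  for (i in seq_len(nrow(coh$mutations)))
    tensor[i, , ] <- coh$mutations[i, ] * emb
  fw <- model_forward(fit$model, tensor, priors, return_maps = return_maps)
  c(list(model = fit$model, trace = fit$trace), fw)
}
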