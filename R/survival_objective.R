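# Concordance index under right censoring, its sigmoid smoothing, and the
# training loss: 1 - smoothed c-index + 0.01 * sum of squared parameters.

#' Enumerate comparable patient pairs
#'
#' A pair is comparable when the patient with the shorter observed time
#' experienced the event (Harrell's rule): their relative survival order is
#' then known. Pairs where both patients are censored, or where the
#' earlier-time patient is censored, carry no ordering information and are
#' excluded. Tied observed times are comparable only when exactly one of the
#' two is an event (the censored patient is known to have survived longer).
#'
#' @param times non-negative survival times.
#' @param events event indicators (1 = deceased, 0 = censored).
#' @return data.frame with integer columns `shorter` and `longer`: indices
#'   of the shorter- and longer-surviving patient of each comparable pair.
#' @export
comparable_pairs <- function(times, events) {
  n <- length(times)
  if (n < 2) stop("need at least two patients")
  stopifnot(length(events) == n, all(events %in% c(0, 1)),
            all(is.finite(times)), all(times >= 0))
  idx <- which(events == 1)
  shorter <- integer(0); longer <- integer(0)
  for (i in idx) {
    j <- which(times > times[i] | (times == times[i] & events == 0))
    j <- j[j != i]
    shorter <- c(shorter, rep.int(i, length(j)))
    longer <- c(longer, j)
  }
  # a tied-time pair with one event appears once (event patient as shorter);
  # a tied-time pair with two events appears in neither direction
  data.frame(shorter = shorter, longer = longer)
}

#' Concordance index
#'
#' Fraction of comparable pairs in which the longer-surviving patient
#' received the larger predicted score; tied scores count 0.5.
#'
#' @param scores predicted scores, higher = better predicted survival.
#' @inheritParams comparable_pairs
#' @return proportion in `[0, 1]`.
#' @export
cindex <- function(scores, times, events) {
  pairs <- comparable_pairs(times, events)
  if (!nrow(pairs))
    stop("no comparable pairs: concordance index is undefined")
  d <- scores[pairs$longer] - scores[pairs$shorter]
  mean((d > 0) + 0.5 * (d == 0))
}

#' Sigmoid-smoothed concordance index
#'
#' Replaces each concordance indicator with
#' `plogis(steepness * (score_longer - score_shorter))`, giving a quantity
#' differentiable in the scores that converges to the exact c-index as
#' `steepness` grows (on tie-free data).
#'
#' @inheritParams cindex
#' @param steepness positive slope of the logistic surrogate.
#' @return value in `(0, 1)`.
#' @export
smooth_cindex <- function(scores, times, events, steepness = 1) {
  stopifnot(steepness > 0)
  pairs <- comparable_pairs(times, events)
  if (!nrow(pairs))
    stop("no comparable pairs: concordance index is undefined")
  mean(stats::plogis(steepness * (scores[pairs$longer] - scores[pairs$shorter])))
}

#' Training loss
#'
#' `1 - smooth_cindex + l2_coeff * sum(parameters^2)` over all learnable
#' parameters including the three prior mixers. Minimising it maximises the
#' (smoothed) concordance of predicted scores with observed survival.
#'
#' @param model an `attnsurv_model` (supplies the L2 term).
#' @inheritParams smooth_cindex
#' @param l2_coeff L2 regularisation coefficient (default 0.01).
#' @return scalar loss.
#' @export
surv_loss <- function(model, scores, times, events, l2_coeff = 0.01,
                      steepness = 1) {
  1 - smooth_cindex(scores, times, events, steepness) +
    l2_coeff * param_sumsq(model)
}

# Gradient of (1 - smooth_cindex) with respect to the score vector.
cindex_score_grad <- function(scores, times, events, steepness = 1,
                              pairs = NULL) {
  if (is.null(pairs)) pairs <- comparable_pairs(times, events)
  npair <- nrow(pairs)
  p <- stats::plogis(steepness * (scores[pairs$longer] - scores[pairs$shorter]))
  w <- steepness * p * (1 - p) / npair
  g <- numeric(length(scores))
  agg <- rowsum(c(-w, w), group = c(pairs$longer, pairs$shorter))
  g[as.integer(rownames(agg))] <- agg[, 1]
  g
}
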