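#' Posterior link probabilities
#'
#' The probability estimate of a link is its occurrence frequency over the
#' recorded partition samples: `p_hat(l) = (records containing l) / (total
#' records)`. Only links that occur at least once are stored; all other
#' links have probability zero implicitly.
#'
#' @param samples list of `spt_partition` samples (typically
#'   [pooled_samples()] of both chains).
#' @param obs an `spt_observations` object.
#' @return An object of class `spt_link_probs`: data frame with columns
#'   `a`, `b`, `count`, `p_hat`, and attribute `n_records`.
#' @export
link_probabilities <- function(samples, obs) {
  stopifnot(length(samples) >= 1L)
  n <- nrow(obs)
  keys <- unlist(lapply(samples, function(p)
    unique(.part_link_keys(p$tracks, n))), use.names = FALSE)
  tab <- table(keys)
  key_num <- as.numeric(names(tab))
  a <- floor(key_num / (n + 1))
  b <- key_num - a * (n + 1)
  out <- data.frame(a = as.integer(a), b = as.integer(b),
                    count = as.integer(tab),
                    p_hat = as.integer(tab) / length(samples))
  out <- out[order(-out$p_hat, out$a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_records") <- length(samples)
  class(out) <- c("spt_link_probs", "data.frame")
  out
}

#' Confusion counts at a link-probability threshold
#'
#' A link is *predicted* if its estimated probability satisfies
#' `p_hat >= p_min` (and it occurred at least once; at `p_min = 0` every
#' link that occurred in at least one sample is predicted). True positives
#' are predicted links present in the ground truth, false positives are
#' predicted links absent from it, and false negatives are true links not
#' predicted. No true-negative count is defined.
#'
#' @param table an `spt_link_probs` object.
#' @param truth matrix of true links with columns `a`, `b`.
#' @param p_min threshold in `[0, 1]`.
#' @param obs an `spt_observations` object.
#' @return A list with `TP`, `FP`, `FN`.
#' @export
confusion <- function(table, truth, p_min, obs) {
  stopifnot(p_min >= 0, p_min <= 1)
  n <- nrow(obs)
  pred <- table[table$p_hat >= p_min, , drop = FALSE]
  pred_keys <- as.numeric(pred$a) * (n + 1) + as.numeric(pred$b)
  true_keys <- if (nrow(truth)) {
    as.numeric(truth[, "a"]) * (n + 1) + as.numeric(truth[, "b"])
  } else {
    numeric()
  }
  TP <- sum(pred_keys %in% true_keys)
  list(TP = TP, FP = length(pred_keys) - TP,
       FN = length(true_keys) - TP)
}

#' Jaccard similarity, recall and precision
#'
#' `JSC = TP / (TP + FP + FN)`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`; all in `[0, 1]`, larger is better. A zero
#' denominator yields `NaN`.
#'
#' @param c a confusion list from [confusion()].
#' @return Named numeric vector `jsc`, `recall`, `precision`.
#' @export
scores <- function(c) {
  safe <- function(num, den) if (den > 0) num / den else NaN
  c(jsc = safe(c$TP, c$TP + c$FP + c$FN),
    recall = safe(c$TP, c$TP + c$FN),
    precision = safe(c$TP, c$TP + c$FP))
}

#' Link-prediction scores across thresholds
#'
#' Convenience sweep of [confusion()] and [scores()] over a grid of
#' `p_min` values.
#'
#' @param table an `spt_link_probs` object.
#' @param truth true-link matrix.
#' @param obs an `spt_observations` object.
#' @param p_min_grid thresholds to evaluate.
#' @return Data frame with one row per threshold.
#' @export
score_curve <- function(table, truth, obs,
                        p_min_grid = seq(0, 1, by = 0.1)) {
  do.call(rbind, lapply(p_min_grid, function(p) {
    s <- scores(confusion(table, truth, p, obs))
    data.frame(p_min = p, jsc = s["jsc"], recall = s["recall"],
               precision = s["precision"], row.names = NULL)
  }))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The standard two-chain (or m-chain) PSRF from between- and within-chain
#' variances; values near 1 indicate that the chains sample the same
#' distribution.
#'
#' @param chains numeric matrix with one column per chain (equal lengths,
#'   at least 10 draws).
#' @return Scalar PSRF; `Inf` if the within-chain variance vanishes while
#'   the chains disagree.
#' @export
gelman_rubin <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  m <- ncol(chains)
  stopifnot(n >= 10L, m >= 2L)
  means <- colMeans(chains)
  vars <- apply(chains, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B > 0) Inf else 1)
  V <- (n - 1) / n * W + B / n
  sqrt(V / W)
}
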