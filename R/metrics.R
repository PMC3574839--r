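# Clustering-agreement metrics: permutation-minimized misclassification
# error, Rand index and Hubert-Arabie adjusted Rand index, plus the
# replicate summaries (mean / RMSE / SD / proportion-better).

contingency <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors must have the same length", call. = FALSE)
  }
  table(factor(true_labels), factor(pred_labels))
}

# All permutations of 1..k (k <= 8; 8! = 40320 rows).
permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                   sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Misclassification error rate between two partitions
#'
#' The minimum fraction of mismatched items over all one-to-one relabelings
#' of the predicted clusters, found by optimal assignment on the confusion
#' matrix (exhaustive over the at most `max(g) <= 8` cluster permutations).
#'
#' @param true_labels,pred_labels Label vectors of equal length.
#' @return A fraction in `[0, 1]`.
#' @export
error_rate <- function(true_labels, pred_labels) {
  tab <- contingency(true_labels, pred_labels)
  k <- max(dim(tab))
  if (k > 8L) {
    stop("optimal label matching is implemented for up to 8 clusters",
         call. = FALSE)
  }
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- permutations(k)
  best <- 0
  for (r in seq_len(nrow(perms))) {
    hit <- sum(sq[cbind(seq_len(k), perms[r, ])])
    if (hit > best) best <- hit
  }
  1 - best / length(true_labels)
}

#' Rand index
#'
#' Fraction of item pairs on which the two partitions agree: together in
#' both or apart in both, computed from the contingency table.
#'
#' @inheritParams error_rate
#' @return A fraction in `[0, 1]`; 1 for identical partitions.
#' @export
rand_index <- function(true_labels, pred_labels) {
  tab <- contingency(true_labels, pred_labels)
  n <- length(true_labels)
  total <- choose(n, 2)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  (total + 2 * s_ij - s_a - s_b) / total
}

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Rand index corrected for chance under the permutation model:
#' `(RI - E[RI]) / (max RI - E[RI])`, computed from the contingency table.
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @inheritParams error_rate
#' @return A scalar in `(-1, 1]`.
#' @export
adjusted_rand_index <- function(true_labels, pred_labels) {
  tab <- contingency(true_labels, pred_labels)
  n <- length(true_labels)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps) return(0)
  (s_ij - expected) / (max_index - expected)
}

#' Summarize a metric over replicates for two methods
#'
#' Computes, per method, the mean, the RMSE relative to the metric's ideal
#' value (0 for error rates, 1 for Rand-type indices) and the sample
#' standard deviation (divisor n-1), together with the fraction of
#' replicates where method A beats method B (strictly, or `not_worse` for
#' the non-strict variant).
#'
#' @param metric_a,metric_b Per-replicate metric values for the two methods
#'   (`metric_b` may be `NULL` to summarize a single method).
#' @param reference Ideal value the RMSE is taken about: 0 for error rates,
#'   1 for Rand indices.
#' @param better One of `"lower"` (error rates) or `"higher"` (indices).
#' @param not_worse If `TRUE`, the proportion counts ties in favour of
#'   method A.
#' @return A data frame with rows `A` and `B` (columns `mean`, `rmse`,
#'   `sd`, `n`) carrying the proportion in attribute `proportion_better`.
#' @export
summarize_replicates <- function(metric_a, metric_b = NULL, reference = 0,
                                 better = c("lower", "higher"),
                                 not_worse = FALSE) {
  better <- match.arg(better)
  if (length(metric_a) < 2L) {
    stop("need at least 2 replicates to summarize", call. = FALSE)
  }
  summ <- function(x) {
    data.frame(mean = mean(x),
               rmse = sqrt(mean((x - reference)^2)),
               sd = stats::sd(x),
               n = length(x))
  }
  out <- summ(metric_a)
  rownames(out) <- "A"
  prop <- NA_real_
  if (!is.null(metric_b)) {
    if (length(metric_b) != length(metric_a)) {
      stop("the two methods must have the same number of replicates",
           call. = FALSE)
    }
    out <- rbind(A = summ(metric_a), B = summ(metric_b))
    delta <- if (better == "lower") metric_b - metric_a else metric_a - metric_b
    prop <- if (not_worse) mean(delta >= 0) else mean(delta > 0)
  }
  attr(out, "proportion_better") <- prop
  out
}
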