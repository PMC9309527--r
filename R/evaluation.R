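# Performance indicators for pocket classification.
#
# Classifying power: accuracy, precision = TP/(TP+FP), recall = TP/(TP+FN),
# F1 = 2*P*R/(P+R), computed from a pooled confusion matrix over all
# pockets. Ranking power: the fraction of proteins whose true allosteric
# pocket appears within the top-k pockets sorted by predicted probability.

#' Confusion matrix from 0/1 label vectors
#'
#' @param truth,predicted Equal-length 0/1 integer vectors.
#' @return A `confusion_matrix`: list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  stopifnot(all(truth %in% c(0L, 1L)), all(predicted %in% c(0L, 1L)))
  structure(
    list(
      tp = sum(truth == 1L & predicted == 1L),
      fp = sum(truth == 0L & predicted == 1L),
      fn = sum(truth == 1L & predicted == 0L),
      tn = sum(truth == 0L & predicted == 0L)
    ),
    class = "confusion_matrix"
  )
}

#' Build a confusion matrix from explicit counts
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

#' Classifying-power metrics from a confusion matrix
#'
#' Accuracy, precision, recall, and F1. A zero denominator (e.g. no
#' predicted positives) yields 0 for the affected metric rather than an
#' error, with the metric's name recorded in `degenerate` — so multi-run
#' aggregation never aborts on a pathological run.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report`: list with `accuracy`, `precision`,
#'   `recall`, `f1`, and `degenerate` (character vector).
#' @export
metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  stopifnot(total > 0)
  degenerate <- character()
  safe_ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_ratio(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (precision + recall == 0) {
    degenerate <- c(degenerate, "f1")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(accuracy = (cm$tp + cm$tn) / total, precision = precision,
         recall = recall, f1 = f1, degenerate = degenerate),
    class = "metrics_report"
  )
}

#' Top-k ranking power over proteins
#'
#' Per protein, pockets are sorted by descending predicted probability,
#' ties broken by the better (lower) FPocket rank. A protein counts as a
#' top-k success if any truly positive pocket sits at sorted position
#' <= k. Proteins with no positive pocket are excluded from the
#' denominator (their count is reported).
#'
#' @param profiles List of per-protein lists, each with numeric `prob`,
#'   integer 0/1 `truth`, and integer `rank` (FPocket rank, used for tie
#'   breaks; defaults to input order).
#' @param ks Integer vector of k values.
#' @return A `ranking_report`: list with `topk` (named numeric, fractions
#'   in [0,1]), `n_proteins` (denominator), `n_excluded`, and
#'   `rank_histogram` (tabulated best sorted position of the positive
#'   pocket).
#' @export
ranking_power <- function(profiles, ks = c(1L, 2L, 3L)) {
  stopifnot(length(profiles) > 0, all(ks >= 1))
  best_pos <- integer()
  n_excluded <- 0L
  for (pr in profiles) {
    prob <- pr$prob
    truth <- pr$truth
    stopifnot(length(prob) == length(truth), all(is.finite(prob)))
    if (sum(truth) == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    rank <- if (!is.null(pr$rank)) pr$rank else seq_along(prob)
    ord <- order(-prob, rank)
    pos <- which(truth[ord] == 1L)
    best_pos <- c(best_pos, min(pos))
  }
  n <- length(best_pos)
  if (n == 0) {
    stop("No protein with a positive pocket; ranking power undefined",
         call. = FALSE)
  }
  topk <- vapply(ks, function(k) mean(best_pos <= k), 0)
  names(topk) <- paste0("top", ks)
  structure(
    list(topk = topk, n_proteins = n, n_excluded = n_excluded,
         rank_histogram = table(best_pos)),
    class = "ranking_report"
  )
}

#' Aggregate metrics over independent runs
#'
#' Sample mean and sample standard deviation (n-1 denominator) per metric.
#'
#' @param reports Non-empty list of `metrics_report`s.
#' @return List with `mean` and `sd` (each a named numeric over accuracy,
#'   precision, recall, f1), `n_runs`, and the pooled count of degenerate
#'   metric evaluations.
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) == 0) {
    stop("Need at least one metrics report to aggregate", call. = FALSE)
  }
  keys <- c("accuracy", "precision", "recall", "f1")
  m <- vapply(reports, function(r) unlist(r[keys]), numeric(4))
  list(
    mean = rowMeans(m),
    sd = if (ncol(m) > 1) apply(m, 1, stats::sd) else
      stats::setNames(rep(NA_real_, 4), keys),
    n_runs = length(reports),
    n_degenerate = sum(vapply(reports, function(r) length(r$degenerate), 0L))
  )
}
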