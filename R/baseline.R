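#' Baseline predictor: top-scored pocket is positive
#'
#' The reference predictor for allosteric site detection: the pocket with
#' the highest FPocket pocket score (rank 1) in each protein is predicted
#' positive, every other pocket negative. Exactly one positive is emitted
#' per protein, so over a dataset the number of predicted positives equals
#' the number of proteins.
#'
#' @param labeled_set A `labeled_pocket_set` (labels are not consulted,
#'   only ranks).
#' @return A `baseline_prediction`: list with `protein_id`, `pocket_index`
#'   vector, and `predicted` 0/1 vector aligned with `labeled_set$pockets`.
#' @export
baseline_predict <- function(labeled_set) {
  pockets <- labeled_set$pockets
  if (length(pockets) == 0) {
    stop("Cannot run the baseline on an empty pocket list", call. = FALSE)
  }
  ranks <- vapply(pockets, function(p) p$rank, 0L)
  structure(
    list(
      protein_id = labeled_set$protein_id,
      pocket_index = vapply(pockets, function(p) p$pocket_index, 0L),
      predicted = as.integer(ranks == 1L)
    ),
    class = "baseline_prediction"
  )
}

#' Evaluate the baseline over a collection of proteins
#'
#' @param labeled_sets List of `labeled_pocket_set`s.
#' @return List with the pooled `confusion` matrix, its `metrics`, and
#'   `top1_rate` — the fraction of proteins whose rank-1 pocket is truly
#'   positive.
#' @export
baseline_evaluate <- function(labeled_sets) {
  truth <- integer()
  pred <- integer()
  top1_hits <- 0L
  for (s in labeled_sets) {
    p <- baseline_predict(s)
    y <- set_labels(s)
    truth <- c(truth, y)
    pred <- c(pred, p$predicted)
    top1_hits <- top1_hits + as.integer(y[p$predicted == 1L] == 1L)
  }
  cm <- confusion(truth, pred)
  list(confusion = cm, metrics = metrics(cm),
       top1_rate = top1_hits / length(labeled_sets))
}
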