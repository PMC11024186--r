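#' Enumerate topic-to-level bijections
#'
#' All `T!` ways to assign the `T` latent topics to the `T` health-status
#' levels, optionally restricted by per-topic admissible sets (prior
#' knowledge such as "topic 1 can only be infection or stress" cuts the
#' candidate list down). Matchings are returned in lexicographic order of the
#' topic -> level-index mapping.
#'
#' @param levels character vector of the health-status levels (length T).
#' @param constraints optional named/indexed list: `constraints[[t]]` is the
#'   character vector of levels admissible for topic `t` (NULL = all).
#' @return list of matchings; each is a character vector of length T whose
#'   t-th entry is the level matched to topic t.
#' @export
enumerate_matchings <- function(levels, constraints = NULL) {
  levels <- as.character(levels)
  T <- length(levels)
  if (T < 1L) stop("need at least one level")
  if (anyDuplicated(levels)) stop("duplicate levels")
  admissible <- lapply(seq_len(T), function(t) {
    if (is.null(constraints) || t > length(constraints) ||
        is.null(constraints[[t]])) return(seq_len(T))
    idx <- match(constraints[[t]], levels)
    if (anyNA(idx))
      stop("constraint for topic ", t, " names unknown level(s): ",
           paste(constraints[[t]][is.na(idx)], collapse = ", "))
    sort(idx)
  })
  out <- list()
  assign_next <- function(t, used, acc) {
    if (t > T) { out[[length(out) + 1L]] <<- levels[acc]; return(invisible()) }
    for (i in admissible[[t]]) {
      if (!used[i]) {
        used[i] <- TRUE
        assign_next(t + 1L, used, c(acc, i))
        used[i] <- FALSE
      }
    }
  }
  assign_next(1L, logical(T), integer(0))
  if (length(out) == 0L) stop("constraints admit no bijection")
  out
}

#' Confusion matrix with true classes in columns
#'
#' Fixed orientation throughout the package: **columns index the true
#' classes, rows the predicted classes**, both in `level_order`. Column sums
#' are therefore the true class sizes and the per-class true-positive rate is
#' the diagonal divided by the column sum.
#'
#' @param truth a [label_vector()] (or character vector of true levels).
#' @param predicted character vector of predicted levels, same length.
#' @param level_order level order; taken from `truth` when it is a
#'   `label_vector`.
#' @return C x C integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, level_order = NULL) {
  if (inherits(truth, "label_vector")) {
    if (is.null(level_order)) level_order <- truth$level_order
    truth <- truth$labels
  }
  if (is.null(level_order)) level_order <- unique(c(truth, predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length")
  bad <- setdiff(c(truth, predicted), level_order)
  if (length(bad) > 0L)
    stop("unknown level(s): ", paste(unique(bad), collapse = ", "))
  cm <- table(factor(predicted, levels = level_order),
              factor(truth, levels = level_order))
  cm <- matrix(as.integer(cm), nrow = length(level_order),
               dimnames = list(predicted = level_order, true = level_order))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Class-weighted accuracy (weighted mean of true-positive rates)
#'
#' `A_w = sum_t w_t * TPR_t` with `TPR_t = cm[t, t] / colsum_t`: the
#' class-weighted mean of per-class recalls, suited to unbalanced classes
#' where a rare class (e.g. infection) must not be swamped. A positively
#' weighted class absent from the truth leaves its TPR undefined and is an
#' error.
#'
#' @param cm a [confusion_matrix()] (columns = true).
#' @param w non-negative class weights summing to 1, in column order.
#' @return scalar in `[0, 1]`.
#' @export
weighted_accuracy <- function(cm, w) {
  cm <- unclass(cm)
  stopifnot(nrow(cm) == ncol(cm), length(w) == ncol(cm))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  cs <- colSums(cm)
  if (any(w > 0 & cs == 0))
    stop("true class with positive weight has no subjects: ",
         paste(colnames(cm)[w > 0 & cs == 0], collapse = ", "))
  tpr <- ifelse(cs > 0, diag(cm) / cs, 0)
  sum(w * tpr)
}

#' Weighted accuracy, precision and recall from a confusion matrix
#'
#' Weighted recall and weighted accuracy are both the class-weighted mean of
#' true-positive rates; weighted precision is the symmetric analogue over the
#' prediction margins, `sum_t w_t * cm[t, t] / rowsum_t`, with `0/0 -> 0`
#' when a class is never predicted.
#'
#' @inheritParams weighted_accuracy
#' @return named numeric vector `c(weighted_accuracy, weighted_precision,
#'   weighted_recall)`.
#' @export
weighted_metrics <- function(cm, w) {
  acc <- weighted_accuracy(cm, w)
  cmu <- unclass(cm)
  rs <- rowSums(cmu)
  prec <- sum(w * ifelse(rs > 0, diag(cmu) / rs, 0))
  c(weighted_accuracy = acc, weighted_precision = prec, weighted_recall = acc)
}

#' Find the topic-to-level matching that maximises weighted accuracy
#'
#' Scores every admissible bijection between topics and levels by relabelling
#' the hard topic assignments and computing the weighted accuracy against the
#' observed labels; the highest-scoring matching wins (ties break by
#' enumeration order). This is the semi-supervised step: the topics were
#' learned without labels, and the labels only choose their interpretation.
#'
#' @param assignments a [assign_topics()] result (or integer topic vector).
#' @param labels a [label_vector()]; `length(level_order)` must equal the
#'   number of topics.
#' @param w class weights in level order; default `(0.6, 0.15, 0.25)` style
#'   uniform fallback when NULL (equal weights).
#' @param constraints optional per-topic admissible level sets (see
#'   [enumerate_matchings()]).
#' @return list of class `matching_result`: `matching` (character vector,
#'   topic t -> level), `score`, `cm`, `candidates` (data.frame of every
#'   matching and its score).
#' @export
best_matching <- function(assignments, labels, w = NULL, constraints = NULL) {
  topic <- if (inherits(assignments, "topic_assignment"))
    assignments$topic else as.integer(assignments)
  stopifnot(inherits(labels, "label_vector"))
  levels <- labels$level_order
  T <- length(levels)
  if (max(topic) > T)
    stop(sprintf("topic index %d exceeds the number of levels (%d)",
                 max(topic), T))
  if (length(topic) != length(labels$labels))
    stop("assignments and labels differ in length")
  if (is.null(w)) w <- rep(1 / T, T)
  cands <- enumerate_matchings(levels, constraints)
  scores <- numeric(length(cands))
  cms <- vector("list", length(cands))
  for (k in seq_along(cands)) {
    predicted <- cands[[k]][topic]
    cms[[k]] <- confusion_matrix(labels, predicted)
    scores[k] <- weighted_accuracy(cms[[k]], w)
  }
  win <- which.max(scores) # first maximum = enumeration order tie-break
  structure(list(
    matching = cands[[win]], score = scores[win], cm = cms[[win]],
    candidates = data.frame(
      matching = vapply(cands, paste, character(1), collapse = ">"),
      score = scores, winner = seq_along(cands) == win)),
    class = "matching_result")
}

#' @export
print.matching_result <- function(x, ...) {
  cat(sprintf("matching: %s  (A_w = %.4f)\n",
              paste(sprintf("topic%d->%s", seq_along(x$matching), x$matching),
                    collapse = ", "), x$score))
  invisible(x)
}

#' Grid-search class weights
#'
#' Scores [best_matching()] over a user-supplied grid of weight vectors and
#' returns the grid with the achieved optimum per row.
#'
#' @param assignments,labels,constraints as in [best_matching()].
#' @param w_grid matrix (rows = weight vectors) or list of weight vectors.
#' @return data.frame of weights and the best achievable weighted accuracy.
#' @export
weight_grid_search <- function(assignments, labels, w_grid, constraints = NULL) {
  if (is.matrix(w_grid)) w_grid <- split(w_grid, row(w_grid))
  res <- lapply(w_grid, function(w) {
    bm <- best_matching(assignments, labels, w, constraints)
    c(w, score = bm$score)
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c(paste0("w", seq_len(length(res[[1]]) - 1L)), "score")
  rownames(out) <- NULL
  out
}
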