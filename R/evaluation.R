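#' Stratified train/test split with per-class floor rounding
#'
#' Per class, exactly `floor(train_fraction * n_c)` subjects are drawn
#' uniformly into the training set and the remainder go to test. With class
#' sizes (66, 6, 17) and an 80% fraction this yields a 52 + 4 + 13 = 69
#' subject training set and 20 test subjects.
#'
#' @param labels a [label_vector()].
#' @param train_fraction share of each class placed in training, in (0, 1).
#' @param seed RNG seed.
#' @return list with character vectors `train` and `test` of subject IDs.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(labels, "label_vector"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  with_seed(seed, {
    train <- character(0)
    for (lev in labels$level_order) {
      ids <- labels$subject_ids[labels$labels == lev]
      n_tr <- floor(train_fraction * length(ids))
      if (n_tr == 0L)
        warning(sprintf("class '%s' has no training subjects", lev))
      if (n_tr == length(ids))
        warning(sprintf("class '%s' has no test subjects", lev))
      train <- c(train, ids[sample.int(length(ids), n_tr)])
    }
    train <- labels$subject_ids[labels$subject_ids %in% train]
    list(train = train, test = setdiff(labels$subject_ids, train))
  })
}

#' Stratified k-fold assignment
#'
#' Shuffles each class and deals its subjects round-robin over the folds, so
#' fold test sizes are as equal as the class sizes allow.
#'
#' @param labels a [label_vector()].
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold numbers (1..k), named by subject ID.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(inherits(labels, "label_vector"), k >= 2L)
  with_seed(seed, {
    fold <- setNames(integer(length(labels$subject_ids)), labels$subject_ids)
    offset <- 0L
    for (lev in labels$level_order) {
      ids <- labels$subject_ids[labels$labels == lev]
      ids <- ids[sample.int(length(ids))]
      fold[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
      offset <- offset + length(ids)
    }
    fold
  })
}

subset_labels <- function(labels, ids) {
  keep <- labels$subject_ids %in% ids
  label_vector(labels$labels[keep], labels$subject_ids[keep],
               labels$level_order)
}

subset_counts <- function(counts, ids) {
  count_table(counts$counts[counts$subject_ids %in% ids, , drop = FALSE])
}

# one train/test round: fit + match on train only, fold test subjects in
eval_one_split <- function(counts, labels, train_ids, test_ids, w, T,
                           alpha, eta, iter, burnin, seed) {
  tr_c <- subset_counts(counts, train_ids)
  tr_l <- subset_labels(labels, train_ids)
  missing <- setdiff(labels$level_order, unique(tr_l$labels))
  if (length(missing) > 0L)
    stop("class(es) absent from training data: ",
         paste(missing, collapse = ", "))
  fit <- fit_lda(tr_c, T = T, alpha = alpha, eta = eta,
                 iter = iter, burnin = burnin, seed = seed)
  bm <- best_matching(assign_topics(fit$theta), tr_l, w)
  train_metrics <- weighted_metrics(bm$cm, w)
  te_c <- subset_counts(counts, test_ids)
  te_l <- subset_labels(labels, test_ids)
  te_theta <- infer_theta(fit, te_c)
  te_pred <- bm$matching[assign_topics(te_theta)$topic]
  te_cm <- confusion_matrix(te_l, te_pred)
  test_metrics <- weighted_metrics(te_cm, w)
  list(train = train_metrics, test = test_metrics, matching = bm$matching,
       train_cm = bm$cm, test_cm = te_cm,
       n_train = length(train_ids), n_test = length(test_ids))
}

#' Evaluate the semi-supervised classifier on held-out subjects
#'
#' Honest evaluation protocol: the topic model is fitted and the
#' topic-to-level matching chosen on training subjects only; test subjects
#' are folded in with the topic-taxon distributions frozen, hard-assigned to
#' their dominant topic, and classified through the *trained* matching.
#' Either a single stratified split or a stratified k-fold rotation.
#'
#' @param counts a [count_table()].
#' @param labels a [label_vector()].
#' @param w class weights in level order (NULL = equal).
#' @param T topics; default = number of levels.
#' @param split optional list(train, test) of subject IDs; when NULL, k-fold.
#' @param folds number of folds when `split` is NULL.
#' @param alpha,eta,iter,burnin passed to [fit_lda()].
#' @param seed master seed (split/folds and fits derive child seeds).
#' @return list of class `eval_report`: `per_fold` (data.frame of train/test
#'   metrics per fold), `aggregate` (mean metrics), `folds` (assignment),
#'   `details` (per-fold matchings and confusion matrices).
#' @export
evaluate_semisupervised <- function(counts, labels, w = NULL, T = NULL,
                                    split = NULL, folds = 5L,
                                    alpha = NULL, eta = 0.1,
                                    iter = 300L, burnin = 150L, seed = 1L) {
  stopifnot(inherits(counts, "count_table"), inherits(labels, "label_vector"))
  if (is.null(T)) T <- length(labels$level_order)
  if (is.null(w)) w <- rep(1 / length(labels$level_order),
                           length(labels$level_order))
  if (!is.null(split)) {
    parts <- list(split)
    fold_of <- setNames(rep(1L, length(split$test)), split$test)
  } else {
    fold_of <- make_folds(labels, k = folds, seed = child_seed(seed, "folds"))
    parts <- lapply(seq_len(folds), function(f)
      list(train = names(fold_of)[fold_of != f],
           test = names(fold_of)[fold_of == f]))
  }
  res <- lapply(seq_along(parts), function(f)
    eval_one_split(counts, labels, parts[[f]]$train, parts[[f]]$test, w, T,
                   alpha, eta, iter, burnin,
                   seed = child_seed(seed, paste0("fit-fold", f))))
  per_fold <- do.call(rbind, lapply(seq_along(res), function(f) {
    data.frame(fold = f, n_train = res[[f]]$n_train, n_test = res[[f]]$n_test,
               train_accuracy = res[[f]]$train[["weighted_accuracy"]],
               train_precision = res[[f]]$train[["weighted_precision"]],
               train_recall = res[[f]]$train[["weighted_recall"]],
               test_accuracy = res[[f]]$test[["weighted_accuracy"]],
               test_precision = res[[f]]$test[["weighted_precision"]],
               test_recall = res[[f]]$test[["weighted_recall"]])
  }))
  agg <- colMeans(per_fold[, -1])
  structure(list(per_fold = per_fold, aggregate = agg, folds = fold_of,
                 details = res),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report over", nrow(x$per_fold), "fold(s):\n")
  print(round(x$aggregate, 4))
  invisible(x)
}
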