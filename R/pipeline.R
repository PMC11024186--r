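#' Run the full RFSLDA pipeline
#'
#' End-to-end orchestration: (1) filter taxa by abundance-prevalence
#' concordance and aggregate the rest into "Others"; (2) optionally balance
#' the classes by SCUT; (3) fit the topic model; (4) match topics to
#' health-status levels by exhaustive enumeration under the weighted-accuracy
#' metric; (5) optionally run the randomized feature search and refit on the
#' selected subset; (6) derive per-class taxon profiles and within-group
#' similarity labels. Deterministic given (inputs, config seed): the report
#' is byte-identical across reruns.
#'
#' @param counts a [count_table()].
#' @param labels a [label_vector()]; its level count must equal `config$T`.
#' @param config an [rfslda_config()].
#' @param out optional output directory; when given, writes `report.json`,
#'   `confusion_matrix.tsv`, `theta.tsv`, `beta.tsv`,
#'   `similarity_labels.tsv`, and `selected_features.txt`/`rfs_trace.tsv`
#'   when the feature search ran.
#' @return list of class `rfslda_report` with elements `keep`, `matching`,
#'   `metrics`, `cm`, `model`, `similarity`, `profiles`, `rfs` (NULL when
#'   disabled), `selected`, `config`.
#' @export
run_pipeline <- function(counts, labels, config = rfslda_config(), out = NULL) {
  stopifnot(inherits(counts, "count_table"), inherits(labels, "label_vector"))
  validate_config(config)
  t_start <- as.numeric(Sys.time())
  B <- ncol(counts$counts)
  if (config$K > B)
    stop_stage("preprocess", "K = %d exceeds the number of taxa (%d)",
               config$K, B)
  if (config$T != length(labels$level_order))
    stop_stage("matching", "T = %d but there are %d label levels",
               config$T, length(labels$level_order))

  pre <- preprocess_counts(counts, K = config$K, omega = config$omega,
                           labels = labels, per_class = config$per_class_filter)
  Z <- pre$counts
  stage_log("preprocess", dim(Z$counts), t0 = t_start)

  if (isTRUE(config$balance$enabled)) {
    bal <- scut_balance(Z, labels, target = config$balance$target,
                        k = config$balance$k,
                        seed = child_seed(config$seed, "balance"),
                        on = config$balance$on)
    Z <- bal$counts; labels <- bal$labels
    stage_log("balance", dim(Z$counts), t0 = t_start)
  }

  fit_seed <- child_seed(config$seed, "fit")
  fit <- fit_lda(Z, T = config$T, alpha = config$alpha,
                 iter = config$lda$iter, burnin = config$lda$burnin,
                 seed = fit_seed)
  bm <- best_matching(assign_topics(fit$theta), labels, config$w)
  stage_log("fit+match", dim(Z$counts), seed = fit_seed, t0 = t_start)

  rfs <- NULL
  selected <- Z$taxon_names
  if (isTRUE(config$rfs$enabled)) {
    n <- length(Z$taxon_names)
    cfg_rfs <- rfs_config(n = n, c = config$rfs$c, p = config$rfs$p,
                          t0 = config$rfs$t0, u = config$rfs$u,
                          R = config$rfs$R, patience = config$rfs$patience,
                          max_moves = config$rfs$max_moves,
                          seed = child_seed(config$seed, "rfs"))
    scorer <- make_lda_scorer(Z, labels, w = config$w, T = config$T,
                              lda_seed = fit_seed,
                              iter = config$lda$iter,
                              burnin = config$lda$burnin,
                              alpha = config$alpha)
    rfs <- rfs_multi_restart(Z$taxon_names, cfg_rfs, scorer)
    selected <- rfs$best_subset
    Zsel <- count_table(Z$counts[, selected, drop = FALSE],
                        Z$subject_ids, selected)
    fit <- fit_lda(Zsel, T = config$T, alpha = config$alpha,
                   iter = config$lda$iter, burnin = config$lda$burnin,
                   seed = fit_seed)
    bm <- best_matching(assign_topics(fit$theta), labels, config$w)
    stage_log("feature-search", dim(Zsel$counts), seed = cfg_rfs$seed,
              t0 = t_start)
  }

  metrics <- weighted_metrics(bm$cm, config$w)
  sim <- similarity_labels(fit$theta, bm$matching, lambda = config$lambda)
  profiles <- class_feature_profile(fit, bm$matching,
                                    top_n = min(10L, ncol(fit$beta)))
  report <- structure(list(keep = pre$keep, tau = pre$tau,
                           matching = bm$matching, score = bm$score,
                           metrics = metrics, cm = bm$cm, model = fit,
                           similarity = sim, profiles = profiles,
                           rfs = rfs, selected = selected, config = config),
                      class = "rfslda_report")
  if (!is.null(out)) write_report(report, out)
  stage_log("report", t0 = t_start)
  report
}

#' @export
print.rfslda_report <- function(x, ...) {
  cat("RFSLDA report\n")
  cat(sprintf("  matching : %s\n",
              paste(sprintf("topic%d->%s", seq_along(x$matching), x$matching),
                    collapse = ", ")))
  cat(sprintf("  weighted accuracy = %.4f, precision = %.4f, recall = %.4f\n",
              x$metrics[["weighted_accuracy"]],
              x$metrics[["weighted_precision"]],
              x$metrics[["weighted_recall"]]))
  cat(sprintf("  features : %d selected of %d kept (+Others)\n",
              length(x$selected), length(x$keep)))
  invisible(x)
}

#' Write a pipeline report bundle to a directory
#'
#' Emits `report.json` (matching, metrics, selected taxa, config echo; fixed
#' numeric formatting so reruns are byte-identical), `confusion_matrix.tsv`
#' (columns = true classes), `theta.tsv`, `beta.tsv`,
#' `similarity_labels.tsv`, and the feature-search trace when present.
#'
#' @param report an `rfslda_report`.
#' @param out output directory (created if needed).
#' @return `out`, invisibly.
#' @export
write_report <- function(report, out) {
  stopifnot(inherits(report, "rfslda_report"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cm <- unclass(report$cm)
  payload <- list(
    matching = setNames(as.list(report$matching),
                        paste0("topic", seq_along(report$matching))),
    weighted_accuracy = round(report$metrics[["weighted_accuracy"]], 10),
    weighted_precision = round(report$metrics[["weighted_precision"]], 10),
    weighted_recall = round(report$metrics[["weighted_recall"]], 10),
    kept_taxa = report$keep,
    selected_taxa = report$selected,
    rfs_best_score = if (is.null(report$rfs)) NULL
                     else round(report$rfs$best_score, 10),
    seed = report$config$seed,
    T = report$config$T, K = report$config$K,
    w = report$config$w, lambda = report$config$lambda)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, file.path(out, "report.json"))
  write.table(cbind(predicted = rownames(cm), as.data.frame(cm)),
              file.path(out, "confusion_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(subject_id = rownames(report$model$theta),
                         report$model$theta, check.names = FALSE),
              file.path(out, "theta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(topic = rownames(report$model$beta),
                         report$model$beta, check.names = FALSE),
              file.path(out, "beta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$similarity, file.path(out, "similarity_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$rfs)) {
    write.table(report$rfs$trace, file.path(out, "rfs_trace.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(report$selected, file.path(out, "selected_features.txt"))
  }
  invisible(out)
}
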