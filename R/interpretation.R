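#' Per-health-status taxon profiles from the fitted topics
#'
#' For each health-status level, takes the beta row of the topic matched to
#' that level, sorts the taxa by estimated proportion and truncates to the
#' `top_n` largest. The row itself is left normalised over all taxa, so the
#' reported proportions are the topic's actual taxon probabilities.
#'
#' @param model a fitted [fit_lda()] model.
#' @param matching character vector from [best_matching()] (`matching[t]` =
#'   level matched to topic t).
#' @param top_n number of taxa reported per level.
#' @return named list (by level) of data.frames with columns `taxon`,
#'   `proportion`, in decreasing proportion.
#' @export
class_feature_profile <- function(model, matching, top_n = 10L) {
  stopifnot(inherits(model, "topic_model"))
  if (inherits(matching, "matching_result")) matching <- matching$matching
  if (length(matching) != model$T)
    stop("matching must cover all topics")
  if (top_n > ncol(model$beta))
    stop(sprintf("top_n = %d exceeds the number of taxa (%d)",
                 top_n, ncol(model$beta)))
  out <- lapply(seq_len(model$T), function(t) {
    row <- model$beta[t, ]
    ord <- order(-row, names(row))
    data.frame(taxon = names(row)[ord][seq_len(top_n)],
               proportion = unname(row[ord][seq_len(top_n)]))
  })
  names(out) <- matching
  out
}

#' Within-group similarity labels from topic proportions
#'
#' Each subject's primary level is the matched level of its largest topic
#' proportion. Subjects whose largest proportion reaches the threshold
#' `lambda` are labelled "Predominantly <level>"; the rest are labelled
#' "<level>-<second level>" by their top two matched levels, exposing which
#' subjects within a group are borderline between statuses. Ties (for the
#' first or the second slot) break toward the lowest topic index.
#'
#' @param theta M x T row-stochastic matrix of topic proportions.
#' @param matching character vector, `matching[t]` = level of topic t.
#' @param lambda similarity threshold in `(0, 1]`; default 0.7.
#' @param subject_ids optional subject IDs (defaults to theta rownames).
#' @return data.frame with columns `subject_id`, `primary`, `label`, `pi1`,
#'   `pi2`.
#' @export
similarity_labels <- function(theta, matching, lambda = 0.7,
                              subject_ids = rownames(theta)) {
  theta <- as.matrix(theta)
  if (inherits(matching, "matching_result")) matching <- matching$matching
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  if (length(matching) != ncol(theta))
    stop("matching must cover all topics")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(theta)))
  first <- max.col(theta, ties.method = "first")
  pi1 <- theta[cbind(seq_len(nrow(theta)), first)]
  theta2 <- theta
  theta2[cbind(seq_len(nrow(theta)), first)] <- -Inf
  second <- max.col(theta2, ties.method = "first")
  pi2 <- theta[cbind(seq_len(nrow(theta)), second)]
  primary <- matching[first]
  label <- ifelse(pi1 >= lambda,
                  paste("Predominantly", primary),
                  paste(primary, matching[second], sep = "-"))
  data.frame(subject_id = subject_ids, primary = primary, label = label,
             pi1 = pi1, pi2 = pi2)
}
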