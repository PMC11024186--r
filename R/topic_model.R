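#' Fit the latent Dirichlet allocation model to a count table
#'
#' Subjects play the role of documents and taxa the role of words: each
#' subject is a mixture over `T` latent sub-communities (topics), each topic
#' a probability distribution over taxa. The model is estimated by collapsed
#' Gibbs sampling with a symmetric Dirichlet(alpha) prior on the per-subject
#' topic proportions theta and a symmetric Dirichlet(eta) prior on the
#' per-topic taxon distributions beta; theta and beta are posterior means
#' averaged over the post-burn-in sweeps. The fit never sees health-status
#' labels (unsupervised contract); the Poisson law for per-subject totals in
#' the generative story is ancillary once counts are observed and plays no
#' role in estimation.
#'
#' @param counts a [count_table()] with positive row totals.
#' @param T number of topics, `T >= 1`.
#' @param alpha symmetric Dirichlet concentration for theta; default `50 / T`.
#' @param eta symmetric Dirichlet smoothing for beta (keeps every taxon
#'   probability positive, so perplexity is finite); default 0.1.
#' @param iter total Gibbs sweeps.
#' @param burnin sweeps discarded before averaging.
#' @param seed integer seed; the same seed reproduces the fit exactly.
#' @return an object of class `topic_model`: `theta` (M x T, rows sum to 1),
#'   `beta` (T x B, rows sum to 1), `alpha`, `eta`, `T`, `loglik` (per-sweep
#'   joint log-likelihood trace), `seed`, `method`, `taxon_names`,
#'   `subject_ids`.
#' @export
fit_lda <- function(counts, T = 3L, alpha = NULL, eta = 0.1,
                    iter = 300L, burnin = 150L, seed = 1L) {
  stopifnot(inherits(counts, "count_table"))
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  M <- nrow(counts$counts); B <- ncol(counts$counts)
  if (any(rowSums(counts$counts) == 0))
    stop("subject(s) with zero total count: ",
         paste(counts$subject_ids[rowSums(counts$counts) == 0], collapse = ", "))
  if (T > M) warning(sprintf("T = %d exceeds the number of subjects (%d)", T, M))
  if (is.null(alpha)) alpha <- 50 / T
  if (alpha <= 0 || eta <= 0) stop("alpha and eta must be positive")
  fit <- .lda_gibbs_cpp(counts$counts, T, alpha, eta,
                        as.integer(iter), as.integer(burnin), as.integer(seed))
  theta <- fit$theta; beta <- fit$beta
  dimnames(theta) <- list(counts$subject_ids, paste0("topic", seq_len(T)))
  dimnames(beta) <- list(paste0("topic", seq_len(T)), counts$taxon_names)
  structure(list(theta = theta, beta = beta, alpha = alpha, eta = eta,
                 T = T, loglik = fit$loglik, seed = as.integer(seed),
                 method = "collapsed-gibbs", iter = as.integer(iter),
                 burnin = as.integer(burnin),
                 taxon_names = counts$taxon_names,
                 subject_ids = counts$subject_ids),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("topic_model: T=%d, %d subjects x %d taxa (%s, alpha=%.3g)\n",
              x$T, nrow(x$theta), ncol(x$beta), x$method, x$alpha))
  invisible(x)
}

#' Infer topic proportions for subjects with the topic-taxon distributions
#' held fixed
#'
#' Fold-in inference for held-out subjects: `beta` is frozen from the fitted
#' model and only the per-subject mixture theta is estimated, by EM on the
#' multinomial mixture with the same Dirichlet(alpha) posterior-mean
#' smoothing the sampler uses. Deterministic (no sampling).
#'
#' @param model a fitted [fit_lda()] model.
#' @param counts a [count_table()] whose taxa match the model's.
#' @param max_iter EM iterations cap.
#' @param tol convergence tolerance on theta (max absolute change).
#' @return M x T row-stochastic matrix of topic proportions.
#' @export
infer_theta <- function(model, counts, max_iter = 200L, tol = 1e-10) {
  stopifnot(inherits(model, "topic_model"), inherits(counts, "count_table"))
  if (!identical(counts$taxon_names, model$taxon_names))
    stop("taxon names of counts do not match the fitted model")
  tot <- rowSums(counts$counts)
  if (any(tot == 0))
    stop("subject(s) with zero total count: ",
         paste(counts$subject_ids[tot == 0], collapse = ", "))
  T <- model$T; alpha <- model$alpha
  beta <- model$beta
  M <- nrow(counts$counts)
  theta <- matrix(1 / T, M, T)
  for (i in seq_len(M)) {
    n <- counts$counts[i, ]
    keep <- which(n > 0)
    nl <- n[keep]; bl <- beta[, keep, drop = FALSE] # T x |keep|
    th <- rep(1 / T, T)
    for (it in seq_len(max_iter)) {
      resp <- th * bl                       # T x |keep|
      resp <- sweep(resp, 2, colSums(resp), "/")
      ct <- as.numeric(resp %*% nl)         # expected tokens per topic
      th_new <- (ct + alpha) / (sum(nl) + T * alpha)
      if (max(abs(th_new - th)) < tol) { th <- th_new; break }
      th <- th_new
    }
    theta[i, ] <- th
  }
  dimnames(theta) <- list(counts$subject_ids, colnames(model$theta))
  theta
}

#' Model perplexity on a count table
#'
#' `exp(-log L / N)` where `log L` sums, over every read, the log of the
#' subject's mixture probability `sum_t theta[i, t] * beta[t, l]` and `N` is
#' the total read count. For the training subjects the fitted theta is used;
#' for new subjects theta is folded in first. Lower is better; used to choose
#' the number of topics.
#'
#' @param model a fitted [fit_lda()] model.
#' @param counts a [count_table()] sharing the model's taxa.
#' @return a positive scalar.
#' @export
perplexity <- function(model, counts) {
  stopifnot(inherits(model, "topic_model"), inherits(counts, "count_table"))
  if (!identical(counts$taxon_names, model$taxon_names))
    stop("taxon names of counts do not match the fitted model")
  theta <- if (identical(counts$subject_ids, model$subject_ids))
    model$theta else infer_theta(model, counts)
  mix <- theta %*% model$beta               # M x B
  ll <- sum(counts$counts * log(mix))
  exp(-ll / sum(counts$counts))
}

#' Hard topic labels from topic proportions
#'
#' Assigns each subject the topic with the highest proportion; ties break
#' toward the lowest topic index.
#'
#' @param theta M x T row-stochastic matrix (rows must sum to 1).
#' @return an object of class `topic_assignment`: integer vector `topic`
#'   (1-based) plus the `theta` it came from.
#' @export
assign_topics <- function(theta) {
  theta <- as.matrix(theta)
  if (nrow(theta) == 0L) stop("empty theta")
  if (any(abs(rowSums(theta) - 1) > 1e-6))
    stop("theta rows must sum to 1")
  structure(list(topic = max.col(theta, ties.method = "first"),
                 theta = theta),
            class = "topic_assignment")
}

#' Choose the number of topics by held-out perplexity
#'
#' Refits the model over a grid of `T` and reports training perplexity for
#' each; the minimising `T` is flagged.
#'
#' @param counts a [count_table()].
#' @param T_grid candidate topic counts.
#' @param seed seed shared across fits.
#' @param ... further arguments to [fit_lda()].
#' @return data.frame with columns `T`, `perplexity`, `best`.
#' @export
select_T <- function(counts, T_grid = 2:10, seed = 1L, ...) {
  px <- vapply(T_grid, function(Tt) {
    m <- fit_lda(counts, T = Tt, seed = seed, ...)
    perplexity(m, counts)
  }, numeric(1))
  data.frame(T = T_grid, perplexity = px, best = seq_along(px) == which.min(px))
}
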