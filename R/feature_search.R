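#' Configuration for the randomized feature search
#'
#' Settings of the add/remove/swap local search over taxon subsets:
#' `c` features changed per move (default 1), initial subset size
#' `p = ceiling(n/2)`, improvement tolerance `t0 = 1e-4`, stay probability
#' `u = 0.5` on non-improving moves, `R = 50` restarts, and stopping after
#' `patience` consecutive moves without an improvement larger than `t0`
#' (hard-capped at `max_moves`).
#'
#' @param n size of the feature space searched.
#' @param c features changed per move.
#' @param p initial subset size; NULL for `ceiling(n/2)`.
#' @param t0 minimum improvement counted as progress.
#' @param u probability of staying put when a move does not improve.
#' @param R number of independent restarts.
#' @param patience consecutive non-improving moves before stopping.
#' @param max_moves hard cap on moves per restart.
#' @param seed master seed for the search.
#' @return list of class `rfs_config`.
#' @export
rfs_config <- function(n, c = 1L, p = NULL, t0 = 1e-4, u = 0.5, R = 50L,
                       patience = 100L, max_moves = 2000L, seed = 1L) {
  n <- as.integer(n)
  if (is.null(p)) p <- as.integer(ceiling(n / 2))
  p <- as.integer(p)
  stopifnot(n >= 1L, p >= 1L, p <= n, c >= 1L, t0 >= 0, u >= 0, u <= 1,
            R >= 1L, patience >= 1L, max_moves >= 0L)
  structure(list(n = n, c = as.integer(c), p = p, t0 = t0, u = u,
                 R = as.integer(R), patience = as.integer(patience),
                 max_moves = as.integer(max_moves), seed = as.integer(seed)),
            class = "rfs_config")
}

#' Propose a neighbouring feature subset
#'
#' One move of the search, driven by an unbiased three-sided coin:
#' side 1 swaps `c` members for `c` non-members (size preserved), side 2
#' removes `c` members, side 3 adds `c` non-members. A side whose move would
#' push the subset size outside `[1, n]` is infeasible and the coin is
#' redrawn uniformly among the feasible sides. Uses R's RNG; seed outside.
#'
#' @param current character vector, the current subset.
#' @param full character vector, the whole feature space.
#' @param coin 1, 2 or 3; NULL to flip internally.
#' @param c features changed per move.
#' @return the proposed subset (character vector) with attribute `coin`
#'   (the side actually used).
#' @export
propose_move <- function(current, full, coin = NULL, c = 1L) {
  stopifnot(length(current) >= 1L, all(current %in% full))
  n <- length(full)
  pick <- function(x, k) x[sample.int(length(x), k)] # no scalar surprise
  outside <- setdiff(full, current)
  feasible <- c(`1` = length(current) >= c && length(outside) >= c,
                `2` = length(current) - c >= 1L,
                `3` = length(current) + c <= n)
  if (!any(feasible)) return(structure(current, coin = NA_integer_))
  if (is.null(coin)) coin <- sample.int(3L, 1L)
  if (!feasible[coin]) coin <- pick(which(feasible), 1L)
  out <- switch(coin,
    c(setdiff(current, pick(current, c)), pick(outside, c)),
    setdiff(current, pick(current, c)),
    c(current, pick(outside, c)))
  structure(out, coin = as.integer(coin))
}

#' Accept or reject a proposed move
#'
#' A strictly better score always moves; otherwise the search stays with
#' probability `u` and moves anyway with probability `1 - u`, so it can walk
#' out of local maxima.
#'
#' @param new_score,old_score weighted accuracies of proposal and incumbent.
#' @param u stay probability on non-improvement.
#' @return `"move"` or `"stay"`.
#' @export
accept_move <- function(new_score, old_score, u = 0.5) {
  stopifnot(is.finite(new_score), is.finite(old_score))
  if (new_score > old_score) return("move")
  if (runif(1) < u) "stay" else "move"
}

#' Build the default subset scorer: the semi-supervised LDA pipeline
#'
#' Returns a deterministic function `subset -> A_w` that restricts the count
#' table to the subset's columns (dropped features are simply excluded, with
#' no re-aggregation), refits the topic model with a fixed seed, finds the
#' best topic-to-level matching, and returns its weighted accuracy. Scores
#' are cached by subset, since the search revisits subsets often and the LDA
#' refit dominates the cost. Subjects whose reads vanish entirely under a
#' candidate subset make the LDA unfittable; such subsets score `-Inf`.
#'
#' @param counts a [count_table()].
#' @param labels a [label_vector()].
#' @param w class weights in level order.
#' @param T topics; default = number of levels.
#' @param lda_seed fixed seed for every refit (scorer determinism).
#' @param iter,burnin Gibbs settings for the refits.
#' @param alpha,eta passed to [fit_lda()].
#' @param constraints optional matching constraints.
#' @return function of a character subset returning its weighted accuracy.
#' @export
make_lda_scorer <- function(counts, labels, w = NULL, T = NULL,
                            lda_seed = 1L, iter = 150L, burnin = 75L,
                            alpha = NULL, eta = 0.1, constraints = NULL) {
  stopifnot(inherits(counts, "count_table"), inherits(labels, "label_vector"))
  if (is.null(T)) T <- length(labels$level_order)
  cache <- new.env(parent = emptyenv())
  function(subset) {
    key <- paste(sort(subset), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    score <- tryCatch({
      sub <- count_table(counts$counts[, subset, drop = FALSE],
                         counts$subject_ids, subset)
      if (any(rowSums(sub$counts) == 0)) stop("empty subject under subset")
      fit <- fit_lda(sub, T = T, alpha = alpha, eta = eta,
                     iter = iter, burnin = burnin, seed = lda_seed)
      best_matching(assign_topics(fit$theta), labels, w, constraints)$score
    }, error = function(e) -Inf)
    cache[[key]] <- score
    score
  }
}

#' One restart of the randomized feature search
#'
#' Starts from a uniformly random subset of size `p`, then repeatedly flips
#' the three-sided coin, proposes, scores and accepts/rejects until the best
#' score has failed to improve by more than `t0` for `patience` consecutive
#' moves (or `max_moves` is hit). The best-scoring subset ever visited is
#' returned together with the full move trace.
#'
#' @param full character vector, the feature space.
#' @param cfg an [rfs_config()].
#' @param scorer function subset -> score (see [make_lda_scorer()]).
#' @param seed seed for this restart.
#' @return list: `best_subset`, `best_score`, `trace` (data.frame with move,
#'   coin, accepted, score, best).
#' @export
rfs_single_run <- function(full, cfg, scorer, seed = cfg$seed) {
  stopifnot(inherits(cfg, "rfs_config"), length(full) == cfg$n)
  with_seed(seed, {
    current <- full[sample.int(cfg$n, cfg$p)]
    cur_score <- scorer(current)
    best_subset <- current; best_score <- cur_score
    trace <- list(list(move = 0L, coin = NA_integer_, accepted = NA,
                       score = cur_score, best = best_score))
    stale <- 0L; move <- 0L
    while (stale < cfg$patience && move < cfg$max_moves && cfg$n > 1L) {
      move <- move + 1L
      prop <- propose_move(current, full, coin = NULL, c = cfg$c)
      prop_score <- scorer(as.character(prop))
      decision <- accept_move(prop_score, cur_score, cfg$u)
      if (decision == "move") {
        current <- as.character(prop); cur_score <- prop_score
      }
      if (prop_score > best_score + cfg$t0) {
        best_score <- prop_score; best_subset <- as.character(prop)
        stale <- 0L
      } else {
        if (prop_score > best_score) {
          best_score <- prop_score; best_subset <- as.character(prop)
        }
        stale <- stale + 1L
      }
      trace[[length(trace) + 1L]] <-
        list(move = move, coin = attr(prop, "coin"),
             accepted = decision == "move", score = prop_score,
             best = best_score)
    }
    trace <- do.call(rbind, lapply(trace, as.data.frame))
    list(best_subset = best_subset, best_score = best_score, trace = trace)
  })
}

#' Multi-restart randomized feature search
#'
#' Runs [rfs_single_run()] `R` times from independent random initial subsets
#' (child seeds derived from `cfg$seed`) and returns the restart with the
#' highest best score (ties: lowest restart index), so the selected subset is
#' not an artefact of one initialisation.
#'
#' @inheritParams rfs_single_run
#' @return list of class `rfs_result`: `best_subset`, `best_score`,
#'   `winner` (restart index), `restarts` (per-restart results), `trace`
#'   (row-bound traces with a restart column).
#' @export
rfs_multi_restart <- function(full, cfg, scorer) {
  runs <- vector("list", cfg$R)
  for (r in seq_len(cfg$R)) {
    runs[[r]] <- rfs_single_run(full, cfg, scorer,
                                seed = child_seed(cfg$seed, paste0("restart", r)))
  }
  scores <- vapply(runs, `[[`, numeric(1), "best_score")
  win <- which.max(scores)
  trace <- do.call(rbind, lapply(seq_along(runs), function(r)
    cbind(restart = r, runs[[r]]$trace)))
  structure(list(best_subset = runs[[win]]$best_subset,
                 best_score = scores[win], winner = win,
                 restart_scores = scores, restarts = runs, trace = trace),
            class = "rfs_result")
}

#' @export
print.rfs_result <- function(x, ...) {
  cat(sprintf("rfs_result: best A_w = %.4f (restart %d), %d features:\n  %s\n",
              x$best_score, x$winner, length(x$best_subset),
              paste(x$best_subset, collapse = ", ")))
  invisible(x)
}
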