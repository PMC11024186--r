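#' Convert counts to within-subject relative abundances
#'
#' Each row of the count table is divided by its total, giving the M x B
#' matrix of proportions p[i, l] used by the abundance and prevalence
#' summaries. A subject with zero total reads has no composition and is an
#' error.
#'
#' @param counts a [count_table()].
#' @return an object of class `proportion_table` with fields `props`,
#'   `subject_ids`, `taxon_names`.
#' @export
compute_proportions <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  tot <- rowSums(counts$counts)
  if (any(tot == 0))
    stop("subject(s) with zero total count: ",
         paste(counts$subject_ids[tot == 0], collapse = ", "))
  structure(list(props = counts$counts / tot,
                 subject_ids = counts$subject_ids,
                 taxon_names = counts$taxon_names),
            class = "proportion_table")
}

#' Per-taxon abundance and prevalence
#'
#' Abundance of taxon l is the column sum of the proportion table (total
#' relative abundance across subjects, so the abundances sum to M).
#' Prevalence is the number of subjects whose proportion of the taxon meets
#' the detection threshold `omega`.
#'
#' @param P a `proportion_table` from [compute_proportions()].
#' @param omega detection threshold in `[0, 1)`.
#' @return an object of class `feature_summary` with fields `abundance`,
#'   `prevalence`, `omega`, `indicator` (the M x B detection matrix) and
#'   `taxon_names`.
#' @export
summarize_features <- function(P, omega = 0.001) {
  stopifnot(inherits(P, "proportion_table"))
  if (omega < 0 || omega >= 1) stop("omega must lie in [0, 1)")
  ind <- P$props >= omega
  structure(list(abundance = colSums(P$props),
                 prevalence = as.integer(colSums(ind)),
                 omega = omega, indicator = ind,
                 taxon_names = P$taxon_names),
            class = "feature_summary")
}

# Kendall tau between abundance and prevalence restricted to a set of taxa;
# degenerate (constant) vectors count as perfect concordance.
subset_tau <- function(a, p, idx) {
  if (length(idx) < 2L) return(1)
  if (length(unique(a[idx])) < 2L || length(unique(p[idx])) < 2L) return(1)
  suppressWarnings(cor(a[idx], p[idx], method = "kendall"))
}

#' Rank taxa by abundance-prevalence concordance and keep the top K
#'
#' A deterministic surrogate for tau-path filtering: taxa are first ordered
#' by descending rank-sum of their abundance rank and prevalence rank (ties
#' broken by taxon name), then backward-eliminated from the tail -- at each
#' step the tail-most taxon whose removal raises the Kendall tau between
#' abundance and prevalence over the retained set is dropped (the plain tail
#' taxon if no removal helps) -- until exactly K remain.
#'
#' @param summary a `feature_summary` from [summarize_features()].
#' @param K number of taxa to keep, `1 <= K <= B`.
#' @return character vector of the K kept taxon names (concordance order),
#'   with attribute `tau` = Kendall tau of the kept set.
#' @export
taupath_rank <- function(summary, K) {
  stopifnot(inherits(summary, "feature_summary"))
  B <- length(summary$taxon_names)
  if (K < 1L || K > B) stop(sprintf("K must lie in [1, %d], got %s", B, K))
  a <- summary$abundance; p <- summary$prevalence
  nm <- summary$taxon_names
  ra <- rank(a, ties.method = "average")
  rp <- rank(p, ties.method = "average")
  rs <- ra + rp
  # descending rank-sum; lexicographic taxon name breaks ties
  ord <- order(-rs, nm)
  retained <- ord
  while (length(retained) > K) {
    tau_now <- subset_tau(a, p, retained)
    drop_at <- length(retained) # default: drop the tail
    for (j in rev(seq_along(retained))) {
      if (subset_tau(a, p, retained[-j]) > tau_now + 1e-12) { drop_at <- j; break }
    }
    retained <- retained[-drop_at]
  }
  structure(nm[retained], tau = subset_tau(a, p, retained))
}

#' Filter per class and union the selections
#'
#' Alternative preprocessing: apply [taupath_rank()] within each health-status
#' class separately and keep the union of the per-class top-K sets.
#'
#' @param counts a [count_table()].
#' @param labels a [label_vector()].
#' @param K per-class number of taxa to keep.
#' @param omega detection threshold.
#' @return character vector of kept taxon names (original column order).
#' @export
taupath_rank_per_class <- function(counts, labels, K, omega = 0.001) {
  stopifnot(inherits(counts, "count_table"), inherits(labels, "label_vector"))
  keep <- character(0)
  for (lev in labels$level_order) {
    rows <- which(labels$labels == lev)
    if (length(rows) == 0L) next
    sub <- count_table(counts$counts[rows, , drop = FALSE])
    s <- summarize_features(compute_proportions(sub), omega)
    keep <- union(keep, taupath_rank(s, min(K, ncol(counts$counts))))
  }
  counts$taxon_names[counts$taxon_names %in% keep]
}

#' Aggregate non-selected taxa into a single "Others" column
#'
#' Keeps the selected taxa (in their given order) and sums all remaining
#' columns into one trailing column so that per-subject totals are conserved
#' exactly.
#'
#' @param counts a [count_table()].
#' @param keep character vector of taxon names to keep.
#' @param others_name name for the aggregate column.
#' @return a [count_table()] with `length(keep) + 1` columns.
#' @export
aggregate_others <- function(counts, keep, others_name = "Others") {
  stopifnot(inherits(counts, "count_table"))
  keep <- as.character(keep)
  if (anyDuplicated(keep)) stop("duplicate taxa in keep set")
  missing <- setdiff(keep, counts$taxon_names)
  if (length(missing) > 0L)
    stop("keep set not in table: ", paste(missing, collapse = ", "))
  if (others_name %in% keep)
    stop(sprintf("'%s' collides with a kept taxon name", others_name))
  drop <- setdiff(counts$taxon_names, keep)
  others <- if (length(drop) > 0L)
    as.integer(rowSums(counts$counts[, drop, drop = FALSE]))
  else rep(0L, nrow(counts$counts))
  out <- cbind(counts$counts[, keep, drop = FALSE], others)
  colnames(out) <- c(keep, others_name)
  count_table(out, counts$subject_ids, colnames(out))
}

#' Full preprocessing step: filter and aggregate
#'
#' Computes proportions, abundance and prevalence, keeps the top-K taxa by
#' concordance (globally, or per class when `per_class`), and folds the rest
#' into "Others".
#'
#' @param counts a [count_table()].
#' @param K taxa to keep.
#' @param omega detection threshold.
#' @param labels optional [label_vector()], needed for `per_class`.
#' @param per_class filter within classes and union the picks.
#' @return list with `counts` (the filtered table), `keep`, `summary`, `tau`.
#' @export
preprocess_counts <- function(counts, K = 50L, omega = 0.001,
                              labels = NULL, per_class = FALSE) {
  s <- summarize_features(compute_proportions(counts), omega)
  if (per_class) {
    if (is.null(labels)) stop("per-class filtering needs labels")
    keep <- taupath_rank_per_class(counts, labels, K, omega)
    tau <- NA_real_
  } else {
    keep <- taupath_rank(s, min(K, length(counts$taxon_names)))
    tau <- attr(keep, "tau")
  }
  list(counts = aggregate_others(counts, as.character(keep)),
       keep = as.character(keep), summary = s, tau = tau)
}
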