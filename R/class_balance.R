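#' SMOTE oversampling of one class
#'
#' Synthetic minority oversampling: each synthetic row is
#' `x + delta * (x_nn - x)` where `x` is an existing row of the class,
#' `x_nn` one of its `k` nearest same-class neighbours (Euclidean) and
#' `delta ~ Uniform(0, 1)` -- a point on the segment between the two, which
#' enlarges the minority decision region. For count semantics the synthetic
#' rows are rounded to non-negative integers; the pre-rounding rows are kept
#' as the `raw` attribute so the convexity bound can be audited. `k` is
#' clamped to `nrow(X) - 1` for tiny classes; a singleton class replicates
#' itself.
#'
#' @param X numeric matrix, the rows of one class.
#' @param target desired number of rows, `>= nrow(X)`.
#' @param k nearest-neighbour count.
#' @param seed RNG seed.
#' @return matrix with `target` rows: the originals followed by synthetic
#'   rows; attributes `raw` (pre-rounding synthetic rows) and `provenance`
#'   (data.frame seed_row, neighbor_row, delta).
#' @export
smote_oversample <- function(X, target, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1L) stop("class is empty")
  if (target < n) stop("target below current class size")
  n_syn <- target - n
  if (n_syn == 0L) return(structure(X, raw = X[0, , drop = FALSE],
                                    provenance = data.frame()))
  k <- max(1L, min(as.integer(k), n - 1L))
  with_seed(seed, {
    if (n == 1L) {
      nn_idx <- matrix(1L, 1L, 1L)
    } else {
      D <- as.matrix(dist(X))
      diag(D) <- Inf
      nn_idx <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
    }
    base <- rep_len(seq_len(n), n_syn) # cycle through seeds evenly
    nb <- vapply(base, function(i) nn_idx[i, sample.int(ncol(nn_idx), 1L)],
                 integer(1))
    delta <- runif(n_syn)
    raw <- X[base, , drop = FALSE] +
      delta * (X[nb, , drop = FALSE] - X[base, , drop = FALSE])
    syn <- pmax(round(raw), 0)
    out <- rbind(X, syn)
    structure(out, raw = raw,
              provenance = data.frame(seed_row = base, neighbor_row = nb,
                                      delta = delta))
  })
}

#' Cluster-based undersampling of one class
#'
#' Partitions the class rows into `min(target, #distinct rows)` clusters by
#' seeded k-means and keeps, per cluster, the rows closest to the cluster
#' centre -- at least one from every cluster -- until exactly `target`
#' original rows remain. Keeping one representative per sub-cluster preserves
#' the spread of the majority class better than uniform thinning.
#'
#' @param X numeric matrix, the rows of one class.
#' @param target desired number of rows, `<= nrow(X)`.
#' @param seed RNG seed.
#' @return integer vector of the kept row indices (sorted).
#' @export
cluster_undersample <- function(X, target, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (target > n) stop("target above current class size")
  if (target == n) return(seq_len(n))
  n_distinct <- nrow(unique(X))
  n_clust <- min(target, n_distinct)
  with_seed(seed, {
    km <- kmeans(X, centers = n_clust, nstart = 5L, iter.max = 50L)
    # within each cluster, order rows by distance to the centre
    ranked <- lapply(seq_len(n_clust), function(cl) {
      rows <- which(km$cluster == cl)
      d <- rowSums((X[rows, , drop = FALSE] -
                    matrix(km$centers[cl, ], length(rows), ncol(X),
                           byrow = TRUE))^2)
      rows[order(d, rows)]
    })
    kept <- integer(0)
    rank <- 1L
    while (length(kept) < target) { # round-robin: one per cluster, then seconds, ...
      for (cl in seq_len(n_clust)) {
        if (length(kept) >= target) break
        if (rank <= length(ranked[[cl]])) kept <- c(kept, ranked[[cl]][rank])
      }
      rank <- rank + 1L
    }
    sort(kept)
  })
}

#' SCUT hybrid balancing of a labelled count table
#'
#' Equalises the class sizes of a subjects-by-taxa table: classes below the
#' per-class target are SMOTE-oversampled, classes above it are
#' cluster-undersampled, classes at the target pass through unchanged. The
#' default target `round(M / C)` turns the study-shaped class sizes
#' (66, 6, 17) into 30 + 30 + 30 = 90 subjects. Synthetic subjects get IDs
#' `<seed subject>_syn<k>`.
#'
#' @param counts a [count_table()].
#' @param labels a [label_vector()].
#' @param target per-class size; NULL for `round(M / C)`.
#' @param k SMOTE neighbour count (clamped per class).
#' @param seed master seed; per-class child seeds are derived from it.
#' @param on `"counts"` (SMOTE on raw counts, default) or `"proportions"`
#'   (SMOTE on relative abundances, rescaled by the class median depth).
#' @return list with `counts` (balanced [count_table()]), `labels`
#'   (balanced [label_vector()]) and `provenance` (per-class SMOTE records).
#' @export
scut_balance <- function(counts, labels, target = NULL, k = 5L, seed = 1L,
                         on = c("counts", "proportions")) {
  stopifnot(inherits(counts, "count_table"), inherits(labels, "label_vector"))
  on <- match.arg(on)
  M <- nrow(counts$counts)
  C <- length(labels$level_order)
  if (is.null(target)) target <- round(M / C)
  target <- as.integer(target)
  if (target < 1L) stop("target must be >= 1")
  sizes <- table(factor(labels$labels, levels = labels$level_order))
  if (any(sizes == 0)) stop("empty class: ",
                            paste(names(sizes)[sizes == 0], collapse = ", "))
  rows_out <- NULL; ids_out <- character(0); labs_out <- character(0)
  provenance <- list()
  for (lev in labels$level_order) {
    idx <- which(labels$labels == lev)
    Xc <- counts$counts[idx, , drop = FALSE]
    ids <- counts$subject_ids[idx]
    s <- child_seed(seed, paste0("balance:", lev))
    if (length(idx) > target) {
      kept <- cluster_undersample(Xc, target, seed = s)
      Xb <- Xc[kept, , drop = FALSE]; idb <- ids[kept]
    } else if (length(idx) < target) {
      feat <- if (on == "proportions") Xc / rowSums(Xc) else Xc
      sm <- smote_oversample(feat, target, k = k, seed = s)
      prov <- attr(sm, "provenance")
      syn <- if (on == "proportions") {
        depth <- stats::median(rowSums(Xc))
        pmax(round(attr(sm, "raw") * depth), 0)
      } else sm[-seq_len(length(idx)), , drop = FALSE]
      idb <- c(ids, paste0(ids[prov$seed_row], "_syn", seq_len(nrow(syn))))
      Xb <- rbind(Xc, syn)
      prov$level <- lev
      prov$synthetic_id <- paste0(ids[prov$seed_row], "_syn", seq_len(nrow(syn)))
      prov$raw <- I(asplit(attr(sm, "raw"), 1))
      provenance[[lev]] <- prov
    } else {
      Xb <- Xc; idb <- ids
    }
    rows_out <- rbind(rows_out, Xb)
    ids_out <- c(ids_out, idb)
    labs_out <- c(labs_out, rep(lev, nrow(Xb)))
  }
  storage.mode(rows_out) <- "integer"
  list(counts = count_table(rows_out, ids_out, counts$taxon_names),
       labels = label_vector(labs_out, ids_out, labels$level_order),
       provenance = provenance)
}
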