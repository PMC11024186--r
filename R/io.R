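#' Construct a subjects-by-taxa count table
#'
#' The central container of the package: an M x B matrix of non-negative
#' integer read counts with unique subject IDs on the rows and unique taxon
#' names on the columns. Subjects are always rows (the M x B convention used
#' throughout the methods).
#'
#' @param counts integer matrix (or coercible), subjects in rows.
#' @param subject_ids character vector of unique row identifiers.
#' @param taxon_names character vector of unique column identifiers.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, subject_ids = rownames(counts),
                        taxon_names = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(taxon_names)) taxon_names <- paste0("taxon", seq_len(ncol(counts)))
  subject_ids <- as.character(subject_ids)
  taxon_names <- as.character(taxon_names)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table must have at least one subject and one taxon")
  if (length(subject_ids) != nrow(counts) || length(taxon_names) != ncol(counts))
    stop("dimension names do not match the count matrix")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject IDs: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_names))
    stop("duplicate taxon names: ",
         paste(unique(taxon_names[duplicated(taxon_names)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "invalid count at subject '%s', taxon '%s': must be a non-negative integer",
      subject_ids[bad[1, 1]], taxon_names[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(subject_ids, taxon_names)
  structure(list(counts = counts, subject_ids = subject_ids,
                 taxon_names = taxon_names),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d subjects x %d taxa, %d reads total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Construct a health-status label vector paired with a count table
#'
#' Labels are categorical health-status levels, one per subject, in the same
#' subject order as the paired count table. Self-reported labels of this kind
#' are fuzzy: noisy but informative ground truth.
#'
#' @param labels character/factor vector of health-status values.
#' @param subject_ids subject identifiers, same order as `labels`.
#' @param level_order ordered vector of the distinct levels; defaults to
#'   first-appearance order.
#' @return an object of class `label_vector`.
#' @export
label_vector <- function(labels, subject_ids, level_order = NULL) {
  labels <- as.character(labels)
  subject_ids <- as.character(subject_ids)
  stopifnot(length(labels) == length(subject_ids))
  if (is.null(level_order)) level_order <- unique(labels)
  level_order <- as.character(level_order)
  if (!all(labels %in% level_order))
    stop("labels outside level_order: ",
         paste(setdiff(labels, level_order), collapse = ", "))
  if (length(level_order) < 2L)
    stop("need at least two health-status levels")
  structure(list(subject_ids = subject_ids, labels = labels,
                 level_order = level_order),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  tb <- table(factor(x$labels, levels = x$level_order))
  cat("label_vector:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a subjects-by-taxa count table from TSV/CSV
#'
#' Expects a header row of taxon names and a first column of subject IDs.
#' The delimiter is sniffed from the first line (tab beats comma) unless
#' given. Files exported with taxa in rows can be read with
#' `transpose = TRUE`.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to sniff.
#' @param transpose set `TRUE` for taxa-in-rows files.
#' @return a [count_table()].
#' @export
read_counts <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("count file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 rownames(df)[bad[1, 1]], colnames(df)[bad[1, 2]], path))
  }
  if (transpose) m <- t(m)
  count_table(m)
}

#' Write a count table to TSV/CSV
#'
#' @param x a [count_table()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(subject_id = x$subject_ids, x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read subject health-status labels and align them to a count table
#'
#' Two-column file (subject_id, label). Rows may come in any order; the
#' result is re-ordered to match `counts$subject_ids`.
#'
#' @param path file path.
#' @param counts the paired [count_table()].
#' @param sep delimiter; `NULL` to sniff.
#' @param level_order optional explicit level order.
#' @return a [label_vector()].
#' @export
read_labels <- function(path, counts, sep = NULL, level_order = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  stopifnot(inherits(counts, "count_table"))
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns: subject_id, label")
  ids <- as.character(df[[1]]); labs <- as.character(df[[2]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    conf <- vapply(unique(dup), function(d)
      length(unique(labs[ids == d])) > 1L, logical(1))
    if (any(conf))
      stop("conflicting duplicate labels for subject(s): ",
           paste(unique(dup)[conf], collapse = ", "))
    keep <- !duplicated(ids); ids <- ids[keep]; labs <- labs[keep]
  }
  unknown <- setdiff(ids, counts$subject_ids)
  if (length(unknown) > 0L)
    stop("labels for unknown subject(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(counts$subject_ids, ids)
  if (length(missing) > 0L)
    stop("subject(s) missing a label: ", paste(missing, collapse = ", "))
  ord <- match(counts$subject_ids, ids)
  if (is.null(level_order)) level_order <- unique(labs[ord])
  label_vector(labs[ord], counts$subject_ids, level_order)
}

#' Write a label vector to TSV
#' @param x a [label_vector()].
#' @param path output path.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "label_vector"))
  write.table(data.frame(subject_id = x$subject_ids, label = x$labels),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
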