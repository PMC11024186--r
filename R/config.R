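#' Build a pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated list. Defaults
#' follow the study conventions: T = 3 topics matched to C = 3 health-status
#' levels, K = 50 taxa kept before aggregating the remainder into "Others",
#' class weights w = (0.6, 0.15, 0.25) in level order, similarity threshold
#' lambda = 0.7, and the randomized feature-search settings c = 1,
#' p = ceiling(n/2), t0 = 1e-4, R = 50 restarts.
#'
#' @param T number of latent topics.
#' @param K number of taxa kept by the concordance filter.
#' @param omega detection threshold for prevalence, a relative abundance
#'   in `[0, 1)`; default 0.001 (0.1%).
#' @param w class weights summing to 1, in label level order.
#' @param lambda within-group similarity threshold in `(0, 1]`.
#' @param alpha symmetric Dirichlet concentration for topic proportions;
#'   default `50 / T`.
#' @param rfs list of feature-search settings: `enabled`, `c`, `p` (NULL for
#'   ceiling(n/2)), `t0`, `u`, `R`, `patience`, `max_moves`.
#' @param lda list of sampler settings: `iter`, `burnin`.
#' @param balance list: `enabled`, `target` (NULL for round(M/C)), `k`
#'   SMOTE neighbours, `on` = "counts" or "proportions".
#' @param per_class_filter apply the concordance filter within each class and
#'   union the results instead of globally.
#' @param train_fraction train share for a stratified split.
#' @param folds number of cross-validation folds.
#' @param seed master seed; all stages derive child seeds from it.
#' @return an object of class `rfslda_config`.
#' @export
rfslda_config <- function(T = 3L, K = 50L, omega = 0.001,
                          w = c(0.6, 0.15, 0.25), lambda = 0.7,
                          alpha = NULL,
                          rfs = list(), lda = list(), balance = list(),
                          per_class_filter = FALSE,
                          train_fraction = 0.8, folds = 5L, seed = 1L) {
  rfs <- modifyList(list(enabled = FALSE, c = 1L, p = NULL, t0 = 1e-4,
                         u = 0.5, R = 50L, patience = 100L,
                         max_moves = 2000L), rfs)
  lda <- modifyList(list(iter = 300L, burnin = 150L), lda)
  balance <- modifyList(list(enabled = FALSE, target = NULL, k = 5L,
                             on = "counts"), balance)
  cfg <- list(T = as.integer(T), K = as.integer(K), omega = omega, w = w,
              lambda = lambda, alpha = alpha, rfs = rfs, lda = lda,
              balance = balance, per_class_filter = isTRUE(per_class_filter),
              train_fraction = train_fraction, folds = as.integer(folds),
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "rfslda_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$T >= 1L, cfg$K >= 1L)
  if (cfg$omega < 0 || cfg$omega >= 1) stop("omega must lie in [0, 1)")
  if (abs(sum(cfg$w) - 1) > 1e-9) stop("class weights w must sum to 1")
  if (any(cfg$w < 0)) stop("class weights must be non-negative")
  if (cfg$lambda <= 0 || cfg$lambda > 1) stop("lambda must lie in (0, 1]")
  if (!is.null(cfg$alpha) && cfg$alpha <= 0) stop("alpha must be positive")
  with(cfg$rfs, {
    if (c < 1L) stop("rfs$c must be >= 1")
    if (t0 < 0) stop("rfs$t0 must be >= 0")
    if (u < 0 || u > 1) stop("rfs$u must lie in [0, 1]")
    if (R < 1L) stop("rfs$R must be >= 1")
  })
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' A flat key/value document mirroring the [rfslda_config()] fields; nested
#' keys for `rfs`, `lda` and `balance` are accepted. Unknown keys are errors
#' so that typos never silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return an `rfslda_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(rfslda_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in c("rfs", "lda", "balance")) {
    if (!is.null(raw[[nm]])) {
      ok <- switch(nm,
        rfs = c("enabled", "c", "p", "t0", "u", "R", "patience", "max_moves"),
        lda = c("iter", "burnin"),
        balance = c("enabled", "target", "k", "on"))
      bad <- setdiff(names(raw[[nm]]), ok)
      if (length(bad) > 0L)
        stop(sprintf("unknown config key(s) under %s: %s", nm,
                     paste(bad, collapse = ", ")))
    }
  }
  do.call(rfslda_config, raw)
}
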