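#' Derive a reproducible child seed from a master seed and a stage name
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' master seed so that stages can be re-run in isolation and the pipeline is
#' bitwise reproducible end to end. The derivation is a small multiplicative
#' hash kept strictly below 2^31 so the result is always a valid R integer.
#'
#' @param seed master seed (single integer).
#' @param stage character tag naming the stage (e.g. `"fit"`, `"restart3"`).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  s <- ((abs(seed) %% m) * 48271 + h) %% m
  as.integer(s %% (m - 1L) + 1)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One structured log line per pipeline stage.
stage_log <- function(stage, shape = NULL, seed = NULL, t0 = NULL) {
  parts <- c(
    sprintf("stage=%s", stage),
    if (!is.null(shape)) sprintf("shape=%s", paste(shape, collapse = "x")),
    if (!is.null(seed)) sprintf("seed=%d", seed),
    if (!is.null(t0)) sprintf("elapsed=%.2fs", as.numeric(Sys.time()) - t0)
  )
  message(paste(parts, collapse = " "))
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}

# Dirichlet sampler via normalised gammas; rows of the result are draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# total-variation distance between two probability vectors
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
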