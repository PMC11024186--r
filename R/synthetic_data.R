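#' Configure a synthetic Dirichlet-multinomial corpus
#'
#' Parameterises the generative process the topic model assumes: per subject,
#' a total read count `N ~ Poisson(lambda)` (resampled if 0), topic
#' proportions `theta ~ Dirichlet(alpha)` (symmetric), and for each read a
#' topic from `Multinomial(theta)` then a taxon from the topic's
#' distribution. Optional extras emulate real stool-profile features: class
#' imbalance (subjects are rejection-sampled until their dominant topic
#' matches a prescribed class layout), label noise, zero-inflation (random
#' zeroing of count cells after generation), and planted
#' informative/noise taxa for feature-selection benchmarks.
#'
#' @param M subjects.
#' @param B taxa.
#' @param T topics.
#' @param lambda Poisson mean of per-subject totals.
#' @param alpha symmetric Dirichlet concentration of theta.
#' @param beta explicit T x B row-stochastic matrix, or NULL to generate a
#'   block-structured one with `block_share` of each topic's mass on its own
#'   taxon block.
#' @param block_share own-block mass for generated beta (controls topic
#'   separation; pairwise total variation >= block_share).
#' @param n_informative,n_noise planted-feature benchmark sizes; when
#'   `n_informative > 0`, beta is built by [plant_informative_features()].
#' @param rho label-noise rate in `[0, 1]`.
#' @param pi0 zero-inflation probability in `[0, 1)`.
#' @param class_sizes optional integer vector (length T) of subjects whose
#'   dominant topic must be topic t; must sum to M.
#' @param levels level names used for labels; default `L1..LT`.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(M = 100L, B = 20L, T = 3L, lambda = 500,
                       alpha = 0.1, beta = NULL, block_share = 0.7,
                       n_informative = 0L, n_noise = 0L,
                       rho = 0, pi0 = 0, class_sizes = NULL,
                       levels = NULL, seed = 1L) {
  M <- as.integer(M); B <- as.integer(B); T <- as.integer(T)
  stopifnot(M >= 1L, B >= 2L, T >= 1L, lambda > 0, alpha > 0,
            rho >= 0, rho <= 1, pi0 >= 0, pi0 < 1,
            n_informative + n_noise <= B)
  if (n_informative > 0L && n_informative < T)
    stop("n_informative must be >= T")
  if (!is.null(class_sizes)) {
    class_sizes <- as.integer(class_sizes)
    stopifnot(length(class_sizes) == T, sum(class_sizes) == M,
              all(class_sizes >= 1L))
  }
  if (is.null(levels)) levels <- paste0("L", seq_len(T))
  stopifnot(length(levels) == T)
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    stopifnot(nrow(beta) == T, ncol(beta) == B, all(beta >= 0),
              all(abs(rowSums(beta) - 1) < 1e-8))
  }
  structure(list(M = M, B = B, T = T, lambda = lambda, alpha = alpha,
                 beta = beta, block_share = block_share,
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise), rho = rho, pi0 = pi0,
                 class_sizes = class_sizes, levels = as.character(levels),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Study-shaped simulation preset
#'
#' The default conditions every end-to-end test runs under: M = 89 subjects,
#' B = 109 taxa, T = 3 topics matched to 3 levels with unbalanced sizes
#' (66, 6, 17), sequencing depth lambda = 5000 reads, and 30% zero-inflation
#' of count cells -- the shape of a zero-inflated 16S stool profile with a
#' rare but important infection class.
#'
#' @param seed master seed.
#' @param ... overrides forwarded to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset_study <- function(seed = 1L, ...) {
  args <- modifyList(
    list(M = 89L, B = 109L, T = 3L, lambda = 5000, alpha = 0.1,
         block_share = 0.7, pi0 = 0.3, class_sizes = c(66L, 6L, 17L),
         levels = c("Healthy", "Infection", "Stress"), seed = seed),
    list(...))
  do.call(sim_config, args)
}

# block-structured topic-taxon distributions: topic t spreads `share` of its
# mass (Dirichlet-perturbed) over its own block of taxa and the rest evenly.
make_block_beta <- function(T, B, share) {
  blocks <- split(seq_len(B), rep_len(seq_len(T), B))
  beta <- matrix((1 - share) / B, T, B)
  for (t in seq_len(T)) {
    bl <- blocks[[t]]
    beta[t, bl] <- beta[t, bl] + share * as.numeric(rdirichlet(1, rep(5, length(bl))))
  }
  beta / rowSums(beta)
}

#' Build a planted-feature topic-taxon matrix
#'
#' For feature-selection benchmarks: the first `n_informative` taxa carry all
#' the topic signal (each topic owns a share of them, round-robin, and puts
#' `block_share` of its mass there), while the `n_noise` taxa that follow get
#' identical mass under every topic, so they are pure distractors. Pairwise
#' row total variation is at least `block_share`.
#'
#' @param cfg a [sim_config()] with `n_informative >= T`.
#' @return T x B row-stochastic matrix with attributes `informative` and
#'   `noise` (taxon index vectors).
#' @export
plant_informative_features <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ni <- cfg$n_informative; nn <- cfg$n_noise
  if (ni < cfg$T) stop("n_informative must be >= T")
  B <- cfg$B; T <- cfg$T
  share <- cfg$block_share
  inf_idx <- seq_len(ni)
  noise_idx <- ni + seq_len(nn)
  rest <- setdiff(seq_len(B), c(inf_idx, noise_idx))
  owner <- rep_len(seq_len(T), ni) # round-robin topic ownership
  beta <- matrix(0, T, B)
  flat <- c(noise_idx, rest)
  for (t in seq_len(T)) {
    own <- inf_idx[owner == t]
    beta[t, own] <- share / length(own)
    if (length(flat) > 0L) beta[t, flat] <- (1 - share) / length(flat)
    else beta[t, own] <- beta[t, own] + (1 - share) / length(own)
  }
  structure(beta / rowSums(beta), informative = inf_idx, noise = noise_idx,
            owner = owner)
}

#' Generate a synthetic corpus from the LDA generative process
#'
#' Draws every subject's topic proportions, total read count and taxon counts
#' under the configured model, then applies zero-inflation if requested
#' (independent Bernoulli zeroing of cells; a row losing all its reads keeps
#' its largest cell so downstream proportions stay defined). Labels are the
#' level of each subject's dominant true topic, flipped to a uniformly random
#' other level with probability `rho`.
#'
#' @param cfg a [sim_config()].
#' @return list of class `synthetic_corpus`: `counts` ([count_table()]),
#'   `labels` ([label_vector()]), `theta` (true M x T), `beta` (true T x B),
#'   `dominant` (true dominant topic per subject), `config`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    T <- cfg$T; B <- cfg$B; M <- cfg$M
    beta <- cfg$beta
    if (is.null(beta)) {
      beta <- if (cfg$n_informative > 0L) plant_informative_features(cfg)
              else make_block_beta(T, B, cfg$block_share)
    }
    # topic layout per subject (imbalanced classes via rejection on argmax)
    want <- if (is.null(cfg$class_sizes)) NULL
            else rep(seq_len(T), cfg$class_sizes)
    theta <- matrix(0, M, T)
    for (i in seq_len(M)) {
      repeat {
        th <- as.numeric(rdirichlet(1, rep(cfg$alpha, T)))
        if (is.null(want) || which.max(th) == want[i]) break
      }
      theta[i, ] <- th
    }
    counts <- matrix(0L, M, B)
    for (i in seq_len(M)) {
      N <- 0L
      while (N == 0L) N <- rpois(1, cfg$lambda)
      nz <- as.integer(rmultinom(1, N, theta[i, ]))
      row <- integer(B)
      for (t in seq_len(T)) if (nz[t] > 0L)
        row <- row + as.integer(rmultinom(1, nz[t], beta[t, ]))
      counts[i, ] <- row
    }
    if (cfg$pi0 > 0) {
      zero <- matrix(runif(M * B) < cfg$pi0, M, B)
      for (i in seq_len(M)) { # never zero a whole subject out
        if (all(zero[i, ] | counts[i, ] == 0L))
          zero[i, which.max(counts[i, ])] <- FALSE
      }
      counts[zero] <- 0L
    }
    subject_ids <- sprintf("S%03d", seq_len(M))
    taxon_names <- sprintf("taxon%03d", seq_len(B))
    ct <- count_table(counts, subject_ids, taxon_names)
    dominant <- max.col(theta, ties.method = "first")
    labs <- cfg$levels[dominant]
    if (cfg$rho > 0) {
      flip <- runif(M) < cfg$rho
      for (i in which(flip)) {
        others <- setdiff(cfg$levels, labs[i])
        labs[i] <- others[sample.int(length(others), 1L)]
      }
    }
    lv <- if (length(cfg$levels) >= 2L)
      label_vector(labs, subject_ids, cfg$levels) else NULL
    structure(list(counts = ct, labels = lv, theta = theta, beta = beta,
                   dominant = dominant, config = cfg),
              class = "synthetic_corpus")
  })
}

#' Relabel a corpus with fresh noise
#'
#' Regenerates the label vector of an existing corpus under a given
#' topic-to-level matching and noise rate, without touching the counts.
#'
#' @param corpus a [generate_corpus()] result.
#' @param matching character vector, level of each topic; default the
#'   corpus's own level layout.
#' @param rho label-noise rate.
#' @param seed RNG seed.
#' @return a [label_vector()].
#' @export
generate_labels <- function(corpus, matching = NULL, rho = 0, seed = 1L) {
  stopifnot(inherits(corpus, "synthetic_corpus"), rho >= 0, rho <= 1)
  if (is.null(matching)) matching <- corpus$config$levels
  stopifnot(length(matching) == corpus$config$T)
  with_seed(seed, {
    labs <- matching[corpus$dominant]
    if (rho > 0) {
      flip <- runif(length(labs)) < rho
      for (i in which(flip)) {
        others <- setdiff(unique(matching), labs[i])
        labs[i] <- others[sample.int(length(others), 1L)]
      }
    }
    label_vector(labs, corpus$counts$subject_ids, unique(matching))
  })
}
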