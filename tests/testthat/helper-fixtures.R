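# Shared fixtures, all generated in code at test time.

# tiny deterministic count table
tiny_counts <- function() {
  m <- matrix(c(2L, 3L, 5L, 0L,
                1L, 0L, 4L, 5L,
                7L, 1L, 1L, 1L), nrow = 3, byrow = TRUE)
  count_table(m, c("s1", "s2", "s3"), c("taxA", "taxB", "taxC", "taxD"))
}

tiny_labels <- function(counts = tiny_counts()) {
  label_vector(c("Healthy", "Infection", "Healthy"), counts$subject_ids,
               c("Healthy", "Infection"))
}

# labelled corpus with well-separated topics, for matching/eval tests
small_corpus <- function(seed = 42L, M = 60L, lambda = 300) {
  generate_corpus(sim_config(
    M = M, B = 15L, T = 3L, lambda = lambda, alpha = 0.1, block_share = 0.7,
    class_sizes = round(M * c(0.6, 0.15, 0.25)),
    levels = c("Healthy", "Infection", "Stress"), seed = seed))
}

# planted-feature benchmark corpus for the feature search
planted_corpus <- function(seed = 11L, M = 60L, lambda = 200) {
  generate_corpus(sim_config(
    M = M, B = 15L, T = 5L, lambda = lambda, alpha = 0.1,
    n_informative = 5L, n_noise = 10L, block_share = 0.6,
    levels = paste0("L", 1:5), seed = seed))
}

# all permutations of 1..n, recursively (independent of the package)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- as.integer(append(p, n, after = pos - 1))
  }
  out
}

# one random probability vector (uniform on the simplex)
rdirichlet_test <- function(k) { x <- rgamma(k, 1); x / sum(x) }

# random label vector over given levels
random_labels <- function(n, levels, seed = 1L) {
  set.seed(seed)
  label_vector(sample(levels, n, replace = TRUE), paste0("s", seq_len(n)),
               levels)
}
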