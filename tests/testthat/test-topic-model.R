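test_that("single-topic fit collapses to pooled taxon proportions", {
  co <- generate_corpus(sim_config(M = 20L, B = 10L, T = 2L, lambda = 200,
                                   seed = 2L))
  fit <- fit_lda(co$counts, T = 1L, iter = 60L, burnin = 30L, seed = 1L)
  expect_equal(unname(fit$theta[, 1]), rep(1, 20))
  pooled <- colSums(co$counts$counts) / sum(co$counts$counts)
  expect_lt(0.5 * sum(abs(fit$beta[1, ] - pooled)), 0.01)
})

test_that("fits are deterministic given the seed and row-stochastic", {
  co <- small_corpus(seed = 4L, M = 30L, lambda = 150)
  f1 <- fit_lda(co$counts, T = 3L, iter = 80L, burnin = 40L, seed = 99L)
  f2 <- fit_lda(co$counts, T = 3L, iter = 80L, burnin = 40L, seed = 99L)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$beta, f2$beta)
  expect_true(all(abs(rowSums(f1$theta) - 1) < 1e-8))
  expect_true(all(abs(rowSums(f1$beta) - 1) < 1e-8))
  expect_true(all(f1$theta >= 0) && all(f1$beta >= 0))
  f3 <- fit_lda(co$counts, T = 3L, iter = 80L, burnin = 40L, seed = 100L)
  expect_false(identical(f1$theta, f3$theta))
})

test_that("the sampler improves the joint likelihood from its random start", {
  co <- small_corpus(seed = 6L, M = 40L, lambda = 200)
  fit <- fit_lda(co$counts, T = 3L, iter = 100L, burnin = 50L, seed = 5L)
  ll <- fit$loglik
  expect_gt(mean(tail(ll, 25)), ll[1])
  # post-burn-in stationarity: last two quarters on the same level
  q3 <- mean(ll[51:75]); q4 <- mean(ll[76:100])
  expect_lt(abs(q4 - q3) / abs(q3), 0.02)
})

test_that("two disjoint-support topics are recovered to within 0.05 TV", {
  B <- 20L
  beta <- rbind(c(rep(0.1, 10), rep(0, 10)),
                c(rep(0, 10), rep(0.1, 10)))
  co <- generate_corpus(sim_config(M = 100L, B = B, T = 2L, lambda = 400,
                                   alpha = 0.1, beta = beta, seed = 17L,
                                   levels = c("A", "B")))
  fit <- fit_lda(co$counts, T = 2L, alpha = 0.1, iter = 150L, burnin = 75L,
                 seed = 3L)
  # best permutation alignment
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  d_id <- mean(c(tv(fit$beta[1, ], beta[1, ]), tv(fit$beta[2, ], beta[2, ])))
  d_sw <- mean(c(tv(fit$beta[1, ], beta[2, ]), tv(fit$beta[2, ], beta[1, ])))
  expect_lt(min(d_id, d_sw), 0.05)
})

test_that("three planted topics are recovered across seeds (mean TV <= 0.1)", {
  # well-separated design: pairwise beta TV >= 0.5, moderate corpus
  ok <- 0L
  for (s in 1:5) {
    co <- generate_corpus(sim_config(M = 200L, B = 30L, T = 3L, lambda = 500,
                                     alpha = 0.1, block_share = 0.7,
                                     seed = 100L + s))
    fit <- fit_lda(co$counts, T = 3L, alpha = 0.1, iter = 150L, burnin = 75L,
                   seed = s)
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    tvs <- sapply(perms, function(p)
      mean(sapply(1:3, function(t) 0.5 * sum(abs(fit$beta[p[t], ] - co$beta[t, ])))))
    if (min(tvs) <= 0.1) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("fold-in inference is consistent and concentrates when forced", {
  co <- small_corpus(seed = 7L, M = 40L, lambda = 300)
  fit <- fit_lda(co$counts, T = 3L, alpha = 0.1, iter = 150L, burnin = 75L,
                 seed = 2L)
  th <- infer_theta(fit, co$counts)
  expect_true(all(abs(rowSums(th) - 1) < 1e-8))
  tv <- 0.5 * rowSums(abs(th - fit$theta))
  expect_lt(max(tv), 0.05)
  # a subject carried entirely by one topic's dominant taxa
  top_taxa <- order(fit$beta[1, ] - pmax(fit$beta[2, ], fit$beta[3, ]),
                    decreasing = TRUE)[1:3]
  row <- integer(ncol(co$counts$counts)); row[top_taxa] <- c(200L, 150L, 150L)
  forced <- count_table(matrix(row, 1), "x", co$counts$taxon_names)
  thf <- infer_theta(fit, forced)
  expect_gte(thf[1, 1], 0.9)
  # zero-count subject is an error
  zero <- count_table(matrix(0L, 1, ncol(co$counts$counts)), "z",
                      co$counts$taxon_names)
  expect_error(infer_theta(fit, zero), "zero total")
  # mismatched taxa are an error
  bad <- count_table(matrix(1L, 1, 3), "y", c("u", "v", "w"))
  expect_error(infer_theta(fit, bad), "taxon")
})

test_that("perplexity equals the token-by-token oracle and is 1 for a
           single-taxon vocabulary", {
  co <- small_corpus(seed = 12L, M = 20L, lambda = 100)
  fit <- fit_lda(co$counts, T = 3L, iter = 80L, burnin = 40L, seed = 4L)
  px <- perplexity(fit, co$counts)
  # independent oracle: explicit sum over every read
  mix <- fit$theta %*% fit$beta
  ll <- 0
  for (i in seq_len(nrow(co$counts$counts)))
    for (l in seq_len(ncol(co$counts$counts)))
      if (co$counts$counts[i, l] > 0)
        ll <- ll + co$counts$counts[i, l] * log(mix[i, l])
  expect_equal(px, exp(-ll / sum(co$counts$counts)), tolerance = 1e-6)
  expect_gt(px, 1)

  one <- count_table(matrix(c(5L, 7L), 2, 1), c("s1", "s2"), "only")
  fit1 <- fit_lda(one, T = 1L, iter = 20L, burnin = 10L, seed = 1L)
  expect_equal(perplexity(fit1, one), 1, tolerance = 1e-6)
})

test_that("the true topic count wins the perplexity comparison on average", {
  px1 <- px3 <- numeric(5)
  for (s in 1:5) {
    co <- generate_corpus(sim_config(M = 60L, B = 20L, T = 3L, lambda = 300,
                                     alpha = 0.1, block_share = 0.7,
                                     seed = 200L + s))
    f1 <- fit_lda(co$counts, T = 1L, iter = 60L, burnin = 30L, seed = s)
    f3 <- fit_lda(co$counts, T = 3L, alpha = 0.5, iter = 100L, burnin = 50L,
                  seed = s)
    px1[s] <- perplexity(f1, co$counts)
    px3[s] <- perplexity(f3, co$counts)
  }
  expect_lt(mean(px3), mean(px1))
})

test_that("select_T scans a topic grid and flags the perplexity minimiser", {
  co <- generate_corpus(sim_config(M = 40L, B = 15L, T = 3L, lambda = 200,
                                   alpha = 0.1, block_share = 0.7, seed = 3L))
  tab <- select_T(co$counts, T_grid = c(1L, 3L), seed = 2L,
                  iter = 60L, burnin = 30L)
  expect_identical(nrow(tab), 2L)
  expect_identical(sum(tab$best), 1L)
  expect_identical(tab$T[tab$best], 3L)
})

test_that("hard topic assignment is argmax with lowest-index tie-break", {
  expect_identical(assign_topics(matrix(c(1, 0, 0), 1))$topic, 1L)
  expect_identical(assign_topics(matrix(c(0.2, 0.4, 0.4), 1))$topic, 2L)
  set.seed(44)
  th <- rdirichlet <- matrix(rgamma(300, 1), 100, 3)
  th <- th / rowSums(th)
  a <- assign_topics(th)
  oracle <- apply(th, 1, function(r) which(r == max(r))[1])
  expect_identical(a$topic, as.integer(oracle))
  expect_error(assign_topics(matrix(c(0.5, 0.4), 1)), "sum to 1")
  expect_error(assign_topics(matrix(numeric(0), 0, 3)), "empty")
})

test_that("the fit never reads labels (unsupervised contract)", {
  expect_false("labels" %in% names(formals(fit_lda)))
  expect_false(any(grepl("label", names(formals(fit_lda)))))
})
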