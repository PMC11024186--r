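full10 <- paste0("f", 1:10)

test_that("swap moves preserve size; remove/add change it by c", {
  set.seed(1)
  cur <- full10[1:5]
  for (i in 1:50) {
    p1 <- propose_move(cur, full10, coin = 1L)
    expect_length(p1, 5)
    expect_false(setequal(p1, cur))
    p2 <- propose_move(cur, full10, coin = 2L)
    expect_length(p2, 4)
    expect_true(all(p2 %in% cur))
    p3 <- propose_move(cur, full10, coin = 3L)
    expect_length(p3, 6)
    expect_true(all(cur %in% p3))
    for (p in list(p1, p2, p3)) {
      expect_identical(anyDuplicated(p), 0L)
      expect_true(all(p %in% full10))
    }
  }
})

test_that("infeasible coin sides are redrawn among the feasible ones", {
  set.seed(2)
  # removing from a singleton is infeasible: coin 2 must become 1 or 3
  for (i in 1:50) {
    p <- propose_move("f1", full10, coin = 2L)
    expect_true(attr(p, "coin") %in% c(1L, 3L))
    expect_gte(length(p), 1)
  }
  # adding to the full set is infeasible; so is swapping (no outside feature)
  for (i in 1:20) {
    p <- propose_move(full10, full10, coin = 3L)
    expect_identical(attr(p, "coin"), 2L)
    expect_length(p, 9)
  }
  # feature space of size 1: no feasible move at all
  p <- propose_move("f1", "f1", coin = 1L)
  expect_identical(as.character(p), "f1")
  expect_true(is.na(attr(p, "coin")))
})

test_that("swap proposals are uniform over (removed, added) pairs", {
  set.seed(13)
  cur <- full10[1:5]
  n_draw <- 10000
  pairs <- character(n_draw)
  for (i in seq_len(n_draw)) {
    p <- propose_move(cur, full10, coin = 1L)
    pairs[i] <- paste(setdiff(cur, p), setdiff(p, cur))
  }
  tab <- table(pairs)
  expect_identical(length(tab), 25L) # 5 removable x 5 addable
  # every cell near uniform and a global chi-square sanity check
  expected <- n_draw / 25
  se <- sqrt(n_draw * (1 / 25) * (1 - 1 / 25))
  expect_true(all(abs(tab - expected) < 4 * se))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("acceptance: strict improvement always moves; ties stay w.p. u", {
  set.seed(4)
  for (i in 1:20) expect_identical(accept_move(0.8, 0.5, u = runif(1)), "move")
  expect_identical(accept_move(0.5, 0.5, u = 1), "stay")
  expect_identical(accept_move(0.4, 0.5, u = 1), "stay")
  expect_identical(accept_move(0.4, 0.5, u = 0), "move")
  stays <- replicate(10000, accept_move(0.3, 0.5, u = 0.5) == "stay")
  expect_gte(mean(stays), 0.48); expect_lte(mean(stays), 0.52)
})

test_that("single runs have monotone best traces and respect size bounds", {
  # deterministic toy scorer: fraction of odd-indexed features present
  target <- paste0("f", c(1, 3, 5, 7, 9))
  scorer <- function(s) length(intersect(s, target)) / 5 -
    0.01 * length(setdiff(s, target))
  # u = 1: pure hill-climbing, which must find the toy optimum (every
  # non-optimal state has a strictly improving single move)
  cfg <- rfs_config(n = 10, p = 5, t0 = 1e-4, u = 1, R = 1,
                    patience = 100, max_moves = 600, seed = 1)
  run <- rfs_single_run(full10, cfg, scorer, seed = 7)
  expect_true(all(diff(run$trace$best) >= 0))
  expect_equal(run$best_score, max(run$trace$score))
  expect_setequal(run$best_subset, target) # toy optimum is reachable
  expect_true(all(run$trace$move == seq_len(nrow(run$trace)) - 1))
})

test_that("a size-1 feature space returns the singleton with no moves", {
  cfg <- rfs_config(n = 1, p = 1, R = 1, seed = 3)
  run <- rfs_single_run("only", cfg, function(s) 0.5, seed = 1)
  expect_identical(run$best_subset, "only")
  expect_identical(nrow(run$trace), 1L)
})

test_that("with t0 = Inf the run stops after exactly `patience` moves", {
  cfg <- rfs_config(n = 10, p = 5, t0 = Inf, patience = 12, max_moves = 1000,
                    R = 1, seed = 2)
  run <- rfs_single_run(full10, cfg, function(s) runif(1), seed = 5)
  expect_identical(nrow(run$trace), 13L) # init row + patience moves
})

test_that("multi-restart returns the max over restarts (ties: lowest index)", {
  scorer <- function(s) length(s) / 10 # favours the full set
  cfg <- rfs_config(n = 10, p = 5, t0 = 1e-4, u = 0.5, R = 5,
                    patience = 25, max_moves = 200, seed = 11)
  res <- rfs_multi_restart(full10, cfg, scorer)
  expect_equal(res$best_score, max(res$restart_scores))
  expect_identical(res$winner,
                   which(res$restart_scores == res$best_score)[1])
  for (r in res$restarts) expect_true(all(diff(r$trace$best) >= 0))
  # R = 1 is identical to a single run with the same child seed
  cfg1 <- rfs_config(n = 10, p = 5, t0 = 1e-4, u = 0.5, R = 1,
                     patience = 25, max_moves = 200, seed = 11)
  res1 <- rfs_multi_restart(full10, cfg1, scorer)
  run1 <- rfs_single_run(full10, cfg1, scorer,
                         seed = child_seed(11, "restart1"))
  expect_identical(res1$best_subset, run1$best_subset)
  expect_identical(res1$best_score, run1$best_score)
})

test_that("paper-convention defaults: c=1, p=ceil(n/2), t0=1e-4, R=50", {
  cfg <- rfs_config(n = 51)
  expect_identical(cfg$c, 1L)
  expect_identical(cfg$p, 26L) # n/2 rounded up for odd n
  expect_equal(cfg$t0, 1e-4)
  expect_identical(cfg$R, 50L)
})

test_that("an unfittable subset scores -Inf instead of erroring", {
  m <- matrix(c(5L, 0L,
                3L, 2L,
                4L, 1L), 3, 2, byrow = TRUE)
  ct <- count_table(m, c("s1", "s2", "s3"), c("a", "b"))
  lv <- label_vector(c("H", "I", "H"), ct$subject_ids, c("H", "I"))
  sc <- make_lda_scorer(ct, lv, T = 2, lda_seed = 1, iter = 20, burnin = 10)
  # restricting to taxon "b" empties subject s1: unscorable, not fatal
  expect_identical(sc("b"), -Inf)
  expect_gt(sc(c("a", "b")), -Inf)
})

test_that("the search recovers planted informative taxa", {
  # 5 informative taxa (one per topic) + 10 distractors shared by all topics
  hits <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    co <- planted_corpus(seed = 500L + s, M = 50L, lambda = 150)
    informative <- co$counts$taxon_names[attr(co$beta, "informative")]
    sc <- make_lda_scorer(co$counts, co$labels, T = 5, lda_seed = 1L,
                          iter = 100, burnin = 50)
    cfg <- rfs_config(n = 15, p = 8, t0 = 1e-4, u = 0.5, R = 1,
                      patience = 25, max_moves = 120, seed = 900L + s)
    run <- rfs_single_run(co$counts$taxon_names, cfg, sc, seed = 900L + s)
    if (sum(run$best_subset %in% informative) >= 4L) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})
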