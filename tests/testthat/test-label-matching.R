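levels3 <- c("Healthy", "Infection", "Stress")

test_that("unconstrained enumeration yields T! bijections in lexicographic order", {
  for (T in 1:5) {
    ms <- enumerate_matchings(paste0("L", seq_len(T)))
    expect_length(ms, factorial(T))
    expect_identical(anyDuplicated(sapply(ms, paste, collapse = "|")), 0L)
  }
  ms3 <- enumerate_matchings(levels3)
  expect_length(ms3, 6)
  # lexicographic in level-index space: first matching is the identity
  expect_identical(ms3[[1]], levels3)
  expect_identical(ms3[[2]], c("Healthy", "Stress", "Infection"))
  expect_identical(ms3[[6]], c("Stress", "Infection", "Healthy"))
})

test_that("constraining topic 1 to infection/stress leaves 4 bijections", {
  ms <- enumerate_matchings(levels3,
                            constraints = list(c("Infection", "Stress")))
  expect_length(ms, 4)
  expect_true(all(sapply(ms, `[`, 1) %in% c("Infection", "Stress")))
  expect_error(enumerate_matchings(levels3,
                                   constraints = list("Nope")), "unknown")
  expect_error(enumerate_matchings(c("A", "B"),
                                   constraints = list("B", "B")),
               "no bijection")
})

test_that("confusion matrix orientation: columns are true classes", {
  cm <- confusion_matrix(c("H", "I"), c("I", "I"), level_order = c("H", "I"))
  expect_identical(unclass(cm)["I", "H"], 1L) # true H predicted I
  expect_identical(unclass(cm)["I", "I"], 1L)
  expect_identical(unclass(cm)["H", "H"], 0L)
  # perfect prediction: diagonal holds the class counts
  lv <- random_labels(50, levels3, seed = 2)
  cmp <- confusion_matrix(lv, lv$labels)
  expect_identical(unname(diag(unclass(cmp))),
                   unname(as.integer(table(factor(lv$labels, levels3)))))
  expect_identical(sum(cmp), 50L)
})

test_that("confusion matrix matches a counting oracle on random labels", {
  set.seed(77)
  tr <- sample(levels3, 200, replace = TRUE)
  pr <- sample(levels3, 200, replace = TRUE)
  cm <- unclass(confusion_matrix(tr, pr, level_order = levels3))
  for (r in levels3) for (c in levels3)
    expect_identical(cm[r, c], sum(pr == r & tr == c))
  expect_identical(unname(as.integer(colSums(cm))),
                   unname(as.integer(table(factor(tr, levels3)))))
  expect_error(confusion_matrix(tr, c(pr[-1], "Zombie"),
                                level_order = levels3), "Zombie")
})

test_that("weighted accuracy is the weighted mean of true positive rates", {
  w <- c(0.6, 0.15, 0.25)
  # cells transcribed from a published-style confusion table, columns = true:
  # H col (50, 8, 8), I col (1, 4, 1), S col (5, 3, 9)
  cm <- matrix(c(50L, 8L, 8L, 1L, 4L, 1L, 5L, 3L, 9L), 3,
               dimnames = list(levels3, levels3))
  # hand-summed oracle, computed before the implementation existed:
  oracle <- 0.6 * (50 / 66) + 0.15 * (4 / 6) + 0.25 * (9 / 17)
  expect_equal(weighted_accuracy(cm, w), oracle, tolerance = 1e-12)
  expect_equal(weighted_accuracy(cm, c(1, 0, 0)), 50 / 66, tolerance = 1e-12)
  # perfect predictions score 1 under any valid weights
  cmp <- diag(c(10L, 5L, 7L)); dimnames(cmp) <- list(levels3, levels3)
  expect_equal(weighted_accuracy(cmp, w), 1)
  expect_equal(weighted_accuracy(cmp, c(0.2, 0.5, 0.3)), 1)
})

test_that("weighted accuracy rejects bad weights and empty weighted classes", {
  cm <- matrix(c(3L, 0L, 0L, 0L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(weighted_accuracy(cm, c(0.5, 0.6)), "sum to 1")
  expect_error(weighted_accuracy(cm, c(0.5, 0.5)), "no subjects")
  expect_equal(weighted_accuracy(cm, c(1, 0)), 1) # zero-weight class skipped
})

test_that("weighted accuracy is invariant to joint permutation of classes", {
  set.seed(3)
  for (rep in 1:20) {
    cm <- matrix(rpois(9, 5) + 1L, 3, dimnames = list(levels3, levels3))
    w <- as.numeric(rdirichlet_test(3))
    p <- sample(3)
    cmp <- cm[p, p, drop = FALSE]
    expect_equal(weighted_accuracy(cm, w), weighted_accuracy(cmp, w[p]),
                 tolerance = 1e-12)
    a <- weighted_accuracy(cm, w)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("weighted precision uses row margins with 0/0 -> 0", {
  w <- c(0.6, 0.15, 0.25)
  # everything predicted as class 1
  cm <- matrix(0L, 3, 3, dimnames = list(levels3, levels3))
  cm[1, ] <- c(40L, 5L, 15L)
  m <- weighted_metrics(cm, w)
  expect_equal(unname(m["weighted_precision"]), 0.6 * (40 / 60))
  expect_equal(unname(m["weighted_recall"]), 0.6)
  expect_equal(unname(m["weighted_accuracy"]), 0.6)
  # random cm against a per-class oracle
  set.seed(10)
  cm2 <- matrix(rpois(9, 4) + 1L, 3, dimnames = list(levels3, levels3))
  m2 <- weighted_metrics(cm2, w)
  prec <- sum(w * diag(cm2) / rowSums(cm2))
  rec <- sum(w * diag(cm2) / colSums(cm2))
  expect_equal(unname(m2["weighted_precision"]), prec, tolerance = 1e-12)
  expect_equal(unname(m2["weighted_recall"]), rec, tolerance = 1e-12)
  # perfect prediction: all three are 1
  cmp <- diag(c(4L, 4L, 4L)); dimnames(cmp) <- list(levels3, levels3)
  expect_equal(unname(weighted_metrics(cmp, w)), c(1, 1, 1))
})

test_that("best_matching equals exhaustive brute force for T <= 4", {
  for (T in 2:4) {
    set.seed(300 + T)
    levs <- paste0("L", seq_len(T))
    n <- 80
    truth <- label_vector(sample(levs, n, replace = TRUE),
                          paste0("s", 1:n), levs)
    topics <- sample.int(T, n, replace = TRUE)
    w <- as.numeric(rdirichlet_test(T))
    bm <- best_matching(topics, truth, w)
    # independent exhaustive scorer over all bijections
    perms <- all_perms(T)
    scores <- sapply(perms, function(p) {
      pred <- levs[p][topics]
      cm <- table(factor(pred, levs), factor(truth$labels, levs))
      sum(w * diag(cm) / pmax(colSums(cm), 1))
    })
    expect_equal(bm$score, max(scores), tolerance = 1e-12)
    expect_gte(bm$score + 1e-12, max(bm$candidates$score))
  }
})

test_that("identity-perfect assignments win with score 1; constraints restrict
           the argmax to admissible candidates", {
  lv <- random_labels(30, levels3, seed = 5)
  topics <- match(lv$labels, levels3)
  bm <- best_matching(topics, lv, c(0.6, 0.15, 0.25))
  expect_identical(bm$matching, levels3)
  expect_equal(bm$score, 1)
  # force topic 1 away from Healthy: winner must respect the constraint
  bmc <- best_matching(topics, lv, c(0.6, 0.15, 0.25),
                       constraints = list(c("Infection", "Stress")))
  expect_true(bmc$matching[1] %in% c("Infection", "Stress"))
  expect_lte(bmc$score, bm$score)
  expect_identical(nrow(bmc$candidates), 4L)
})

test_that("weight grid search reports the best score per weight vector", {
  lv <- random_labels(40, levels3, seed = 6)
  topics <- sample.int(3, 40, replace = TRUE)
  grid <- rbind(c(0.6, 0.15, 0.25), c(1 / 3, 1 / 3, 1 / 3), c(0.2, 0.6, 0.2))
  gs <- weight_grid_search(topics, lv, grid)
  expect_identical(nrow(gs), 3L)
  for (i in 1:3)
    expect_equal(gs$score[i],
                 best_matching(topics, lv, grid[i, ])$score)
})
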