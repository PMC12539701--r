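test_that("confusion matrices count truth rows against prediction columns", {
  cm <- confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  expect_identical(unname(cm$counts), matrix(c(1L, 0L, 1L, 2L), 2))
  expect_equal(unname(rowSums(cm$counts)), c(2, 2))
  # perfect predictions give a diagonal matrix
  y <- sample(letters[1:4], 40, replace = TRUE)
  cmp <- confusion(y, y)
  expect_identical(sum(cmp$counts) - sum(diag(cmp$counts)), 0L)
  expect_error(confusion("a", "z", classes = c("a", "b")), "not in classes")
  expect_error(confusion(c("a", "b"), "a"), "equal length")
})

test_that("metric arithmetic reproduces the hand-computed toy matrix", {
  cm <- structure(list(
    counts = matrix(c(8L, 1L, 2L, 9L), 2,
                    dimnames = list(true = c("x", "y"),
                                    predicted = c("x", "y"))),
    classes = c("x", "y")), class = "confusion_matrix")
  mt <- metrics(cm)
  expect_equal(mt$accuracy, 0.85)
  expect_equal(mt$per_class$precision, c(8 / 9, 9 / 11), tolerance = 1e-12)
  expect_equal(mt$per_class$recall, c(0.8, 0.9), tolerance = 1e-12)
  f1x <- 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8)  # 0.84210...
  f1y <- 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9)  # 0.85714...
  expect_equal(mt$per_class$f1, c(f1x, f1y), tolerance = 1e-12)
  expect_equal(f1x, 0.8421, tolerance = 1e-4)
  expect_equal(f1y, 0.8571, tolerance = 1e-4)
  expect_equal(mt$balanced_accuracy, 0.85)
  expect_equal(mt$macro_f1, mean(c(f1x, f1y)))
  expect_gte(mt$macro_f1, min(mt$per_class$f1))
  expect_lte(mt$macro_f1, max(mt$per_class$f1))
})

test_that("perfect predictions yield all-one metrics for any labels", {
  set.seed(3)
  for (i in 1:5) {
    y <- sample(sprintf("p%d", 1:6), 60, replace = TRUE)
    mt <- metrics(confusion(y, y))
    expect_equal(mt$accuracy, 1)
    expect_equal(mt$balanced_accuracy, 1)
    expect_equal(mt$macro_f1, 1)
    expect_equal(mt$weighted_f1, 1)
  }
})

test_that("zero-division conventions are explicit", {
  # class never predicted: precision 0; class without truth: recall 0
  cm <- confusion(c("a", "a", "b"), c("b", "b", "b"), classes = c("a", "b", "c"))
  mt <- metrics(cm)
  pc <- mt$per_class
  expect_equal(pc$precision[pc$class == "a"], 0)
  expect_equal(pc$f1[pc$class == "a"], 0)
  expect_equal(pc$recall[pc$class == "c"], 0)
})

test_that("municipality rollup is a coarsening and never lowers accuracy", {
  mapping <- c(p1 = "M1", p2 = "M1", p3 = "M2", p4 = "M2")
  # within-municipality confusion: producer-level error, municipality correct
  mt <- municipality_rollup("p1", "p2", mapping)
  expect_equal(mt$accuracy, 1)
  # bijective mapping: rollup equals producer metrics
  bij <- c(p1 = "A", p2 = "B", p3 = "C")
  y <- sample(names(bij), 30, replace = TRUE)
  p <- sample(names(bij), 30, replace = TRUE)
  expect_equal(municipality_rollup(y, p, bij)$accuracy,
               metrics(confusion(y, p))$accuracy)
  # coarsening property on random vectors
  set.seed(13)
  for (i in 1:100) {
    y <- sample(names(mapping), 25, replace = TRUE)
    p <- sample(names(mapping), 25, replace = TRUE)
    expect_gte(municipality_rollup(y, p, mapping)$accuracy,
               metrics(confusion(y, p, names(mapping)))$accuracy)
  }
  expect_error(municipality_rollup("p9", "p1", mapping), "without municipality")
})

test_that("temporal tables report one row per visit with per-visit metrics", {
  y <- rep(c("a", "b"), 20)
  p <- y; p[c(1, 22)] <- c("b", "a")
  visits <- rep(1:4, each = 10)
  tt <- temporal_table(y, p, visits)
  expect_identical(tt$visit, 1:4)
  expect_identical(nrow(tt), 4L)
  # identical predictions and class mix across two visits: identical rows
  y2 <- rep(c("a", "b"), 10); p2 <- rep(c("a", "a"), 10)
  tt2 <- temporal_table(c(y2, y2), c(p2, p2), rep(1:2, each = 20))
  expect_equal(tt2[1, -1], tt2[2, -1], ignore_attr = TRUE)
  # pooling two visits leaves weighted F1 between the per-visit values
  set.seed(17)
  y3 <- sample(c("a", "b", "c"), 60, replace = TRUE)
  p3 <- sample(c("a", "b", "c"), 60, replace = TRUE)
  v3 <- rep(1:2, each = 30)
  tt3 <- temporal_table(y3, p3, v3)
  pooled <- metrics(confusion(y3, p3))$weighted_f1
  expect_gte(pooled, min(tt3$weighted_f1) - 1e-9)
  expect_lte(pooled, max(tt3$weighted_f1) + 1e-9)
})

test_that("test-retest reliability follows the correlation formula", {
  # identical rounds: r12 = 1
  y <- rep(c("a", "b", "c"), each = 8)
  set.seed(19)
  p <- y; p[sample(24, 6)] <- sample(c("a", "b", "c"), 6, replace = TRUE)
  rounds <- rep(c(1L, 2L), 12)
  p[rounds == 2L] <- p[rounds == 1L]  # mirror round 1 into round 2
  y[rounds == 2L] <- y[rounds == 1L]
  rel <- test_retest(y, p, rounds)
  expect_equal(rel$r12, 1.0, tolerance = 1e-12)
  expect_length(rel$f1_round1, 3L)

  # hand-computed opposite 3-vectors give r12 = -1 via the same formula:
  # construct predictions whose per-class F1 are affinely opposite is
  # intricate, so check the formula path directly on its inputs instead
  f1 <- c(0.2, 0.5, 0.8); f2 <- c(0.8, 0.5, 0.2)
  d1 <- f1 - mean(f1); d2 <- f2 - mean(f2)
  expect_equal(sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2)), -1.0)

  # affine transforms with positive slope preserve r12 = 1
  f2b <- 0.1 + 0.5 * f1
  d2b <- f2b - mean(f2b)
  expect_equal(sum(d1 * d2b) / sqrt(sum(d1^2) * sum(d2b^2)), 1.0)

  # preconditions
  expect_error(test_retest(rep(c("a", "b"), 4), rep("a", 8), rep(1:2, 4)),
               "3 producers")
  # constant per-producer F1 (all perfect) is an explicit error
  expect_error(test_retest(y, y, rounds), "constant")
  # producer missing from one round
  expect_error(
    test_retest(c("a", "a", "b", "b", "c", "c"),
                c("a", "a", "b", "b", "c", "c"),
                c(1L, 2L, 1L, 2L, 1L, 1L)),
    "round 2")
})
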