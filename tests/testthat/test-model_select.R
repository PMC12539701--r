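# well-separated 2-D Gaussian blobs for separability checks
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  list(x = x, y = rep(letters[seq_len(nrow(centers))], each = n_per))
}

test_that("spec construction validates family-specific ranges", {
  expect_error(classifier_spec("svm_poly", list(degree = 3, C = 1)), "4, 10")
  expect_error(classifier_spec("svm_poly", list(degree = 11, C = 1)), "4, 10")
  expect_error(classifier_spec("svm_poly", list(degree = 5, C = -1)), "C")
  expect_error(classifier_spec("random_forest", list(n_trees = 300)), "200")
  expect_silent(classifier_spec("mlp", list(hidden = 32L)))
})

test_that("the default grid covers the documented candidates", {
  grid <- default_grid()
  keys <- vapply(grid, spec_key, character(1))
  # reference configuration present exactly once
  winning <- spec_key(classifier_spec(
    "svm_poly", list(degree = 6, C = 0.91, coef0 = 1.3), "uv", 32L))
  expect_identical(sum(keys == winning), 1L)
  # all svm degrees within 4..10
  svm <- Filter(function(s) s$family == "svm_poly", grid)
  degs <- vapply(svm, function(s) s$params$degree, numeric(1))
  expect_true(all(degs >= 4 & degs <= 10))
  # size = (7 svm + 3 rf + 3 mlp) x 4 representations x 1 k
  expect_length(grid, (7 + 3 + 3) * 4)
  # restricted grids multiply out
  g2 <- default_grid(representations = "uv", ks = c(16L, 32L),
                     svm_degrees = c(4L, 6L), families = "svm_poly")
  expect_length(g2, 2 * 2)
})

test_that("stratified folds preserve class proportions and are deterministic", {
  y <- rep(c("a", "b"), each = 50)
  f <- stratified_folds(y, n_folds = 10L, seed = 3L)
  for (k in 1:10) {
    expect_identical(sum(y[f == k] == "a"), 5L)
    expect_identical(sum(y[f == k] == "b"), 5L)
  }
  expect_identical(stratified_folds(y, 10L, seed = 3L), f)
  # class smaller than the fold count is an error naming the class
  expect_error(stratified_folds(c(rep("a", 7), rep("b", 20)), 10L), "a")
  # 20 unbalanced classes: per-fold count within 1 of ceiling(n_c/10)
  set.seed(7)
  y20 <- unlist(lapply(1:20, function(i) rep(sprintf("c%02d", i), 10 + i)))
  f20 <- stratified_folds(y20, 10L, seed = 9L)
  for (cl in unique(y20)) {
    n_c <- sum(y20 == cl)
    per_fold <- table(factor(f20[y20 == cl], levels = 1:10))
    expect_true(all(abs(per_fold - ceiling(n_c / 10)) <= 1))
  }
})

test_that("cross-validation scores separable data perfectly and chance data near chance", {
  blobs <- make_blobs(50, rbind(c(0, 0), c(8, 8)), seed = 5)
  # verify separability by a margin before asserting on the classifier
  expect_gt(min(blobs$x[blobs$y == "b", 1]) - max(blobs$x[blobs$y == "a", 1]), 1)
  spec <- classifier_spec("svm_poly", list(degree = 4, C = 0.91, coef0 = 1.3))
  folds <- stratified_folds(blobs$y, 10L, seed = 1L)
  cv <- cross_validate(blobs$x, blobs$y, spec, folds, seed = 1L)
  expect_length(cv$fold_scores, 10L)
  expect_equal(cv$mean_weighted_f1, 1.0)
  expect_equal(cv$mean_weighted_f1, mean(cv$fold_scores))

  # randomly permuted labels over 10 balanced classes: near chance (~0.1)
  chance <- vapply(1:5, function(s) {
    set.seed(s)
    y <- sample(rep(sprintf("c%d", 1:10), each = 10))
    x <- matrix(runif(200), ncol = 2)
    f <- stratified_folds(y, 10L, seed = s)
    cross_validate(x, y, spec, f, seed = s)$mean_weighted_f1
  }, numeric(1))
  expect_lt(mean(chance), 0.25)
  expect_gte(min(chance), 0)
})

test_that("all three classifier families train and predict through the same interface", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(6, 0), c(0, 6)), seed = 11)
  for (spec in list(
    classifier_spec("svm_poly", list(degree = 4, C = 0.91, coef0 = 1.3)),
    classifier_spec("random_forest", list(n_trees = 50L)),
    classifier_spec("mlp", list(hidden = 16L))
  )) {
    model <- train_final(blobs$x, blobs$y, spec, seed = 2L)
    pred <- predict(model, blobs$x)
    expect_gt(mean(pred == blobs$y), 0.95)
    expect_identical(model$classes, c("a", "b", "c"))
    # refitting with the same seed reproduces predictions exactly
    model2 <- train_final(blobs$x, blobs$y, spec, seed = 2L)
    expect_identical(predict(model2, blobs$x), pred)
  }
})

test_that("selection maximizes mean weighted F1 with documented tie rules", {
  mk <- function(score, family, params) {
    structure(list(spec = classifier_spec(family, params),
                   fold_scores = rep(score, 10), mean_weighted_f1 = score),
              class = "cv_result")
  }
  a <- mk(0.90, "svm_poly", list(degree = 6, C = 1, coef0 = 0))
  b <- mk(0.80, "svm_poly", list(degree = 4, C = 1, coef0 = 0))
  expect_identical(select_best(list(a, b)), a$spec)
  expect_identical(select_best(list(b, a)), a$spec)
  expect_identical(select_best(list(b)), b$spec)
  # exact tie: lower-complexity (degree 4) wins regardless of order
  c1 <- mk(0.85, "svm_poly", list(degree = 4, C = 1, coef0 = 0))
  c2 <- mk(0.85, "svm_poly", list(degree = 6, C = 1, coef0 = 0))
  expect_identical(select_best(list(c2, c1))$params$degree, 4)
  expect_identical(select_best(list(c1, c2))$params$degree, 4)
  expect_error(select_best(list()), "no cross-validation")
})

test_that("single-class training folds are scored zero with a warning", {
  x <- matrix(runif(40), ncol = 2)
  y <- c(rep("a", 10), rep("b", 10))
  # adversarial folds: fold 1 holds out every 'b', leaving... construct the
  # converse: fold 1 contains all of 'a' plus nothing else is impossible via
  # stratified_folds, so hand-build folds
  folds <- c(rep(2L, 10), rep(1L, 5), rep(2L, 5))
  # training part of fold 2 = indices with fold 1 = only 'b' members
  spec <- classifier_spec("svm_poly", list(degree = 4, C = 1, coef0 = 0))
  expect_warning(cv <- cross_validate(x, y, spec, folds, seed = 1L),
                 "single-class")
  expect_identical(cv$fold_scores[2], 0)
})
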