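#' Classifier grid, stratified cross-validation and model selection
#'
#' Three multiclass families are considered: support vector machines with
#' polynomial kernels of degree 4-10, random forests with up to 200 trees,
#' and single-hidden-layer perceptrons. Each candidate couples a family and
#' hyperparameters with a color representation and a codebook size k. Model
#' selection uses stratified 10-fold cross-validation on the training split,
#' scored by the weighted mean of per-class F1 (class sizes as weights).
#'
#' @name model_select
NULL

#' Construct a classifier specification
#'
#' @param family `"svm_poly"`, `"random_forest"` or `"mlp"`.
#' @param params named list of family hyperparameters: `degree` (4-10), `C`
#'   (> 0) and `coef0` for `svm_poly`; `n_trees` (1-200) for
#'   `random_forest`; `hidden` (vector of layer sizes; only the first is
#'   used, see Details) for `mlp`.
#' @param representation color representation tag.
#' @param k codebook size.
#' @details The MLP backend (`nnet`) supports a single hidden layer, so
#'   `hidden` is collapsed to its first element.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family, params, representation = "uv", k = 32L) {
  family <- match.arg(family, c("svm_poly", "random_forest", "mlp"))
  if (family == "svm_poly") {
    stopifnot(!is.null(params$degree), !is.null(params$C))
    if (params$degree < 4 || params$degree > 10) {
      stop("svm_poly degree must lie in [4, 10]")
    }
    if (params$C <= 0) stop("C must be > 0")
    if (is.null(params$coef0)) params$coef0 <- 0
  } else if (family == "random_forest") {
    stopifnot(!is.null(params$n_trees))
    if (params$n_trees < 1 || params$n_trees > 200) {
      stop("n_trees must lie in [1, 200]")
    }
  } else {
    stopifnot(!is.null(params$hidden), all(params$hidden >= 1))
  }
  structure(
    list(family = family, params = params,
         representation = tolower(representation), k = as.integer(k)),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(spec_key(x), "\n")
  invisible(x)
}

#' Canonical identity string of a spec
#' @param spec a `classifier_spec`.
#' @return single string.
#' @export
spec_key <- function(spec) {
  pp <- spec$params[order(names(spec$params))]
  pv <- vapply(pp, function(v) paste(v, collapse = "x"), character(1))
  paste0(spec$family, "(", paste(names(pp), pv, sep = "=", collapse = ","),
         ")/", spec$representation, "/k", spec$k)
}

# scalar complexity used by the selection tie rule (fewer parameters wins)
.spec_complexity <- function(spec) {
  switch(spec$family,
    svm_poly = spec$params$degree,
    random_forest = spec$params$n_trees,
    mlp = sum(spec$params$hidden)
  )
}

#' Default candidate grid
#'
#' Cartesian product of the three classifier families (SVM polynomial
#' degrees 4-10 at `C = 0.91`, `coef0 = 1.3`; random forests of 50/100/200
#' trees; MLPs with 32/64/128 hidden units) with the four color
#' representations and the requested codebook sizes. The grid always
#' contains the reference configuration svm_poly(degree 6, C 0.91,
#' coef0 1.3) / uv / k = 32 exactly once (when `"uv"` and 32 are requested).
#'
#' @param representations subset of `c("hsv","luv","hs","uv")`.
#' @param ks codebook sizes, each in `[16, 35]`.
#' @param svm_degrees polynomial degrees, within 4-10.
#' @param svm_C,svm_coef0 SVM cost and independent coefficient values.
#' @param rf_trees forest sizes, each <= 200.
#' @param mlp_sizes list of hidden-layer size vectors.
#' @param families which families to include.
#' @return list of `classifier_spec`.
#' @export
default_grid <- function(representations = c("hsv", "luv", "hs", "uv"),
                         ks = 32L,
                         svm_degrees = 4:10,
                         svm_C = 0.91,
                         svm_coef0 = 1.3,
                         rf_trees = c(50L, 100L, 200L),
                         mlp_sizes = list(32L, 64L, 128L),
                         families = c("svm_poly", "random_forest", "mlp")) {
  grid <- list()
  for (rep_ in representations) for (k in ks) {
    if ("svm_poly" %in% families) {
      for (d in svm_degrees) for (C in svm_C) for (c0 in svm_coef0) {
        grid[[length(grid) + 1L]] <- classifier_spec(
          "svm_poly", list(degree = d, C = C, coef0 = c0), rep_, k)
      }
    }
    if ("random_forest" %in% families) {
      for (nt in rf_trees) {
        grid[[length(grid) + 1L]] <- classifier_spec(
          "random_forest", list(n_trees = nt), rep_, k)
      }
    }
    if ("mlp" %in% families) {
      for (hs in mlp_sizes) {
        grid[[length(grid) + 1L]] <- classifier_spec(
          "mlp", list(hidden = hs), rep_, k)
      }
    }
  }
  grid
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members cyclically across
#' folds, so every fold's per-class count differs from `n_c / n_folds` by at
#' most one.
#'
#' @param labels label vector.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..n_folds`, aligned with `labels`.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < n_folds]
  if (length(small)) {
    stop("class(es) smaller than n_folds = ", n_folds, ": ",
         paste(small, collapse = ", "))
  }
  folds <- integer(length(labels))
  set.seed(.derive_seed(seed, 707L))
  offset <- 0L
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    offset <- offset + length(idx)  # rotate so remainders spread over folds
  }
  folds
}

.feature_matrix <- function(x) {
  x <- as.matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

.fit_classifier <- function(spec, x, y, seed) {
  y <- factor(y)
  x <- .feature_matrix(x)
  switch(spec$family,
    svm_poly = e1071::svm(
      x = x, y = y, kernel = "polynomial",
      degree = spec$params$degree, cost = spec$params$C,
      coef0 = spec$params$coef0, gamma = 1, scale = FALSE),
    random_forest = ranger::ranger(
      x = x, y = y, num.trees = spec$params$n_trees,
      seed = .derive_seed(seed, 808L), num.threads = 1L),
    mlp = {
      set.seed(.derive_seed(seed, 909L))
      nnet::nnet(x = x, y = nnet::class.ind(y),
                 size = spec$params$hidden[1L], softmax = TRUE,
                 maxit = 300L, decay = 1e-4, trace = FALSE,
                 MaxNWts = 100000L)
    }
  )
}

.predict_classifier <- function(fit, spec, x) {
  x <- .feature_matrix(x)
  switch(spec$family,
    svm_poly = as.character(stats::predict(fit, x)),
    random_forest = as.character(stats::predict(fit, data = x)$predictions),
    mlp = {
      pr <- stats::predict(fit, x)
      colnames(pr)[max.col(pr, ties.method = "first")]
    }
  )
}

#' Cross-validate one candidate specification
#'
#' For every fold, fits on the remaining folds and scores weighted F1 on the
#' held-out fold. A fold whose training part contains a single class is
#' scored 0 with a warning.
#'
#' @param features numeric feature matrix (rows = images).
#' @param labels label vector aligned with `features`.
#' @param spec a `classifier_spec`.
#' @param folds fold assignment from [stratified_folds()].
#' @param seed RNG seed for the stochastic learners.
#' @return a `cv_result`: list with `spec`, `fold_scores` and
#'   `mean_weighted_f1`.
#' @export
cross_validate <- function(features, labels, spec, folds, seed = 1L) {
  stopifnot(nrow(features) == length(labels),
            length(folds) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  scores <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2L) {
      warning("fold ", f, ": single-class training data, scored 0")
      return(0)
    }
    fit <- .fit_classifier(spec, features[tr, , drop = FALSE], labels[tr],
                           seed = .derive_seed(seed, f))
    pred <- .predict_classifier(fit, spec, features[!tr, , drop = FALSE])
    metrics(confusion(labels[!tr], pred, classes))$weighted_f1
  }, numeric(1))
  structure(
    list(spec = spec, fold_scores = scores,
         mean_weighted_f1 = mean(scores)),
    class = "cv_result"
  )
}

#' Select the best specification from cross-validation results
#'
#' Highest mean weighted F1 wins; exact ties go to the lower-complexity spec
#' (SVM: degree; forest: number of trees; MLP: hidden units) and then to the
#' lexicographically smaller identity string, so selection does not depend
#' on the order of the results.
#'
#' @param results list of `cv_result`.
#' @return the winning `classifier_spec`.
#' @export
select_best <- function(results) {
  if (!length(results)) stop("no cross-validation results to select from")
  scores <- vapply(results, function(r) r$mean_weighted_f1, numeric(1))
  cx <- vapply(results, function(r) .spec_complexity(r$spec), numeric(1))
  keys <- vapply(results, function(r) spec_key(r$spec), character(1))
  ord <- order(-scores, cx, keys)
  results[[ord[1L]]]$spec
}

#' Fit the final model on the full training data
#'
#' @param features training feature matrix.
#' @param labels training labels.
#' @param spec the chosen `classifier_spec`.
#' @param seed RNG seed.
#' @param codebook optional `pollen_codebook` stored in the bundle so the
#'   model can be applied to raw images.
#' @return a `pollen_model` bundle: `spec`, `fit`, `classes` (sorted unique
#'   labels) and `codebook`.
#' @export
train_final <- function(features, labels, spec, seed = 1L, codebook = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- as.character(labels)
  fit <- .fit_classifier(spec, features, labels, seed = seed)
  structure(
    list(spec = spec, fit = fit, classes = sort(unique(labels)),
         codebook = codebook),
    class = "pollen_model"
  )
}

#' Predict producer labels from feature histograms
#'
#' @param object a `pollen_model`.
#' @param features feature matrix (rows = images).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.pollen_model <- function(object, features, ...) {
  spec <- object$spec
  if (!inherits(spec, "classifier_spec")) class(spec) <- "classifier_spec"
  .predict_classifier(object$fit, spec, as.matrix(features))
}

#' @export
print.pollen_model <- function(x, ...) {
  cat("pollen_model:", spec_key(x$spec), "-", length(x$classes),
      "classes\n")
  invisible(x)
}
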