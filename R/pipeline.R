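#' End-to-end producer-classification pipeline
#'
#' Runs the full chain on a dataset manifest: segmentation (local entropy +
#' Otsu + shadow removal), codebook fitting on training-split pixels,
#' histogram featurization, candidate-grid selection by stratified
#' cross-validated weighted F1, final training, and evaluation on the test
#' split at producer, municipality and visit level, plus test-retest
#' reliability between the two acquisition rounds.
#'
#' @param manifest a `pollen_manifest` (or path to a manifest CSV).
#' @param representation color representation for the codebook.
#' @param k codebook size.
#' @param grid list of `classifier_spec` candidates; `NULL` uses
#'   [default_grid()] restricted to `representation` and `k`.
#' @param n_folds cross-validation folds.
#' @param seed run-level seed; all stochastic stages derive their seeds
#'   from it.
#' @param max_per_image pixel cap per image when pooling for the codebook.
#' @param shadow_rule passed to [remove_shadows()].
#' @param codebook_scope `"train_only"` (default) fits the codebook on
#'   training pixels only; `"all"` pools every image.
#' @param radius entropy neighborhood radius.
#' @return list with `model` (a `pollen_model`), `cv_results`, `best_spec`,
#'   `predictions` (test-split data frame with truth, prediction, visit,
#'   round), `producer_metrics`, `municipality_metrics`, `temporal`,
#'   `reliability` (may be `NULL` with a warning when the correlation is
#'   undefined), and `masks`.
#' @export
run_pipeline <- function(manifest, representation = "uv", k = 32L,
                         grid = NULL, n_folds = 10L, seed = 1L,
                         max_per_image = 2000L,
                         shadow_rule = "remove_low",
                         codebook_scope = c("train_only", "all"),
                         radius = 5L) {
  codebook_scope <- match.arg(codebook_scope)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "pollen_manifest"))
  rec <- manifest$records

  masks <- compute_masks(manifest, radius = radius,
                         shadow_rule = shadow_rule)
  pool_split <- if (codebook_scope == "train_only") "train" else "all"
  pixels <- pool_pixels(manifest, masks, representation,
                        max_per_image = max_per_image, seed = seed,
                        split = pool_split)
  codebook <- fit_codebook(pixels, k = k, seed = seed,
                           representation = representation,
                           scope = codebook_scope)
  feats <- dataset_features(manifest, masks, codebook)

  keep <- rec$image_path %in% rownames(feats)
  rec <- rec[keep, , drop = FALSE]
  feats <- feats[rec$image_path, , drop = FALSE]
  tr <- rec$split == "train"
  te <- rec$split == "test"
  if (!any(tr) || !any(te)) stop("manifest needs both train and test images")

  if (is.null(grid)) {
    grid <- default_grid(representations = representation, ks = k)
  }
  folds <- stratified_folds(rec$producer_id[tr], n_folds = n_folds,
                            seed = seed)
  cv_results <- lapply(grid, function(spec) {
    cross_validate(feats[tr, , drop = FALSE], rec$producer_id[tr],
                   spec, folds, seed = seed)
  })
  best <- select_best(cv_results)
  model <- train_final(feats[tr, , drop = FALSE], rec$producer_id[tr],
                       best, seed = seed, codebook = codebook)

  pred <- predict(model, feats[te, , drop = FALSE])
  predictions <- data.frame(
    image_path = rec$image_path[te],
    producer_id = rec$producer_id[te],
    predicted = pred,
    municipality = rec$municipality[te],
    visit = rec$visit[te],
    acquisition_round = rec$acquisition_round[te],
    stringsAsFactors = FALSE
  )

  producer_metrics <- metrics(confusion(predictions$producer_id,
                                        predictions$predicted,
                                        model$classes))
  municipality_metrics <- municipality_rollup(
    predictions$producer_id, predictions$predicted,
    manifest$producer_to_municipality)
  temporal <- temporal_table(predictions$producer_id,
                             predictions$predicted, predictions$visit)
  reliability <- tryCatch(
    test_retest(predictions$producer_id, predictions$predicted,
                predictions$acquisition_round),
    error = function(e) {
      warning("reliability not computed: ", conditionMessage(e))
      NULL
    }
  )

  list(model = model, cv_results = cv_results, best_spec = best,
       predictions = predictions,
       producer_metrics = producer_metrics,
       municipality_metrics = municipality_metrics,
       temporal = temporal, reliability = reliability,
       masks = masks)
}

#' Apply a trained model to a manifest
#'
#' Segments and featurizes the images with the model's own codebook and
#' returns predictions.
#'
#' @param model a `pollen_model` carrying its codebook.
#' @param manifest a `pollen_manifest` or manifest CSV path.
#' @param shadow_rule,radius preprocessing parameters, as in
#'   [run_pipeline()].
#' @return data frame with `image_path`, `producer_id` (truth) and
#'   `predicted`.
#' @export
predict_manifest <- function(model, manifest, shadow_rule = "remove_low",
                             radius = 5L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(model$codebook)) stop("model bundle carries no codebook")
  masks <- compute_masks(manifest, radius = radius,
                         shadow_rule = shadow_rule)
  feats <- dataset_features(manifest, masks, model$codebook)
  rec <- manifest$records[manifest$records$image_path %in% rownames(feats), ]
  data.frame(image_path = rec$image_path,
             producer_id = rec$producer_id,
             predicted = predict(model, feats[rec$image_path, , drop = FALSE]),
             stringsAsFactors = FALSE)
}
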