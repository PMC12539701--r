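#' Reading and writing datasets, features and model bundles
#'
#' A pollen image dataset is a directory of photographs plus a CSV manifest
#' binding each image to its producer, the producer's municipality, the
#' sampling visit (1-4), the acquisition round (1-2, the two time-separated
#' repeat acquisitions used for test-retest reliability) and the train/test
#' split. Image paths in a manifest are relative to the manifest's directory.
#'
#' @name dataset_io
NULL

MANIFEST_COLUMNS <- c("image_path", "producer_id", "municipality",
                      "visit", "acquisition_round", "split")

BUNDLE_VERSION <- "1"

.validate_manifest <- function(df) {
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!df$visit %in% 1:4)) stop("visit must be an integer in 1..4")
  if (any(!df$acquisition_round %in% 1:2)) {
    stop("acquisition_round must be 1 or 2")
  }
  if (any(!df$split %in% c("train", "test"))) {
    stop("split must be 'train' or 'test'")
  }
  if (any(!nzchar(df$image_path))) stop("image_path must be nonempty")
  map <- unique(df[, c("producer_id", "municipality")])
  dup <- unique(map$producer_id[duplicated(map$producer_id)])
  if (length(dup)) {
    stop("producer(s) mapped to more than one municipality: ",
         paste(dup, collapse = ", "))
  }
  invisible(df)
}

.new_manifest <- function(records, directory = ".") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$visit <- as.integer(records$visit)
  records$acquisition_round <- as.integer(records$acquisition_round)
  .validate_manifest(records)
  map <- unique(records[, c("producer_id", "municipality")])
  mapping <- stats::setNames(map$municipality, map$producer_id)
  structure(
    list(records = records[, MANIFEST_COLUMNS],
         producer_to_municipality = mapping,
         directory = directory),
    class = "pollen_manifest"
  )
}

#' Read a dataset manifest
#'
#' @param path path to a manifest CSV with header
#'   `image_path,producer_id,municipality,visit,acquisition_round,split`.
#' @return A `pollen_manifest`: a list with `records` (data frame, one row
#'   per image, row order preserved), `producer_to_municipality` (named
#'   character vector) and `directory` (base directory for image paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$visit <- as.integer(df$visit)
  df$acquisition_round <- as.integer(df$acquisition_round)
  .new_manifest(df, directory = dirname(path))
}

#' Write a dataset manifest
#'
#' @param manifest a `pollen_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "pollen_manifest"))
  utils::write.csv(manifest$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pollen_manifest <- function(x, ...) {
  cat("pollen_manifest:", nrow(x$records), "images,",
      length(x$producer_to_municipality), "producers,",
      length(unique(x$producer_to_municipality)), "municipalities\n")
  cat("  train:", sum(x$records$split == "train"),
      " test:", sum(x$records$split == "test"), "\n")
  invisible(x)
}

#' Resolve the image paths of a manifest
#'
#' @param manifest a `pollen_manifest`.
#' @return character vector of absolute-or-relative paths usable from the
#'   current working directory.
#' @export
manifest_paths <- function(manifest) {
  file.path(manifest$directory, manifest$records$image_path)
}

#' Load an RGB image
#'
#' Reads an 8-bit PNG or JPEG image and returns an H x W x 3 array of values
#' in `[0, 1]`. An alpha channel is dropped; grayscale (single-channel)
#' images are rejected.
#'
#' @param path image file path.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (expected PNG or JPEG)")
  )
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L) {
    stop("image is not RGB (single-channel input): ", path)
  }
  img[, , 1:3, drop = FALSE]
}

#' Write an RGB image or a binary mask as PNG
#'
#' @param img H x W x 3 array in `[0, 1]`, or an H x W logical/numeric matrix
#'   for masks.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_image_png <- function(img, path) {
  if (is.logical(img)) img <- img * 1.0
  png::writePNG(img, path)
  invisible(path)
}

#' Write / read a color codebook as CSV plus metadata sidecar
#'
#' The codebook table holds one centroid per row; the sidecar
#' (`<path>.meta.json`) records the representation tag, k, the fitting seed
#' and the pixel scope.
#'
#' @param codebook a `pollen_codebook`, see [fit_codebook()].
#' @param path CSV output path.
#' @return `path` (write) / a `pollen_codebook` (read).
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "pollen_codebook"))
  utils::write.csv(as.data.frame(codebook$centroids), path, row.names = FALSE)
  meta <- list(representation = codebook$representation,
               k = codebook$k, seed = codebook$seed,
               scope = codebook$scope, version = BUNDLE_VERSION)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  centroids <- as.matrix(utils::read.csv(path))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("codebook metadata sidecar missing: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(
    list(centroids = centroids, representation = meta$representation,
         k = as.integer(meta$k), seed = meta$seed, scope = meta$scope),
    class = "pollen_codebook"
  )
}

#' Write / read an image feature table
#'
#' One row per image: `image_path` followed by the k codebook frequencies.
#'
#' @param features matrix of histograms (rows = images) with rownames set to
#'   image paths, or a data frame as returned by [read_features()].
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(image_path = rownames(features),
                   as.data.frame(unname(features)), check.names = FALSE)
  names(df)[-1L] <- paste0("c", seq_len(ncol(features)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$image_path
  m
}

#' Read a YAML run configuration
#'
#' @param path YAML file of key/value pairs.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

#' Persist a trained model bundle to a directory
#'
#' The bundle directory contains `codebook.csv` (+ JSON sidecar),
#' `metadata.json` (bundle version, classifier spec, class list,
#' representation) and `classifier.rds` (the fitted classifier object).
#'
#' @param bundle a `pollen_model` as returned by [train_final()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
persist_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "pollen_model"))
  if (is.null(bundle$codebook)) stop("bundle has no codebook")
  if (is.null(bundle$fit) || is.null(bundle$classes)) {
    stop("bundle is incomplete (missing classifier fit or class list)")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_codebook(bundle$codebook, file.path(path, "codebook.csv"))
  meta <- list(version = BUNDLE_VERSION,
               spec = unclass(bundle$spec),
               classes = bundle$classes,
               representation = bundle$codebook$representation)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(bundle$fit, file.path(path, "classifier.rds"))
  invisible(path)
}

#' Load a trained model bundle
#'
#' @param path bundle directory written by [persist_model()].
#' @return a `pollen_model`.
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop("not a model bundle (metadata.json missing): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$version), BUNDLE_VERSION)) {
    stop("incompatible bundle version '", meta$version,
         "' (this package reads version ", BUNDLE_VERSION, ")")
  }
  fit <- tryCatch(readRDS(file.path(path, "classifier.rds")),
                  error = function(e) {
                    stop("incompatible or truncated bundle: ",
                         conditionMessage(e))
                  })
  codebook <- read_codebook(file.path(path, "codebook.csv"))
  spec <- meta$spec
  if (!is.null(spec)) class(spec) <- "classifier_spec"
  structure(
    list(spec = spec, fit = fit, classes = meta$classes,
         codebook = codebook),
    class = "pollen_model"
  )
}
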