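MODEL_FORMAT_VERSION <- "bpac-model-1"

#' Random-forest model configuration
#'
#' Defaults follow the study constants: 100 trees, and the number of
#' features tried at each split equal to the nearest integer to the square
#' root of the number of selected features.
#'
#' @param n_trees Number of trees (>= 1; default 100).
#' @param features Feature subset to train on (names from
#'   [bpac_features()]; default all 11).
#' @param features_per_split Features tried per split; default
#'   `round(sqrt(length(features)))`.
#' @param seed Integer RNG seed (default 42).
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_trees = 100L, features = bpac_features(),
                         features_per_split = NULL, seed = 42L) {
  if (n_trees < 1L) stop("n_trees must be at least 1")
  bad <- setdiff(features, bpac_features())
  if (length(bad) > 0L)
    stop(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")))
  if (is.null(features_per_split))
    features_per_split <- max(1L, round(sqrt(length(features))))
  if (features_per_split > length(features))
    stop("features_per_split cannot exceed the number of selected features")
  structure(list(n_trees = as.integer(n_trees),
                 features = features,
                 features_per_split = as.integer(features_per_split),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Train the binding classifier
#'
#' Fits a random forest (bootstrap-resampled decision trees, unlimited
#' depth) to the labeled feature table.  Deterministic for a fixed seed
#' and input.
#'
#' @param dataset A [labeled_dataset] containing both classes and at least
#'   10 sites.
#' @param config A [model_config].
#' @return An object of class `trained_model`.
#' @export
train_model <- function(dataset, config = model_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- dataset_size(dataset)
  if (n < 10L) stop("need at least 10 samples to train")
  tab <- table(factor(dataset$labels, levels = c(0L, 1L)))
  if (tab[["1"]] == 0L) stop("training data contains no bound class")
  if (tab[["0"]] == 0L) stop("training data contains no unbound class")
  x <- dataset$features[, config$features, drop = FALSE]
  y <- factor(dataset$labels, levels = c(0L, 1L))
  set.seed(config$seed)
  if (all(vapply(x, function(v) length(unique(v)) == 1L, logical(1)))) {
    # no split is possible: the ensemble degenerates to root-only trees,
    # each voting its bootstrap majority; the vote average is the bagged
    # prevalence, i.e. a constant (chance-level) score
    boots <- vapply(seq_len(config$n_trees), function(i)
      mean(sample(dataset$labels, n, replace = TRUE) == 1L) >= 0.5,
      logical(1))
    forest <- list(constant_score = mean(boots))
  } else {
    forest <- randomForest::randomForest(
      x = x, y = y, ntree = config$n_trees, mtry = config$features_per_split)
  }
  structure(list(forest = forest, config = config,
                 feature_order = config$features,
                 provenance = list(tf = dataset$tf, cell = dataset$cell,
                                   genome_tag = dataset$genome_tag,
                                   n_samples = n,
                                   prevalence = mean(dataset$labels),
                                   seed = config$seed),
                 version = MODEL_FORMAT_VERSION),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "trained_model: %d trees, %d features, trained on %s @ %s (n=%d)\n",
    x$config$n_trees, length(x$feature_order), x$provenance$tf,
    x$provenance$cell, x$provenance$n_samples))
  invisible(x)
}

#' Predict per-site binding scores
#'
#' The score of a site is the fraction of trees voting "bound", so scores
#' always lie in [0, 1].
#'
#' @param model A [trained_model].
#' @param newdata A [labeled_dataset] or feature data.frame containing the
#'   model's training features.
#' @return Numeric vector of scores in [0, 1].
#' @export
predict_scores <- function(model, newdata) {
  feats <- if (inherits(newdata, "labeled_dataset")) newdata$features
           else as.data.frame(newdata)
  missing <- setdiff(model$feature_order, colnames(feats))
  if (length(missing) > 0L)
    stop(sprintf("feature columns do not match training order: expected [%s], received [%s]",
                 paste(model$feature_order, collapse = ", "),
                 paste(colnames(feats), collapse = ", ")))
  x <- feats[, model$feature_order, drop = FALSE]
  if (!is.null(model$forest$constant_score))
    return(rep(model$forest$constant_score, nrow(x)))
  as.numeric(stats::predict(model$forest, x, type = "prob")[, "1"])
}

#' Split a dataset for self-prediction
#'
#' Uniform random partition without replacement;
#' `|train| = round(train_fraction * n)`.  The study benchmark trains on
#' 2/3 of sites and evaluates on the remaining 1/3.
#'
#' @param dataset A [labeled_dataset] with at least 3 sites.
#' @param train_fraction Fraction in (0, 1); default 2/3.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both [labeled_dataset]s.
#' @export
split_self <- function(dataset, train_fraction = 2 / 3, seed = 42L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- dataset_size(dataset)
  if (n < 3L) stop("need at least 3 samples to split")
  set.seed(seed)
  idx <- sample.int(n, round(train_fraction * n))
  subset_ds <- function(i) labeled_dataset(
    dataset$sites[i, , drop = FALSE],
    dataset$features[i, , drop = FALSE],
    dataset$labels[i], dataset$tf, dataset$cell, dataset$genome_tag)
  list(train = subset_ds(sort(idx)),
       test = subset_ds(setdiff(seq_len(n), idx)))
}

#' Save a trained model
#'
#' Writes a versioned serialized ensemble plus a JSON sidecar
#' (`<path>.json`) carrying the configuration, provenance and feature
#' order contract.
#'
#' @param model A [trained_model].
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  sidecar <- list(version = model$version,
                  config = unclass(model$config),
                  provenance = model$provenance,
                  feature_order = model$feature_order)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a trained model
#'
#' Refuses files with a missing or mismatched format version; a truncated
#' or corrupt file raises an error rather than yielding a partial model.
#'
#' @param path File written by [save_model].
#' @return A [trained_model].
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path),
                    error = function(e) stop(sprintf(
                      "cannot read model file '%s': %s", path,
                      conditionMessage(e))))
  if (!inherits(model, "trained_model") ||
      !identical(model$version, MODEL_FORMAT_VERSION))
    stop(sprintf("model file version mismatch: expected %s",
                 MODEL_FORMAT_VERSION))
  model
}
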