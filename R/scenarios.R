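registry_key <- function(tf, cell) paste(tf, cell, sep = "@")

#' Registry of labeled datasets keyed by (TF, cell type)
#'
#' @param datasets Optional list of [labeled_dataset]s to add.
#' @return An object of class `dataset_registry`.
#' @export
dataset_registry <- function(datasets = list()) {
  reg <- structure(list(datasets = list()), class = "dataset_registry")
  for (ds in datasets) reg <- registry_add(reg, ds)
  reg
}

#' Add a dataset to a registry
#' @param registry A [dataset_registry].
#' @param dataset A [labeled_dataset]; its (tf, cell) key must be new.
#' @return The updated registry.
#' @export
registry_add <- function(registry, dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  key <- registry_key(dataset$tf, dataset$cell)
  if (key %in% names(registry$datasets))
    stop(sprintf("duplicate registry key '%s'", key))
  registry$datasets[[key]] <- dataset
  registry
}

#' Fetch a dataset from a registry
#' @param registry A [dataset_registry].
#' @param tf,cell Key components.
#' @return A [labeled_dataset].
#' @export
registry_get <- function(registry, tf, cell) {
  key <- registry_key(tf, cell)
  ds <- registry$datasets[[key]]
  if (is.null(ds)) stop(sprintf("no dataset registered for '%s'", key))
  ds
}

#' TFs present in a registry for a given cell type
#' @param registry A [dataset_registry].
#' @param cell Cell type.
#' @return Character vector of TF names.
#' @export
registry_tfs <- function(registry, cell) {
  keys <- names(registry$datasets)
  parts <- strsplit(keys, "@", fixed = TRUE)
  tfs <- vapply(parts, `[[`, character(1), 1L)
  cells <- vapply(parts, `[[`, character(1), 2L)
  unique(tfs[cells == cell])
}

#' Pool several labeled datasets into one training set
#'
#' Concatenates rows unweighted (each site one row, so larger datasets
#' dominate the pool).
#'
#' @param datasets List of [labeled_dataset]s sharing the feature schema.
#' @return A [labeled_dataset] with concatenated provenance.
#' @export
pool_datasets <- function(datasets) {
  if (length(datasets) == 0L) stop("cannot pool an empty dataset list")
  if (length(datasets) == 1L) return(datasets[[1L]])
  sites <- do.call(rbind, lapply(datasets, function(d) {
    s <- d$sites
    s$global_id <- site_keys(d)
    s
  }))
  feats <- do.call(rbind, lapply(datasets, `[[`, "features"))
  labels <- unlist(lapply(datasets, `[[`, "labels"))
  rownames(sites) <- rownames(feats) <- NULL
  labeled_dataset(sites, feats, labels,
                  tf = paste(unique(vapply(datasets, `[[`, "", "tf")),
                             collapse = "+"),
                  cell = paste(unique(vapply(datasets, `[[`, "", "cell")),
                               collapse = "+"),
                  genome_tag = datasets[[1L]]$genome_tag)
}

assert_no_leakage <- function(train_keys, test_keys) {
  if (length(intersect(train_keys, test_keys)) > 0L)
    stop("leakage guard: training rows overlap the evaluation dataset")
  invisible(TRUE)
}

train_and_eval <- function(train_ds, test_ds, config, scenario) {
  assert_no_leakage(site_keys(train_ds), site_keys(test_ds))
  model <- train_model(train_ds, config)
  scores <- predict_scores(model, test_ds)
  evaluate_scores(scores, test_ds$labels, scenario)
}

#' Self-prediction
#'
#' Trains on a 2/3 random split of the (TF, cell) dataset and evaluates
#' on the held-out 1/3.
#'
#' @param registry A [dataset_registry].
#' @param tf,cell Target key.
#' @param config A [model_config]; its seed drives the split and the
#'   forest.
#' @param train_fraction Training fraction (default 2/3).
#' @return An [evaluate_scores] result tagged "self".
#' @export
run_self <- function(registry, tf, cell, config = model_config(),
                     train_fraction = 2 / 3) {
  ds <- registry_get(registry, tf, cell)
  parts <- split_self(ds, train_fraction, seed = config$seed)
  train_and_eval(parts$train, parts$test, config, "self")
}

#' Cross-TF prediction
#'
#' Trains on one or more other TFs in the same cell type and evaluates on
#' the full dataset of the target TF.  The target TF must not appear in
#' the training list.
#'
#' @param registry A [dataset_registry].
#' @param training_tfs Character vector of training TFs.
#' @param target_tf Target TF (excluded from training).
#' @param cell Shared cell type.
#' @param config A [model_config].
#' @return An [evaluate_scores] result tagged "cross_tf" (one training
#'   TF) or "multi_tf" (several).
#' @export
run_cross_tf <- function(registry, training_tfs, target_tf, cell,
                         config = model_config()) {
  if (length(training_tfs) == 0L) stop("no training TFs supplied")
  if (target_tf %in% training_tfs)
    stop("leakage guard: target TF appears in the training TFs")
  train_ds <- pool_datasets(lapply(training_tfs, registry_get,
                                   registry = registry, cell = cell))
  test_ds <- registry_get(registry, target_tf, cell)
  tag <- if (length(training_tfs) > 1L) "multi_tf" else "cross_tf"
  train_and_eval(train_ds, test_ds, config, tag)
}

#' Cross-cell-type prediction
#'
#' Trains on the same TF in another cell type and evaluates on the full
#' target-cell dataset.
#'
#' @param registry A [dataset_registry].
#' @param tf TF name (same on both sides).
#' @param training_cell,target_cell Distinct cell types.
#' @param config A [model_config].
#' @return An [evaluate_scores] result tagged "cross_cell".
#' @export
run_cross_cell <- function(registry, tf, training_cell, target_cell,
                           config = model_config()) {
  if (identical(training_cell, target_cell))
    stop("training and target cell types must differ")
  train_ds <- registry_get(registry, tf, training_cell)
  test_ds <- registry_get(registry, tf, target_cell)
  train_and_eval(train_ds, test_ds, config, "cross_cell")
}

#' Mixed (universal-model) prediction
#'
#' Pools training data across TFs and cell types; the target (TF, cell)
#' pair must be absent from the training keys.
#'
#' @param registry A [dataset_registry].
#' @param training_keys List of `c(tf, cell)` pairs (or a 2-column
#'   data.frame).
#' @param target_tf,target_cell Target key.
#' @param config A [model_config].
#' @return An [evaluate_scores] result tagged "mixed".
#' @export
run_mixed <- function(registry, training_keys, target_tf, target_cell,
                      config = model_config()) {
  if (is.data.frame(training_keys))
    training_keys <- lapply(seq_len(nrow(training_keys)), function(i)
      c(training_keys[i, 1L], training_keys[i, 2L]))
  if (length(training_keys) == 0L) stop("no training keys supplied")
  for (k in training_keys)
    if (identical(as.character(k[[1L]]), target_tf) &&
        identical(as.character(k[[2L]]), target_cell))
      stop("leakage guard: target (TF, cell) appears in the training keys")
  train_ds <- pool_datasets(lapply(training_keys, function(k)
    registry_get(registry, as.character(k[[1L]]), as.character(k[[2L]]))))
  test_ds <- registry_get(registry, target_tf, target_cell)
  train_and_eval(train_ds, test_ds, config, "mixed")
}

#' Sweep the number of training TFs
#'
#' For each N, samples `repeats` random N-subsets of the available
#' training TFs (without replacement within a combination), runs cross-TF
#' prediction against the target, and reports the mean and sd of the AUC.
#' The study swept N in {3, 5, 8, 12, 16, 20, 25, 30} with 100 random
#' combinations each.
#'
#' @param registry A [dataset_registry].
#' @param n_values Integer vector of N values.
#' @param repeats Combinations sampled per N.
#' @param target_tf Target TF (never sampled for training).
#' @param cell Shared cell type.
#' @param config A [model_config]; its seed makes the sampled
#'   combinations reproducible.
#' @return data.frame with columns n, mean_auc, sd_auc.
#' @export
sweep_n_tfs <- function(registry, n_values, repeats, target_tf, cell,
                        config = model_config()) {
  pool <- setdiff(registry_tfs(registry, cell), target_tf)
  if (max(n_values) > length(pool))
    stop(sprintf("N = %d exceeds the %d available training TFs",
                 max(n_values), length(pool)))
  out <- lapply(n_values, function(n) {
    set.seed(config$seed + n)
    combos <- replicate(repeats, sample(pool, n), simplify = FALSE)
    aucs <- vapply(combos, function(tfs)
      run_cross_tf(registry, tfs, target_tf, cell, config)$auc, numeric(1))
    data.frame(n = n, mean_auc = mean(aucs), sd_auc = stats::sd(aucs))
  })
  do.call(rbind, out)
}
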