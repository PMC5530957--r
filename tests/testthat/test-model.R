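planted_rule_dataset <- function(n, seed, flip = FALSE) {
  # label = 1 iff reads_at_site exceeds its median (a single-feature rule)
  ds <- synth_dataset(n, integer(n), seed = seed)
  lab <- as.integer(ds$features$reads_at_site >
                      stats::median(ds$features$reads_at_site))
  if (flip) lab <- 1L - lab
  labeled_dataset(ds$sites, ds$features, lab, ds$tf, ds$cell)
}

test_that("config defaults follow the study constants", {
  cfg <- model_config()
  expect_equal(cfg$n_trees, 100L)
  expect_equal(cfg$features_per_split, round(sqrt(11)))
  expect_equal(cfg$features_per_split, 3L)
  cfg3 <- model_config(features = static_features())
  expect_equal(cfg3$features_per_split, 2L)
  expect_error(model_config(features = "pwm_score", features_per_split = 2),
               "cannot exceed")
  expect_error(model_config(features = "not_a_feature"), "unknown feature")
})

test_that("training is deterministic and recovers a planted rule", {
  ds <- planted_rule_dataset(400, seed = 2)
  parts <- split_self(ds, seed = 5)
  m1 <- train_model(parts$train, model_config(seed = 11))
  m2 <- train_model(parts$train, model_config(seed = 11))
  s1 <- predict_scores(m1, parts$test)
  expect_identical(s1, predict_scores(m2, parts$test))
  expect_true(all(s1 >= 0 & s1 <= 1))
  ev <- evaluate_scores(s1, parts$test$labels)
  expect_gt(ev$auc, 0.95)
})

test_that("label-permuted data scores at chance", {
  set.seed(99)
  ds <- synth_dataset(2000, sample(rep(c(0L, 1L), 1000)), seed = 3)
  parts <- split_self(ds, seed = 7)
  m <- train_model(parts$train, model_config(seed = 7))
  ev <- evaluate_scores(predict_scores(m, parts$test), parts$test$labels)
  expect_gt(ev$auc, 0.45)
  expect_lt(ev$auc, 0.55)
})

test_that("single-tree scores are votes; constant feature is uninformative", {
  ds <- planted_rule_dataset(200, seed = 4)
  m1 <- train_model(ds, model_config(n_trees = 1L, seed = 1))
  expect_true(all(predict_scores(m1, ds) %in% c(0, 1)))
  # a constant feature carries no signal
  f <- ds$features
  f$conservation_score <- 0.5
  dsc <- labeled_dataset(ds$sites, f, ds$labels, ds$tf, ds$cell)
  parts <- split_self(dsc, seed = 2)
  mc <- train_model(parts$train,
                    model_config(features = "conservation_score",
                                 features_per_split = 1L, seed = 2))
  sc <- predict_scores(mc, parts$test)
  # a constant design cannot be split: every tree votes its bootstrap
  # majority, so the score is constant and the AUC sits exactly at chance
  expect_equal(length(unique(sc)), 1L)
  expect_equal(evaluate_scores(sc, parts$test$labels)$auc, 0.5)
})

test_that("degenerate training inputs are rejected", {
  ds0 <- synth_dataset(50, integer(50), seed = 1)
  expect_error(train_model(ds0), "no bound class")
  ds1 <- synth_dataset(50, rep(1L, 50), seed = 1)
  expect_error(train_model(ds1), "no unbound class")
  tiny <- synth_dataset(6, rep(c(0L, 1L), 3), seed = 1)
  expect_error(train_model(tiny), "at least 10")
  # prediction with wrong columns names the expected order
  ds <- planted_rule_dataset(100, seed = 6)
  m <- train_model(ds)
  expect_error(predict_scores(m, ds$features[, 1:5]),
               "expected \\[pwm_score")
})

test_that("split_self partitions exhaustively and reproducibly", {
  ds <- synth_dataset(9, rep(c(0L, 1L, 0L), 3), seed = 8)
  parts <- split_self(ds, 2 / 3, seed = 3)
  expect_equal(dataset_size(parts$train), 6L)
  expect_equal(dataset_size(parts$test), 3L)
  expect_setequal(c(parts$train$sites$site_id, parts$test$sites$site_id),
                  ds$sites$site_id)
  expect_length(intersect(parts$train$sites$site_id,
                          parts$test$sites$site_id), 0L)
  parts2 <- split_self(ds, 2 / 3, seed = 3)
  expect_identical(parts2$train$sites$site_id, parts$train$sites$site_id)
  expect_error(split_self(synth_dataset(2, c(0L, 1L))), "at least 3")
})

test_that("save/load round-trips predictions bit-exactly", {
  ds <- planted_rule_dataset(150, seed = 12)
  m <- train_model(ds, model_config(seed = 5))
  before <- predict_scores(m, ds)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(predict_scores(back, ds), before)
  expect_equal(back$provenance, m$provenance)
  expect_equal(back$feature_order, m$feature_order)
  # truncated file refuses to load
  bad <- withr::local_tempfile(fileext = ".rds")
  raw <- readBin(path, "raw", n = 200L)
  writeBin(raw, bad)
  expect_error(load_model(bad), "cannot read model file")
  # files without the expected version are refused
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), "version mismatch")
})
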