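test_that("positive-class weight is the rounded-half-up negative:positive ratio", {
  expect_equal(compute_class_weight(796, 2187), 3)
  expect_equal(compute_class_weight(300, 300), 1)
  expect_equal(compute_class_weight(100, 450), 5)  # 4.5 rounds half-up
  expect_equal(compute_class_weight(100, 30), 1)   # floor at 1
  expect_error(compute_class_weight(0, 10), "at least one")
})

test_that("weighted cross-entropy matches direct substitution and the c=1 limit", {
  expect_lt(weighted_bce_loss(0.999999, 1, 3), 1e-5)
  expect_equal(weighted_bce_loss(0.5, 0, 7), log(2))
  expect_equal(weighted_bce_loss(0.5, 1, 3), 3 * log(2))

  withr::local_seed(1)
  p <- runif(20, 0.01, 0.99)
  y <- rbinom(20, 1, 0.4)
  plain <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_bce_loss(p, y, 1), plain, tolerance = 1e-12)
  expect_error(weighted_bce_loss(p, y, 1, integer()), "no nodes")
})

test_that("splits are stratified, disjoint, covering and seed-deterministic", {
  y <- factor(c(rep("positive", 80), rep("negative", 240), rep("unlabeled", 30)),
              levels = c("positive", "negative", "unlabeled"))
  mc <- model_config(seed = 3)
  plan <- make_splits(y, mc)
  expect_length(plan, 10)
  for (sp in plan) {
    expect_length(sp$test, 80)                       # 25% of 320
    expect_equal(sum(y[sp$test] == "positive"), 20)  # stratified 20/60
    expect_equal(sum(y[sp$test] == "negative"), 60)
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_idx), which(y != "unlabeled"))  # disjoint cover
    expect_equal(length(all_idx), length(unique(all_idx)))
  }
  expect_equal(make_splits(y, mc), plan)
  expect_false(identical(make_splits(y, model_config(seed = 4)), plan))

  few <- factor(c(rep("positive", 5), rep("negative", 40)),
                levels = c("positive", "negative", "unlabeled"))
  expect_error(make_splits(few, mc), "too few labeled")
})

test_that("k-fold scheme partitions the labeled set into disjoint test folds", {
  y <- factor(c(rep("positive", 30), rep("negative", 60), rep("unlabeled", 10)),
              levels = c("positive", "negative", "unlabeled"))
  mc <- model_config(seed = 5, cv_folds = 5, split_scheme = "kfold")
  plan <- make_splits(y, mc)
  tests <- lapply(plan, `[[`, "test")
  expect_equal(sort(unlist(tests)), which(y != "unlabeled"))
  expect_equal(sum(lengths(tests)), 90)  # folds are disjoint and cover
})

test_that("training solves the separable two-clique fixture and is seed-reproducible", {
  ds <- clique_fixture()
  mc <- tiny_config(seed = 11, cv_folds = 2, max_epochs = 300, patience = 50)
  sp <- make_splits(ds$y, mc)
  fr <- train_fold(ds, sp[[1]], mc)
  expect_equal(fr$metrics$ACC, 1.0)
  expect_equal(fr$metrics$AUROC, 1.0)
  # train-mask accuracy from the returned full probability vector
  expect_true(all((fr$probs[sp[[1]]$train] >= 0.5) ==
                    (ds$y[sp[[1]]$train] == "positive")))

  fr2 <- train_fold(ds, sp[[1]], mc)
  expect_identical(fr$probs, fr2$probs)
  expect_identical(fr$epochs_run, fr2$epochs_run)
})

test_that("compiled and reference training engines produce identical results", {
  # with dropout off both loops are RNG-free after initialization, so the
  # trajectories must coincide
  withr::local_seed(20)
  ds <- random_dataset(n = 14, p = 0.3, d = 5, n_pos = 4, n_neg = 5)
  for (br in c("both", "gcn", "gat")) {
    mc_cpp <- tiny_config(seed = 7, cv_folds = 2, max_epochs = 25,
                          patience = 25, dropout = 0, branches = br)
    mc_ref <- mc_cpp; mc_ref$engine <- "reference"
    sp <- make_splits(ds$y, mc_cpp)
    f_cpp <- train_fold(ds, sp[[1]], mc_cpp)
    f_ref <- train_fold(ds, sp[[1]], mc_ref)
    expect_equal(f_cpp$probs, f_ref$probs, tolerance = 1e-12)
    expect_equal(f_cpp$best_val_loss, f_ref$best_val_loss, tolerance = 1e-12)
    expect_identical(f_cpp$epochs_run, f_ref$epochs_run)
  }
})

test_that("early stopping halts soon after the validation loss stops improving", {
  # patience 1: training must stop at the first epoch without improvement,
  # which dropout noise guarantees long before the epoch cap
  ds <- clique_fixture()
  mc <- tiny_config(seed = 12, cv_folds = 2, max_epochs = 2000, patience = 1)
  sp <- make_splits(ds$y, mc)
  fr <- train_fold(ds, sp[[1]], mc)
  expect_lt(fr$epochs_run, 2000)
  expect_equal(fr$epochs_run, fr$best_epoch + 1)
})

test_that("cross-validation aggregates fold metrics and averages probabilities", {
  ds <- clique_fixture()
  mc <- tiny_config(seed = 13, cv_folds = 3, max_epochs = 200, patience = 30)
  cv <- run_cross_validation(ds, mc)
  expect_length(cv$folds, mc$cv_folds)
  expect_equal(unname(cv$metrics_mean["AUROC"]),
               mean(vapply(cv$folds, function(f) f$metrics$AUROC, 0)))
  expect_equal(unname(cv$metrics_mean["AUROC"]), 1.0)
  expect_true(all(cv$probs > 0 & cv$probs < 1))
  expect_equal(names(cv$probs), ds$network$nodes)
  manual <- Reduce(`+`, lapply(cv$folds, `[[`, "probs")) / length(cv$folds)
  expect_equal(cv$probs, manual)
})

test_that("probability tables round-trip through the TSV interface", {
  ds <- clique_fixture()
  mc <- tiny_config(seed = 14, cv_folds = 2, max_epochs = 50, patience = 20)
  cv <- run_cross_validation(ds, mc)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probabilities(cv, ds$y, f)
  df <- read_probabilities(f)
  expect_equal(names(df), c("gene", "probability", "label", "fold_count"))
  expect_equal(df$gene, names(cv$probs))
  expect_equal(df$probability, unname(cv$probs), tolerance = 1e-12)
  expect_true(all(df$fold_count == 2))
})
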