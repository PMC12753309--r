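test_that("gradient normalization is min-max, idempotent and affine-invariant", {
  expect_equal(normalize_gradient(c(10, 20, 30)), c(0, 0.5, 1))
  v <- c(0, 0.2, 0.7, 1)
  expect_equal(normalize_gradient(v), v)
  x <- runif(10)
  expect_equal(normalize_gradient(3.7 * x - 2), normalize_gradient(x),
               tolerance = 1e-12)
  expect_error(normalize_gradient(rep(2, 5)), "constant")
})

test_that("cross-validation recovers separable structure and respects the split", {
  set.seed(1)
  f <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  y <- rep(c("A", "B"), each = 20)
  res <- cross_validate(f, y, "knn", cv_repeats = 3, seed = 2)
  expect_equal(res$metric, 1.0)
  expect_identical(res$metric_name, "accuracy")
  expect_identical(res$n_train, 24L)  # 60% of each class
  expect_identical(res$n_test, 16L)
  # regression on a noiseless signal column
  g <- runif(40)
  fg <- cbind(g, 0.01 * rnorm(40))
  resg <- cross_validate(fg, g, "knn", cv_repeats = 3, seed = 3)
  expect_identical(resg$metric_name, "rmse")
  expect_lt(resg$metric, 0.05)
  resrf <- cross_validate(f, y, "rf", rf_trees = 100, seed = 4)
  expect_equal(resrf$metric, 1.0)
})

test_that("label-permuted accuracy sits at chance level", {
  set.seed(5)
  f <- matrix(rnorm(50 * 4), 50, 4)
  y <- rep(paste0("C", 1:5), each = 10)
  accs <- vapply(1:15, function(s) {
    cross_validate(f, sample(y), "knn", cv_repeats = 2, seed = s)$metric
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.2), 0.12)
})

test_that("cross-validation is deterministic under its seed", {
  set.seed(6)
  f <- matrix(rnorm(30 * 3), 30, 3)
  y <- rep(c("A", "B", "C"), each = 10)
  a <- cross_validate(f, y, "knn", cv_repeats = 2, seed = 11)
  b <- cross_validate(f, y, "knn", cv_repeats = 2, seed = 11)
  expect_identical(a, b)
})

test_that("transfer on an identical 'ancient' copy reproduces in-domain accuracy", {
  ds <- toy_dataset(71, n = 24, p = 40, k = 3, de_factor = c(4, 8))
  anc <- ds  # degenerate transfer: ancient = exact copy, all level 0
  rec <- transfer_evaluate(ds, anc,
                           list(feature_space = "composition",
                                transform = "hellinger"),
                           algorithm = "knn", cv_repeats = 2, seed = 1)
  expect_equal(rec$transfer[rec$effect_level == "all"], 1.0)
  expect_identical(unique(rec$effect_level), c("all", "0"))
  # permuted-label ancient data drops transfer accuracy to chance
  perm <- ds
  set.seed(2)
  perm$metadata$cluster <- sample(perm$metadata$cluster)
  recp <- transfer_evaluate(ds, perm,
                            list(feature_space = "composition",
                                 transform = "hellinger"),
                            algorithm = "knn", cv_repeats = 2, seed = 1)
  expect_lt(recp$transfer[recp$effect_level == "all"], 0.7)
})

test_that("embedding-space transfer is stratified by effect level", {
  ds <- toy_dataset(72, n = 24, p = 50, k = 3, de_factor = c(4, 8))
  plan <- assign_effect_levels(ds, "cluster", seed = 3)
  anc <- degrade_counts(ds, plan)
  rec <- transfer_evaluate(ds, anc,
                           list(feature_space = "embedding",
                                transform = "prop", index = "bray",
                                ordination = "pcoa"),
                           algorithm = "knn", cv_repeats = 2, seed = 4)
  expect_setequal(rec$effect_level, c("all", "0", "0.25", "0.5", "0.75"))
  expect_true(all(rec$n[rec$effect_level != "all"] == 6L))
  expect_true(all(rec$transfer >= 0 & rec$transfer <= 1))
  r2 <- transfer_evaluate(ds, anc,
                          list(feature_space = "embedding",
                               transform = "prop", index = "bray",
                               ordination = "pcoa"),
                          algorithm = "knn", cv_repeats = 2, seed = 4)
  expect_identical(rec, r2)
})

test_that("gradient transfer reports RMSE per level", {
  ds <- toy_dataset(73, n = 24, p = 50, mode = "path", de_factor = c(4, 8))
  plan <- assign_effect_levels(ds, "gradient", seed = 5)
  anc <- degrade_counts(ds, plan)
  rec <- transfer_evaluate(ds, anc,
                           list(feature_space = "composition",
                                transform = "prop"),
                           algorithm = "rf", rf_trees = 150, seed = 6)
  expect_identical(rec$metric_name[1], "rmse")
  expect_true(all(rec$transfer >= 0))
  expect_setequal(rec$effect_level, c("all", "0", "0.25", "0.5", "0.75"))
})

test_that("Tukey aggregation produces sane compact letter displays", {
  # all approaches drawn from one distribution: a single shared letter
  set.seed(9)
  base <- expand.grid(ds = 1:6, combo_id = 1:3,
                      approach = c("composition_knn", "composition_rf",
                                   "embedding_knn", "embedding_rf"),
                      effect_level = c("0.25", "0.5"))
  fs_alg <- do.call(rbind, strsplit(as.character(base$approach), "_"))
  rec <- data.frame(
    feature_space = fs_alg[, 1], algorithm = fs_alg[, 2],
    transform = paste0("t", base$combo_id), index = "bray",
    ordination = "pcoa", effect_level = as.character(base$effect_level),
    transfer = rnorm(nrow(base), 0.8, 0.02), metric_name = "accuracy",
    stringsAsFactors = FALSE)
  out <- aggregate_transfer(rec, top_n = 2)
  expect_true(all(out$comparison$letters == out$comparison$letters[1]))
  # two clearly separated approaches get distinct letters
  rec2 <- rec
  rec2$transfer <- ifelse(rec2$feature_space == "embedding",
                          rnorm(nrow(rec2), 0.95, 0.01),
                          rnorm(nrow(rec2), 0.40, 0.01))
  out2 <- aggregate_transfer(rec2, top_n = 2)
  cmp <- out2$comparison[out2$comparison$effect_level == "0.5", ]
  emb <- cmp$letters[grepl("embedding", cmp$approach)]
  com <- cmp$letters[grepl("composition", cmp$approach)]
  expect_length(intersect(strsplit(paste(emb, collapse = ""), "")[[1]],
                          strsplit(paste(com, collapse = ""), "")[[1]]), 0)
  # top-n selection equals a manual median sort
  med <- tapply(rec2$transfer[rec2$feature_space == "embedding" &
                                rec2$algorithm == "knn"],
                rec2$transform[rec2$feature_space == "embedding" &
                                 rec2$algorithm == "knn"], median)
  manual <- names(sort(med, decreasing = TRUE))[1:2]
  got <- out2$top$combo[out2$top$approach == "embedding_knn"]
  expect_setequal(sub("\\+.*", "", got), manual)
  expect_error(aggregate_transfer(rec[rec$feature_space == "composition" &
                                        rec$algorithm == "knn", ]),
               "at least 2")
})
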