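# toy two-class Gaussian features
toy_features <- function(n_per_class, sep = 4, p = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = sep / sqrt(p)), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = as.data.frame(x),
       y = factor(rep(c("a", "b"), each = n_per_class)))
}

test_that("splits have the 70/15/15 sizes and are seed-stable", {
  toy <- toy_features(50)
  sp <- split_dataset(toy$x, split_spec(seed = 3), toy$y)
  expect_identical(length(sp$train), 70L)
  expect_identical(length(sp$val), 15L)
  expect_identical(length(sp$test), 15L)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), 1:100)
  sp2 <- split_dataset(toy$x, split_spec(seed = 3), toy$y)
  expect_identical(sp[c("train", "val", "test")], sp2[c("train", "val", "test")])
  sp3 <- split_dataset(toy$x, split_spec(seed = 4), toy$y)
  expect_false(identical(sp$train, sp3$train))
  # stratification keeps both classes everywhere
  expect_setequal(unique(toy$y[sp$test]), c("a", "b"))
})

test_that("standardisation uses train statistics and is exact there", {
  toy <- toy_features(50)
  sp <- split_dataset(toy$x, split_spec(seed = 1), toy$y)
  xs <- standardize_features(toy$x, sp$scaler)
  expect_equal(colMeans(xs[sp$train, ]), rep(0, 3) |> setNames(colnames(xs)),
               tolerance = 1e-9)
  expect_equal(apply(xs[sp$train, ], 2, sd),
               rep(1, 3) |> setNames(colnames(xs)), tolerance = 1e-9)
})

test_that("tabular models separate separable classes and not shuffled ones", {
  toy <- toy_features(60, sep = 8)
  for (kind in c("random_forest", "svm")) {
    m <- train_tabular(toy$x, toy$y, kind, seed = 2)
    expect_identical(m$report$accuracy, 1)
  }
  set.seed(5)
  m0 <- train_tabular(toy$x, sample(toy$y), "random_forest", seed = 2)
  band <- chance_band(m0$report$n)
  expect_gte(m0$report$accuracy, band[1])
  expect_lte(m0$report$accuracy, band[2])
  expect_error(train_tabular(toy$x, factor(rep("a", 120)), "random_forest"),
               "binary")
})

test_that("tabular training is bit-reproducible under fixed seeds", {
  toy <- toy_features(40, sep = 2)
  m1 <- train_tabular(toy$x, toy$y, "random_forest", seed = 7)
  m2 <- train_tabular(toy$x, toy$y, "random_forest", seed = 7)
  expect_identical(m1$report, m2$report)
  expect_identical(predict(m1, toy$x, type = "prob"),
                   predict(m2, toy$x, type = "prob"))
})

test_that("classifier reports follow the row-normalised convention", {
  truth <- factor(c(rep("a", 50), rep("b", 50)), levels = c("a", "b"))
  pred <- factor(c(rep("a", 45), rep("b", 5), rep("a", 10), rep("b", 40)),
                 levels = c("a", "b"))
  rep <- classifier_report(truth, pred)
  expect_equal(unname(rowSums(rep$confusion)), c(1, 1), tolerance = 1e-9)
  expect_equal(rep$accuracy, (0.90 + 0.80) / 2)
  expect_equal(unname(rep$tpr["b"]), 0.80)
  expect_equal(unname(rep$fpr["b"]), 0.10)
  # perfect and constant predictors
  perf <- classifier_report(truth, truth)
  expect_identical(unname(perf$confusion), diag(2))
  expect_identical(perf$accuracy, 1)
  const <- classifier_report(truth, factor(rep("a", 100), levels = c("a", "b")))
  expect_equal(const$accuracy, 0.5)
  expect_error(classifier_report(factor(character()), factor(character())),
               "empty")
  # tidy/glance accessors
  td <- tidy(rep)
  expect_identical(nrow(td), 4L)
  expect_equal(sum(td$count), 100)
  expect_equal(glance(rep)$accuracy, 0.85)
})

# minimal deterministic classifier used by the cross-validation test
train_deterministic_centroid <- function(x, y) {
  mu <- lapply(split(as.data.frame(x), y), colMeans)
  structure(list(mu = mu, classes = levels(y)), class = "centroid_clf")
}

predict.centroid_clf <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  d <- sapply(object$mu, function(m) rowSums(sweep(x, 2, m)^2))
  factor(object$classes[apply(d, 1, which.min)], levels = object$classes)
}
registerS3method("predict", "centroid_clf", predict.centroid_clf)

test_that("cross-validation is stratified with exact fold sizes", {
  toy <- toy_features(50, sep = 8)
  builder <- function(x, y) train_deterministic_centroid(x, y)
  cv <- cross_validate(builder, toy$x, toy$y, k = 5, seed = 2)
  expect_identical(length(cv$fold_accuracy), 5L)
  expect_true(all(vapply(cv$reports, `[[`, numeric(1), "n") == 20))
  expect_equal(cv$mean, mean(cv$fold_accuracy), tolerance = 1e-12)
  # a deterministic, well-separated problem gives identical folds: SEM 0
  expect_identical(cv$sem, 0)
})
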