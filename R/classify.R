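# Classification protocol shared by all model families: shuffled stratified
# 70/15/15 split, train-only standardisation, validation-based
# hyperparameter selection, held-out test report, stratified k-fold
# cross-validation.

#' Train/validation/test split specification
#'
#' @param ratios Partition fractions (train, validation, test); must sum
#'   to 1.
#' @param seed Shuffle seed.
#' @param stratified Preserve class proportions in every partition.
#' @return A `dc_split_spec`.
#' @export
split_spec <- function(ratios = c(0.70, 0.15, 0.15), seed = 1,
                       stratified = TRUE) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-8) stop("split ratios must sum to 1", call. = FALSE)
  structure(list(ratios = ratios, seed = as.integer(seed),
                 stratified = stratified),
            class = "dc_split_spec")
}

#' Split samples into train/validation/test partitions
#'
#' Shuffled, seeded and (by default) stratified by label. When `features`
#' is supplied, per-feature standardisation statistics (mean, SD) are
#' computed on the training partition only.
#'
#' @param n_or_features Number of samples, or a numeric feature
#'   data.frame/matrix.
#' @param spec A [split_spec()].
#' @param labels Optional label vector (required for stratification).
#' @return List: `train`, `val`, `test` (index vectors), `scaler` (NULL
#'   without features).
#' @export
split_dataset <- function(n_or_features, spec = split_spec(), labels = NULL) {
  features <- NULL
  if (is.numeric(n_or_features) && length(n_or_features) == 1) {
    n <- as.integer(n_or_features)
  } else {
    features <- n_or_features
    n <- nrow(features)
  }
  if (n < 20) stop("need at least 20 samples to split", call. = FALSE)
  set.seed(spec$seed)
  # largest-remainder apportionment of `total` slots over class sizes m
  apportion <- function(m, frac, total, cap = m) {
    raw <- pmin(frac * m, cap)
    base <- floor(raw)
    left <- total - sum(base)
    if (left > 0) {
      ord <- order(raw - base, decreasing = TRUE)
      ord <- ord[(cap - base)[ord] > 0][seq_len(min(left, length(ord)))]
      base[ord] <- base[ord] + 1
    }
    base
  }
  if (spec$stratified && !is.null(labels)) {
    stopifnot(length(labels) == n)
    groups <- split(seq_len(n), labels)
    m <- lengths(groups)
    t_c <- apportion(m, spec$ratios[1], round(spec$ratios[1] * n))
    v_c <- apportion(m, spec$ratios[2], round(spec$ratios[2] * n),
                     cap = m - t_c)
    out <- list(train = integer(), val = integer(), test = integer())
    for (g in seq_along(groups)) {
      idx <- groups[[g]][sample.int(m[g])]
      out$train <- c(out$train, idx[seq_len(t_c[g])])
      out$val <- c(out$val, idx[t_c[g] + seq_len(v_c[g])])
      out$test <- c(out$test, idx[(t_c[g] + v_c[g] + 1):m[g]])
    }
    out <- lapply(out, sort)
  } else {
    idx <- sample.int(n)
    n_train <- round(spec$ratios[1] * n)
    n_val <- min(round(spec$ratios[2] * n), n - n_train - 1)
    out <- list(train = idx[seq_len(n_train)],
                val = idx[n_train + seq_len(n_val)],
                test = idx[(n_train + n_val + 1):n])
  }
  if (!is.null(labels)) {
    classes <- unique(labels)
    for (p in c("train", "val", "test")) {
      if (!all(classes %in% labels[out[[p]]])) {
        stop("a class is absent from the ", p, " partition", call. = FALSE)
      }
    }
  }
  out$scaler <- if (!is.null(features)) {
    xm <- as.matrix(features)[out$train, , drop = FALSE]
    list(mean = colMeans(xm), sd = apply(xm, 2, stats::sd))
  }
  out
}

#' Standardise features with train-partition statistics
#'
#' @param features Numeric data.frame or matrix.
#' @param scaler List with `mean` and `sd` (from [split_dataset()]).
#' @return Matrix of standardised features (constant features pass
#'   through unscaled).
#' @export
standardize_features <- function(features, scaler) {
  x <- as.matrix(features)
  sdv <- ifelse(scaler$sd > 0, scaler$sd, 1)
  scale(x, center = scaler$mean, scale = sdv)[, , drop = FALSE]
}

# ---- classifier report ----------------------------------------------------

#' Classification report from truth and predictions
#'
#' Confusion matrix normalised by true-label counts (rows sum to 1),
#' accuracy as the mean of the normalised diagonal, and per-class TPR/FPR
#' (class taken as positive in turn).
#'
#' @param truth Factor (or vector) of true labels.
#' @param pred Predicted labels in the same level set.
#' @return A `dc_report`.
#' @export
classifier_report <- function(truth, pred) {
  if (length(truth) == 0) stop("empty test set", call. = FALSE)
  lev <- if (is.factor(truth)) levels(truth) else sort(unique(as.character(truth)))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  counts <- table(truth = truth, pred = pred)
  norm <- sweep(counts, 1, pmax(rowSums(counts), 1), "/")
  tpr <- diag(norm)
  fpr <- vapply(seq_along(lev), function(i) {
    neg <- truth != lev[i]
    if (!any(neg)) return(NA_real_)
    mean(pred[neg] == lev[i])
  }, numeric(1))
  names(fpr) <- lev
  structure(
    list(confusion = unclass(norm), counts = unclass(counts),
         accuracy = mean(diag(norm)), tpr = tpr, fpr = fpr,
         classes = lev, n = length(truth)),
    class = "dc_report"
  )
}

#' @export
print.dc_report <- function(x, ...) {
  cat(sprintf("<dc_report> accuracy %.3f on %d samples\n", x$accuracy, x$n))
  print(round(x$confusion, 3))
  invisible(x)
}

#' @describeIn classifier_report Long-format confusion matrix
#'   (`truth`, `pred`, `fraction`, `count`).
#' @param x A `dc_report`.
#' @param ... Unused.
#' @export
tidy.dc_report <- function(x, ...) {
  conf <- as.data.frame(as.table(x$confusion))
  names(conf) <- c("truth", "pred", "fraction")
  conf$count <- as.vector(x$counts)
  tibble::as_tibble(conf)
}

#' @describeIn classifier_report One-row summary (accuracy, per-class
#'   TPR/FPR, n).
#' @export
glance.dc_report <- function(x, ...) {
  out <- tibble::tibble(accuracy = x$accuracy, n = x$n)
  for (cl in x$classes) {
    out[[paste0("tpr_", cl)]] <- unname(x$tpr[cl])
    out[[paste0("fpr_", cl)]] <- unname(x$fpr[cl])
  }
  out
}

#' @describeIn classifier_report Confusion-matrix heatmap.
#' @param object A `dc_report`.
#' @export
autoplot.dc_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$truth,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$fraction))) +
    ggplot2::scale_y_discrete(limits = rev(object$classes)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("accuracy %.1f%%", 100 * object$accuracy))
}

# ---- tabular models -------------------------------------------------------

#' Train a tabular phenotype classifier (random forest or SVM)
#'
#' Standardises features with train-partition statistics, selects
#' hyperparameters on the validation partition, and reports accuracy,
#' confusion matrix and TPR/FPR on the held-out test partition.
#'
#' @param features Numeric feature data.frame/matrix (rows = cells).
#' @param labels Two-level factor (or coercible) of phenotypes.
#' @param model_kind "random_forest" or "svm".
#' @param hyper Optional named list overriding the search grid:
#'   random forest `mtry`, `nodesize`, `ntree`; SVM `cost`, `gamma`.
#' @param spec A [split_spec()].
#' @param seed Seed for model fitting.
#' @return A `dc_tabular_model`: fitted model, scaler, split indices,
#'   chosen hyperparameters, validation table and test `report`.
#' @export
train_tabular <- function(features, labels,
                          model_kind = c("random_forest", "svm"),
                          hyper = list(), spec = split_spec(), seed = 1) {
  model_kind <- match.arg(model_kind)
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) {
    stop("train_tabular expects a binary labelling", call. = FALSE)
  }
  keep <- stats::complete.cases(features)
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  sp <- split_dataset(features, spec, labels)
  x <- standardize_features(features, sp$scaler)
  p <- ncol(x)
  grid <- if (model_kind == "random_forest") {
    expand.grid(
      mtry = hyper$mtry %||% unique(pmin(p, c(1, 2, max(1, floor(sqrt(p)))))),
      nodesize = hyper$nodesize %||% c(1, 5),
      ntree = hyper$ntree %||% 300
    )
  } else {
    expand.grid(
      cost = hyper$cost %||% c(0.5, 2, 8),
      gamma = (hyper$gamma %||% c(0.5, 1, 2)) / p
    )
  }
  fit_one <- function(row) {
    set.seed(seed)
    if (model_kind == "random_forest") {
      randomForest::randomForest(
        x = x[sp$train, , drop = FALSE], y = labels[sp$train],
        mtry = row$mtry, nodesize = row$nodesize, ntree = row$ntree
      )
    } else {
      e1071::svm(x = x[sp$train, , drop = FALSE], y = labels[sp$train],
                 cost = row$cost, gamma = row$gamma, kernel = "radial",
                 probability = TRUE)
    }
  }
  val_acc <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fits[[g]] <- fit_one(grid[g, , drop = FALSE])
    pred <- predict(fits[[g]], x[sp$val, , drop = FALSE])
    val_acc[g] <- mean(pred == labels[sp$val])
  }
  best <- which.max(val_acc)
  fit <- fits[[best]]
  report <- classifier_report(labels[sp$test],
                              predict(fit, x[sp$test, , drop = FALSE]))
  structure(
    list(fit = fit, kind = model_kind, scaler = sp$scaler, split = sp,
         hyper = as.list(grid[best, , drop = FALSE]),
         validation = dplyr::bind_cols(tibble::as_tibble(grid),
                                       tibble::tibble(val_accuracy = val_acc)),
         report = report, feature_names = colnames(x),
         classes = levels(labels), seed = seed),
    class = "dc_tabular_model"
  )
}

#' @export
print.dc_tabular_model <- function(x, ...) {
  cat(sprintf("<dc_tabular_model> %s on %d features; test accuracy %.3f\n",
              x$kind, length(x$feature_names), x$report$accuracy))
  invisible(x)
}

#' Predict phenotypes (or class probabilities) from a tabular model
#'
#' @param object A `dc_tabular_model`.
#' @param newdata Raw-scale feature data.frame/matrix.
#' @param type "class" or "prob" (probability of the second class level).
#' @param ... Unused.
#' @export
predict.dc_tabular_model <- function(object, newdata, type = c("class", "prob"),
                                     ...) {
  type <- match.arg(type)
  x <- standardize_features(as.data.frame(newdata)[, object$feature_names,
                                                   drop = FALSE],
                            object$scaler)
  if (type == "class") return(predict(object$fit, x))
  pos <- object$classes[2]
  if (object$kind == "random_forest") {
    unname(predict(object$fit, x, type = "prob")[, pos])
  } else {
    pr <- predict(object$fit, x, probability = TRUE)
    unname(attr(pr, "probabilities")[, pos])
  }
}

#' @describeIn train_tabular Broom-style one-row model summary.
#' @param x A `dc_tabular_model`.
#' @param ... Unused.
#' @export
glance.dc_tabular_model <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(kind = x$kind), glance(x$report))
}

# ---- evaluation and cross-validation --------------------------------------

#' Evaluate a fitted model on a labelled sample set
#'
#' @param model A fitted mechanodc model (tabular or sequence).
#' @param samples Feature table, `dc_sequences`, or `dc_mask_sequences`
#'   matching the model family.
#' @param labels True labels.
#' @param ... Passed to methods.
#' @return A `dc_report` (see [classifier_report()]).
#' @export
evaluate <- function(model, samples, labels, ...) UseMethod("evaluate")

#' @export
evaluate.dc_tabular_model <- function(model, samples, labels, ...) {
  classifier_report(factor(labels, levels = model$classes),
                    predict(model, samples))
}

#' Subset a sample container by index
#'
#' Used by [cross_validate()] to slice feature tables and sequence sets
#' with one interface.
#'
#' @param samples Sample container.
#' @param idx Integer indices.
#' @return Container of the same type restricted to `idx`.
#' @export
subset_samples <- function(samples, idx) UseMethod("subset_samples")

#' @export
subset_samples.data.frame <- function(samples, idx) samples[idx, , drop = FALSE]

#' @export
subset_samples.matrix <- function(samples, idx) samples[idx, , drop = FALSE]

#' @export
subset_samples.dc_sequences <- function(samples, idx) {
  out <- samples
  out$x <- samples$x[idx, , , drop = FALSE]
  out$mask <- samples$mask[idx, , drop = FALSE]
  out$lengths <- samples$lengths[idx]
  out$ids <- samples$ids[idx]
  out$phenotype <- samples$phenotype[idx]
  out
}

#' @export
subset_samples.dc_mask_sequences <- function(samples, idx) {
  out <- samples
  out$pooled <- samples$pooled[idx]
  out$mask <- samples$mask[idx, , drop = FALSE]
  out$lengths <- samples$lengths[idx]
  out$ids <- samples$ids[idx]
  out$phenotype <- samples$phenotype[idx]
  out$trajectories <- samples$trajectories[idx]
  out
}

#' Stratified k-fold cross-validation
#'
#' Each fold's model is trained from scratch by `model_builder` on the
#' remaining folds and scored on the held-out fold.
#'
#' @param model_builder `function(samples, labels)` returning a fitted
#'   model with a `predict(model, samples)` method yielding class labels.
#' @param samples Sample container (see [subset_samples()]).
#' @param labels Label vector.
#' @param k Number of folds (>= 2).
#' @param seed Fold-assignment seed.
#' @return List: `fold_accuracy` (length k), `mean`, `sem`, `reports`.
#' @export
cross_validate <- function(model_builder, samples, labels, k = 5, seed = 1) {
  stopifnot(k >= 2)
  labels <- as.factor(labels)
  n <- length(labels)
  set.seed(seed)
  fold <- integer(n)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("class '", cl, "' has fewer samples than folds",
                              call. = FALSE)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  reports <- vector("list", k)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    model <- model_builder(subset_samples(samples, tr), labels[tr])
    pred <- predict(model, subset_samples(samples, te))
    reports[[f]] <- classifier_report(labels[te], pred)
    acc[f] <- reports[[f]]$accuracy
  }
  list(fold_accuracy = acc, mean = mean(acc),
       sem = stats::sd(acc) / sqrt(k), reports = reports)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
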