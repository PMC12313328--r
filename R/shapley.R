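# Shapley-value feature attribution for tabular phenotype classifiers.
# Interventional (marginal) value function: v(S) is the mean model output
# with the features in S taken from the explained sample and the rest from
# background rows. Exact subset enumeration up to `exact_limit` features;
# permutation sampling above. Both satisfy the efficiency identity
# sum(phi) = f(x) - E[f(background)] exactly.

shapley_exact <- function(f, x_row, background, p) {
  nb <- nrow(background)
  n_sub <- 2^p
  subsets <- matrix(FALSE, n_sub, p)
  for (j in seq_len(p)) {
    subsets[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0
  }
  # one prediction batch: every subset stacked over every background row
  synth <- background[rep(seq_len(nb), times = n_sub), , drop = FALSE]
  sel <- subsets[rep(seq_len(n_sub), each = nb), , drop = FALSE]
  xrep <- matrix(x_row, nrow(synth), p, byrow = TRUE)
  synth[sel] <- xrep[sel]
  v <- as.numeric(rowsum(f(synth), rep(seq_len(n_sub), each = nb))) / nb
  sizes <- rowSums(subsets)
  # w(s) = s! (p - s - 1)! / p!
  lw <- lfactorial(sizes) + lfactorial(p - sizes - 1) - lfactorial(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- !subsets[, j]
    idx_without <- which(without)
    idx_with <- idx_without + 2^(j - 1)
    w <- exp(lw[idx_without])
    phi[j] <- sum(w * (v[idx_with] - v[idx_without]))
  }
  list(phi = phi, base = v[1])
}

shapley_sampled <- function(f, x_row, background, p, n_perm, seed_offset) {
  nb <- nrow(background)
  phi <- numeric(p)
  base <- mean(f(background))
  for (s in seq_len(n_perm)) {
    perm <- sample.int(p)
    cur <- background
    v_prev <- base
    for (j in perm) {
      cur[, j] <- x_row[j]
      v_cur <- mean(f(cur))
      phi[j] <- phi[j] + (v_cur - v_prev)
      v_prev <- v_cur
    }
  }
  list(phi = phi / n_perm, base = base)
}

#' Shapley-value feature attributions for a tabular model
#'
#' Attributes the model's predicted probability of the positive class to
#' individual features, per explained sample, with interventional Shapley
#' values against a background sample. The report orders features by mean
#' absolute attribution (global importance).
#'
#' @param model A `dc_tabular_model` from [train_tabular()].
#' @param background Raw-scale feature rows representing the data
#'   distribution (typically training rows).
#' @param samples Raw-scale feature rows to explain.
#' @param exact_limit Enumerate subsets exactly up to this many features
#'   (default 12); above it, permutation sampling with `n_perm`
#'   permutations per sample.
#' @param n_perm Permutations per sample in sampling mode.
#' @param seed Seed for permutation sampling.
#' @return A `dc_importance`: `importance` tibble (feature, mean_abs_phi,
#'   descending), `phi` matrix (samples x features), `base_value`,
#'   `prediction` (per explained sample), `method`.
#' @export
feature_importance <- function(model, background, samples,
                               exact_limit = 12, n_perm = 64, seed = 1) {
  stopifnot(inherits(model, "dc_tabular_model"))
  if (is.null(model$fit)) stop("model is not fitted", call. = FALSE)
  bg <- as.matrix(as.data.frame(background)[, model$feature_names, drop = FALSE])
  xs <- as.matrix(as.data.frame(samples)[, model$feature_names, drop = FALSE])
  p <- ncol(bg)
  f <- function(m) {
    colnames(m) <- model$feature_names
    predict(model, m, type = "prob")
  }
  exact <- p <= exact_limit
  set.seed(seed)
  res <- lapply(seq_len(nrow(xs)), function(i) {
    if (exact) shapley_exact(f, xs[i, ], bg, p)
    else shapley_sampled(f, xs[i, ], bg, p, n_perm, i)
  })
  phi <- do.call(rbind, lapply(res, `[[`, "phi"))
  colnames(phi) <- model$feature_names
  imp <- tibble::tibble(
    feature = model$feature_names,
    mean_abs_phi = colMeans(abs(phi))
  )
  imp <- dplyr::arrange(imp, dplyr::desc(.data$mean_abs_phi))
  structure(
    list(importance = imp, phi = phi, base_value = res[[1]]$base,
         prediction = f(xs), method = if (exact) "exact" else "sampled"),
    class = "dc_importance"
  )
}

#' @export
print.dc_importance <- function(x, ...) {
  cat(sprintf("<dc_importance> (%s Shapley values, base value %.3f)\n",
              x$method, x$base_value))
  print(x$importance, n = 10)
  invisible(x)
}

#' @describeIn feature_importance Importance table (feature,
#'   mean_abs_phi).
#' @param x A `dc_importance`.
#' @param ... Unused.
#' @export
tidy.dc_importance <- function(x, ...) x$importance

#' @describeIn feature_importance Bar plot of mean absolute attributions.
#' @param object A `dc_importance`.
#' @export
autoplot.dc_importance <- function(object, ...) {
  df <- object$importance
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_abs_phi, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |Shapley value| (impact on P(class 2))",
                  y = NULL)
}
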