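# A compact gated recurrent unit (GRU) classifier, written directly in
# vectorised R: masked forward pass, backpropagation through time, Adam
# optimisation, validation-based epoch selection. Sized for the short
# (<= 50 step) padded shape sequences this package produces; all arithmetic
# is dense double-precision matrix algebra, deterministic under a seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

gru_layer_init <- function(input_dim, units) {
  list(
    Wz = glorot(input_dim, units), Uz = glorot(units, units),
    bz = rep(0, units),
    Wr = glorot(input_dim, units), Ur = glorot(units, units),
    br = rep(0, units),
    Wn = glorot(input_dim, units), Un = glorot(units, units),
    bn = rep(0, units)
  )
}

gru_params_init <- function(input_dim, units, layers, seed) {
  set.seed(seed)
  lay <- vector("list", layers)
  dim_in <- input_dim
  for (l in seq_len(layers)) {
    lay[[l]] <- gru_layer_init(dim_in, units)
    dim_in <- units
  }
  list(layers = lay, w_out = glorot(units, 1), b_out = 0)
}

# forward one GRU layer over a (B, T, C) array with (B, T) validity mask.
# Returns hidden-state sequence (B, T, H) and caches for backprop.
gru_layer_forward <- function(par, x, mask) {
  B <- dim(x)[1]; T <- dim(x)[2]
  H <- ncol(par$Wz)
  h <- matrix(0, B, H)
  hs <- array(0, c(B, T, H))
  cache <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- matrix(x[, t, ], B)
    hp <- h
    z <- sigmoid(xt %*% par$Wz + hp %*% par$Uz +
                   matrix(par$bz, B, H, byrow = TRUE))
    r <- sigmoid(xt %*% par$Wr + hp %*% par$Ur +
                   matrix(par$br, B, H, byrow = TRUE))
    n <- tanh(xt %*% par$Wn + (r * hp) %*% par$Un +
                matrix(par$bn, B, H, byrow = TRUE))
    hn <- z * hp + (1 - z) * n
    m <- mask[, t]
    h <- hn * m + hp * (1 - m)
    hs[, t, ] <- h
    cache[[t]] <- list(xt = xt, hp = hp, z = z, r = r, n = n)
  }
  list(hs = hs, h_final = h, cache = cache)
}

# backprop one GRU layer. dh_seq: (B, T, H) gradients wrt the layer's
# masked outputs; returns parameter gradients and dx (B, T, C).
gru_layer_backward <- function(par, fwd, mask, dh_seq) {
  Tn <- dim(dh_seq)[2]; B <- dim(dh_seq)[1]
  H <- ncol(par$Wz); C <- nrow(par$Wz)
  g <- lapply(par, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else rep(0, length(p)))
  dx <- array(0, c(B, Tn, C))
  dh_next <- matrix(0, B, H)   # gradient flowing into h_t from t+1
  for (t in rev(seq_len(Tn))) {
    ca <- fwd$cache[[t]]
    dh <- matrix(dh_seq[, t, ], B) + dh_next
    m <- mask[, t]
    dh_new <- dh * m              # through the update branch
    dh_prev <- dh * (1 - m)       # padded steps pass h through unchanged
    z <- ca$z; r <- ca$r; n <- ca$n; hp <- ca$hp
    dz_pre <- dh_new * (hp - n) * z * (1 - z)
    dn_pre <- dh_new * (1 - z) * (1 - n^2)
    dh_prev <- dh_prev + dh_new * z
    drhp <- dn_pre %*% t(par$Un)
    dr_pre <- drhp * hp * r * (1 - r)
    dh_prev <- dh_prev + drhp * r +
      dz_pre %*% t(par$Uz) + dr_pre %*% t(par$Ur)
    g$Wz <- g$Wz + crossprod(ca$xt, dz_pre)
    g$Wr <- g$Wr + crossprod(ca$xt, dr_pre)
    g$Wn <- g$Wn + crossprod(ca$xt, dn_pre)
    g$Uz <- g$Uz + crossprod(hp, dz_pre)
    g$Ur <- g$Ur + crossprod(hp, dr_pre)
    g$Un <- g$Un + crossprod(r * hp, dn_pre)
    g$bz <- g$bz + colSums(dz_pre)
    g$br <- g$br + colSums(dr_pre)
    g$bn <- g$bn + colSums(dn_pre)
    dx[, t, ] <- (dz_pre %*% t(par$Wz) + dr_pre %*% t(par$Wr) +
                    dn_pre %*% t(par$Wn))
    dh_next <- dh_prev
  }
  list(grads = g, dx = dx)
}

gru_forward <- function(params, x, mask, drop_mask = NULL) {
  layer_fwd <- vector("list", length(params$layers))
  inp <- x
  for (l in seq_along(params$layers)) {
    layer_fwd[[l]] <- gru_layer_forward(params$layers[[l]], inp, mask)
    inp <- layer_fwd[[l]]$hs
  }
  hs <- layer_fwd[[length(layer_fwd)]]$hs
  # masked mean-over-time readout: every valid step contributes, which
  # keeps gradients alive over the whole (short) sequence
  B <- dim(hs)[1]; H <- dim(hs)[3]
  len <- pmax(rowSums(mask), 1)
  h_read <- matrix(0, B, H)
  for (t in seq_len(dim(hs)[2])) {
    h_read <- h_read + matrix(hs[, t, ], B) * mask[, t]
  }
  h_read <- h_read / len
  if (!is.null(drop_mask)) h_read <- h_read * drop_mask  # inverted dropout
  logits <- as.numeric(h_read %*% params$w_out) + params$b_out
  list(layer_fwd = layer_fwd, h_read = h_read, len = len, logits = logits,
       drop_mask = drop_mask)
}

gru_backward <- function(params, fwd, x, mask, dlogits) {
  B <- length(dlogits)
  L <- length(params$layers)
  H <- length(params$w_out)
  g_out <- list(w_out = crossprod(fwd$h_read, dlogits),
                b_out = sum(dlogits))
  dh_read <- outer(dlogits, as.numeric(params$w_out))  # B x H
  if (!is.null(fwd$drop_mask)) dh_read <- dh_read * fwd$drop_mask
  Tn <- dim(x)[2]
  dh_seq <- array(0, c(B, Tn, H))
  for (t in seq_len(Tn)) {
    dh_seq[, t, ] <- dh_read * (mask[, t] / fwd$len)
  }
  layer_grads <- vector("list", L)
  dcur <- dh_seq
  for (l in rev(seq_len(L))) {
    bk <- gru_layer_backward(params$layers[[l]], fwd$layer_fwd[[l]], mask, dcur)
    layer_grads[[l]] <- bk$grads
    dcur <- bk$dx
  }
  list(layers = layer_grads, w_out = g_out$w_out, b_out = g_out$b_out,
       dx = dcur)
}

# flatten/unflatten parameter trees for the Adam updater
flatten_params <- function(p) unlist(p, use.names = FALSE)

relist_params <- function(vec, skeleton) {
  out <- utils::relist(vec, skeleton)
  # relist drops matrix dims; restore them
  restore <- function(tmpl, val) {
    if (is.list(tmpl)) {
      for (nm in seq_along(tmpl)) val[[nm]] <- restore(tmpl[[nm]], val[[nm]])
      val
    } else if (is.matrix(tmpl)) {
      matrix(unlist(val), nrow(tmpl), ncol(tmpl))
    } else {
      unlist(val)
    }
  }
  restore(skeleton, out)
}

adam_init <- function(n) list(m = rep(0, n), v = rep(0, n), t = 0)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = state)
}

bce_loss_grad <- function(logits, y) {
  p <- sigmoid(logits)
  list(loss = -mean(y * log(pmax(p, 1e-12)) +
                      (1 - y) * log(pmax(1 - p, 1e-12))),
       dlogits = (p - y) / length(y))
}

clip_grad <- function(g, max_norm = 5) {
  nrm <- sqrt(sum(g^2))
  if (nrm > max_norm) g * (max_norm / nrm) else g
}

# standardise sequence channels using statistics over valid steps of the
# given (train) indices
sequence_scaler <- function(x, mask, idx) {
  C <- dim(x)[3]
  mu <- sdv <- numeric(C)
  for (c in seq_len(C)) {
    vals <- x[idx, , c][mask[idx, ]]
    mu[c] <- mean(vals)
    sdv[c] <- max(stats::sd(vals), 1e-12)
  }
  list(mean = mu, sd = sdv)
}

scale_sequences <- function(x, mask, scaler) {
  out <- x
  for (c in seq_len(dim(x)[3])) {
    out[, , c] <- (x[, , c] - scaler$mean[c]) / scaler$sd[c]
  }
  # keep padded steps at zero
  out <- out * array(mask, dim(x))
  out
}

#' Train a GRU classifier on padded shape sequences
#'
#' A gated-recurrent-unit network consumes the four-channel per-frame shape
#' sequences (AR, perimeter, rD, area), respecting the validity mask so
#' padding never contributes; a sigmoid head classifies the final hidden
#' state. Channels are standardised with train-partition statistics. The
#' epoch with the best validation accuracy is kept and the held-out test
#' partition is reported.
#'
#' @param sequences A `dc_sequences` from [prepare_sequences()], or a list
#'   with `x` (n, T, C array) and `mask` (n, T logical).
#' @param labels Two-level factor (or coercible), one per sequence.
#' @param units Hidden units per GRU layer.
#' @param layers Number of stacked GRU layers (1 or 2).
#' @param dropout Dropout rate on the sequence readout during training
#'   (inverted dropout; 0 disables).
#' @param epochs Training epochs (the full protocol uses 175; smaller
#'   budgets already saturate on the bundled synthetic fixtures).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param spec A [split_spec()].
#' @param seed Initialisation/shuffle seed.
#' @param verbose Print per-epoch validation accuracy.
#' @return A `dc_seq_model` with the fitted parameters, scaler, history
#'   and test `report`.
#' @export
train_gru <- function(sequences, labels, units = 16, layers = 1,
                      dropout = 0, epochs = 175, batch_size = 32, lr = 0.01,
                      spec = split_spec(), seed = 1, verbose = FALSE) {
  x <- sequences$x; msk <- sequences$mask * 1
  stopifnot(length(dim(x)) == 3, nrow(msk) == dim(x)[1])
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2, length(labels) == dim(x)[1])
  y <- as.numeric(labels == levels(labels)[2])
  sp <- split_dataset(dim(x)[1], spec, labels)
  scaler <- sequence_scaler(x, sequences$mask, sp$train)
  xs <- scale_sequences(x, msk, scaler)
  params <- gru_params_init(dim(x)[3], units, layers, seed)
  skeleton <- params
  theta <- flatten_params(params)
  opt <- adam_init(length(theta))
  best <- list(acc = -1, theta = theta, epoch = 0)
  history <- numeric(epochs)
  predict_idx <- function(theta, idx) {
    par <- relist_params(theta, skeleton)
    fw <- gru_forward(par, xs[idx, , , drop = FALSE],
                      msk[idx, , drop = FALSE])
    sigmoid(fw$logits)
  }
  set.seed(seed + 1)
  for (ep in seq_len(epochs)) {
    ord <- sample(sp$train)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (b in batches) {
      par <- relist_params(theta, skeleton)
      drop_mask <- if (dropout > 0) {
        matrix(stats::rbinom(length(b) * units, 1, 1 - dropout),
               length(b)) / (1 - dropout)
      }
      fw <- gru_forward(par, xs[b, , , drop = FALSE], msk[b, , drop = FALSE],
                        drop_mask = drop_mask)
      lg <- bce_loss_grad(fw$logits, y[b])
      bk <- gru_backward(par, fw, xs[b, , , drop = FALSE],
                         msk[b, , drop = FALSE], lg$dlogits)
      grad <- clip_grad(flatten_params(bk[c("layers", "w_out", "b_out")]))
      st <- adam_step(opt, theta, grad, lr)
      theta <- st$theta; opt <- st$state
    }
    val_acc <- mean((predict_idx(theta, sp$val) > 0.5) == y[sp$val])
    history[ep] <- val_acc
    if (val_acc > best$acc) best <- list(acc = val_acc, theta = theta, epoch = ep)
    if (verbose) message(sprintf("epoch %3d val accuracy %.3f", ep, val_acc))
  }
  params <- relist_params(best$theta, skeleton)
  model <- structure(
    list(kind = "gru", params = params, scaler = scaler, units = units,
         layers = layers, classes = levels(labels), split = sp,
         history = history, best_epoch = best$epoch, seed = seed),
    class = "dc_seq_model"
  )
  prob <- predict(model, subset_sequences_raw(x, msk, sp$test), type = "prob")
  pred <- model$classes[(prob > 0.5) + 1]
  model$report <- classifier_report(labels[sp$test], pred)
  model
}

subset_sequences_raw <- function(x, msk, idx) {
  list(x = x[idx, , , drop = FALSE], mask = msk[idx, , drop = FALSE])
}

#' Predict from a fitted sequence model
#'
#' @param object A `dc_seq_model`.
#' @param newdata A `dc_sequences` / `dc_mask_sequences` (matching the
#'   model kind) or list with `x` and `mask`.
#' @param type "class" or "prob" (probability of the second class level).
#' @param ... Unused.
#' @export
predict.dc_seq_model <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  prob <- if (object$kind == "gru") {
    xs <- scale_sequences(newdata$x, newdata$mask * 1, object$scaler)
    fw <- gru_forward(object$params, xs, newdata$mask * 1)
    sigmoid(fw$logits)
  } else {
    cnn_gru_prob(object, newdata)
  }
  if (type == "prob") prob else factor(object$classes[(prob > 0.5) + 1],
                                       levels = object$classes)
}

#' @export
print.dc_seq_model <- function(x, ...) {
  cat(sprintf("<dc_seq_model> %s (%d units x %d layer(s)); test accuracy %.3f (best epoch %d)\n",
              x$kind, x$units, x$layers,
              if (!is.null(x$report)) x$report$accuracy else NA,
              x$best_epoch))
  invisible(x)
}

#' @export
evaluate.dc_seq_model <- function(model, samples, labels, ...) {
  classifier_report(factor(labels, levels = model$classes),
                    predict(model, samples))
}

#' @describeIn train_gru Broom-style one-row summary of a sequence model.
#' @param x A `dc_seq_model`.
#' @param ... Unused.
#' @export
glance.dc_seq_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(kind = x$kind, units = x$units, layers = x$layers,
                   best_epoch = x$best_epoch),
    glance(x$report)
  )
}
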