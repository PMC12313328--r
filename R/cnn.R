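# Convolutional encoder shared across timesteps, feeding the GRU
# (CNN-GRU), plus a single-frame CNN head used as the undeformed-shape
# control. The encoder runs on average-pooled two-channel mask frames
# (see prepare_mask_sequences): conv (kernel k, stride s, F filters) ->
# ReLU -> 2x2 max pool -> dense -> ReLU. Written as im2col matrix algebra;
# identical weights are applied at every timestep.

conv_geometry <- function(side, kernel, stride, channels = 2) {
  osz <- floor((side - kernel) / stride) + 1
  # patch-major column index table: rows = kernel elements, cols = patches
  idx <- matrix(0L, kernel * kernel * channels, osz * osz)
  p <- 0L
  for (j in seq_len(osz)) {        # output col
    for (i in seq_len(osz)) {      # output row (row-fastest patch order)
      p <- p + 1L
      r0 <- (i - 1L) * stride; c0 <- (j - 1L) * stride
      e <- 0L
      for (ch in seq_len(channels)) {
        off <- (ch - 1L) * side * side
        for (cc in seq_len(kernel)) {
          for (rr in seq_len(kernel)) {
            e <- e + 1L
            idx[e, p] <- off + (c0 + cc - 1L) * side + r0 + rr
          }
        }
      }
    }
  }
  # 2x2 max-pool groups over the osz x osz patch grid
  psz <- osz %/% 2
  pool_groups <- array(0L, c(psz * psz, 4))
  q <- 0L
  for (j in seq_len(psz)) {
    for (i in seq_len(psz)) {
      q <- q + 1L
      base <- (2L * i - 1L) + ((2L * j - 2L)) * osz
      pool_groups[q, ] <- c(base, base + 1L, base + osz, base + osz + 1L)
    }
  }
  list(side = side, kernel = kernel, stride = stride, channels = channels,
       osz = osz, psz = psz, idx = idx, pool_groups = pool_groups,
       k_elems = kernel * kernel * channels, n_patch = osz * osz,
       flat_dim = psz * psz)
}

cnn_params_init <- function(geom, filters, embed) {
  list(Wc = glorot(geom$k_elems, filters), bc = rep(0, filters),
       Wd = glorot(geom$flat_dim * filters, embed), bd = rep(0, embed))
}

# frames: N x (side^2 * channels) matrix -> list(embed N x E, caches)
cnn_forward <- function(par, geom, frames) {
  N <- nrow(frames)
  P <- geom$n_patch; K <- geom$k_elems; F <- ncol(par$Wc)
  xcol <- matrix(0, N * P, K)
  for (k in seq_len(K)) xcol[, k] <- frames[, geom$idx[k, ]]
  a <- xcol %*% par$Wc + matrix(par$bc, N * P, F, byrow = TRUE)
  relu_mask <- a > 0
  a[!relu_mask] <- 0
  # max pool over 2x2 patch blocks: rows of `a` are (frame, patch) pairs
  # with frame fastest, so patch p occupies rows (p-1)*N + 1:N
  psz2 <- geom$flat_dim
  pooled <- matrix(-Inf, N * psz2, F)
  argmax <- matrix(1L, N * psz2, F)
  for (g in 1:4) {
    rows <- rep((geom$pool_groups[, g] - 1L) * N, each = N) + seq_len(N)
    cand <- a[rows, , drop = FALSE]
    upd <- cand > pooled
    pooled[upd] <- cand[upd]
    argmax[upd] <- g
  }
  flat <- matrix(0, N, psz2 * F)
  for (f in seq_len(F)) {
    flat[, ((f - 1) * psz2 + 1):(f * psz2)] <- matrix(pooled[, f], N, psz2)
  }
  e_pre <- flat %*% par$Wd + matrix(par$bd, N, ncol(par$Wd), byrow = TRUE)
  e_mask <- e_pre > 0
  e <- e_pre * e_mask
  list(embed = e, xcol = xcol, relu_mask = relu_mask, argmax = argmax,
       flat = flat, e_mask = e_mask, N = N)
}

# de: N x E gradient wrt embeddings -> conv/dense gradients
cnn_backward <- function(par, geom, fw, de) {
  N <- fw$N; F <- ncol(par$Wc); psz2 <- geom$flat_dim
  de <- de * fw$e_mask
  gWd <- crossprod(fw$flat, de)
  gbd <- colSums(de)
  dflat <- de %*% t(par$Wd)
  dpooled <- matrix(0, N * psz2, F)
  for (f in seq_len(F)) {
    dpooled[, f] <- as.vector(dflat[, ((f - 1) * psz2 + 1):(f * psz2)])
  }
  da <- matrix(0, N * geom$n_patch, F)
  for (g in 1:4) {
    sel <- fw$argmax == g
    if (!any(sel)) next
    rows_all <- rep((geom$pool_groups[, g] - 1L) * N, each = N) + seq_len(N)
    # scatter: row index within pooled grid -> row in `a`
    sel_idx <- which(sel)
    target <- rows_all[(sel_idx - 1L) %% (N * psz2) + 1L] +
      ((sel_idx - 1L) %/% (N * psz2)) * (N * geom$n_patch)
    da[target] <- dpooled[sel_idx]
  }
  da[!fw$relu_mask] <- 0
  gWc <- crossprod(fw$xcol, da)
  gbc <- colSums(da)
  list(Wc = gWc, bc = gbc, Wd = gWd, bd = gbd)
}

# stack the valid frames of a dc_mask_sequences subset into one matrix,
# with a (B, T) row lookup (0 = padded)
stack_frames <- function(ms, idx) {
  mats <- ms$pooled[idx]
  n_each <- vapply(mats, nrow, integer(1))
  frames <- do.call(rbind, mats)
  B <- length(idx); T <- ms$max_len
  lookup <- matrix(0L, B, T)
  at <- 0L
  for (i in seq_len(B)) {
    lookup[i, seq_len(n_each[i])] <- at + seq_len(n_each[i])
    at <- at + n_each[i]
  }
  list(frames = frames, lookup = lookup)
}

cnn_gru_prob <- function(object, newdata) {
  stopifnot(inherits(newdata, "dc_mask_sequences"))
  st <- stack_frames(newdata, seq_along(newdata$pooled))
  fr <- sweep(st$frames, 2, object$frame_center)
  fw <- cnn_forward(object$params$cnn, object$geom, fr)
  B <- nrow(st$lookup); T <- ncol(st$lookup)
  E <- ncol(fw$embed)
  xseq <- array(0, c(B, T, E))
  valid <- which(st$lookup > 0, arr.ind = TRUE)
  rows <- st$lookup[st$lookup > 0]
  for (e in seq_len(E)) {
    xseq[cbind(valid, e)] <- fw$embed[rows, e]
  }
  gfw <- gru_forward(object$params$gru, xseq, (newdata$mask) * 1)
  sigmoid(gfw$logits)
}

#' Train a convolutional-recurrent classifier on mask-image sequences
#'
#' A convolutional encoder (weights shared across timesteps) embeds each
#' two-channel mask frame; a GRU consumes the embedding sequence under the
#' validity mask and a sigmoid head classifies its final state. Only the
#' mask images are used - no derived scalar features. Validation-selected
#' epoch, held-out test report.
#'
#' @param mask_sequences A `dc_mask_sequences` from
#'   [prepare_mask_sequences()].
#' @param labels Two-level factor, one per sequence.
#' @param filters Convolution filters.
#' @param kernel,stride Convolution kernel size and stride (on the pooled
#'   frame grid).
#' @param embed Frame embedding dimension.
#' @param units GRU hidden units.
#' @param epochs,batch_size,lr Optimiser settings (Adam).
#' @param spec A [split_spec()].
#' @param seed Initialisation/shuffle seed.
#' @param verbose Print per-epoch validation accuracy.
#' @return A `dc_seq_model` (kind "cnn_gru") with test `report`.
#' @export
train_cnn_gru <- function(mask_sequences, labels, filters = 8, kernel = 5,
                          stride = 2, embed = 24, units = 16, epochs = 175,
                          batch_size = 32, lr = 0.005, spec = split_spec(),
                          seed = 1, verbose = FALSE) {
  ms <- mask_sequences
  stopifnot(inherits(ms, "dc_mask_sequences"))
  labels <- droplevels(as.factor(labels))
  n <- length(ms$pooled)
  stopifnot(nlevels(labels) == 2, length(labels) == n)
  y <- as.numeric(labels == levels(labels)[2])
  side <- ms$crop / ms$pool
  geom <- conv_geometry(side, kernel, stride)
  sp <- split_dataset(n, spec, labels)
  # centre pixels with the global mean occupancy of training frames
  tr_stack <- stack_frames(ms, sp$train)
  frame_center <- colMeans(tr_stack$frames)
  set.seed(seed)
  params <- list(cnn = cnn_params_init(geom, filters, embed),
                 gru = gru_params_init(embed, units, 1, seed + 1))
  skeleton <- params
  theta <- flatten_params(params)
  opt <- adam_init(length(theta))
  msk <- ms$mask * 1

  forward_idx <- function(par, idx) {
    st <- stack_frames(ms, idx)
    fr <- sweep(st$frames, 2, frame_center)
    cf <- cnn_forward(par$cnn, geom, fr)
    B <- length(idx); T <- ms$max_len; E <- ncol(cf$embed)
    xseq <- array(0, c(B, T, E))
    valid <- which(st$lookup > 0, arr.ind = TRUE)
    rows <- st$lookup[st$lookup > 0]
    for (e in seq_len(E)) {
      xseq[cbind(valid, e)] <- cf$embed[rows, e]
    }
    gf <- gru_forward(par$gru, xseq, msk[idx, , drop = FALSE])
    list(st = st, cf = cf, xseq = xseq, gf = gf, idx = idx)
  }
  predict_prob <- function(theta, idx) {
    par <- relist_params(theta, skeleton)
    sigmoid(forward_idx(par, idx)$gf$logits)
  }
  best <- list(acc = -1, theta = theta, epoch = 0)
  history <- numeric(epochs)
  set.seed(seed + 2)
  for (ep in seq_len(epochs)) {
    ord <- sample(sp$train)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (b in batches) {
      par <- relist_params(theta, skeleton)
      fw <- forward_idx(par, b)
      lg <- bce_loss_grad(fw$gf$logits, y[b])
      gbk <- gru_backward(par$gru, fw$gf, fw$xseq, msk[b, , drop = FALSE],
                          lg$dlogits)
      # gather embedding gradients for the valid frames
      valid <- which(fw$st$lookup > 0, arr.ind = TRUE)
      rows <- fw$st$lookup[fw$st$lookup > 0]
      E <- ncol(fw$cf$embed)
      de <- matrix(0, nrow(fw$cf$embed), E)
      for (e in seq_len(E)) {
        de[rows, e] <- gbk$dx[cbind(valid, e)]
      }
      cbk <- cnn_backward(par$cnn, geom, fw$cf, de)
      grad <- clip_grad(flatten_params(list(
        cnn = cbk,
        gru = gbk[c("layers", "w_out", "b_out")]
      )))
      st <- adam_step(opt, theta, grad, lr)
      theta <- st$theta; opt <- st$state
    }
    val_acc <- mean((predict_prob(theta, sp$val) > 0.5) == y[sp$val])
    history[ep] <- val_acc
    if (val_acc > best$acc) best <- list(acc = val_acc, theta = theta, epoch = ep)
    if (verbose) message(sprintf("epoch %3d val accuracy %.3f", ep, val_acc))
  }
  params <- relist_params(best$theta, skeleton)
  model <- structure(
    list(kind = "cnn_gru", params = params, geom = geom,
         frame_center = frame_center, units = units, layers = 1,
         filters = filters, embed = embed, classes = levels(labels),
         split = sp, history = history, best_epoch = best$epoch, seed = seed),
    class = "dc_seq_model"
  )
  prob <- cnn_gru_prob(model, subset_samples(ms, sp$test))
  pred <- model$classes[(prob > 0.5) + 1]
  model$report <- classifier_report(labels[sp$test], pred)
  model
}

#' Train a single-frame CNN on undeformed cavity masks
#'
#' Control model: can phenotypes be told apart from the relaxed (cavity)
#' shape alone, without any deformation dynamics? Uses the same
#' convolutional encoder as the CNN-GRU on one cavity frame per cell,
#' followed by a logistic head.
#'
#' @param frames Matrix (n x pooled-frame length) of cavity frames, e.g.
#'   from [cavity_frames()].
#' @param labels Two-level factor.
#' @inheritParams train_cnn_gru
#' @return A `dc_cnn_model` with test `report`.
#' @export
train_cavity_cnn <- function(frames, labels, filters = 8, kernel = 5,
                             stride = 2, embed = 24, epochs = 30,
                             batch_size = 32, lr = 0.005,
                             spec = split_spec(), seed = 1) {
  labels <- droplevels(as.factor(labels))
  n <- nrow(frames)
  stopifnot(nlevels(labels) == 2, length(labels) == n)
  y <- as.numeric(labels == levels(labels)[2])
  side <- as.integer(sqrt(ncol(frames) / 2))
  stopifnot(2 * side^2 == ncol(frames))
  geom <- conv_geometry(side, kernel, stride)
  sp <- split_dataset(n, spec, labels)
  frame_center <- colMeans(frames[sp$train, , drop = FALSE])
  set.seed(seed)
  params <- list(cnn = cnn_params_init(geom, filters, embed),
                 w_out = glorot(embed, 1), b_out = 0)
  skeleton <- params
  theta <- flatten_params(params)
  opt <- adam_init(length(theta))
  fwd <- function(par, idx) {
    fr <- sweep(frames[idx, , drop = FALSE], 2, frame_center)
    cf <- cnn_forward(par$cnn, geom, fr)
    logits <- as.numeric(cf$embed %*% par$w_out) + par$b_out
    list(cf = cf, logits = logits)
  }
  best <- list(acc = -1, theta = theta, epoch = 0)
  set.seed(seed + 2)
  for (ep in seq_len(epochs)) {
    ord <- sample(sp$train)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      par <- relist_params(theta, skeleton)
      fw <- fwd(par, b)
      lg <- bce_loss_grad(fw$logits, y[b])
      de <- outer(lg$dlogits, as.numeric(par$w_out))
      cbk <- cnn_backward(par$cnn, geom, fw$cf, de)
      grad <- clip_grad(flatten_params(list(
        cnn = cbk,
        w_out = crossprod(fw$cf$embed, lg$dlogits),
        b_out = sum(lg$dlogits)
      )))
      st <- adam_step(opt, theta, grad, lr)
      theta <- st$theta; opt <- st$state
    }
    par <- relist_params(theta, skeleton)
    val_acc <- mean((sigmoid(fwd(par, sp$val)$logits) > 0.5) == y[sp$val])
    if (val_acc > best$acc) best <- list(acc = val_acc, theta = theta, epoch = ep)
  }
  params <- relist_params(best$theta, skeleton)
  fw_test <- fwd(params, sp$test)
  pred <- levels(labels)[(sigmoid(fw_test$logits) > 0.5) + 1]
  structure(
    list(kind = "cavity_cnn", params = params, geom = geom,
         frame_center = frame_center, classes = levels(labels), split = sp,
         report = classifier_report(labels[sp$test], pred),
         best_epoch = best$epoch, frames_dim = ncol(frames)),
    class = "dc_cnn_model"
  )
}

#' @export
print.dc_cnn_model <- function(x, ...) {
  cat(sprintf("<dc_cnn_model> single-frame CNN; test accuracy %.3f\n",
              x$report$accuracy))
  invisible(x)
}

#' Extract one pooled cavity frame per trajectory
#'
#' Picks the frame whose centroid is closest to the cavity midpoint (the
#' cell's most relaxed shape) from a `dc_mask_sequences` object.
#'
#' @param ms A `dc_mask_sequences`.
#' @param geometry A [channel_geometry()].
#' @return Matrix (n x pooled frame length), rows aligned with `ms$ids`.
#' @export
cavity_frames <- function(ms, geometry) {
  stopifnot(inherits(ms, "dc_mask_sequences"))
  bounds <- step_positions(geometry)
  mid <- (bounds[2] + bounds[3]) / 2
  acq <- ms$acquisition
  out <- matrix(0, length(ms$pooled), ncol(ms$pooled[[1]]))
  for (i in seq_along(ms$pooled)) {
    tr <- ms$trajectories[[i]]
    cx <- purrr::map_dbl(tr$mask, ~ mask_centroid_um(.x, acq)[["x"]])
    out[i, ] <- ms$pooled[[i]][which.min(abs(cx - mid)), ]
  }
  out
}
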