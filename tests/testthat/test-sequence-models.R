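# Gradient correctness and learnability of the recurrent and
# convolutional-recurrent engines.

test_that("GRU backpropagation matches finite differences (masked, stacked)", {
  set.seed(42)
  B <- 3; Tn <- 5; C <- 2; H <- 4
  skeleton <- mechanodc:::gru_params_init(C, H, layers = 2, seed = 9)
  x <- array(rnorm(B * Tn * C), c(B, Tn, C))
  mask <- matrix(1, B, Tn); mask[1, 4:5] <- 0; mask[2, 5] <- 0
  y <- c(1, 0, 1)
  theta <- mechanodc:::flatten_params(skeleton)
  loss_of <- function(th) {
    par <- mechanodc:::relist_params(th, skeleton)
    fw <- mechanodc:::gru_forward(par, x, mask)
    mechanodc:::bce_loss_grad(fw$logits, y)$loss
  }
  par <- mechanodc:::relist_params(theta, skeleton)
  fw <- mechanodc:::gru_forward(par, x, mask)
  lg <- mechanodc:::bce_loss_grad(fw$logits, y)
  bk <- mechanodc:::gru_backward(par, fw, x, mask, lg$dlogits)
  ga <- mechanodc:::flatten_params(bk[c("layers", "w_out", "b_out")])
  idx <- sort(sample(length(theta), 50))
  eps <- 1e-6
  gn <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_of(tp) - loss_of(tm)) / (2 * eps)
  }, numeric(1))
  expect_equal(ga[idx], gn, tolerance = 1e-5)
})

test_that("conv encoder backpropagation matches finite differences", {
  set.seed(11)
  side <- 12; n <- 6
  geom <- mechanodc:::conv_geometry(side, kernel = 5, stride = 2)
  frames <- matrix(runif(n * 2 * side^2), n)
  y <- c(1, 0, 1, 0, 1, 0)
  skeleton <- list(cnn = mechanodc:::cnn_params_init(geom, filters = 3, embed = 4),
                   w_out = mechanodc:::glorot(4, 1), b_out = 0)
  theta <- mechanodc:::flatten_params(skeleton)
  loss_of <- function(th) {
    p <- mechanodc:::relist_params(th, skeleton)
    cf <- mechanodc:::cnn_forward(p$cnn, geom, frames)
    lgt <- as.numeric(cf$embed %*% p$w_out) + p$b_out
    mechanodc:::bce_loss_grad(lgt, y)$loss
  }
  p <- mechanodc:::relist_params(theta, skeleton)
  cf <- mechanodc:::cnn_forward(p$cnn, geom, frames)
  lgt <- as.numeric(cf$embed %*% p$w_out) + p$b_out
  lg <- mechanodc:::bce_loss_grad(lgt, y)
  de <- outer(lg$dlogits, as.numeric(p$w_out))
  cbk <- mechanodc:::cnn_backward(p$cnn, geom, cf, de)
  ga <- mechanodc:::flatten_params(list(cnn = cbk,
                                        w_out = crossprod(cf$embed, lg$dlogits),
                                        b_out = sum(lg$dlogits)))
  idx <- sort(sample(length(theta), 50))
  eps <- 1e-6
  gn <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_of(tp) - loss_of(tm)) / (2 * eps)
  }, numeric(1))
  expect_equal(ga[idx], gn, tolerance = 1e-5)
})

test_that("a GRU learns a label encoded in the first sequence step", {
  set.seed(1)
  n <- 120; Tn <- 50
  x <- array(rnorm(n * Tn * 4, 0, 0.3), c(n, Tn, 4))
  lab <- rep(c("a", "b"), each = n / 2)
  x[lab == "b", 1, 1] <- x[lab == "b", 1, 1] + 3
  mask <- matrix(FALSE, n, Tn)
  lens <- sample(30:50, n, TRUE)
  for (i in seq_len(n)) mask[i, seq_len(lens[i])] <- TRUE
  x <- x * array(mask, dim(x))
  m <- train_gru(list(x = x, mask = mask), lab, units = 12, epochs = 40,
                 seed = 2)
  expect_gte(m$report$accuracy, 0.98)
  # label permutation control stays within the chance band
  set.seed(7)
  m0 <- train_gru(list(x = x, mask = mask), sample(lab), units = 12,
                  epochs = 20, seed = 2)
  band <- chance_band(m0$report$n)
  expect_gte(m0$report$accuracy, band[1])
  expect_lte(m0$report$accuracy, band[2])
})

test_that("the CNN-GRU separates static shape families", {
  set.seed(5)
  n <- 60
  trajs <- c(lapply(seq_len(n / 2), function(i) disc_traj(20, n = 30)),
             lapply(seq_len(n / 2), function(i)
               make_shape_traj(rep(list(raster_ellipse(28, 14)), 30))))
  names(trajs) <- sprintf("t%02d", seq_len(n))
  lab <- rep(c("disc", "ell"), each = n / 2)
  ms <- prepare_mask_sequences(trajs, channel_geometry(), acquisition_config())
  m <- train_cnn_gru(ms, lab, epochs = 15, seed = 4)
  expect_gte(m$report$accuracy, 0.95)
  # all-zero (fully padded) inputs cannot beat the majority rate
  ms0 <- ms; ms0$pooled <- lapply(ms0$pooled, function(p) p * 0)
  m0 <- train_cnn_gru(ms0, lab, epochs = 5, seed = 4)
  expect_lte(m0$report$accuracy, max(table(lab[m0$split$test])) /
               m0$report$n + 1e-9)
})

test_that("sequence-model training is reproducible under one seed", {
  set.seed(1)
  n <- 40; Tn <- 20
  x <- array(rnorm(n * Tn * 4), c(n, Tn, 4))
  mask <- matrix(TRUE, n, Tn)
  lab <- rep(c("a", "b"), each = n / 2)
  m1 <- train_gru(list(x = x, mask = mask), lab, units = 6, epochs = 5,
                  seed = 3)
  m2 <- train_gru(list(x = x, mask = mask), lab, units = 6, epochs = 5,
                  seed = 3)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$report$accuracy, m2$report$accuracy)
})
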