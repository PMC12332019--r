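test_that("decoder construction is shaped, bounded and seed-deterministic", {
  cfg <- decoder_config(k = 5, side = 8, c1 = 6, c2 = 4, epochs = 2,
                        seed = 3)
  dec <- build_decoder(cfg)
  X <- matrix(runif(7 * 5), 7, 5)
  out <- predict(dec, X)
  expect_equal(dim(out), c(7, 64))
  expect_true(all(out > 0 & out < 1))

  dec2 <- build_decoder(cfg)
  expect_identical(dec$params, dec2$params)

  expect_error(decoder_config(k = 5, side = 10), "divisible by 4")
})

test_that("analytic gradients match finite differences", {
  set.seed(19)
  cfg <- decoder_config(k = 3, side = 4, c1 = 4, c2 = 3, seed = 5)
  dec <- build_decoder(cfg)
  X <- matrix(runif(6 * 3), 6, 3)
  Y <- matrix(runif(6 * 16), 6, 16)
  fw <- qubofs:::decoder_forward(dec, X, cache = TRUE)
  grads <- qubofs:::decoder_backward(dec, fw, 2 * (fw$out - Y) / length(Y))
  loss <- function(d) mean((qubofs:::decoder_forward(d, X) - Y)^2)
  eps <- 1e-6
  for (probe in list(
    list(g = function() grads$W0[2, 3],
         bump = function(d) { d$params$W0[2, 3] <- d$params$W0[2, 3] + eps; d }),
    list(g = function() grads$W1[[6]][1, 2],
         bump = function(d) { d$params$W1[[6]][1, 2] <-
           d$params$W1[[6]][1, 2] + eps; d }),
    list(g = function() grads$W2[[11]][3, 1],
         bump = function(d) { d$params$W2[[11]][3, 1] <-
           d$params$W2[[11]][3, 1] + eps; d }),
    list(g = function() grads$b1[2],
         bump = function(d) { d$params$b1[2] <- d$params$b1[2] + eps; d }),
    list(g = function() grads$b2[1],
         bump = function(d) { d$params$b2[1] <- d$params$b2[1] + eps; d }))) {
    numeric_g <- (loss(probe$bump(dec)) - loss(dec)) / eps
    expect_equal(probe$g(), numeric_g, tolerance = 1e-4)
  }
})

test_that("training fits a constant dataset and is reproducible", {
  img <- matrix(rep(c(0.2, 0.8), each = 8), 4, 4)
  imgs <- array(rep(img, each = 20), dim = c(20, 4, 4))
  fd <- flatten(image_dataset(imgs, rep(0L, 20)))
  mask <- select_random(16, 3, 2)
  cfg <- decoder_config(k = 3, side = 4, c1 = 6, c2 = 4, epochs = 80,
                        batch_size = 5, lr = 0.02, seed = 4)
  fit <- train_decoder(build_decoder(cfg), mask_inputs(fd, mask),
                       fd$features)
  expect_length(fit$loss_history, 80)
  expect_true(all(is.finite(fit$loss_history)))
  expect_lt(fit$loss_history[80], fit$loss_history[1])
  expect_lt(evaluate_mse(fit$decoder, mask_inputs(fd, mask), fd$features),
            0.01)

  fit2 <- train_decoder(build_decoder(cfg), mask_inputs(fd, mask),
                        fd$features)
  expect_equal(fit$loss_history, fit2$loss_history, tolerance = 1e-6)
  expect_equal(evaluate_mse(fit$decoder, mask_inputs(fd, mask), fd$features),
               evaluate_mse(fit2$decoder, mask_inputs(fd, mask), fd$features),
               tolerance = 1e-6)
})

test_that("MSE evaluation matches closed forms and is order-invariant", {
  cfg <- decoder_config(k = 2, side = 4, c1 = 3, c2 = 2, seed = 6)
  dec <- build_decoder(cfg)
  # zero all weights, set the output bias: constant sigmoid(b2) prediction
  dec$params <- lapply(dec$params, function(p) {
    if (is.list(p)) lapply(p, function(m) m * 0) else p * 0
  })
  dec$params$b2 <- 0.7
  const <- 1 / (1 + exp(-0.7))
  set.seed(66)
  X <- matrix(runif(10 * 2), 10, 2)
  Y <- matrix(runif(10 * 16), 10, 16)
  expect_equal(evaluate_mse(dec, X, Y), mean((const - Y)^2),
               tolerance = 1e-12)

  perm <- sample(10)
  expect_equal(evaluate_mse(dec, X[perm, ], Y[perm, ]),
               evaluate_mse(dec, X, Y), tolerance = 1e-12)
  expect_gte(evaluate_mse(dec, X, Y), 0)
})

test_that("mask inputs follow row-major selected-coordinate order", {
  set.seed(8)
  ds <- image_dataset(array(runif(3 * 4 * 4), dim = c(3, 4, 4)),
                      c(0L, 1L, 0L))
  fd <- flatten(ds)
  mask <- integer(16); mask[c(2, 7, 11)] <- 1L
  Xm <- mask_inputs(fd, mask)
  expect_equal(dim(Xm), c(3, 3))
  expect_equal(Xm[, 1], ds$images[, 1, 2])
  expect_equal(Xm[, 2], ds$images[, 2, 3])
  expect_equal(Xm[, 3], ds$images[, 3, 3])
  expect_error(mask_inputs(fd, mask[-1]), "length")
})

test_that("autoencoder and SPCA adapters produce k features and train", {
  spec <- synthetic_spec(n_samples = 80, height = 4, width = 4,
                         n_classes = 2, informative_pixels = 2,
                         redundancy_groups = 1, group_size = 2, seed = 12)
  fd <- flatten(generate_synthetic(spec))
  tr <- spca_features(fd$features, 3)
  Z <- tr$transform(fd$features)
  expect_equal(dim(Z), c(80, 3))
  expect_true(all(colSums(tr$loadings != 0) >= 1))
  expect_true(all(colSums(tr$loadings != 0) <= 16))

  cfg <- decoder_config(k = 3, side = 4, c1 = 4, c2 = 3, epochs = 2,
                        batch_size = 40, seed = 1)
  ae <- add_linear_encoder(build_decoder(cfg), 16)
  fit <- train_decoder(ae, fd$features, fd$features)
  expect_true(all(is.finite(fit$loss_history)))
  expect_equal(dim(predict(fit$decoder, fd$features)), c(80, 16))
})
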