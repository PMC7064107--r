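cfg_small <- unet_config(depth = 2, base_channels = 4, se_reduction = 2)

test_that("normalization uses the set maximum and round-trips exactly", {
  imgs <- list(matrix(c(-0.01, 0.005), 2, 2), matrix(0.02, 2, 2))
  norm <- normalize_images(imgs)
  expect_equal(norm$norm_constant, 0.02)
  expect_equal(max(abs(unlist(norm$images))), 1)
  restored <- lapply(norm$images, function(im) im * norm$norm_constant)
  expect_equal(restored, imgs)
  expect_equal(normalize_images(list(matrix(0.004, 3, 3)))$images[[1]],
               matrix(1, 3, 3))
  expect_error(normalize_images(list(matrix(0, 2, 2))), "degenerate")
  expect_error(normalize_images(list()), "empty")
})

test_that("network output preserves input size and builds deterministically", {
  net <- build_unet(cfg_small, seed = 4)
  net2 <- build_unet(cfg_small, seed = 4)
  net3 <- build_unet(cfg_small, seed = 5)
  expect_identical(net$params, net2$params)
  expect_false(identical(net$params, net3$params))
  x <- array(runif(32 * 32, -1, 1), c(32, 32, 1, 1))
  y <- unet_forward(net, x)
  expect_equal(dim(y), c(32, 32, 1, 1))
  expect_true(all(is.finite(y)))
  expect_error(unet_forward(net, array(0, c(30, 30, 1, 1))), "divisible")
  # parameter count is a pure function of the architecture
  expect_equal(unet_param_count(net), unet_param_count(net3))
  wider <- build_unet(unet_config(depth = 2, base_channels = 8,
                                  se_reduction = 2), 1)
  expect_gt(unet_param_count(wider), unet_param_count(net))
})

test_that("SE gates lie in (0,1), saturate to identity, and act channel-wise", {
  set.seed(6)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  w1 <- matrix(rnorm(2 * 4), 2, 4)
  w2 <- matrix(rnorm(4 * 2), 4, 2)
  out <- se_recalibrate(x, w1, rnorm(2), w2, rnorm(4), return_gates = TRUE)
  expect_true(all(out$gates > 0 & out$gates < 1))
  # saturated bias drives every gate to 1: output equals input
  sat <- se_recalibrate(x, w1 * 0, c(0, 0), w2 * 0, rep(30, 4))
  expect_equal(sat, x, tolerance = 1e-10)
  # spatially uniform channels stay uniform under channel-wise gating
  xu <- array(rep(1:8, each = 16), c(4, 4, 4, 2))
  yu <- se_recalibrate(xu, w1, rnorm(2), w2, rnorm(4))
  for (c in 1:4) for (b in 1:2)
    expect_equal(sd(yu[, , c, b]), 0)
})

test_that("backpropagation matches finite-difference gradients", {
  for (mode in c("bilinear", "deconv")) {
    cfg <- unet_config(depth = 1, base_channels = 4, se_reduction = 2,
                       up_mode = mode)
    net <- build_unet(cfg, seed = 7)
    set.seed(8)
    x <- array(runif(8 * 8 * 2, -1, 1), c(8, 8, 1, 2))
    tgt <- array(runif(8 * 8 * 2, -1, 1), c(8, 8, 1, 2))
    fw <- laxm:::unet_fwd(net, x, training = TRUE)
    grads <- laxm:::unet_bwd(net, fw$caches,
                             2 * (fw$out - tgt) / length(fw$out))
    loss <- function(n) mean((laxm:::unet_fwd(n, x, TRUE)$out - tgt)^2)
    eps <- 1e-6
    for (nm in sample(names(net$params), 6)) {
      p <- net$params[[nm]]
      for (i in sample(length(p), min(3, length(p)))) {
        n2 <- net
        n2$params[[nm]][i] <- p[i] + eps
        up <- loss(n2)
        n2$params[[nm]][i] <- p[i] - eps
        dn <- loss(n2)
        num <- (up - dn) / (2 * eps)
        expect_lt(abs(num - grads[[nm]][i]) /
                    max(1e-6, abs(num) + abs(grads[[nm]][i])), 1e-3)
      }
    }
  }
})

test_that("the learning-rate schedule plateaus then decays geometrically", {
  tc <- train_config(epochs = 500, lr_start = 1e-3, lr_end = 1e-5,
                     lr_plateau_epochs = 100)
  expect_equal(lr_schedule(1, tc), 1e-3)
  expect_equal(lr_schedule(100, tc), 1e-3)
  expect_equal(lr_schedule(500, tc), 1e-5)
  mid <- lr_schedule(300, tc)
  expect_lt(mid, 1e-3)
  expect_gt(mid, 1e-5)
  # geometric: equal ratios over equal epoch spans
  r1 <- lr_schedule(200, tc) / lr_schedule(150, tc)
  r2 <- lr_schedule(250, tc) / lr_schedule(200, tc)
  expect_equal(r1, r2)
  expect_error(train_config(lr_start = 1e-6, lr_end = 1e-3), "lr_start")
  expect_error(train_config(epochs = 10, lr_plateau_epochs = 20), "epochs")
})

test_that("training reduces the loss and is reproducible under its seed", {
  pairs <- toy_training_pairs(8, size = 32, seed = 21)
  tc <- train_config(epochs = 12, lr_plateau_epochs = 4, batch_size = 4,
                     holdout_fraction = 0, seed = 5)
  res <- train_unet(pairs, cfg_small, tc)
  expect_lt(tail(res$log$train_loss, 1), res$log$train_loss[1])
  expect_equal(nrow(res$log), 12)
  expect_gt(res$net$norm_constant, 0)
  res2 <- train_unet(pairs, cfg_small, tc)
  expect_identical(res$log, res2$log)
  expect_identical(res$net$params, res2$net$params)
  expect_error(train_unet(list(), cfg_small, tc), "empty")
})

test_that("artifact subtraction is the identity under a zeroed output head", {
  net <- build_unet(cfg_small, seed = 2)
  net$params[["final.w"]][] <- 0
  net$params[["final.b"]][] <- 0
  net$norm_constant <- 0.02
  img <- slice_image(matrix(runif(32 * 32, 0, 0.02), 32, 32), 43.8, 16)
  out <- predict_clean(img, net)
  expect_equal(unclass(out), unclass(img), tolerance = 1e-12)
  # inference is a pure function
  net2 <- build_unet(cfg_small, seed = 3)
  net2$norm_constant <- 0.02
  a <- predict_clean(img, net2)
  b <- predict_clean(img, net2)
  expect_identical(a, b)
  net2$norm_constant <- -1
  expect_error(predict_clean(img, net2), "norm_constant")
})

test_that("the bilinear decoder suppresses the 2-pixel checkerboard mode", {
  pairs <- toy_training_pairs(8, size = 32, seed = 31)
  nyquist_energy <- function(up_mode) {
    cfg <- unet_config(depth = 2, base_channels = 4, se_reduction = 2,
                       up_mode = up_mode)
    res <- train_unet(pairs, cfg,
                      train_config(epochs = 8, lr_plateau_epochs = 8,
                                   batch_size = 4, holdout_fraction = 0,
                                   seed = 9))
    e <- 0
    for (p in pairs[1:4]) {
      art <- unclass(p$input) - unclass(predict_clean(p$input, res$net))
      F <- abs(fft(art))
      # energy in the highest-frequency (period-2) rows and columns
      e <- e + mean(F[17, ]) + mean(F[, 17])
    }
    e
  }
  expect_lt(nyquist_energy("bilinear"), nyquist_energy("deconv"))
})
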