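#' Configuration of the artifact-prediction U-Net
#'
#' Encoder-decoder with skip concatenations. Every convolution block is a
#' zero-padded 3x3 convolution followed by ReLU, batch normalization and a
#' squeeze-and-excitation channel gate; down-sampling is 2x2 max pooling;
#' up-sampling is bilinear resizing followed by a 2x2 convolution (a
#' transposed-convolution decoder is available for comparison); the output
#' head is a 1x1 convolution with no activation, producing a one-channel
#' artifact image the same size as the input.
#'
#' @param depth Number of down-sampling levels (>= 1). Input spatial size
#'   must be divisible by `2^depth`.
#' @param base_channels Channels at the first level; doubled per level.
#' @param se_reduction Bottleneck reduction ratio of the SE gates.
#' @param up_mode `"bilinear"` (resize + 2x2 convolution) or `"deconv"`
#'   (2x2 stride-2 transposed convolution).
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 64L, se_reduction = 16L,
                        up_mode = c("bilinear", "deconv")) {
  if (depth < 1) stopf("depth must be >= 1")
  if (base_channels < 1) stopf("base_channels must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 se_reduction = as.integer(se_reduction),
                 up_mode = match.arg(up_mode)),
            class = "unet_config")
}

#' Training schedule configuration
#'
#' Adam with mean-squared-error loss on predicted artifact images plus an
#' l2 penalty on convolution weights. The learning rate is constant for the
#' first `lr_plateau_epochs` epochs and then decays geometrically to
#' `lr_end` at the final epoch.
#'
#' @param epochs Total epochs.
#' @param lr_start,lr_end Initial and final learning rate.
#' @param lr_plateau_epochs Epochs at `lr_start` before the decay begins.
#' @param l2_weight l2 regularization weight on convolution kernels.
#' @param batch_size Mini-batch size.
#' @param holdout_fraction Fraction of pairs held out for a validation-loss
#'   log (0 disables the split and trains on everything).
#' @param seed Seed for initialization, shuffling and batching.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, lr_start = 1e-3, lr_end = 1e-5,
                         lr_plateau_epochs = 100L, l2_weight = 1e-4,
                         batch_size = 4L, holdout_fraction = 0.05,
                         seed = 1L) {
  if (!(lr_start >= lr_end && lr_end > 0)) stopf("need lr_start >= lr_end > 0")
  if (epochs < lr_plateau_epochs) stopf("epochs must be >= lr_plateau_epochs")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), lr_start = lr_start,
                 lr_end = lr_end,
                 lr_plateau_epochs = as.integer(lr_plateau_epochs),
                 l2_weight = l2_weight, batch_size = as.integer(batch_size),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param epoch Epoch number (1-based).
#' @param tc A [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(epoch, tc) {
  if (epoch <= tc$lr_plateau_epochs || tc$epochs == tc$lr_plateau_epochs)
    return(tc$lr_start)
  frac <- (epoch - tc$lr_plateau_epochs) / (tc$epochs - tc$lr_plateau_epochs)
  tc$lr_start * (tc$lr_end / tc$lr_start)^frac
}

# block plan: name, kind (conv_block / up / final), cin, cout
unet_blocks <- function(config) {
  C <- config$base_channels
  D <- config$depth
  blocks <- list()
  add <- function(name, kind, cin, cout)
    blocks[[length(blocks) + 1L]] <<- list(name = name, kind = kind,
                                           cin = cin, cout = cout)
  for (l in seq_len(D)) {
    cin <- if (l == 1) 1L else C * 2^(l - 2)
    add(paste0("enc", l, "a"), "conv_block", cin, C * 2^(l - 1))
    add(paste0("enc", l, "b"), "conv_block", C * 2^(l - 1), C * 2^(l - 1))
  }
  add("bota", "conv_block", C * 2^(D - 1), C * 2^D)
  add("botb", "conv_block", C * 2^D, C * 2^D)
  for (l in rev(seq_len(D))) {
    add(paste0("up", l), "up", C * 2^l, C * 2^(l - 1))
    add(paste0("dec", l, "a"), "conv_block", C * 2^l, C * 2^(l - 1))
    add(paste0("dec", l, "b"), "conv_block", C * 2^(l - 1), C * 2^(l - 1))
  }
  add("final", "final", C, 1L)
  blocks
}

se_bottleneck <- function(cout, reduction) max(1L, as.integer(round(cout / reduction)))

#' Build an untrained artifact-prediction network
#'
#' He-initialized convolution kernels; batch-normalization scale 1, shift
#' 0; SE bottleneck widths `max(1, round(channels / se_reduction))`. The
#' same seed always yields identical initial parameters, and the parameter
#' count is a deterministic function of the configuration.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for the initialization.
#' @return Object of class `unet` with elements `config`, `params`,
#'   `buffers`, `norm_constant` (NA until trained).
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  params <- list()
  buffers <- list()
  with_seed(seed, {
    for (b in unet_blocks(config)) {
      k <- if (b$kind == "conv_block") 3L else if (b$kind == "up") 2L else 1L
      sd <- sqrt(2 / (k * k * b$cin))
      params[[paste0(b$name, ".w")]] <-
        array(rnorm(k * k * b$cin * b$cout, sd = sd), c(k, k, b$cin, b$cout))
      params[[paste0(b$name, ".b")]] <- numeric(b$cout)
      if (b$kind == "conv_block") {
        params[[paste0(b$name, ".gamma")]] <- rep(1, b$cout)
        params[[paste0(b$name, ".beta")]] <- numeric(b$cout)
        r <- se_bottleneck(b$cout, config$se_reduction)
        params[[paste0(b$name, ".se_w1")]] <-
          matrix(rnorm(r * b$cout, sd = sqrt(2 / b$cout)), r, b$cout)
        params[[paste0(b$name, ".se_b1")]] <- numeric(r)
        params[[paste0(b$name, ".se_w2")]] <-
          matrix(rnorm(b$cout * r, sd = sqrt(1 / r)), b$cout, r)
        params[[paste0(b$name, ".se_b2")]] <- numeric(b$cout)
        buffers[[paste0(b$name, ".rm")]] <- numeric(b$cout)
        buffers[[paste0(b$name, ".rv")]] <- rep(1, b$cout)
      }
    }
  })
  structure(list(config = config, params = params, buffers = buffers,
                 norm_constant = NA_real_), class = "unet")
}

#' Number of trainable parameters of a network
#'
#' @param net A `unet`.
#' @return Integer parameter count.
#' @export
unet_param_count <- function(net) sum(vapply(net$params, length, integer(1)))

#' Squeeze-and-excitation channel recalibration
#'
#' Global average pooling squeezes each channel to one descriptor; a
#' two-layer bottleneck with sigmoid output turns the descriptors into
#' per-channel gates in (0, 1) that rescale the feature map channel-wise.
#'
#' @param features 4-d array `(H, W, C, B)`.
#' @param w1,b1 First (reduction) layer weights `(r x C)` and biases.
#' @param w2,b2 Second (expansion) layer weights `(C x r)` and biases.
#' @param return_gates Also return the gate matrix.
#' @return Recalibrated array, or a list with `y` and `gates`.
#' @export
se_recalibrate <- function(features, w1, b1, w2, b2, return_gates = FALSE) {
  out <- se_forward(features, w1, b1, w2, b2)
  if (return_gates) list(y = out$y, gates = out$cache$g) else out$y
}

cb_forward <- function(params, buffers, name, x, training) {
  a <- conv_same_forward(x, params[[paste0(name, ".w")]],
                         params[[paste0(name, ".b")]])
  r <- relu_forward(a)
  bn <- bn_forward(r, params[[paste0(name, ".gamma")]],
                   params[[paste0(name, ".beta")]],
                   buffers[[paste0(name, ".rm")]],
                   buffers[[paste0(name, ".rv")]], training)
  se <- se_forward(bn$y, params[[paste0(name, ".se_w1")]],
                   params[[paste0(name, ".se_b1")]],
                   params[[paste0(name, ".se_w2")]],
                   params[[paste0(name, ".se_b2")]])
  list(y = se$y,
       cache = list(x = x, a = a, bn = bn$cache, se = se$cache),
       rm = bn$rm, rv = bn$rv)
}

cb_backward <- function(params, name, gy, cache, grads) {
  se <- se_backward(gy, params[[paste0(name, ".se_w1")]],
                    params[[paste0(name, ".se_w2")]], cache$se)
  grads[[paste0(name, ".se_w1")]] <- se$gw1
  grads[[paste0(name, ".se_b1")]] <- se$gb1
  grads[[paste0(name, ".se_w2")]] <- se$gw2
  grads[[paste0(name, ".se_b2")]] <- se$gb2
  bn <- bn_backward(se$gx, params[[paste0(name, ".gamma")]], cache$bn)
  grads[[paste0(name, ".gamma")]] <- bn$ggamma
  grads[[paste0(name, ".beta")]] <- bn$gbeta
  gr <- relu_backward(cache$a, bn$gx)
  cv <- conv_same_backward(cache$x, params[[paste0(name, ".w")]], gr)
  grads[[paste0(name, ".w")]] <- cv$gw
  grads[[paste0(name, ".b")]] <- cv$gb
  list(gx = cv$gx, grads = grads)
}

# full forward pass; returns output, caches for backprop, updated buffers
unet_fwd <- function(net, x, training = FALSE) {
  cfg <- net$config
  d <- dim(x)
  if (d[1] %% 2^cfg$depth || d[2] %% 2^cfg$depth)
    stopf("input spatial size (%d x %d) must be divisible by 2^depth = %d",
          d[1], d[2], 2^cfg$depth)
  p <- net$params
  buf <- net$buffers
  caches <- list()
  skips <- list()
  run_block <- function(name, x) {
    cb <- cb_forward(p, buf, name, x, training)
    buf[[paste0(name, ".rm")]] <<- cb$rm
    buf[[paste0(name, ".rv")]] <<- cb$rv
    caches[[name]] <<- cb$cache
    cb$y
  }
  h <- x
  for (l in seq_len(cfg$depth)) {
    h <- run_block(paste0("enc", l, "a"), h)
    h <- run_block(paste0("enc", l, "b"), h)
    skips[[l]] <- h
    mp <- cpp_maxpool_forward(h)
    caches[[paste0("pool", l)]] <- mp$idx
    h <- mp$y
  }
  h <- run_block("bota", h)
  h <- run_block("botb", h)
  for (l in rev(seq_len(cfg$depth))) {
    upname <- paste0("up", l)
    if (cfg$up_mode == "bilinear") {
      ups <- cpp_bilinear_up_forward(h)
      caches[[paste0(upname, ".in")]] <- ups
      h <- conv_same_forward(ups, p[[paste0(upname, ".w")]],
                             p[[paste0(upname, ".b")]])
    } else {
      caches[[paste0(upname, ".in")]] <- h
      h <- cpp_deconv2_forward(h, p[[paste0(upname, ".w")]],
                               p[[paste0(upname, ".b")]])
    }
    caches[[paste0(upname, ".skipc")]] <- dim(skips[[l]])[3]
    h <- concat_channels(skips[[l]], h)
    h <- run_block(paste0("dec", l, "a"), h)
    h <- run_block(paste0("dec", l, "b"), h)
  }
  caches[["final.x"]] <- h
  out <- conv_same_forward(h, p[["final.w"]], p[["final.b"]])
  list(out = out, caches = caches, buffers = buf)
}

unet_bwd <- function(net, caches, gout) {
  cfg <- net$config
  p <- net$params
  grads <- list()
  fin <- conv_same_backward(caches[["final.x"]], p[["final.w"]], gout)
  grads[["final.w"]] <- fin$gw
  grads[["final.b"]] <- fin$gb
  g <- fin$gx
  gskips <- list()
  for (l in seq_len(cfg$depth)) {
    bb <- cb_backward(p, paste0("dec", l, "b"), g, caches[[paste0("dec", l, "b")]], grads)
    grads <- bb$grads
    aa <- cb_backward(p, paste0("dec", l, "a"), bb$gx, caches[[paste0("dec", l, "a")]], grads)
    grads <- aa$grads
    upname <- paste0("up", l)
    sp <- split_channels(aa$gx, caches[[paste0(upname, ".skipc")]])
    gskips[[l]] <- sp[[1]]
    if (cfg$up_mode == "bilinear") {
      cv <- conv_same_backward(caches[[paste0(upname, ".in")]],
                               p[[paste0(upname, ".w")]], sp[[2]])
      grads[[paste0(upname, ".w")]] <- cv$gw
      grads[[paste0(upname, ".b")]] <- cv$gb
      g <- cpp_bilinear_up_backward(cv$gx)
    } else {
      dv <- cpp_deconv2_backward(caches[[paste0(upname, ".in")]],
                                 p[[paste0(upname, ".w")]], sp[[2]])
      grads[[paste0(upname, ".w")]] <- dv$gw
      grads[[paste0(upname, ".b")]] <- dv$gb
      g <- dv$gx
    }
  }
  bb <- cb_backward(p, "botb", g, caches[["botb"]], grads)
  grads <- bb$grads
  aa <- cb_backward(p, "bota", bb$gx, caches[["bota"]], grads)
  grads <- aa$grads
  g <- aa$gx
  for (l in rev(seq_len(cfg$depth))) {
    g <- cpp_maxpool_backward(g, caches[[paste0("pool", l)]])
    g <- g + gskips[[l]]
    bb <- cb_backward(p, paste0("enc", l, "b"), g, caches[[paste0("enc", l, "b")]], grads)
    grads <- bb$grads
    aa <- cb_backward(p, paste0("enc", l, "a"), bb$gx, caches[[paste0("enc", l, "a")]], grads)
    grads <- aa$grads
    g <- aa$gx
  }
  grads
}

#' Forward pass of the network
#'
#' In inference mode (the default) batch normalization uses accumulated
#' running statistics, so the network is a pure function of its input.
#'
#' @param net A `unet` from [build_unet()] or [train_unet()].
#' @param x 4-d array `(H, W, 1, B)`, a matrix (taken as one image), or a
#'   [slice_image()].
#' @param training Use mini-batch statistics (internal training mode).
#' @return 4-d array `(H, W, 1, B)` of predicted artifact images.
#' @export
unet_forward <- function(net, x, training = FALSE) {
  if (is.matrix(x)) x <- array(unclass(x), c(nrow(x), ncol(x), 1, 1))
  unet_fwd(net, x, training)$out
}

#' Normalize a set of images to \[-1, 1\]
#'
#' The normalization constant is the maximum absolute intensity over the
#' whole set; every image is divided by it, so all scaled values lie in
#' \[-1, 1\] and multiplying by the constant restores the originals exactly.
#'
#' @param images Non-empty list of matrices.
#' @return List with `images` (scaled) and `norm_constant`.
#' @export
normalize_images <- function(images) {
  if (!length(images)) stopf("empty image set")
  for (im in images) check_finite(im, "image")
  norm <- max(vapply(images, function(im) max(abs(im)), numeric(1)))
  if (norm == 0) stopf("degenerate scale: all images are zero")
  list(images = lapply(images, function(im) im / norm), norm_constant = norm)
}

#' Train the artifact-prediction network
#'
#' Minimizes the mean squared error between predicted and target artifact
#' images (both scaled to \[-1, 1\] by one shared constant) plus an l2
#' penalty on convolution kernels, using Adam with the schedule of the
#' train config. Fully seeded: identical seeds give identical loss curves.
#'
#' @param pairs Non-empty list of `list(input, target)` matrices in
#'   physical units (1/micrometre); the shared normalization constant is
#'   computed from the inputs and stored with the model.
#' @param net_config A [unet_config()].
#' @param tc A [train_config()].
#' @return List with `net` (trained, including `norm_constant`) and `log`
#'   (data frame: epoch, lr, train_loss, val_loss).
#' @export
train_unet <- function(pairs, net_config = unet_config(), tc = train_config()) {
  if (!length(pairs)) stopf("empty training set")
  norm <- max(vapply(pairs, function(p) max(abs(p$input)), numeric(1)))
  if (norm == 0) stopf("degenerate scale: all training inputs are zero")
  net <- build_unet(net_config, seed = tc$seed)
  net$norm_constant <- norm
  n <- length(pairs)
  adam_m <- lapply(net$params, function(p) p * 0)
  adam_v <- lapply(net$params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  conv_w <- grep("\\.w$", names(net$params), value = TRUE)
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), val_loss = numeric())
  with_seed(tc$seed + 1L, {
    perm <- sample.int(n)
    n_val <- if (tc$holdout_fraction > 0) max(0L, floor(tc$holdout_fraction * n)) else 0L
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer()
    tr_idx <- setdiff(perm, val_idx)
    if (!length(tr_idx)) stopf("no training pairs left after holdout split")
    make_batch <- function(idx) {
      h <- nrow(pairs[[idx[1]]]$input)
      w <- ncol(pairs[[idx[1]]]$input)
      x <- array(0, c(h, w, 1, length(idx)))
      t <- array(0, c(h, w, 1, length(idx)))
      for (i in seq_along(idx)) {
        x[, , 1, i] <- unclass(pairs[[idx[i]]]$input) / norm
        t[, , 1, i] <- unclass(pairs[[idx[i]]]$target) / norm
      }
      list(x = x, t = t)
    }
    for (epoch in seq_len(tc$epochs)) {
      lr <- lr_schedule(epoch, tc)
      order <- sample(tr_idx)
      losses <- numeric()
      for (start in seq(1, length(order), by = tc$batch_size)) {
        idx <- order[seq(start, min(start + tc$batch_size - 1, length(order)))]
        b <- make_batch(idx)
        fw <- unet_fwd(net, b$x, training = TRUE)
        net$buffers <- fw$buffers
        resid <- fw$out - b$t
        losses <- c(losses, mean(resid^2))
        grads <- unet_bwd(net, fw$caches, 2 * resid / length(resid))
        step <- step + 1L
        for (nm in names(net$params)) {
          g <- grads[[nm]]
          if (tc$l2_weight > 0 && nm %in% conv_w)
            g <- g + tc$l2_weight * net$params[[nm]]
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      val_loss <- NA_real_
      if (length(val_idx)) {
        vb <- make_batch(val_idx)
        val_loss <- mean((unet_fwd(net, vb$x, training = FALSE)$out - vb$t)^2)
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   train_loss = mean(losses),
                                   val_loss = val_loss))
    }
  })
  list(net = net, log = log)
}

#' Subtract the predicted artifact image from a reconstruction
#'
#' The network input is the reconstruction scaled by the stored
#' normalization constant; the predicted artifact is scaled back to
#' physical units and subtracted, yielding the deep-learning
#' reconstruction.
#'
#' @param image [slice_image()] or matrix (1/micrometre).
#' @param net A trained `unet`.
#' @param norm_constant Normalization constant; defaults to the one stored
#'   with the model.
#' @return Cleaned image of the same type.
#' @export
predict_clean <- function(image, net, norm_constant = net$norm_constant) {
  if (is.na(norm_constant) || norm_constant <= 0)
    stopf("norm_constant must be positive")
  x <- array(unclass(image) / norm_constant,
             c(nrow(image), ncol(image), 1, 1))
  artifact <- unet_fwd(net, x, training = FALSE)$out[, , 1, 1] * norm_constant
  out <- unclass(image) - artifact
  if (inherits(image, "slice_image"))
    slice_image(out, attr(image, "pixel_pitch"), attr(image, "fov_radius"))
  else out
}
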