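#' Training configuration for the segmentation demonstrator
#'
#' Collects the encoder-decoder architecture and optimization settings.
#' The optimization constants follow the reference training recipe for
#' this pipeline: kernel width 5, batch size 40, 200 samples per epoch,
#' RMSProp at learning rate 1e-4 with binary cross-entropy, and early
#' stopping after 7 epochs without validation improvement. Architecture
#' size is scaled by `input_size`, `depth`, `base_filters` and
#' `conv_per_block`: the `"desk"` preset (64-px inputs, depth 3, 6 base
#' filters, one convolution per block) trains in minutes on one CPU
#' core, while `"paper_scale"` (256-px inputs, depth 4, 32 base filters,
#' classic double-convolution blocks) reproduces the full-size model
#' with on the order of 2e7 parameters. Inputs of any resolution are
#' resized to `input_size` on entry and predictions resized back on
#' exit.
#'
#' @param preset `"desk"` (default) or `"paper_scale"`.
#' @param input_size Square model input resolution in pixels; must be
#'   divisible by `2^depth`.
#' @param kernel_width Convolution kernel size (odd).
#' @param depth Number of pooling levels.
#' @param base_filters Channels of the first encoder block; doubles per
#'   level.
#' @param conv_per_block Convolutions per encoder/decoder block (2 =
#'   classic double-convolution blocks; the desk preset uses 1).
#' @param batch_size,samples_per_epoch,learning_rate,early_stop_patience
#'   Optimization constants (see Description).
#' @param max_epochs Per-round epoch cap.
#' @param rho,epsilon RMSProp decay and stabilizer.
#' @param binarize_threshold Confidence threshold used when binary output
#'   is needed (prediction masks, per-item F-scores).
#' @param seed Seed for weight initialization and epoch sampling.
#' @return A `train_config` object (list).
#' @export
train_config <- function(preset = c("desk", "paper_scale"),
                         input_size = NULL, kernel_width = 5,
                         depth = NULL, base_filters = NULL,
                         conv_per_block = NULL,
                         batch_size = 40, samples_per_epoch = 200,
                         learning_rate = 1e-4, early_stop_patience = 7,
                         max_epochs = 40, rho = 0.9, epsilon = 1e-8,
                         binarize_threshold = 0.5, seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    desk = list(input_size = 64L, depth = 3L, base_filters = 6L,
                conv_per_block = 1L),
    paper_scale = list(input_size = 256L, depth = 4L, base_filters = 32L,
                       conv_per_block = 2L)
  )
  if (is.null(input_size)) input_size <- defaults$input_size
  if (is.null(depth)) depth <- defaults$depth
  if (is.null(base_filters)) base_filters <- defaults$base_filters
  if (is.null(conv_per_block)) conv_per_block <- defaults$conv_per_block
  stopifnot(input_size >= 1, kernel_width >= 1, kernel_width %% 2 == 1,
            depth >= 1, base_filters >= 1, conv_per_block >= 1,
            batch_size >= 1, samples_per_epoch >= 1, learning_rate > 0,
            early_stop_patience >= 1, max_epochs >= 1)
  if (input_size %% 2^depth != 0) {
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  }
  structure(
    list(preset = preset, input_size = as.integer(input_size),
         kernel_width = as.integer(kernel_width), depth = as.integer(depth),
         base_filters = as.integer(base_filters),
         conv_per_block = as.integer(conv_per_block),
         batch_size = as.integer(batch_size),
         samples_per_epoch = as.integer(samples_per_epoch),
         learning_rate = learning_rate,
         early_stop_patience = as.integer(early_stop_patience),
         max_epochs = as.integer(max_epochs), rho = rho, epsilon = epsilon,
         binarize_threshold = binarize_threshold, seed = as.integer(seed)),
    class = "train_config"
  )
}

new_conv <- function(k, cin, cout) {
  # He-scaled fan-in initialization; biases start at zero
  list(W = matrix(stats::rnorm(k * k * cin * cout,
                               sd = sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

#' Build the encoder-decoder segmentation model
#'
#' Symmetric U-shaped network: `depth` encoder blocks (each
#' `conv_per_block` convolutions with ReLU, then 2x2 max pooling), a
#' bottleneck block, and mirrored decoder blocks (2x nearest-neighbour
#' upsampling, concatenation with the same-level encoder activation --
#' the skip connection -- then convolutions), closed by a 1x1 convolution
#' and a sigmoid that yields a per-pixel confidence in `[0, 1]`.
#'
#' @param config A [train_config()].
#' @return An object of class `ga_unet` holding the flat convolution
#'   parameter list, the block structure, and the config.
#' @examples
#' m <- build_model(train_config(seed = 1))
#' n_parameters(m)
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "train_config"))
  withr::local_seed(config$seed)
  depth <- config$depth
  k <- config$kernel_width
  ch <- config$base_filters * 2^(0:(depth - 1))
  cb <- config$base_filters * 2^depth
  convs <- list()
  idx <- function(n_new) (length(convs) + 1):(length(convs) + n_new)
  add_block <- function(cin, cout) {
    ids <- idx(config$conv_per_block)
    convs[[ids[1]]] <<- new_conv(k, cin, cout)
    if (config$conv_per_block > 1) {
      for (t in ids[-1]) convs[[t]] <<- new_conv(k, cout, cout)
    }
    ids
  }
  enc <- vector("list", depth)
  cin <- 1L
  for (i in seq_len(depth)) {
    enc[[i]] <- add_block(cin, ch[i])
    cin <- ch[i]
  }
  bott <- add_block(ch[depth], cb)
  dec <- vector("list", depth)
  cab <- cb
  for (i in depth:1) {
    dec[[i]] <- add_block(cab + ch[i], ch[i])
    cab <- ch[i]
  }
  final_conv <- new_conv(1L, ch[1], 1L)
  # start the output near a typical lesion prevalence rather than 0.5:
  # standard bias initialization for class-imbalanced segmentation, which
  # removes the long calibration ramp at this low learning rate
  final_conv$b[] <- stats::qlogis(0.1)
  convs[[length(convs) + 1]] <- final_conv
  structure(
    list(convs = convs,
         blocks = list(enc = enc, bott = bott, dec = dec,
                       final = length(convs)),
         ch = ch, cb = cb, config = config, trained = FALSE),
    class = "ga_unet"
  )
}

#' Number of trainable parameters
#' @param model A `ga_unet`.
#' @return Integer-valued count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$convs, function(cv) length(cv$W) + length(cv$b), 0))
}

#' @export
print.ga_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ga_unet:%s> input %dpx, depth %d, base %d, %s parameters%s\n",
    cfg$preset, cfg$input_size, cfg$depth, cfg$base_filters,
    format(n_parameters(x), big.mark = ","),
    if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

relu_ <- function(z) { z[z < 0] <- 0; z }

conv_forward <- function(cv, x, H, W) {
  cpp_conv_fwd(x, cv$W, cv$b, H, W, cv$cin, cv$cout, cv$k)
}

# Forward pass over a flattened input (length input_size^2); returns the
# sigmoid confidence vector and, when cache = TRUE, everything backward
# needs (per-conv inputs and pre-activations, pooling argmaxes).
unet_forward <- function(model, x, cache = FALSE) {
  cfg <- model$config
  H <- cfg$input_size
  W <- H
  depth <- cfg$depth
  cc <- list(convs = vector("list", length(model$convs)),
             pools = vector("list", depth), skips = vector("list", depth))
  a <- as.numeric(x)
  run_block <- function(ids, a, H, W) {
    for (ci in ids) {
      z <- conv_forward(model$convs[[ci]], a, H, W)
      if (cache) cc$convs[[ci]] <<- list(input = a, z = z)
      a <- relu_(z)
    }
    a
  }
  for (i in seq_len(depth)) {
    a <- run_block(model$blocks$enc[[i]], a, H, W)
    cc$skips[[i]] <- a
    p <- cpp_maxpool2(a, H, W, model$ch[i])
    if (cache) cc$pools[[i]] <- p$argmax
    a <- p$values
    H <- H / 2; W <- W / 2
  }
  a <- run_block(model$blocks$bott, a, H, W)
  for (i in depth:1) {
    cup <- if (i == depth) model$cb else model$ch[i + 1]
    a <- cpp_upsample2(a, H, W, cup)
    H <- H * 2; W <- W * 2
    a <- c(a, cc$skips[[i]])
    a <- run_block(model$blocks$dec[[i]], a, H, W)
  }
  fi <- model$blocks$final
  zf <- conv_forward(model$convs[[fi]], a, H, W)
  if (cache) cc$convs[[fi]] <- list(input = a, z = zf)
  p <- 1 / (1 + exp(-zf))
  if (cache) list(p = p, cache = cc) else list(p = p)
}

# Backward pass for binary cross-entropy; returns flat gradient lists
# (gW, gb) aligned with model$convs.
unet_backward <- function(model, fw, target) {
  cfg <- model$config
  depth <- cfg$depth
  n_out <- length(fw$p)
  gW <- vector("list", length(model$convs))
  gb <- vector("list", length(model$convs))
  block_backward <- function(ids, da, H, W) {
    for (ci in rev(ids)) {
      cv <- model$convs[[ci]]
      cz <- model_cache$convs[[ci]]
      dz <- da * (cz$z > 0)
      g <- cpp_conv_bwd_weights(cz$input, dz, H, W, cv$cin, cv$cout, cv$k)
      gW[[ci]] <<- g$dW
      gb[[ci]] <<- g$db
      da <- cpp_conv_bwd_input(dz, cv$W, H, W, cv$cin, cv$cout, cv$k)
    }
    da
  }
  model_cache <- fw$cache
  fi <- model$blocks$final
  fcv <- model$convs[[fi]]
  dzf <- (fw$p - target) / n_out
  gfin <- cpp_conv_bwd_weights(model_cache$convs[[fi]]$input, dzf,
                               cfg$input_size, cfg$input_size,
                               fcv$cin, fcv$cout, fcv$k)
  gW[[fi]] <- gfin$dW
  gb[[fi]] <- gfin$db
  da <- cpp_conv_bwd_input(dzf, fcv$W, cfg$input_size, cfg$input_size,
                           fcv$cin, fcv$cout, fcv$k)
  H <- cfg$input_size; W <- H
  skip_grads <- vector("list", depth)
  for (i in 1:depth) {
    bb_ids <- model$blocks$dec[[i]]
    # gradient through decoder block i at resolution H/2^(i-1)... track dims
    Hd <- cfg$input_size / 2^(i - 1)
    Wd <- Hd
    da <- block_backward(bb_ids, da, Hd, Wd)
    cup <- if (i == depth) model$cb else model$ch[i + 1]
    nup <- Hd * Wd * cup
    skip_grads[[i]] <- da[-seq_len(nup)]
    da <- cpp_upsample2_backward(da[seq_len(nup)], Hd / 2, Wd / 2, cup)
  }
  Hb <- cfg$input_size / 2^depth
  da <- block_backward(model$blocks$bott, da, Hb, Hb)
  for (j in depth:1) {
    Hj <- cfg$input_size / 2^(j - 1)
    da <- cpp_maxpool2_backward(da, model_cache$pools[[j]], Hj, Hj,
                                model$ch[j]) + skip_grads[[j]]
    da <- block_backward(model$blocks$enc[[j]], da, Hj, Hj)
  }
  list(gW = gW, gb = gb)
}

bce_loss <- function(p, target) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Predict a confidence map for one image
#'
#' The image is resized (bilinear) to the model's input resolution and
#' standardized to zero mean / unit variance; the returned confidence map
#' is resized back to the image's native resolution by bilinear
#' interpolation, which places the eventual 0.5-threshold boundary at
#' sub-model-grid precision instead of snapping it to model-grid cells.
#'
#' @param object A `ga_unet`.
#' @param image Numeric matrix (any resolution).
#' @param ... Unused.
#' @return Numeric matrix of per-pixel confidences in `[0, 1]`, same shape
#'   as `image`.
#' @export
predict.ga_unet <- function(object, image, ...) {
  s <- object$config$input_size
  x <- standardize_image(resize_bilinear(image, s, s))
  p <- unet_forward(object, x)$p
  pmin(pmax(resize_bilinear(matrix(p, s, s), nrow(image), ncol(image)),
            0), 1)
}

standardize_image <- function(m) {
  sdv <- stats::sd(m)
  if (sdv == 0) sdv <- 1
  (m - mean(m)) / sdv
}
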