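#' Configuration of the 1D residual network
#'
#' The architecture is a spectral ResNet: an initial strided convolution
#' (stem), six residual blocks of four convolutions each, and a fully
#' connected two-class head. Downsampling by stride 2 happens once in the
#' stem and once in the first convolution of every block (seven halvings in
#' the default configuration), with a strided 1x1 projection on each
#' shortcut. The default channel width of 100 puts the model at about 1.27
#' million parameters, matching the published parameter budget of the
#' architecture this follows.
#'
#' @param input_length Number of spectral points (default 1174).
#' @param initial_filters Channels out of the stem convolution.
#' @param block_channels Integer vector of channels per residual block
#'   (length `n_blocks`).
#' @param kernel_size Convolution kernel size (odd; default 5).
#' @param downsample_stride Stride of the downsampling convolutions.
#' @param n_blocks Number of residual blocks (default 6).
#' @param convs_per_block Convolutions per block (default 4).
#' @param n_classes Output classes (binary head by default).
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_length = 1174, initial_filters = 100,
                         block_channels = rep(100L, 6), kernel_size = 5,
                         downsample_stride = 2, n_blocks = 6,
                         convs_per_block = 4, n_classes = 2) {
  if (kernel_size %% 2 != 1) stop("invalid config: kernel_size must be odd")
  if (length(block_channels) == 1)
    block_channels <- rep(block_channels, n_blocks)
  if (length(block_channels) != n_blocks)
    stop("invalid config: block_channels must have n_blocks entries")
  n_down <- n_blocks + 1L
  min_len <- downsample_stride^n_down
  if (input_length < min_len)
    stop(sprintf("input_length %d too short for %d stride-%d stages (minimum %d)",
                 input_length, n_down, downsample_stride, min_len))
  structure(list(input_length = as.integer(input_length),
                 initial_filters = as.integer(initial_filters),
                 block_channels = as.integer(block_channels),
                 kernel_size = as.integer(kernel_size),
                 downsample_stride = as.integer(downsample_stride),
                 n_blocks = as.integer(n_blocks),
                 convs_per_block = as.integer(convs_per_block),
                 n_classes = as.integer(n_classes)),
            class = "model_config")
}

# Feature lengths after the stem and after each block (iterated ceil(L/s)).
feature_lengths <- function(config) {
  pad <- (config$kernel_size - 1L) %/% 2L
  lens <- integer(config$n_blocks + 1L)
  l <- config$input_length
  for (i in seq_len(config$n_blocks + 1L)) {
    l <- conv_out_len(l, config$kernel_size, config$downsample_stride, pad)
    lens[i] <- l
  }
  lens
}

he_init <- function(n_out, fan_in) {
  matrix(stats::rnorm(n_out * fan_in, 0, sqrt(2 / fan_in)), n_out, fan_in)
}

#' Build a randomly initialized 1D ResNet
#'
#' Parameters live in a flat named list; names are prefixed by their group
#' (`stem`, `block_1` ... `block_6`, `head`) so that groups can be frozen or
#' adapted selectively. Batch-normalization affine parameters are
#' additionally addressable as one set via [bn_parameter_names()].
#'
#' @param config A [model_config()].
#' @param seed Integer seed; same seed, same initialization.
#' @return An object of class `resnet1d` with fields `config`, `params`,
#'   `buffers` (batch-norm running statistics), `groups`.
#' @export
build_resnet1d <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "model_config"))
  k <- config$kernel_size
  withr::with_seed(seed, {
    params <- list(); buffers <- list(); groups <- list()
    add_bn <- function(prefix, C) {
      params[[paste0(prefix, ".gamma")]] <<- rep(1, C)
      params[[paste0(prefix, ".beta")]] <<- rep(0, C)
      buffers[[paste0(prefix, ".mean")]] <<- rep(0, C)
      buffers[[paste0(prefix, ".var")]] <<- rep(1, C)
    }
    f0 <- config$initial_filters
    params[["stem.conv.W"]] <- he_init(f0, 1L * k)
    add_bn("stem.bn", f0)
    groups$stem <- grep("^stem\\.", names(params), value = TRUE)
    c_prev <- f0
    for (b in seq_len(config$n_blocks)) {
      cb <- config$block_channels[b]
      pre <- sprintf("block_%d", b)
      before <- names(params)
      for (j in seq_len(config$convs_per_block)) {
        cin <- if (j == 1) c_prev else cb
        params[[sprintf("%s.conv_%d.W", pre, j)]] <- he_init(cb, cin * k)
        add_bn(sprintf("%s.bn_%d", pre, j), cb)
      }
      params[[sprintf("%s.short.W", pre)]] <- he_init(cb, c_prev * 1L)
      add_bn(sprintf("%s.bn_s", pre), cb)
      groups[[pre]] <- setdiff(names(params), before)
      c_prev <- cb
    }
    l_final <- utils::tail(feature_lengths(config), 1)
    params[["head.W"]] <- matrix(
      stats::rnorm(config$n_classes * c_prev * l_final, 0,
                   sqrt(1 / (c_prev * l_final))),
      config$n_classes, c_prev * l_final)
    params[["head.b"]] <- rep(0, config$n_classes)
    groups$head <- c("head.W", "head.b")
    structure(list(config = config, params = params, buffers = buffers,
                   groups = groups), class = "resnet1d")
  })
}

#' @export
print.resnet1d <- function(x, ...) {
  cat(sprintf("resnet1d: input %d, %d blocks, channels %s, %s parameters\n",
              x$config$input_length, x$config$n_blocks,
              paste(unique(x$config$block_channels), collapse = "/"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Names of all batch-normalization affine parameters
#'
#' @param model A `resnet1d`.
#' @return Character vector of parameter names (`*.gamma`, `*.beta`).
#' @export
bn_parameter_names <- function(model) {
  grep("\\.bn[^.]*\\.(gamma|beta)$", names(model$params), value = TRUE)
}

#' Count model parameters
#'
#' @param model A `resnet1d`.
#' @param trainable_only Count only parameters in `trainable_groups`.
#' @param trainable_groups Group names considered trainable (used with
#'   `trainable_only`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, trainable_only = FALSE,
                             trainable_groups = NULL) {
  nms <- names(model$params)
  if (trainable_only) {
    if (is.null(trainable_groups)) stop("trainable_groups required")
    unknown <- setdiff(trainable_groups, names(model$groups))
    if (length(unknown) > 0)
      stop(sprintf("unknown group(s): %s (valid: %s)",
                   paste(unknown, collapse = ", "),
                   paste(names(model$groups), collapse = ", ")))
    nms <- unlist(model$groups[trainable_groups], use.names = FALSE)
  }
  sum(vapply(model$params[nms], length, 1L))
}

# --- forward / backward -------------------------------------------------

# mode: "train" (batch statistics, running buffers updated),
#       "eval" (running buffers used, treated as constants),
#       "fixed" (statistics from `stats_override`, treated as constants;
#                used by test-time adaptation with patient-batch statistics)
#
# from_stage: 1 = stem, 1 + b = block_b. When from_stage > 1, `x_batch` is
# an activation array (channels, length, batch) produced by
# `resnet_features()` — used to train on a frozen, precomputed feature
# extractor without re-running it.
resnet_forward <- function(model, x_batch, mode = "eval",
                           stats_override = NULL, want_cache = FALSE,
                           momentum = 0.1, from_stage = 1L) {
  cfg <- model$config
  s <- cfg$downsample_stride
  if (from_stage == 1L) {
    if (ncol(x_batch) != cfg$input_length)
      stop(sprintf("spectrum length mismatch: expected %d, got %d",
                   cfg$input_length, ncol(x_batch)))
    x <- array(t(x_batch), c(1L, cfg$input_length, nrow(x_batch)))
  } else {
    stopifnot(length(dim(x_batch)) == 3)
    x <- x_batch
  }
  caches <- list()
  buffers <- model$buffers
  p <- model$params

  run_bn <- function(prefix, h) {
    if (mode == "train") {
      st <- bn_batch_stats(h)
      m_use <- st$mean; v_use <- st$var
      nn <- st$n
      unb <- if (nn > 1) st$var * nn / (nn - 1) else st$var
      buffers[[paste0(prefix, ".mean")]] <<-
        (1 - momentum) * buffers[[paste0(prefix, ".mean")]] + momentum * st$mean
      buffers[[paste0(prefix, ".var")]] <<-
        (1 - momentum) * buffers[[paste0(prefix, ".var")]] + momentum * unb
    } else if (mode == "fixed" && !is.null(stats_override[[paste0(prefix, ".mean")]])) {
      m_use <- stats_override[[paste0(prefix, ".mean")]]
      v_use <- stats_override[[paste0(prefix, ".var")]]
    } else {
      m_use <- buffers[[paste0(prefix, ".mean")]]
      v_use <- buffers[[paste0(prefix, ".var")]]
    }
    bn <- bn_forward(h, p[[paste0(prefix, ".gamma")]],
                     p[[paste0(prefix, ".beta")]], m_use, v_use)
    if (want_cache) caches[[prefix]] <<- list(xhat = bn$xhat, inv_sd = bn$inv_sd)
    bn$y
  }
  run_conv <- function(name, h, stride) {
    W <- p[[paste0(name, ".W")]]
    kk <- ncol(W) %/% dim(h)[1]
    cv <- conv1d_forward(h, W, stride, (kk - 1L) %/% 2L)
    if (want_cache) caches[[name]] <<- list(cols = cv$cols, x_dim = dim(h))
    cv$y
  }
  run_relu <- function(name, h) {
    rl <- relu_forward(h)
    if (want_cache) caches[[name]] <<- rl$mask
    rl$y
  }

  h <- x
  if (from_stage <= 1L) {
    h <- run_conv("stem.conv", h, s)
    h <- run_bn("stem.bn", h)
    h <- run_relu("stem.relu", h)
  }
  for (b in seq_len(cfg$n_blocks)) {
    if (b + 1L < from_stage) next
    pre <- sprintf("block_%d", b)
    inp <- h
    for (j in seq_len(cfg$convs_per_block)) {
      h <- run_conv(sprintf("%s.conv_%d", pre, j), h, if (j == 1) s else 1L)
      h <- run_bn(sprintf("%s.bn_%d", pre, j), h)
      if (j < cfg$convs_per_block) h <- run_relu(sprintf("%s.relu_%d", pre, j), h)
    }
    sc <- run_conv(sprintf("%s.short", pre), inp, s)
    sc <- run_bn(sprintf("%s.bn_s", pre), sc)
    h <- run_relu(sprintf("%s.relu_out", pre), h + sc)
  }
  d <- dim(h)
  h_flat <- matrix(h, d[1] * d[2], d[3])
  if (want_cache) caches[["head.in_dim"]] <- d
  logits <- linear_forward(h_flat, p[["head.W"]], p[["head.b"]])
  if (want_cache) caches[["head.x"]] <- h_flat
  list(logits = logits, caches = if (want_cache) caches else NULL,
       buffers = buffers)
}

# bn_mode: "train" uses the full batch-norm backward; "fixed"/"eval" treat
# normalization statistics as constants (affine-only adaptation).
# to_stage: stop descending below this stage (1 = stem, 1 + b = block_b);
# gradients w.r.t. the input of the stopping stage are never computed.
resnet_backward <- function(model, caches, dlogits, bn_mode = "train",
                            to_stage = 1L) {
  cfg <- model$config
  p <- model$params
  s <- cfg$downsample_stride
  grads <- list()
  bn_back <- if (bn_mode == "train") bn_backward_train else bn_backward_eval

  grads[["head.W"]] <- tcrossprod(dlogits, caches[["head.x"]])
  grads[["head.b"]] <- rowSums(dlogits)
  dh <- crossprod(p[["head.W"]], dlogits)
  dim(dh) <- caches[["head.in_dim"]]

  back_bn <- function(prefix, dh) {
    r <- bn_back(dh, caches[[prefix]], p[[paste0(prefix, ".gamma")]])
    grads[[paste0(prefix, ".gamma")]] <<- r$dgamma
    grads[[paste0(prefix, ".beta")]] <<- r$dbeta
    r$dx
  }
  back_conv <- function(name, dh, stride, need_dx = TRUE) {
    cc <- caches[[name]]
    W <- p[[paste0(name, ".W")]]
    kk <- ncol(W) %/% cc$x_dim[1]
    r <- conv1d_backward(dh, cc$cols, W, cc$x_dim, stride,
                         (kk - 1L) %/% 2L, need_dx)
    grads[[paste0(name, ".W")]] <<- r$dW
    if (need_dx) r$dx else NULL
  }

  for (b in rev(seq_len(cfg$n_blocks))) {
    stage <- b + 1L
    if (stage < to_stage) break
    at_boundary <- (stage == to_stage)
    pre <- sprintf("block_%d", b)
    dh <- relu_backward(dh, caches[[sprintf("%s.relu_out", pre)]])
    dsc <- back_bn(sprintf("%s.bn_s", pre), dh)
    dinp <- back_conv(sprintf("%s.short", pre), dsc, s,
                      need_dx = !at_boundary)
    dmain <- dh
    for (j in rev(seq_len(cfg$convs_per_block))) {
      if (j < cfg$convs_per_block)
        dmain <- relu_backward(dmain, caches[[sprintf("%s.relu_%d", pre, j)]])
      dmain <- back_bn(sprintf("%s.bn_%d", pre, j), dmain)
      dmain <- back_conv(sprintf("%s.conv_%d", pre, j), dmain,
                         if (j == 1) s else 1L,
                         need_dx = !(at_boundary && j == 1))
    }
    if (at_boundary) return(grads)
    dh <- dmain + dinp
  }
  dh <- relu_backward(dh, caches[["stem.relu"]])
  dh <- back_bn("stem.bn", dh)
  back_conv("stem.conv", dh, s, need_dx = FALSE)
  grads
}

# Evaluation-mode activations at the input of `stage` (2 = input of
# block_1, ..., 7 = input of block_6); used to precompute the frozen feature
# extractor once during efficient fine-tuning.
resnet_features <- function(model, x_batch, upto_stage) {
  cfg <- model$config
  stopifnot(upto_stage >= 2, upto_stage <= cfg$n_blocks + 1L)
  if (ncol(x_batch) != cfg$input_length)
    stop(sprintf("spectrum length mismatch: expected %d, got %d",
                 cfg$input_length, ncol(x_batch)))
  s <- cfg$downsample_stride
  p <- model$params
  x <- array(t(x_batch), c(1L, cfg$input_length, nrow(x_batch)))
  run_bn_eval <- function(prefix, h) {
    bn_forward(h, p[[paste0(prefix, ".gamma")]], p[[paste0(prefix, ".beta")]],
               model$buffers[[paste0(prefix, ".mean")]],
               model$buffers[[paste0(prefix, ".var")]])$y
  }
  run_conv <- function(name, h, stride) {
    W <- p[[paste0(name, ".W")]]
    kk <- ncol(W) %/% dim(h)[1]
    conv1d_forward(h, W, stride, (kk - 1L) %/% 2L)$y
  }
  h <- run_conv("stem.conv", x, s)
  h <- run_bn_eval("stem.bn", h)
  h <- relu_forward(h)$y
  b <- 1L
  while (b + 1L < upto_stage) {
    pre <- sprintf("block_%d", b)
    inp <- h
    for (j in seq_len(cfg$convs_per_block)) {
      h <- run_conv(sprintf("%s.conv_%d", pre, j), h, if (j == 1) s else 1L)
      h <- run_bn_eval(sprintf("%s.bn_%d", pre, j), h)
      if (j < cfg$convs_per_block) h <- relu_forward(h)$y
    }
    sc <- run_conv(sprintf("%s.short", pre), inp, s)
    sc <- run_bn_eval(sprintf("%s.bn_s", pre), sc)
    h <- relu_forward(h + sc)$y
    b <- b + 1L
  }
  h
}

#' Predict class probabilities
#'
#' Runs the network in evaluation mode (stored running normalization
#' statistics, no state mutated) and returns the softmax class distribution
#' per spectrum.
#'
#' @param model A `resnet1d`.
#' @param spectra Numeric matrix, measurements x `input_length`.
#' @return Matrix (measurements x classes) of probabilities; columns
#'   `normal` and `cancer` for the binary head. Rows sum to 1.
#' @export
predict_proba <- function(model, spectra) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, 1)
  out <- resnet_forward(model, spectra, mode = "eval")
  pr <- t(softmax_cols(out$logits))
  colnames(pr) <- if (ncol(pr) == 2) c("normal", "cancer")
                  else paste0("class_", seq_len(ncol(pr)))
  rownames(pr) <- rownames(spectra)
  pr
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the format version, the
#' model configuration, all parameters, the batch-norm running statistics and
#' the parameter-group name map, so that freezing and adaptation behave
#' identically after a round trip.
#'
#' @param model A `resnet1d`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `resnet1d`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "resnet1d"))
  saveRDS(list(format = "ramanadapt-checkpoint", version = 1L,
               config = model$config, params = model$params,
               buffers = model$buffers, groups = model$groups), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config Optional [model_config()]; if supplied, it must match the
#'   checkpoint's configuration (differing fields are listed in the error).
#' @export
load_checkpoint <- function(path, config = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ramanadapt-checkpoint"))
    stop("not a ramanadapt checkpoint file")
  if (!is.null(config)) {
    diffs <- names(config)[!vapply(names(config), function(f)
      identical(config[[f]], obj$config[[f]]), TRUE)]
    if (length(diffs) > 0)
      stop(sprintf("checkpoint config mismatch in field(s): %s",
                   paste(diffs, collapse = ", ")))
  }
  structure(list(config = obj$config, params = obj$params,
                 buffers = obj$buffers, groups = obj$groups),
            class = "resnet1d")
}
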