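#' Training configuration
#'
#' Defaults follow the study protocol: up to 25 epochs with early stopping
#' after 8 consecutive epochs without improvement in validation accuracy,
#' Adam at learning rate 0.001, binary cross-entropy loss.
#'
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   accuracy improvement); must not exceed `max_epochs`.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for shuffling and splits.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 25, patience = 8, learning_rate = 0.001,
                         batch_size = 32, seed = 1) {
  if (patience > max_epochs) stop("invalid config: patience must be <= max_epochs")
  if (learning_rate <= 0) stop("invalid config: learning_rate must be > 0")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Fine-tuning configuration (half-frozen transfer)
#'
#' The early feature extractor (stem and first three residual blocks) stays
#' frozen; the last three residual blocks and the fully connected head are
#' adapted. This halves the trainable parameter count and curbs overfitting
#' on small target cohorts.
#'
#' @inheritParams train_config
#' @param frozen_groups Parameter-group names kept bitwise unchanged.
#' @param trainable_groups Parameter-group names to adapt.
#' @param frozen_bn `"adapt"` (default): batch-normalization layers inside
#'   frozen groups keep their affine parameters frozen but still normalize
#'   with batch statistics and update their running statistics during
#'   fine-tuning, so the frozen feature extractor recalibrates to the target
#'   intensity statistics (the standard deep-learning-framework behaviour of
#'   freezing only learnable parameters). `"freeze"`: the frozen prefix acts
#'   as a fully fixed feature extractor in evaluation mode (its activations
#'   are precomputed once; fastest, but no statistic recalibration).
#' @return An object of class `finetune_config` (also a `train_config`).
#' @export
finetune_config <- function(frozen_groups = c("stem", "block_1", "block_2",
                                              "block_3"),
                            trainable_groups = c("block_4", "block_5",
                                                 "block_6", "head"),
                            max_epochs = 25, patience = 8,
                            learning_rate = 0.001, batch_size = 32, seed = 1,
                            frozen_bn = c("adapt", "freeze")) {
  if (length(intersect(frozen_groups, trainable_groups)) > 0)
    stop("invalid config: frozen and trainable groups overlap")
  cfg <- train_config(max_epochs, patience, learning_rate, batch_size, seed)
  cfg$frozen_groups <- frozen_groups
  cfg$trainable_groups <- trainable_groups
  cfg$frozen_bn <- match.arg(frozen_bn)
  class(cfg) <- c("finetune_config", "train_config")
  cfg
}

# Extract the model inputs from a labelled cohort.
cohort_xy <- function(cohort) {
  y <- cohort$meta$label
  if (any(is.na(y))) stop("cohort contains unlabelled spectra")
  list(x = cohort$intensities, y = as.integer(y),
       patients = cohort$meta$patient_id)
}

# Patient-level stratified split: patients are assigned to partitions so no
# patient spans two partitions; stratification is on the patient-majority
# label so each partition sees both classes where possible.
split_patients <- function(patients, labels, fractions, seed) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  pt <- unique(patients)
  maj <- vapply(pt, function(p) {
    as.integer(round(mean(labels[patients == p])))
  }, 1L)
  withr::with_seed(seed, {
    assign <- character(length(pt)); names(assign) <- pt
    part_names <- names(fractions)
    if (is.null(part_names)) part_names <- paste0("part", seq_along(fractions))
    for (cls in unique(maj)) {
      ids <- sample(pt[maj == cls])
      n <- length(ids)
      cuts <- round(cumsum(fractions) * n)
      start <- 1
      for (i in seq_along(fractions)) {
        if (cuts[i] >= start)
          assign[ids[start:cuts[i]]] <- part_names[i]
        start <- cuts[i] + 1
      }
    }
    assign
  })
}

snapshot_trainables <- function(model, names) model$params[names]

# Core supervised loop: Adam on the trainable groups, binary cross-entropy,
# early stopping on validation accuracy with best-weights restoration.
# Frozen groups keep both their parameters and their batch-norm running
# statistics untouched.
train_loop <- function(model, x_train, y_train, x_val, y_val, config,
                       trainable_groups) {
  unknown <- setdiff(trainable_groups, names(model$groups))
  if (length(unknown) > 0)
    stop(sprintf("unknown group(s): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(model$groups), collapse = ", ")))
  trainable <- unlist(model$groups[trainable_groups], use.names = FALSE)

  # first trainable stage (stem = 1, block_b = 1 + b, head after blocks);
  # gradients are never propagated below it. With frozen_bn = "freeze" the
  # frozen prefix acts in evaluation mode as a fixed feature extractor whose
  # activations are precomputed once; with the default "adapt" the frozen
  # blocks run in training mode so their batch-norm statistics recalibrate
  # to the target data (their affine parameters stay frozen).
  stage_of <- function(g) {
    if (g == "stem") 1L
    else if (grepl("^block_", g)) 1L + as.integer(sub("block_", "", g))
    else model$config$n_blocks + 2L
  }
  boundary <- min(vapply(trainable_groups, stage_of, 1L))
  boundary <- min(boundary, model$config$n_blocks + 1L)
  cache_features <- boundary > 1L && identical(config$frozen_bn, "freeze")
  from_stage <- if (cache_features) boundary else 1L
  if (cache_features) {
    x_train <- resnet_features(model, x_train, boundary)
    x_val <- resnet_features(model, x_val, boundary)
  }
  take <- function(x, idx) {
    if (cache_features) x[, , idx, drop = FALSE] else x[idx, , drop = FALSE]
  }

  opt <- adam_init(model$params[trainable])
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  best <- list(acc = -Inf, params = model$params, buffers = model$buffers,
               epoch = 0L)
  stall <- 0L
  n <- length(y_train)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        if (length(idx) < 2) next  # batch norm needs >= 2 samples
        fw <- resnet_forward(model, take(x_train, idx), mode = "train",
                             want_cache = TRUE, from_stage = from_stage)
        model$buffers <- fw$buffers
        lg <- ce_loss_grad(fw$logits, y_train[idx])
        losses <- c(losses, lg$loss)
        grads <- resnet_backward(model, fw$caches, lg$dlogits, "train",
                                 to_stage = boundary)
        upd <- adam_step(model$params, grads, opt, config$learning_rate,
                         trainable)
        model$params <- upd$params
        opt <- upd$state
      }
      fv <- resnet_forward(model, x_val, mode = "eval",
                           from_stage = from_stage)
      pv <- softmax_cols(fv$logits)
      val_acc <- mean((pv[2, ] >= 0.5) == (y_val == 1))
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_accuracy = val_acc))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, params = model$params,
                     buffers = model$buffers, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  model$params <- best$params
  model$buffers <- best$buffers
  attr(history, "best_epoch") <- best$epoch
  list(model = model, history = history)
}

#' Pre-train on source-domain cohorts
#'
#' Combines the source cohorts, splits them by patient into
#' training / validation / testing partitions (default 60/20/20, stratified
#' on patient-majority label, no patient in two partitions), and trains the
#' full network with binary cross-entropy under the early-stopping contract
#' of [train_config()]. The best-validation-accuracy weights are restored.
#'
#' @param model A `resnet1d` (randomly initialized or already pre-trained,
#'   for staged pre-training).
#' @param source_cohorts A `raman_cohort` or list of them (processed, on the
#'   model's input grid).
#' @param config A [train_config()].
#' @param split Fractions for train/validation/test (sum to 1).
#' @return List with `model`, `history` (per-epoch train loss and validation
#'   accuracy) and `test_metrics` (held-out source-domain metrics, `NULL`
#'   when the test fraction is 0).
#' @export
pretrain <- function(model, source_cohorts, config = train_config(),
                     split = c(train = 0.6, val = 0.2, test = 0.2)) {
  if (inherits(source_cohorts, "raman_cohort"))
    source_cohorts <- list(source_cohorts)
  stopifnot(length(source_cohorts) >= 1)
  combined <- do.call(bind_cohorts, source_cohorts)
  d <- cohort_xy(combined)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (is.null(names(split)))
    names(split) <- c("train", "val", "test")[seq_along(split)]
  parts <- split_patients(d$patients, d$y, split, config$seed)
  part_of <- parts[d$patients]
  part_names <- names(split)
  tr <- part_of == part_names[1]; va <- part_of == part_names[2]
  for (nm in part_names[split > 0]) {
    ys <- d$y[part_of == nm]
    if (length(unique(ys)) < 2)
      stop(sprintf("partition '%s' contains a single class; change the seed or split", nm))
  }
  fit <- train_loop(model, d$x[tr, , drop = FALSE], d$y[tr],
                    d$x[va, , drop = FALSE], d$y[va], config,
                    names(model$groups))
  test_metrics <- NULL
  if (length(part_names) >= 3 && split[3] > 0) {
    te <- part_of == part_names[3]
    pr <- predict_proba(fit$model, d$x[te, , drop = FALSE])
    test_metrics <- compute_metrics(pr[, 2], d$y[te])
  }
  list(model = fit$model, history = fit$history, test_metrics = test_metrics)
}

#' Efficient fine-tuning on a small labelled target cohort
#'
#' Adapts only `trainable_groups` (by default the last three residual blocks
#' and the head, about half of all parameters); frozen-group parameters and
#' their batch-norm running statistics remain bitwise unchanged. A
#' patient-level validation split drives the early-stopping contract.
#'
#' @param model A pre-trained `resnet1d`.
#' @param target_cohort Labelled `raman_cohort` on the model's input grid.
#' @param config A [finetune_config()].
#' @param val_fraction Fraction of patients held out as validation for early
#'   stopping.
#' @return List with `model` and `history`.
#' @export
finetune_efficient <- function(model, target_cohort,
                               config = finetune_config(),
                               val_fraction = 0.25) {
  d <- cohort_xy(target_cohort)
  parts <- split_patients(d$patients, d$y,
                          c(train = 1 - val_fraction, val = val_fraction),
                          config$seed)
  part_of <- parts[d$patients]
  tr <- part_of == "train"; va <- part_of == "val"
  if (!any(va)) { va <- tr; }  # degenerate tiny cohorts: validate on train
  fit <- train_loop(model, d$x[tr, , drop = FALSE], d$y[tr],
                    d$x[va, , drop = FALSE], d$y[va], config,
                    config$trainable_groups)
  list(model = fit$model, history = fit$history)
}

#' Train a model from random initialization on a target cohort
#'
#' Convenience comparator (no pre-training, all groups trainable).
#'
#' @param config_model A [model_config()].
#' @param target_cohort Labelled `raman_cohort`.
#' @param config A [train_config()].
#' @param seed Seed for the random initialization.
#' @param val_fraction Patient fraction held out for early stopping.
#' @return List with `model` and `history`.
#' @export
train_from_scratch <- function(config_model, target_cohort,
                               config = train_config(), seed = 1,
                               val_fraction = 0.25) {
  model <- build_resnet1d(config_model, seed)
  d <- cohort_xy(target_cohort)
  parts <- split_patients(d$patients, d$y,
                          c(train = 1 - val_fraction, val = val_fraction),
                          config$seed)
  part_of <- parts[d$patients]
  tr <- part_of == "train"; va <- part_of == "val"
  if (!any(va)) va <- tr
  fit <- train_loop(model, d$x[tr, , drop = FALSE], d$y[tr],
                    d$x[va, , drop = FALSE], d$y[va], config,
                    names(model$groups))
  list(model = fit$model, history = fit$history)
}
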