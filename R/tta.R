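#' Prediction entropy
#'
#' Shannon entropy of a class-probability distribution in natural log units,
#' with the convention 0 log 0 = 0. This is the unsupervised objective that
#' test-time adaptation minimizes.
#'
#' @param probabilities Nonnegative vector summing to 1 (tolerance 1e-6).
#' @return Nonnegative scalar entropy.
#' @export
entropy <- function(probabilities) {
  if (any(probabilities < -1e-12))
    stop("invalid probabilities: negative entries")
  if (abs(sum(probabilities) - 1) > 1e-6)
    stop("invalid probabilities: must sum to 1")
  p <- probabilities[probabilities > 0]
  -sum(p * log(p))
}

#' Test-time adaptation configuration
#'
#' @param n_steps Gradient steps per measurement (default 5).
#' @param learning_rate Adam learning rate during adaptation.
#' @param reset_policy `"per_patient"` (adaptation is cumulative across a
#'   patient's measurements, then discarded) or `"per_measurement"` (the
#'   model is restored after every measurement).
#' @param normalization_statistics `"running"` uses the stored running
#'   batch-norm statistics (stable for single-spectrum batches);
#'   `"patient_batch"` freezes statistics computed once from the patient's
#'   whole measurement batch (requires at least `min_batch` spectra, else
#'   falls back to running statistics).
#' @param min_batch Minimum patient batch size for `"patient_batch"`.
#' @param optimizer `"sgd"` (default; update size scales with the entropy
#'   gradient, so confident predictions are barely moved) or `"adam"`
#'   (normalized steps; more aggressive at equal learning rate).
#' @return An object of class `tta_config`.
#' @export
tta_config <- function(n_steps = 5, learning_rate = 0.001,
                       reset_policy = c("per_patient", "per_measurement"),
                       normalization_statistics = c("running", "patient_batch"),
                       min_batch = 8, optimizer = c("sgd", "adam")) {
  if (n_steps < 0) stop("invalid config: n_steps must be >= 0")
  structure(list(n_steps = as.integer(n_steps),
                 learning_rate = learning_rate,
                 reset_policy = match.arg(reset_policy),
                 normalization_statistics = match.arg(normalization_statistics),
                 min_batch = as.integer(min_batch),
                 optimizer = match.arg(optimizer)),
            class = "tta_config")
}

# Collect per-layer batch-norm statistics over a batch by running a
# training-mode forward pass and reading back the batch statistics.
collect_bn_stats <- function(model, x_batch) {
  cfg <- model$config
  # re-run forward in train mode with momentum 1 so the returned buffers are
  # exactly the batch statistics (biased variance wanted for normalization,
  # so undo the unbiased running-buffer convention)
  out <- resnet_forward(model, x_batch, mode = "train", momentum = 1)
  n <- nrow(x_batch)
  st <- out$buffers
  vnames <- grep("\\.var$", names(st), value = TRUE)
  for (nm in vnames) st[[nm]] <- st[[nm]] * (n - 1) / n
  st
}

#' Test-time adaptation of one patient's measurements
#'
#' Processes the patient's measurements in acquisition order. For each
#' measurement the prediction entropy is minimized for `n_steps` Adam steps,
#' updating only the fully connected head and the batch-normalization affine
#' parameters (normalization statistics stay fixed); the prediction is then
#' emitted. Under the default `per_patient` reset policy adaptation is
#' cumulative within the patient; the input model is never modified, so
#' adapting one patient cannot affect another patient's results.
#'
#' @param model A pre-trained `resnet1d` (left untouched).
#' @param measurements Numeric matrix (measurements x `input_length`) of one
#'   patient's spectra, or a single-patient `raman_cohort`.
#' @param config A [tta_config()].
#' @return An `adaptation_result`: list with `predictions` (measurements x
#'   classes probability matrix), `entropy_trace` (measurements x
#'   `n_steps + 1`, column 1 the pre-adaptation entropy), and
#'   `adapted_model` (state after the patient, for inspection).
#' @export
tta_adapt <- function(model, measurements, config = tta_config()) {
  if (inherits(measurements, "raman_cohort")) {
    if (length(unique(measurements$meta$patient_id)) > 1)
      stop("tta_adapt expects measurements from a single patient")
    measurements <- measurements$intensities
  }
  if (is.null(dim(measurements))) measurements <- matrix(measurements, 1)
  if (ncol(measurements) != model$config$input_length)
    stop(sprintf("spectrum length mismatch: expected %d, got %d",
                 model$config$input_length, ncol(measurements)))

  n <- nrow(measurements)
  adapted <- c(model$groups$head, bn_parameter_names(model))
  use_batch <- config$normalization_statistics == "patient_batch" &&
    n >= config$min_batch
  stats <- if (use_batch) collect_bn_stats(model, measurements) else NULL
  mode <- if (use_batch) "fixed" else "eval"

  work <- model
  opt <- adam_init(work$params[adapted])
  preds <- matrix(NA_real_, n, model$config$n_classes)
  trace <- matrix(NA_real_, n, config$n_steps + 1)

  for (i in seq_len(n)) {
    if (config$reset_policy == "per_measurement") {
      work$params <- model$params
      opt <- adam_init(work$params[adapted])
    }
    xi <- measurements[i, , drop = FALSE]
    for (s in 0:config$n_steps) {
      fw <- resnet_forward(work, xi, mode = mode, stats_override = stats,
                           want_cache = (s < config$n_steps))
      eg <- entropy_loss_grad(fw$logits)
      trace[i, s + 1] <- eg$H[1]
      if (s == config$n_steps) {
        preds[i, ] <- eg$p[, 1]
        break
      }
      grads <- resnet_backward(work, fw$caches, eg$dlogits, "eval")
      if (config$optimizer == "sgd") {
        for (nm in adapted) {
          if (!is.null(grads[[nm]]))
            work$params[[nm]] <- work$params[[nm]] -
              config$learning_rate * grads[[nm]]
        }
      } else {
        upd <- adam_step(work$params, grads, opt, config$learning_rate, adapted)
        work$params <- upd$params
        opt <- upd$state
      }
    }
  }
  colnames(preds) <- if (ncol(preds) == 2) c("normal", "cancer")
                     else paste0("class_", seq_len(ncol(preds)))
  rownames(preds) <- rownames(measurements)
  structure(list(predictions = preds, entropy_trace = trace,
                 adapted_model = work),
            class = "adaptation_result")
}

#' Test-time adaptation across a cohort, patient by patient
#'
#' Applies [tta_adapt()] independently to each patient (deterministic
#' patient order by id; the model is reset between patients) and returns
#' pooled predictions aligned with the cohort rows.
#'
#' @param model A pre-trained `resnet1d`.
#' @param cohort Target `raman_cohort`.
#' @param config A [tta_config()].
#' @return List with `predictions` (cohort-aligned probability matrix) and
#'   `traces` (per-patient entropy traces).
#' @export
tta_predict_cohort <- function(model, cohort, config = tta_config()) {
  stopifnot(inherits(cohort, "raman_cohort"))
  preds <- matrix(NA_real_, nrow(cohort$intensities), model$config$n_classes)
  rownames(preds) <- cohort$meta$sample_id
  traces <- list()
  for (pid in sort(unique(cohort$meta$patient_id))) {
    idx <- which(cohort$meta$patient_id == pid)
    res <- tta_adapt(model, cohort$intensities[idx, , drop = FALSE], config)
    preds[idx, ] <- res$predictions
    traces[[pid]] <- res$entropy_trace
  }
  colnames(preds) <- colnames(res$predictions)
  list(predictions = preds, traces = traces)
}
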