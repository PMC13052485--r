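#' Leave-one-patient-out fold plan
#'
#' One fold per patient: that patient's spectra form the test set, everyone
#' else trains. Deterministic ordering by patient id.
#'
#' @param cohort A `raman_cohort` with at least two patients.
#' @return An object of class `fold_plan`: list of folds, each with
#'   `train_patients` and `test_patient`.
#' @export
lopo_folds <- function(cohort) {
  stopifnot(inherits(cohort, "raman_cohort"))
  pts <- sort(unique(cohort$meta$patient_id))
  if (length(pts) < 2) stop("LOPO needs at least 2 patients")
  folds <- lapply(pts, function(p)
    list(train_patients = setdiff(pts, p), test_patient = p))
  structure(list(folds = folds, scheme = "lopo"), class = "fold_plan")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, with ties counted one half.
#'
#' @param scores Numeric scores (higher = more cancer-like).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold classification metrics plus AUC
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold (scores >= threshold predict cancer).
#' @return Named numeric vector `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, with the confusion counts as attribute
#'   `"confusion"`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  out <- c(auc = compute_auc(scores, labels),
           accuracy = (tp + tn) / (tp + tn + fp + fn),
           sensitivity = tp / (tp + fn),
           specificity = tn / (tn + fp),
           ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  attr(out, "confusion") <- c(TP = tp, FN = fn, TN = tn, FP = fp)
  out
}

#' Aggregate repeated-run metrics
#'
#' @param reports List (length >= 2) of named metric vectors, one per
#'   repetition.
#' @return List with `mean`, `sd` (sample SD over repetitions) and `values`
#'   (the retained per-repetition matrix).
#' @export
aggregate_repetitions <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 repetitions to aggregate")
  m <- do.call(rbind, reports)
  list(mean = colMeans(m), sd = apply(m, 2, stats::sd), values = m)
}

#' Compare two models on repetition-level metric values
#'
#' Welch's two-sample t-test on the per-repetition values with a 95%
#' confidence interval for the mean difference (a - b).
#'
#' @param values_a,values_b Numeric vectors (length >= 2) of one metric over
#'   repetitions.
#' @return List with `difference`, `t`, `p_value`, `ci` (lower, upper).
#' @export
compare_models <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  diff <- mean(values_a) - mean(values_b)
  if (stats::sd(values_a) < 1e-12 && stats::sd(values_b) < 1e-12) {
    p <- if (abs(diff) < 1e-12) 1 else 0
    return(list(difference = diff, t = if (p == 1) 0 else Inf, p_value = p,
                ci = c(diff, diff)))
  }
  tt <- stats::t.test(values_a, values_b)
  list(difference = diff, t = unname(tt$statistic), p_value = tt$p.value,
       ci = unname(tt$conf.int))
}

#' Univariate discriminatory analysis of individual Raman peaks
#'
#' For each peak: the standardized mean difference between classes (Cohen's
#' d, the distribution-distance measure), a Welch t-test p-value (cancer
#' versus normal peak intensities), the mean difference with its 95% CI, and
#' the single-feature AUC.
#'
#' @param cohort Labelled, preprocessed `raman_cohort`.
#' @param peaks Peak centers (numeric vector) or a [peak_feature_set()];
#'   defaults to the literature peak list.
#' @param window Half-window (cm^-1) for peak intensity extraction.
#' @return Data frame with one row per peak: `wavenumber`,
#'   `distribution_distance`, `p_value`, `mean_difference`, `ci_lower`,
#'   `ci_upper`, `auc`.
#' @export
univariate_peak_analysis <- function(cohort, peaks = default_peak_centers(),
                                     window = 4) {
  if (!inherits(peaks, "peak_feature_set"))
    peaks <- peak_feature_set("univariate", peaks)
  y <- cohort$meta$label
  if (length(unique(y)) < 2) stop("both classes must be present")
  feats <- extract_peak_features(cohort, peaks, window)
  rows <- lapply(seq_len(ncol(feats)), function(j) {
    xc <- feats[y == 1, j]; xn <- feats[y == 0, j]
    tt <- stats::t.test(xc, xn)
    sp <- sqrt(((length(xc) - 1) * stats::var(xc) +
                (length(xn) - 1) * stats::var(xn)) /
               (length(xc) + length(xn) - 2))
    data.frame(wavenumber = mean(range(peaks$wavenumbers[[j]])),
               distribution_distance = if (sp > 0) (mean(xc) - mean(xn)) / sp else 0,
               p_value = tt$p.value,
               mean_difference = mean(xc) - mean(xn),
               ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
               auc = compute_auc(feats[, j], y))
  })
  do.call(rbind, rows)
}

# --- benchmark harness --------------------------------------------------

#' Benchmark scenario configuration
#'
#' Defines the synthetic multi-domain study on which model variants are
#' compared: source cohorts for pre-training (abundant bacteria-like domain,
#' brain, breast, imbalanced retrospective prostate), a 10-patient prostate
#' target with an additional covariate shift, a reduced-width network, and
#' shortened training schedules sized for repeated desk-scale runs.
#'
#' @param variants Variant names: a pre-training tag from `no_p`, `pB`,
#'   `pC`, `pB+pC` (alias `p`), `pRP`, optionally combined with `+F`
#'   (half-frozen fine-tuning), `+TTA`, or `+F+TTA`; `scratch` (full training
#'   on the target folds, no pre-training); `svm`, `svm_invivo`,
#'   `svm_exvivo`, `rf`.
#' @param n_repetitions Independent repetitions (default 5).
#' @param seed Master seed; data, initializations and schedules all derive
#'   from it.
#' @param net Reduced-width [model_config()] used by all network variants.
#' @param pretrain_cfg,adapt_cfg Training configurations for pre-training
#'   and target-side training.
#' @param tta Test-time adaptation configuration (patient-batch
#'   normalization statistics by default, as every target patient
#'   contributes at least 7 measurements).
#' @param target_shift Covariate shift applied to the target domain on top
#'   of its preset (list with `baseline_scale`, `peak_shift`, `snr_scale`).
#' @param sizes Cohort sizes: named list of `c(n_patients, min_spectra,
#'   max_spectra)` for `bacteria`, `brain`, `breast`, `prostate_retro`,
#'   `target`.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(variants = c("scratch", "p", "p+F", "p+TTA",
                                          "svm", "rf"),
                             n_repetitions = 5, seed = 1,
                             net = model_config(input_length = 587,
                                                initial_filters = 12,
                                                block_channels = rep(12L, 6)),
                             pretrain_cfg = train_config(max_epochs = 20,
                                                         patience = 8,
                                                         batch_size = 32),
                             adapt_cfg = train_config(max_epochs = 10,
                                                      patience = 8,
                                                      batch_size = 32),
                             tta = tta_config(normalization_statistics =
                                                "patient_batch"),
                             target_shift = list(baseline_scale = 3,
                                                 peak_shift = 0,
                                                 snr_scale = 0.3),
                             sizes = list(bacteria = c(30, 8, 12),
                                          brain = c(16, 5, 10),
                                          breast = c(10, 5, 10),
                                          prostate_retro = c(16, 5, 10),
                                          target = c(10, 7, 18))) {
  known_tail <- c("", "+F", "+TTA", "+F+TTA")
  known_pre <- c("no_p", "pB", "pC", "pB+pC", "p", "pRP")
  valid <- c(outer(known_pre, known_tail, paste0), "scratch", "svm",
             "svm_invivo", "svm_exvivo", "rf")
  bad <- setdiff(variants, valid)
  if (length(bad) > 0)
    stop(sprintf("unknown variant(s): %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")))
  structure(list(variants = variants, n_repetitions = n_repetitions,
                 seed = as.integer(seed), net = net,
                 pretrain_cfg = pretrain_cfg, adapt_cfg = adapt_cfg,
                 tta = tta, target_shift = target_shift, sizes = sizes),
            class = "benchmark_config")
}

# benchmark preprocessing: the full deployed chain (cosmic-ray removal,
# averaging, BubbleFill baseline removal, normalization, resampling); the
# residual covariate shift the network sees comes from organ-specific band
# profiles plus baseline-removal artifacts that grow with the target's
# autofluorescence
benchmark_preprocess <- function(cohort, n_points) {
  preprocess_cohort(cohort, preprocess_config(
    target_grid = c(400, 2000, n_points)))
}

benchmark_data <- function(config) {
  s <- config$seed
  sz <- config$sizes
  gen <- function(preset, size, seed, shift = NULL) {
    spec <- domain_preset(preset)
    if (!is.null(shift))
      spec <- shift_domain(spec, shift$baseline_scale, shift$peak_shift,
                           shift$snr_scale)
    benchmark_preprocess(generate_cohort(spec, size[1], size[2:3], seed),
                         config$net$input_length)
  }
  list(bacteria = gen("bacteria_like", sz$bacteria, s * 11 + 1),
       brain = gen("brain", sz$brain, s * 11 + 2),
       breast = gen("breast", sz$breast, s * 11 + 3),
       prostate_retro = gen("prostate_retro", sz$prostate_retro, s * 11 + 4),
       target = gen("prostate_target", sz$target, s * 11 + 5,
                    config$target_shift))
}

parse_variant <- function(v) {
  if (v %in% c("scratch", "svm", "svm_invivo", "svm_exvivo", "rf"))
    return(list(kind = v))
  parts <- strsplit(v, "+", fixed = TRUE)[[1]]
  pre <- parts[1]
  if (identical(parts, c("pB", "pC")) || identical(parts[1:2], c("pB", "pC"))) {
    pre <- "pB+pC"; parts <- parts[-(1:2)]
  } else parts <- parts[-1]
  if (pre == "p") pre <- "pB+pC"
  list(kind = "cnn", pre = pre, finetune = "F" %in% parts,
       tta = "TTA" %in% parts)
}

# pre-train a network for one repetition under a given strategy tag
benchmark_pretrain <- function(pre, data, config, rep_seed) {
  cfg <- config$pretrain_cfg
  cfg$seed <- rep_seed
  model <- build_resnet1d(config$net, rep_seed)
  if (pre == "no_p") return(model)
  if (pre %in% c("pB", "pB+pC")) {
    model <- pretrain(model, data$bacteria, cfg, c(0.6, 0.2, 0.2))$model
  }
  if (pre %in% c("pC", "pB+pC")) {
    cfg$seed <- rep_seed + 1L
    model <- pretrain(model, list(data$brain, data$breast,
                                  data$prostate_retro), cfg,
                      c(0.6, 0.2, 0.2))$model
  }
  if (pre == "pRP") {
    model <- pretrain(model, data$prostate_retro, cfg, c(0.6, 0.2, 0.2))$model
  }
  model
}

lopo_scores_cnn <- function(variant, base_model, target, config, rep_seed) {
  plan <- lopo_folds(target)
  scores <- rep(NA_real_, nrow(target$intensities))
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    tr_idx <- target$meta$patient_id %in% fold$train_patients
    te_idx <- target$meta$patient_id == fold$test_patient
    train_cohort <- subset_cohort(target, tr_idx)
    if (variant$kind == "scratch") {
      cfg <- config$adapt_cfg; cfg$seed <- rep_seed + f
      m <- train_from_scratch(config$net, train_cohort, cfg,
                              seed = rep_seed + 100L + f)$model
    } else if (variant$finetune) {
      cfg <- finetune_config(max_epochs = config$adapt_cfg$max_epochs,
                             patience = config$adapt_cfg$patience,
                             learning_rate = config$adapt_cfg$learning_rate,
                             batch_size = config$adapt_cfg$batch_size,
                             seed = rep_seed + f)
      m <- finetune_efficient(base_model, train_cohort, cfg)$model
    } else {
      m <- base_model
    }
    xt <- target$intensities[te_idx, , drop = FALSE]
    if (isTRUE(variant$tta)) {
      scores[te_idx] <- tta_adapt(m, xt, config$tta)$predictions[, 2]
    } else {
      scores[te_idx] <- predict_proba(m, xt)[, 2]
    }
  }
  scores
}

lopo_scores_classical <- function(kind, target, rep_seed) {
  plan <- lopo_folds(target)
  scores <- rep(NA_real_, nrow(target$intensities))
  for (fold in plan$folds) {
    tr <- target$meta$patient_id %in% fold$train_patients
    te <- target$meta$patient_id == fold$test_patient
    ytr <- target$meta$label[tr]
    if (kind == "rf") {
      fit <- fit_rf(target$intensities[tr, , drop = FALSE], ytr,
                    seed = rep_seed)
      scores[te] <- predict(fit, target$intensities[te, , drop = FALSE])
    } else if (kind == "svm") {
      sel <- select_features_threestep(target$intensities[tr, , drop = FALSE],
                                       ytr)
      fit <- fit_svm(target$intensities[tr, sel, drop = FALSE], ytr)
      scores[te] <- predict(fit, target$intensities[te, sel, drop = FALSE])
    } else {
      set_name <- if (kind == "svm_invivo") "invivo" else "exvivo"
      ps <- literature_peak_sets()[[set_name]]
      ftr <- extract_peak_features(target$intensities[tr, , drop = FALSE],
                                   ps, wavenumbers = target$wavenumbers)
      fte <- extract_peak_features(target$intensities[te, , drop = FALSE],
                                   ps, wavenumbers = target$wavenumbers)
      fit <- fit_svm(ftr, ytr)
      scores[te] <- predict(fit, fte)
    }
  }
  scores
}

#' Run the model-comparison benchmark on the synthetic study
#'
#' For each repetition: pre-trains the requested strategies on the source
#' cohorts, evaluates every variant on the covariate-shifted 10-patient
#' target via leave-one-patient-out cross-validation (predictions pooled
#' across folds before computing metrics), and aggregates metrics over
#' repetitions as mean and SD, with Welch t-test comparisons against the SVM
#' baseline when present. Deterministic given the configuration.
#'
#' @param config A [benchmark_config()].
#' @return An `eval_report`: list with `report` (variant x metric mean/sd
#'   data frame), `values` (per-repetition metric matrices), `comparisons`
#'   (vs the `svm` variant, when requested) and `config`.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  data <- benchmark_data(config)
  target <- data$target
  y <- target$meta$label
  variants <- lapply(config$variants, parse_variant)
  names(variants) <- config$variants
  values <- lapply(config$variants, function(v) list())
  names(values) <- config$variants

  for (r in seq_len(config$n_repetitions)) {
    rep_seed <- config$seed * 1000L + r * 17L
    pres <- unique(vapply(variants[vapply(variants, function(v)
      v$kind == "cnn", TRUE)], function(v) v$pre, ""))
    models <- list()
    for (pre in pres)
      models[[pre]] <- benchmark_pretrain(pre, data, config, rep_seed)
    for (vn in config$variants) {
      v <- variants[[vn]]
      scores <- if (v$kind == "cnn") {
        lopo_scores_cnn(v, models[[v$pre]], target, config, rep_seed)
      } else if (v$kind == "scratch") {
        lopo_scores_cnn(v, NULL, target, config, rep_seed)
      } else {
        lopo_scores_classical(v$kind, target, rep_seed)
      }
      values[[vn]][[r]] <- compute_metrics(scores, y)
    }
  }

  agg <- lapply(values, aggregate_repetitions)
  report <- do.call(rbind, lapply(names(agg), function(vn) {
    data.frame(variant = vn, metric = names(agg[[vn]]$mean),
               mean = unname(agg[[vn]]$mean), sd = unname(agg[[vn]]$sd))
  }))
  comparisons <- NULL
  if ("svm" %in% names(agg)) {
    others <- setdiff(names(agg), "svm")
    comparisons <- do.call(rbind, lapply(others, function(vn) {
      cmp <- compare_models(agg[[vn]]$values[, "auc"],
                            agg[["svm"]]$values[, "auc"])
      data.frame(variant = vn, baseline = "svm", metric = "auc",
                 difference = cmp$difference, p_value = cmp$p_value,
                 ci_lower = cmp$ci[1], ci_upper = cmp$ci[2])
    }))
  }
  structure(list(report = report, values = agg, comparisons = comparisons,
                 config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  wide <- stats::reshape(x$report, idvar = "variant", timevar = "metric",
                         direction = "wide")
  cat("Benchmark results, mean (SD) over",
      x$config$n_repetitions, "repetitions:\n")
  for (i in seq_len(nrow(wide))) {
    cat(sprintf("  %-10s", wide$variant[i]))
    for (m in c("auc", "accuracy", "sensitivity", "specificity")) {
      cat(sprintf(" %s=%.2f (%.2f)", m, wide[[paste0("mean.", m)]][i],
                  wide[[paste0("sd.", m)]][i]))
    }
    cat("\n")
  }
  invisible(x)
}
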