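test_that("entropy matches closed-form values and validates its input", {
  expect_equal(entropy(c(0.5, 0.5)), log(2))
  expect_equal(entropy(c(1, 0)), 0)
  expect_equal(entropy(c(0.9, 0.1)), 0.3251, tolerance = 1e-4)
  expect_equal(entropy(c(0.9, 0.1)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)))
  expect_error(entropy(c(0.7, 0.7)), "sum to 1")
  expect_error(entropy(c(1.2, -0.2)), "negative")
})

test_that("training configs enforce the protocol invariants", {
  cfg <- train_config()
  expect_equal(cfg$max_epochs, 25L)
  expect_equal(cfg$patience, 8L)
  expect_equal(cfg$learning_rate, 0.001)
  expect_error(train_config(max_epochs = 5, patience = 8), "patience")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(finetune_config(frozen_groups = "block_4"), "overlap")
  fc <- finetune_config()
  expect_setequal(c(fc$frozen_groups, fc$trainable_groups),
                  c("stem", paste0("block_", 1:6), "head"))
})

test_that("early stopping halts after patience+1 epochs when validation accuracy is flat", {
  co <- separable_cohort(8, seed = 2)
  # a vanishing learning rate keeps the model (and its validation accuracy)
  # constant, so the stop rule alone decides the epoch count
  cfg <- train_config(max_epochs = 12, patience = 3, learning_rate = 1e-12,
                      seed = 1)
  fit <- pretrain(build_resnet1d(tiny_net(), 1), co, cfg,
                  split = c(0.6, 0.4, 0))
  expect_equal(nrow(fit$history), 3 + 1)
  expect_equal(length(unique(fit$history$val_accuracy)), 1)
})

test_that("a separable two-peak problem is learned to high validation accuracy", {
  ok <- 0
  for (s in 1:3) {
    co <- separable_cohort(20, seed = 100 + s)
    cfg <- train_config(max_epochs = 15, patience = 15, seed = s)
    fit <- pretrain(build_resnet1d(tiny_net(), s), co, cfg,
                    split = c(0.6, 0.2, 0.2))
    if (max(fit$history$val_accuracy) > 0.95) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("training is fully reproducible from its seeds", {
  co <- separable_cohort(8, seed = 3)
  cfg <- train_config(max_epochs = 2, patience = 2, seed = 4)
  f1 <- pretrain(build_resnet1d(tiny_net(), 9), co, cfg, c(0.6, 0.4, 0))
  f2 <- pretrain(build_resnet1d(tiny_net(), 9), co, cfg, c(0.6, 0.4, 0))
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("patient-stratified splits never place a patient in two partitions", {
  co <- separable_cohort(15, seed = 4)
  d <- ramanadapt:::cohort_xy(co)
  parts <- ramanadapt:::split_patients(d$patients, d$y,
                                       c(train = 0.6, val = 0.2, test = 0.2),
                                       seed = 5)
  expect_setequal(names(parts), unique(d$patients))
  per_spectrum <- parts[d$patients]
  tab <- table(d$patients, per_spectrum)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("efficient fine-tuning freezes the early groups bitwise and halves the trainable budget", {
  co <- separable_cohort(10, seed = 6)
  m <- build_resnet1d(tiny_net(), seed = 11)
  cfg <- finetune_config(max_epochs = 3, patience = 3, seed = 2)
  fit <- finetune_efficient(m, co, cfg)
  frozen <- unlist(m$groups[cfg$frozen_groups], use.names = FALSE)
  for (nm in frozen) expect_identical(fit$model$params[[nm]], m$params[[nm]])
  changed <- vapply(unlist(m$groups[cfg$trainable_groups]), function(nm)
    !identical(fit$model$params[[nm]], m$params[[nm]]), TRUE)
  expect_true(any(changed))
  frac <- count_parameters(m, TRUE, cfg$trainable_groups) / count_parameters(m)
  expect_lte(frac, 0.55)
  expect_error(finetune_efficient(m, co, finetune_config(
    trainable_groups = c("block_9", "head"))), "unknown group")
})

test_that("zero training epochs leave the model identical", {
  co <- separable_cohort(6, seed = 7)
  m <- build_resnet1d(tiny_net(), seed = 3)
  fit <- finetune_efficient(m, co, finetune_config(max_epochs = 0,
                                                   patience = 0, seed = 1))
  expect_identical(fit$model$params, m$params)
  expect_identical(fit$model$buffers, m$buffers)
})

test_that("TTA with zero steps reproduces the unadapted predictions", {
  co <- separable_cohort(4, seed = 9)
  m <- build_resnet1d(tiny_net(), seed = 5)
  pid <- co$meta$patient_id == unique(co$meta$patient_id)[1]
  x <- co$intensities[pid, , drop = FALSE]
  res <- tta_adapt(m, x, tta_config(n_steps = 0))
  expect_equal(unname(res$predictions),
               unname(predict_proba(m, x)), tolerance = 1e-12)
  expect_equal(ncol(res$entropy_trace), 1)
})

test_that("TTA records an entropy trace of length n_steps + 1 and adapts only head and BN affine parameters", {
  co <- separable_cohort(4, seed = 10)
  m <- build_resnet1d(tiny_net(), seed = 6)
  pid <- co$meta$patient_id == unique(co$meta$patient_id)[1]
  x <- co$intensities[pid, , drop = FALSE]
  res <- tta_adapt(m, x, tta_config(n_steps = 5))
  expect_equal(dim(res$entropy_trace), c(nrow(x), 6))
  expect_true(all(res$entropy_trace >= 0))
  adapted <- c(m$groups$head, bn_parameter_names(m))
  for (nm in setdiff(names(m$params), adapted))
    expect_identical(res$adapted_model$params[[nm]], m$params[[nm]])
  expect_error(tta_adapt(m, x[, 1:100, drop = FALSE]), "length mismatch")
})

test_that("entropy descent reduces the final entropy for most measurements", {
  fx <- bench_fixture()
  res <- tta_predict_cohort(fx$model, fx$data$target, fx$cfg$tta)
  tr <- do.call(rbind, res$traces)
  frac <- mean(tr[, ncol(tr)] <= tr[, 1] + 1e-12)
  expect_gte(frac, 0.9)
})

test_that("adapting one patient never changes another patient's predictions", {
  fx <- bench_fixture()
  target <- fx$data$target
  pids <- sort(unique(target$meta$patient_id))
  a <- target$intensities[target$meta$patient_id == pids[1], , drop = FALSE]
  b <- target$intensities[target$meta$patient_id == pids[2], , drop = FALSE]
  cfg <- fx$cfg$tta
  res_b_alone <- tta_adapt(fx$model, b, cfg)
  invisible(tta_adapt(fx$model, a, cfg))        # adapt A first
  res_b_after <- tta_adapt(fx$model, b, cfg)
  expect_identical(res_b_alone$predictions, res_b_after$predictions)
  expect_identical(res_b_alone$entropy_trace, res_b_after$entropy_trace)
})
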