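brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

test_that("LOPO fold plans partition patients exactly once each", {
  co <- generate_cohort(domain_preset("prostate_target"), 10, c(7, 18),
                        seed = 40, keep_accumulations = FALSE)
  plan <- lopo_folds(co)
  expect_length(plan$folds, 10)
  test_pats <- vapply(plan$folds, function(f) f$test_patient, "")
  expect_equal(sort(test_pats), sort(unique(co$meta$patient_id)))
  for (f in plan$folds) {
    expect_length(intersect(f$train_patients, f$test_patient), 0)
    expect_setequal(c(f$train_patients, f$test_patient),
                    unique(co$meta$patient_id))
  }
  two <- generate_cohort(domain_preset("brain"), 2, c(3, 3), 4,
                         keep_accumulations = FALSE)
  p2 <- lopo_folds(two)
  expect_length(p2$folds, 2)
  expect_equal(p2$folds[[1]]$train_patients, p2$folds[[2]]$test_patient)
  one <- subset_cohort(two, two$meta$patient_id == two$meta$patient_id[1])
  expect_error(lopo_folds(one), "2 patients")
})

test_that("LOPO partition invariants hold for random cohorts", {
  set.seed(17)
  for (i in 1:50) {
    n_pat <- sample(2:12, 1)
    co <- generate_cohort(domain_preset("brain"), n_pat, c(1, 4),
                          seed = 7000 + i, keep_accumulations = FALSE)
    plan <- lopo_folds(co)
    test_pats <- vapply(plan$folds, function(f) f$test_patient, "")
    expect_equal(sort(test_pats), sort(unique(co$meta$patient_id)))
  }
})

test_that("compute_auc equals the pairwise concordance oracle, ties counted one half", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.7, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(compute_auc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(compute_auc(rep(1, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(compute_auc(1:4, rep(1, 4)), "both classes")
  set.seed(23)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    expect_identical(compute_auc(scores, labels),
                     brute_force_auc(scores, labels))
  }
})

test_that("threshold metrics match their confusion-matrix definitions", {
  # counts TP=83 FN=17 TN=72 FP=28 -> sensitivity 0.83, specificity 0.72
  scores <- c(rep(0.9, 83), rep(0.1, 17), rep(0.1, 72), rep(0.9, 28))
  labels <- c(rep(1, 100), rep(0, 100))
  m <- compute_metrics(scores, labels)
  expect_equal(unname(m["sensitivity"]), 0.83)
  expect_equal(unname(m["specificity"]), 0.72)
  expect_equal(unname(m["accuracy"]), (83 + 72) / 200)
  expect_equal(unname(m["ppv"]), 83 / (83 + 28))
  cm <- attr(m, "confusion")
  expect_equal(unname(cm), c(83, 17, 72, 28))
  # recomputing from the stored confusion matrix reproduces the metrics
  expect_equal(unname(m["accuracy"]),
               unname((cm["TP"] + cm["TN"]) / sum(cm)))

  all_right <- compute_metrics(c(0.6, 0.4), c(1, 0))
  expect_equal(unname(all_right[c("accuracy", "sensitivity", "specificity")]),
               c(1, 1, 1))
})

test_that("repetition aggregation reports mean and sample SD", {
  reps <- list(c(auc = 0.7, accuracy = 0.6), c(auc = 0.8, accuracy = 0.6))
  agg <- aggregate_repetitions(reps)
  expect_equal(unname(agg$mean["auc"]), 0.75)
  expect_equal(unname(agg$sd["auc"]), stats::sd(c(0.7, 0.8)))
  expect_equal(unname(agg$sd["accuracy"]), 0)
  expect_equal(nrow(agg$values), 2)
  same <- aggregate_repetitions(list(c(a = 1), c(a = 1), c(a = 1)))
  expect_equal(unname(same$sd), 0)
  expect_error(aggregate_repetitions(list(c(a = 1))), "2 repetitions")
})

test_that("model comparison matches the closed-form Welch t-test and handles degenerate input", {
  same <- compare_models(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  set.seed(3)
  a <- c(0.9, 0.9, 0.9) + rnorm(3, 0, 1e-4)
  b <- c(0.1, 0.1, 0.1) + rnorm(3, 0, 1e-4)
  cmp <- compare_models(a, b)
  expect_lt(cmp$p_value, 0.001)
  ref <- stats::t.test(a, b)
  expect_equal(cmp$p_value, ref$p.value)
  expect_equal(cmp$ci, unname(ref$conf.int))
  expect_lte(cmp$ci[1], cmp$ci[2])
})

test_that("univariate peak analysis behaves under shuffled and identical class distributions", {
  co <- generate_cohort(domain_preset("prostate_target"), 20, c(6, 9),
                        seed = 55, keep_accumulations = FALSE)
  co$intensities <- t(apply(co$intensities, 1, normalize_spectrum, "minmax"))
  # identical class distributions: duplicate spectra, opposite labels
  dup <- co
  dup$intensities <- rbind(co$intensities, co$intensities)
  dup$meta <- rbind(co$meta, transform(co$meta,
                                       label = 1 - label,
                                       sample_id = paste0(sample_id, "b")))
  rownames(dup$intensities) <- dup$meta$sample_id
  ua <- univariate_peak_analysis(dup, peaks = c(997, 1450))
  expect_equal(ua$mean_difference, rep(0, 2), tolerance = 1e-12)

  # label shuffles: CIs cover 0 in at least 90% of cases
  set.seed(8)
  cover <- 0; total <- 0
  for (i in 1:20) {
    sh <- co
    sh$meta$label <- sample(sh$meta$label)
    u <- univariate_peak_analysis(sh, peaks = c(997))
    total <- total + 1
    if (u$ci_lower <= 0 && u$ci_upper >= 0) cover <- cover + 1
  }
  expect_gte(cover / total, 0.9)
})

test_that("benchmark reports have the requested shape and are reproducible", {
  cfg <- benchmark_config(variants = c("svm_invivo", "rf"),
                          n_repetitions = 2, seed = 77,
                          sizes = list(bacteria = c(2, 2, 3),
                                       brain = c(2, 2, 3),
                                       breast = c(2, 2, 3),
                                       prostate_retro = c(2, 2, 3),
                                       target = c(6, 5, 8)))
  res <- run_benchmark(cfg)
  expect_s3_class(res, "eval_report")
  expect_equal(sort(unique(res$report$variant)), c("rf", "svm_invivo"))
  expect_equal(nrow(res$report), 2 * 5)  # 2 variants x 5 metrics
  expect_equal(nrow(res$values$rf$values), 2)
  res2 <- run_benchmark(cfg)
  expect_identical(res$report, res2$report)
  expect_error(benchmark_config(variants = "warp"), "unknown variant")
})
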