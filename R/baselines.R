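#' Three-step feature selection configuration
#'
#' @param variance_threshold Keep features with training-fold variance above
#'   this (step 1).
#' @param correlation_threshold Keep features whose absolute point-biserial
#'   correlation with the label exceeds this (step 2).
#' @param max_features Cap on the selected feature count (step 3, Lasso).
#' @param fallback_top_k When a filter step empties the feature set, keep
#'   this many top-ranked features instead (recorded in the result).
#' @return An object of class `feature_selection_config`.
#' @export
feature_selection_config <- function(variance_threshold = 0.03,
                                     correlation_threshold = 0.9,
                                     max_features = 10,
                                     fallback_top_k = 50) {
  if (max_features < 1) stop("invalid config: max_features must be >= 1")
  if (variance_threshold < 0 || correlation_threshold < 0)
    stop("invalid config: thresholds must be >= 0")
  structure(list(variance_threshold = variance_threshold,
                 correlation_threshold = correlation_threshold,
                 max_features = as.integer(max_features),
                 fallback_top_k = as.integer(fallback_top_k)),
            class = "feature_selection_config")
}

#' Three-step univariate/Lasso feature selection
#'
#' Step 1 keeps spectral points with variance above `variance_threshold`;
#' step 2 keeps points whose absolute correlation with the binary label
#' exceeds `correlation_threshold` (with a documented top-k fallback, since
#' |r| > 0.9 is rarely attainable on noisy spectra); step 3 runs
#' L1-regularized logistic regression, tightening the penalty until at most
#' `max_features` features survive. Fit on training folds only.
#'
#' @param x Training spectra matrix (samples x points).
#' @param y Binary labels (0/1).
#' @param config A [feature_selection_config()].
#' @return Integer column indices (<= `max_features`), with attribute
#'   `fallback` naming any step whose filter was emptied and replaced by its
#'   top-k fallback.
#' @export
select_features_threestep <- function(x, y, config = feature_selection_config()) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  fallback <- character(0)
  v <- apply(x, 2, stats::var)
  if (all(v == 0)) stop("all features are constant")
  keep1 <- which(v > config$variance_threshold)
  if (length(keep1) == 0) {
    # threshold excluded everything: keep all non-constant features so the
    # label-correlation step still sees the informative points
    keep1 <- which(v > 0)
    fallback <- c(fallback, "variance")
  }
  r <- suppressWarnings(abs(stats::cor(x[, keep1, drop = FALSE], y)))
  r[is.na(r)] <- 0
  keep2 <- keep1[r > config$correlation_threshold]
  if (length(keep2) == 0) {
    keep2 <- keep1[order(r, decreasing = TRUE)[seq_len(min(config$fallback_top_k,
                                                           length(keep1)))]]
    fallback <- c(fallback, "correlation")
  }
  if (length(keep2) <= config$max_features) {
    sel <- sort(keep2)
  } else {
    fit <- suppressWarnings(
      glmnet::glmnet(x[, keep2, drop = FALSE], y, family = "binomial",
                     alpha = 1, nlambda = 100))
    df <- fit$df
    ok <- which(df <= config$max_features & df > 0)
    if (length(ok) == 0) {
      # even the loosest usable penalty keeps too many: take the strongest
      sel <- sort(keep2[order(r[match(keep2, keep1)],
                              decreasing = TRUE)[seq_len(config$max_features)]])
      fallback <- c(fallback, "lasso")
    } else {
      lam_idx <- ok[length(ok)]  # smallest penalty still within the cap
      beta <- fit$beta[, lam_idx]
      sel <- sort(keep2[which(beta != 0)])
    }
  }
  attr(sel, "fallback") <- fallback
  sel
}

#' A named set of literature Raman peaks
#'
#' @param name Set label.
#' @param wavenumbers List whose elements are single centers (cm^-1) or
#'   length-2 intervals (printed ranges such as 1307 to 1310).
#' @return An object of class `peak_feature_set`.
#' @export
peak_feature_set <- function(name, wavenumbers) {
  if (!is.list(wavenumbers)) wavenumbers <- as.list(wavenumbers)
  structure(list(name = name, wavenumbers = wavenumbers),
            class = "peak_feature_set")
}

#' Literature peak sets used by the comparative SVM
#'
#' `invivo`: phenylalanine 994 and 1007, collagen/DNA/RNA 1334, and DNA/RNA,
#' protein and phospholipid bands 1766 and 1772 cm^-1. `exvivo`: tryptophan
#' 881, collagen 1307 to 1310 (full printed interval), beta-carotene 1396,
#' and phenylalanine/tyrosine/tryptophan 1583 and 1602 cm^-1.
#'
#' @return Named list of [peak_feature_set()]s.
#' @export
literature_peak_sets <- function() {
  list(invivo = peak_feature_set("invivo",
                                 list(994, 1007, 1334, 1766, 1772)),
       exvivo = peak_feature_set("exvivo",
                                 list(881, c(1307, 1310), 1396, 1583, 1602)))
}

#' Extract per-peak intensity features
#'
#' One feature per peak: the maximum intensity within `window` cm^-1 of the
#' peak center (or of the full printed interval for range peaks).
#'
#' @param x A `raman_cohort` or intensity matrix.
#' @param peaks A [peak_feature_set()].
#' @param window Half-window (cm^-1) around the peak center; 0 selects the
#'   single nearest on-grid point.
#' @param wavenumbers Grid; taken from the cohort when `x` is one.
#' @return Feature matrix (samples x peaks), columns named by peak.
#' @export
extract_peak_features <- function(x, peaks, window = 4, wavenumbers = NULL) {
  if (inherits(x, "raman_cohort")) {
    wavenumbers <- x$wavenumbers
    x <- x$intensities
  }
  stopifnot(inherits(peaks, "peak_feature_set"), !is.null(wavenumbers))
  if (window < 0) stop("invalid window: must be >= 0")
  cols <- lapply(peaks$wavenumbers, function(wn) {
    lo <- min(wn) - window; hi <- max(wn) + window
    idx <- which(wavenumbers >= lo & wavenumbers <= hi)
    if (length(idx) == 0) {
      # window = 0 off-grid: snap to the nearest grid point if the center
      # lies inside the grid, otherwise refuse
      ctr <- mean(range(wn))
      if (ctr < min(wavenumbers) || ctr > max(wavenumbers))
        stop(sprintf("peak at %.0f cm^-1 outside the grid", ctr))
      idx <- which.min(abs(wavenumbers - ctr))
    }
    apply(x[, idx, drop = FALSE], 1, max)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(peaks$wavenumbers, function(wn)
    paste(round(wn), collapse = "-"), "")
  rownames(out) <- rownames(x)
  out
}

#' Fit the comparative SVM
#'
#' RBF-kernel support vector machine on z-scored features (the scaler is fit
#' on the training fold and stored). Scores are the logistic-mapped decision
#' values, oriented so that higher means cancer; 0.5 corresponds to the SVM
#' decision boundary.
#'
#' @param features Training feature matrix.
#' @param labels Binary labels (0/1).
#' @param kernel,cost Passed to [e1071::svm()].
#' @return An object of class `raman_svm` with a `predict` method returning
#'   scores in \[0, 1\].
#' @export
fit_svm <- function(features, labels, kernel = "radial", cost = 1) {
  if (length(unique(labels)) < 2) stop("training data contain a single class")
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(features, ctr, scl)
  fit <- e1071::svm(xs, factor(labels, levels = c(0, 1)), kernel = kernel,
                    cost = cost, scale = FALSE)
  # orient decision values so positive means the cancer class
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  orient <- if (suppressWarnings(stats::cor(dv, labels)) < 0) -1 else 1
  structure(list(fit = fit, center = ctr, scale = scl, orient = orient),
            class = "raman_svm")
}

#' @export
predict.raman_svm <- function(object, newdata, ...) {
  xs <- scale(newdata, object$center, object$scale)
  dv <- attr(stats::predict(object$fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  stats::plogis(object$orient * dv)
}

#' Fit the comparative random forest
#'
#' 100 trees, maximum depth 5, all features considered at every split, no
#' class-imbalance correction; probability forest so continuous scores are
#' available for the ROC analysis.
#'
#' @param features Training feature matrix.
#' @param labels Binary labels (0/1).
#' @param seed Integer seed (tree growing is stochastic).
#' @return An object of class `raman_rf` with a `predict` method returning
#'   cancer probabilities.
#' @export
fit_rf <- function(features, labels, seed = 1) {
  if (length(unique(labels)) < 2) stop("training data contain a single class")
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.label <- factor(labels, levels = c(0, 1))
  fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                        num.trees = 100, max.depth = 5,
                        mtry = ncol(features), probability = TRUE,
                        seed = seed, num.threads = 1)
  structure(list(fit = fit, n_features = ncol(features)), class = "raman_rf")
}

#' @export
predict.raman_rf <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  names(df) <- paste0("f", seq_len(ncol(df)))
  stats::predict(object$fit, data = df, num.threads = 1)$predictions[, "1"]
}
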