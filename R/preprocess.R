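#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the raw-to-processed chain. The chain
#' order is fixed: cosmic-ray removal, accumulation averaging, optional
#' instrument-response correction, BubbleFill autofluorescence removal,
#' normalization, resampling to the target grid.
#'
#' @param cosmic_ray_threshold Outlier threshold in multiples of the robust
#'   across-accumulation scale (1.4826 x MAD).
#' @param bubble_min_width Smallest bubble width (cm^-1); features narrower
#'   than this are treated as peaks, wider ones as baseline.
#' @param response_curve Optional positive gain vector on the acquisition
#'   grid (instrument response); `NULL` skips the stage.
#' @param normalization One of `"minmax"`, `"area"`, `"vector"`.
#' @param target_grid Length-3 vector `(min cm^-1, max cm^-1, n_points)`.
#' @param dark Optional dark/background vector subtracted before everything
#'   else.
#' @param steps Character vector of stage names to run, in fixed order;
#'   defaults to the full chain. `"baseline"` may be dropped to keep the
#'   autofluorescence background (e.g. for domain-shift experiments).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(cosmic_ray_threshold = 8,
                              bubble_min_width = 100,
                              response_curve = NULL,
                              normalization = c("minmax", "area", "vector"),
                              target_grid = c(400, 2000, 1174),
                              dark = NULL,
                              steps = c("cosmic", "average", "response",
                                        "baseline", "normalize", "resample")) {
  normalization <- match.arg(normalization)
  if (cosmic_ray_threshold <= 0) stop("invalid config: cosmic_ray_threshold must be > 0")
  if (bubble_min_width <= 0) stop("invalid config: bubble_min_width must be > 0")
  if (length(target_grid) != 3 || target_grid[3] < 2)
    stop("invalid config: target_grid must be (min, max, n_points >= 2)")
  steps <- match.arg(steps, several.ok = TRUE)
  structure(list(cosmic_ray_threshold = cosmic_ray_threshold,
                 bubble_min_width = bubble_min_width,
                 response_curve = response_curve,
                 normalization = normalization,
                 target_grid = target_grid, dark = dark, steps = steps),
            class = "preprocess_config")
}

#' Remove cosmic-ray spikes by across-accumulation comparison
#'
#' A cosmic ray hits a single accumulation, so a pixel whose value deviates
#' from the across-accumulation median by more than `threshold` robust scale
#' units (1.4826 x MAD) is replaced by that median. Spikes present in every
#' accumulation are invisible to this comparison; with a single accumulation
#' the function falls back to within-spectrum median filtering and flags it.
#'
#' @param accumulations Numeric matrix, accumulations x points.
#' @param threshold Deviation threshold in robust-scale units.
#' @return Matrix of the same shape with attribute `"n_replaced"` and, for
#'   the single-accumulation fallback, `"fallback" = TRUE`.
#' @export
remove_cosmic_rays <- function(accumulations, threshold = 8) {
  if (!is.matrix(accumulations) || !is.numeric(accumulations))
    stop("invalid accumulations: need a numeric matrix (accumulations x points)")
  n <- nrow(accumulations)
  if (n == 1) {
    # median filter fallback: compare each pixel to its 5-point neighborhood
    y <- accumulations[1, ]
    med <- stats::runmed(y, 5, endrule = "median")
    dev <- abs(y - med)
    sc <- max(1.4826 * stats::median(dev), .Machine$double.eps)
    bad <- dev > threshold * sc
    y[bad] <- med[bad]
    out <- matrix(y, 1)
    attr(out, "n_replaced") <- sum(bad)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  med <- apply(accumulations, 2, stats::median)
  dev <- abs(sweep(accumulations, 2, med))
  mad_col <- 1.4826 * apply(dev, 2, stats::median)
  scale_floor <- max(1.4826 * stats::median(dev), .Machine$double.eps)
  sc <- pmax(mad_col, scale_floor)
  bad <- sweep(dev, 2, threshold * sc) > 0
  out <- accumulations
  out[bad] <- med[col(out)[bad]]
  attr(out, "n_replaced") <- sum(bad)
  out
}

#' Average accumulations into one spectrum
#'
#' @param accumulations Numeric matrix, accumulations x points.
#' @return Pointwise arithmetic mean (numeric vector).
#' @export
average_accumulations <- function(accumulations) {
  if (is.null(dim(accumulations))) accumulations <- matrix(accumulations, 1)
  if (nrow(accumulations) < 1 || length(accumulations) == 0)
    stop("invalid accumulations: empty input")
  colMeans(accumulations)
}

#' Correct for the instrument response
#'
#' Pointwise division by a positive gain curve measured on a fluorescence
#' standard, flattening the wavelength-dependent system throughput.
#'
#' @param spectrum Intensity vector.
#' @param response_curve Positive gain vector of the same length.
#' @return Corrected intensity vector.
#' @export
correct_instrument_response <- function(spectrum, response_curve) {
  if (length(spectrum) != length(response_curve))
    stop("response_curve length does not match spectrum length")
  bad <- which(!(response_curve > 0))
  if (length(bad) > 0)
    stop(sprintf("response_curve must be strictly positive (first bad index: %d)",
                 bad[1]))
  spectrum / response_curve
}

#' BubbleFill autofluorescence baseline removal
#'
#' Estimates the broad fluorescence background as the upper envelope of
#' circular "bubbles" grown from below the spectrum: in an aspect-normalized
#' frame, the largest circle spanning the current interval is pushed up until
#' it touches the spectrum; the touch point splits the interval and the
#' procedure recurses until intervals are narrower than `bubble_min_width`.
#' The baseline therefore contains no feature narrower than the minimum
#' bubble, while narrow Raman peaks are left in the corrected signal.
#'
#' @param spectrum Intensity vector (finite values).
#' @param wavenumbers Strictly increasing grid (cm^-1).
#' @param bubble_min_width Minimum bubble width (cm^-1).
#' @return List with `baseline` and `corrected` (`spectrum - baseline`,
#'   nonnegative up to numerical tolerance).
#' @export
bubblefill_baseline <- function(spectrum, wavenumbers = raman_grid(),
                                bubble_min_width = 100) {
  if (any(!is.finite(spectrum))) stop("invalid spectrum: non-finite values")
  if (length(spectrum) != length(wavenumbers))
    stop("spectrum and wavenumbers lengths differ")
  span <- max(wavenumbers) - min(wavenumbers)
  if (bubble_min_width <= 0) stop("invalid bubble_min_width: must be > 0")
  if (bubble_min_width >= span)
    stop("invalid bubble_min_width: larger than the grid span")

  # aspect-normalized frame: x in [0, 1], y scaled to the same unit range so
  # that bubble circles have comparable curvature in both axes
  u <- (wavenumbers - min(wavenumbers)) / span
  yr <- range(spectrum)
  ysc <- if (diff(yr) > 0) diff(yr) else 1
  y <- (spectrum - yr[1]) / ysc
  n <- length(y)
  min_w <- bubble_min_width / span
  baseline <- rep(-Inf, n)

  # bubble alignment depends on whether the interval touches a data edge:
  # a full-span interval gets a flat line (infinite-radius bubble), an
  # edge interval gets a half-bubble with its apex at the data edge, and an
  # interior interval gets a circle spanning the interval
  grow <- function(l, r) {
    idx <- l:r
    width <- u[r] - u[l]
    if (l == 1L && r == n) {
      arc <- rep(0, length(idx))
    } else if (l == 1L) {
      R <- width
      arc <- sqrt(pmax(R^2 - (u[idx] - u[l])^2, 0)) - R
    } else if (r == n) {
      R <- width
      arc <- sqrt(pmax(R^2 - (u[idx] - u[r])^2, 0)) - R
    } else {
      R <- width / 2
      ctr <- (u[l] + u[r]) / 2
      arc <- sqrt(pmax(R^2 - (u[idx] - ctr)^2, 0)) - R
    }
    lift <- min(y[idx] - arc)
    touch <- idx[which.min(y[idx] - arc)]
    list(vals = arc + lift, touch = touch)
  }

  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- iv[1]; r <- iv[2]
    if (r - l < 1L) next
    full_span <- (l == 1L && r == n)
    if (!full_span && (u[r] - u[l]) < min_w) next
    g <- grow(l, r)
    seg <- l:r
    baseline[seg] <- pmax(baseline[seg], g$vals)
    t <- g$touch
    if (t == l) {
      stack[[length(stack) + 1]] <- c(l + 1L, r)
    } else if (t == r) {
      stack[[length(stack) + 1]] <- c(l, r - 1L)
    } else {
      stack[[length(stack) + 1]] <- c(l, t)
      stack[[length(stack) + 1]] <- c(t, r)
    }
  }

  baseline <- pmin(baseline, y)          # numeric guard
  base_out <- baseline * ysc + yr[1]
  corrected <- spectrum - base_out
  corrected[corrected < 0] <- 0
  list(baseline = base_out, corrected = corrected)
}

#' Normalize a spectrum
#'
#' @param spectrum Intensity vector.
#' @param mode `"minmax"` (range to \[0, 1\]), `"area"` (unit trapezoidal
#'   integral; needs `wavenumbers`), or `"vector"` (unit Euclidean norm).
#' @param wavenumbers Grid, required for `"area"`.
#' @return Normalized intensity vector.
#' @export
normalize_spectrum <- function(spectrum, mode = c("minmax", "area", "vector"),
                               wavenumbers = NULL) {
  mode <- match.arg(mode)
  if (mode == "minmax") {
    r <- range(spectrum)
    if (diff(r) == 0) stop("cannot minmax-normalize a constant spectrum")
    (spectrum - r[1]) / diff(r)
  } else if (mode == "area") {
    if (is.null(wavenumbers)) wavenumbers <- seq_along(spectrum)
    a <- trapz_area(wavenumbers, spectrum)
    if (a == 0) stop("cannot area-normalize: zero integral")
    spectrum / a
  } else {
    nrm <- sqrt(sum(spectrum^2))
    if (nrm == 0) stop("cannot vector-normalize the zero spectrum")
    spectrum / nrm
  }
}

trapz_area <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Resample a spectrum onto an evenly spaced target grid
#'
#' Linear interpolation; extrapolation beyond the source range is refused.
#'
#' @param spectrum Intensity vector.
#' @param wavenumbers Strictly increasing source grid.
#' @param target_grid Length-3 `(min, max, n_points)`.
#' @return List with `wavenumbers` (target grid) and `intensities`.
#' @export
resample_to_grid <- function(spectrum, wavenumbers,
                             target_grid = c(400, 2000, 1174)) {
  if (any(diff(wavenumbers) <= 0))
    stop("invalid wavenumbers: must be strictly increasing")
  grid <- raman_grid(target_grid[1], target_grid[2], target_grid[3])
  if (grid[1] < min(wavenumbers) - 1e-9 || grid[length(grid)] > max(wavenumbers) + 1e-9)
    stop("target grid extends beyond the source range (extrapolation forbidden)")
  list(wavenumbers = grid,
       intensities = stats::approx(wavenumbers, spectrum, xout = grid,
                                   rule = 1)$y)
}

# Run the fixed-order chain on one measurement.
preprocess_one <- function(intensities, accumulations, wavenumbers, config) {
  applied <- character(0)
  y <- intensities
  run <- function(s) s %in% config$steps
  if (!is.null(config$dark)) {
    if (!is.null(accumulations))
      accumulations <- sweep(accumulations, 2, config$dark)
    y <- y - config$dark
    applied <- c(applied, "dark")
  }
  if (run("cosmic") && !is.null(accumulations)) {
    accumulations <- remove_cosmic_rays(accumulations, config$cosmic_ray_threshold)
    applied <- c(applied, "cosmic")
  }
  if (run("average") && !is.null(accumulations)) {
    y <- average_accumulations(accumulations)
    applied <- c(applied, "average")
  }
  if (run("response")) {
    if (is.null(config$response_curve)) {
      applied <- c(applied, "response:skipped")
    } else {
      y <- correct_instrument_response(y, config$response_curve)
      applied <- c(applied, "response")
    }
  }
  if (run("baseline")) {
    y <- bubblefill_baseline(y, wavenumbers, config$bubble_min_width)$corrected
    applied <- c(applied, "baseline")
  }
  if (run("normalize")) {
    y <- normalize_spectrum(y, config$normalization, wavenumbers)
    applied <- c(applied, "normalize")
  }
  if (run("resample")) {
    rs <- resample_to_grid(y, wavenumbers, config$target_grid)
    y <- rs$intensities
    wavenumbers <- rs$wavenumbers
    applied <- c(applied, "resample")
  }
  list(intensities = y, wavenumbers = wavenumbers, applied = applied)
}

#' Run the preprocessing chain on a cohort
#'
#' Applies, per measurement and in fixed order: cosmic-ray removal (on raw
#' accumulations), accumulation averaging, instrument-response correction
#' (skipped when no curve is configured), BubbleFill baseline removal,
#' normalization and resampling to the target grid. The applied stages are
#' recorded in the result's `steps_applied` attribute.
#'
#' @param cohort A `raman_cohort` (raw).
#' @param config A [preprocess_config()].
#' @return A processed `raman_cohort` on the target grid (accumulations
#'   dropped).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  stopifnot(inherits(cohort, "raman_cohort"),
            inherits(config, "preprocess_config"))
  n <- nrow(cohort$intensities)
  out <- NULL; wn_out <- NULL; applied <- NULL
  for (i in seq_len(n)) {
    sid <- cohort$meta$sample_id[i]
    acc <- if (!is.null(cohort$accumulations)) cohort$accumulations[[sid]] else NULL
    res <- tryCatch(
      preprocess_one(cohort$intensities[i, ], acc, cohort$wavenumbers, config),
      error = function(e) stop(sprintf("preprocessing failed for %s: %s",
                                       sid, conditionMessage(e)), call. = FALSE))
    if (is.null(out)) {
      out <- matrix(0, n, length(res$intensities))
      wn_out <- res$wavenumbers
      applied <- res$applied
    }
    out[i, ] <- res$intensities
  }
  rownames(out) <- cohort$meta$sample_id
  proc <- new_cohort(wn_out, out, cohort$meta, NULL)
  attr(proc, "steps_applied") <- applied
  proc
}
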