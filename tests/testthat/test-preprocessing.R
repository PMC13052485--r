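test_that("cosmic-ray removal fixes single-accumulation spikes and only those", {
  set.seed(42)
  acc <- matrix(rnorm(8 * 200, mean = 10, sd = 0.1), 8, 200)
  clean <- remove_cosmic_rays(acc)
  expect_equal(unclass(clean)[, ], acc, ignore_attr = TRUE)

  spiked <- acc
  spiked[3, 57] <- spiked[3, 57] + 50 * 0.1 * 50   # huge spike, one accumulation
  fixed <- remove_cosmic_rays(spiked)
  expect_equal(fixed[3, 57], stats::median(spiked[, 57]), tolerance = 1e-12)
  # all other pixels equal the spike-free twin
  expect_equal(fixed[-3, ], spiked[-3, ], ignore_attr = TRUE)
  expect_gte(attr(fixed, "n_replaced"), 1)

  # spike in every accumulation is invisible to the across-accumulation median
  allspike <- acc
  allspike[, 99] <- allspike[, 99] + 100
  out <- remove_cosmic_rays(allspike)
  expect_equal(out[, 99], allspike[, 99], ignore_attr = TRUE)

  expect_error(remove_cosmic_rays(list(1, 2)), "matrix")
})

test_that("single-accumulation input falls back to median filtering and is flagged", {
  y <- rep(5, 100); y[40] <- 500
  out <- remove_cosmic_rays(matrix(y, 1), threshold = 8)
  expect_true(attr(out, "fallback"))
  expect_equal(out[1, 40], 5)
})

test_that("average_accumulations is the pointwise mean", {
  v <- rnorm(50)
  expect_equal(average_accumulations(matrix(v, 1)), v)
  expect_equal(average_accumulations(rbind(v, -v)), rep(0, 50))
  expect_error(average_accumulations(matrix(numeric(0), 0, 0)), "empty")
  # SD of the average of 10 iid accumulations shrinks like 1/sqrt(10)
  set.seed(7)
  sds <- replicate(1000, stats::sd(average_accumulations(
    matrix(rnorm(10 * 20, sd = 2), 10, 20))))
  expect_equal(mean(sds), 2 / sqrt(10), tolerance = 0.05)
})

test_that("instrument-response correction divides pointwise and validates positivity", {
  s <- runif(30, 1, 2)
  expect_equal(correct_instrument_response(s, rep(1, 30)), s)
  expect_equal(correct_instrument_response(s, s), rep(1, 30))
  expect_equal(correct_instrument_response(s, rep(2, 30)), s / 2)
  r <- rep(1, 30); r[17] <- 0
  expect_error(correct_instrument_response(s, r), "17")
  expect_error(correct_instrument_response(s, rep(1, 29)), "length")
})

test_that("bubblefill flattens constants and broad baselines and keeps narrow peaks", {
  wn <- raman_grid()
  flat <- bubblefill_baseline(rep(3, 1174), wn)
  expect_equal(flat$baseline, rep(3, 1174), tolerance = 1e-9)
  expect_equal(flat$corrected, rep(0, 1174), tolerance = 1e-9)

  base <- 10 * exp(-(wn - 900)^2 / (2 * 400^2))
  bf <- bubblefill_baseline(base, wn)
  expect_lt(max(abs(bf$corrected)), 0.02 * max(base))
  expect_true(all(bf$baseline <= base + 1e-9 * max(base)))
  expect_true(all(bf$corrected >= 0))

  peak <- 2 * exp(-(wn - 997)^2 / (2 * 8^2))
  bf2 <- bubblefill_baseline(base + peak, wn)
  win <- which(wn >= 997 - 40 & wn <= 997 + 40)
  tz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  expect_equal(tz(wn[win], bf2$corrected[win]), tz(wn[win], peak[win]),
               tolerance = 0.05)

  expect_error(bubblefill_baseline(base, wn, bubble_min_width = 2000), "span")
  expect_error(bubblefill_baseline(c(base[-1], NA), wn), "finite")
})

test_that("bubblefill is idempotent within 1% of the corrected maximum", {
  wn <- raman_grid()
  y <- 8 * exp(-(wn - 1000)^2 / (2 * 350^2)) +
    2 * exp(-(wn - 997)^2 / (2 * 8^2)) +
    1.5 * exp(-(wn - 1450)^2 / (2 * 10^2))
  c1 <- bubblefill_baseline(y, wn)$corrected
  c2 <- bubblefill_baseline(c1, wn)$corrected
  expect_lt(max(abs(c2 - c1)), 0.01 * max(c1))
})

test_that("normalization modes satisfy their contracts", {
  s <- c(1, 3)
  expect_equal(normalize_spectrum(s, "minmax"), c(0, 1))
  s2 <- runif(100, 2, 7)
  m <- normalize_spectrum(s2, "minmax")
  expect_equal(range(m), c(0, 1))
  expect_equal(normalize_spectrum(m, "minmax"), m)
  wn <- seq_along(s2)
  a <- normalize_spectrum(s2, "area", wn)
  expect_equal(sum(diff(wn) * (utils::head(a, -1) + utils::tail(a, -1)) / 2), 1)
  v <- normalize_spectrum(s2, "vector")
  expect_equal(sqrt(sum(v^2)), 1)
  expect_error(normalize_spectrum(rep(2, 5), "minmax"), "constant")
})

test_that("resampling is exact on affine spectra and refuses extrapolation", {
  wn <- raman_grid(380, 2050, 1500)
  s <- 0.3 * wn + 7
  out <- resample_to_grid(s, wn, c(400, 2000, 1174))
  expect_length(out$intensities, 1174)
  expect_equal(out$intensities, 0.3 * out$wavenumbers + 7, tolerance = 1e-10)
  ident <- resample_to_grid(s, wn, c(380, 2050, 1500))
  expect_equal(ident$intensities, s, tolerance = 1e-10)
  expect_error(resample_to_grid(s, wn, c(300, 2000, 1174)), "extrapolation")
})

test_that("the full pipeline recovers injected peak positions and records its stages", {
  spec <- domain_preset("brain")
  co <- generate_cohort(spec, 2, c(3, 3), seed = 21)
  proc <- preprocess_cohort(co)
  expect_equal(dim(proc$intensities), c(nrow(co$intensities), 1174))
  expect_equal(range(proc$wavenumbers), c(400, 2000))
  expect_true("response:skipped" %in% attr(proc, "steps_applied"))
  expect_identical(attr(proc, "steps_applied")[1:2], c("cosmic", "average"))

  # top-3 maxima of the processed spectrum sit within one grid step of
  # injected peak centers
  dgrid <- diff(proc$wavenumbers[1:2])
  y <- proc$intensities[1, ]
  centers <- spec$peaks$center
  found <- c()
  for (k in 1:3) {
    i <- which.max(y)
    found <- c(found, proc$wavenumbers[i])
    y[max(1, i - 10):min(length(y), i + 10)] <- 0
  }
  for (f in found) expect_lt(min(abs(f - centers)), dgrid + 1e-9)

  # deterministic: same input and config give bit-identical output
  proc2 <- preprocess_cohort(co)
  expect_identical(proc$intensities, proc2$intensities)
})

test_that("baseline removal brings spectra closer to the peak-only truth than the raw input", {
  spec <- domain_preset("prostate_target")
  co <- generate_cohort(spec, 2, c(4, 4), seed = 31)
  proc <- preprocess_cohort(co)
  wn <- proc$wavenumbers
  for (i in 1:2) {
    lab <- co$meta$label[i]
    truth <- render_clean(spec, lab, wn, include_baseline = FALSE)
    raw_r <- stats::cor(co$intensities[i, ], truth)
    proc_r <- stats::cor(proc$intensities[i, ], truth)
    expect_gt(proc_r, raw_r)
  }
})
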