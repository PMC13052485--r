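#' Default wavenumber grid
#'
#' Evenly spaced grid of 1174 Raman-shift points covering 400 to 2000 cm^-1,
#' the fingerprint-region convention used throughout the package.
#'
#' @param min_wn,max_wn Grid end points (cm^-1).
#' @param n_points Number of grid points.
#' @return Numeric vector of strictly increasing wavenumbers.
#' @export
raman_grid <- function(min_wn = 400, max_wn = 2000, n_points = 1174) {
  if (n_points < 2) stop("invalid grid: n_points must be >= 2")
  if (max_wn <= min_wn) stop("invalid grid: max_wn must exceed min_wn")
  seq(min_wn, max_wn, length.out = n_points)
}

#' Describe a single Raman peak
#'
#' @param center Peak center (cm^-1).
#' @param width Half-width (cm^-1); for Lorentzian peaks this is the
#'   half-width at half-maximum.
#' @param base_amplitude Peak amplitude for the normal class (a.u.).
#' @param class_effect Multiplicative amplitude factor applied to the cancer
#'   class; 1 means no class signal at this peak.
#' @param shape `"lorentzian"` (narrow vibrational bands) or `"gaussian"`
#'   (broad components).
#' @return One-row data frame usable as a row of a peak table.
#' @export
peak_spec <- function(center, width, base_amplitude, class_effect = 1,
                      shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (!is.finite(width) || width <= 0) stop("invalid PeakSpec: width must be > 0")
  if (!is.finite(base_amplitude) || base_amplitude < 0)
    stop("invalid PeakSpec: base_amplitude must be >= 0")
  if (!is.finite(class_effect) || class_effect < 0)
    stop("invalid PeakSpec: class_effect must be >= 0")
  data.frame(center = center, width = width, base_amplitude = base_amplitude,
             class_effect = class_effect, shape = shape,
             stringsAsFactors = FALSE)
}

#' Literature Raman peak locations for prostate tissue
#'
#' The peak set used by default across the simulator, the peak-feature
#' extractor and the univariate analysis: 881 (tryptophan), 994 and 997 and
#' 1007 (phenylalanine), 1308 (collagen, representing the 1307 to 1310
#' interval), 1334 (collagen/DNA/RNA), 1396 (beta-carotene), 1583 and 1602
#' (phenylalanine/tyrosine/tryptophan) and 1766/1772 (DNA/RNA, proteins,
#' phospholipids) cm^-1.
#'
#' @return Numeric vector of peak centers (cm^-1).
#' @export
default_peak_centers <- function() {
  c(881, 994, 997, 1007, 1308, 1334, 1396, 1583, 1602, 1766, 1772)
}

# Default peak table shared by all tissue-like domains. Amplitudes and class
# effects are free simulator parameters chosen to give a subtle, realistic
# class signal; the cancer signature raises the phenylalanine and nucleic
# acid bands and lowers the tryptophan/collagen bands. On top of the
# analysis peaks, strong class-neutral structural bands (collagen backbone
# 855/935, amide III 1245, CH2 deformation 1450, amide I 1655 cm^-1)
# dominate the spectrum, as they do in tissue, so that normalization anchors
# on class-independent features.
default_peak_table <- function() {
  centers <- c(default_peak_centers(), 855, 935, 1245, 1450, 1655)
  widths  <- c(9, 7, 6, 8, 10, 9, 8, 9, 8, 7, 7,
               10, 10, 12, 12, 14)
  amps    <- c(0.55, 0.30, 0.85, 0.40, 0.65, 0.60, 0.35, 0.45, 0.40, 0.30, 0.28,
               0.50, 0.45, 0.70, 2.40, 1.80)
  effects <- c(0.88, 1.12, 1.20, 1.12, 0.88, 1.15, 0.92, 1.10, 1.10, 1.08, 1.08,
               1.00, 1.00, 1.00, 1.00, 1.00)
  do.call(rbind, lapply(seq_along(centers), function(i)
    peak_spec(centers[i], widths[i], amps[i], effects[i], "lorentzian")))
}

#' Describe a spectral domain (organ / instrument condition)
#'
#' A domain bundles everything the simulator needs to draw raw spectra with a
#' given statistical structure: the peak table, the autofluorescence
#' baseline, the noise level, cosmic-ray contamination, patient-level
#' heterogeneity, the number of detector accumulations per measurement and
#' the class balance.
#'
#' @param name Domain label (e.g. `"prostate_target"`).
#' @param peaks Data frame of peaks as returned by [peak_spec()] rows.
#' @param baseline_amplitude Amplitude of the broad autofluorescence
#'   background (a.u.); prostate tissue is strongly autofluorescent.
#' @param baseline_smoothness Characteristic width of the baseline
#'   components (cm^-1); must be much larger than peak widths.
#' @param noise_sd Gaussian noise SD per accumulation (a.u.).
#' @param cosmic_ray_rate Expected number of cosmic-ray spikes per
#'   accumulation (Poisson rate).
#' @param patient_effect_sd SD of the per-patient log-normal multiplicative
#'   intensity factor.
#' @param n_accumulations Detector accumulations per measurement.
#' @param class_balance Fraction of cancer-labelled measurement sites.
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(name, peaks = default_peak_table(),
                        baseline_amplitude = 5, baseline_smoothness = 300,
                        noise_sd = 0.05, cosmic_ray_rate = 0.05,
                        patient_effect_sd = 0.25, n_accumulations = 10,
                        class_balance = 0.5) {
  if (class_balance < 0 || class_balance > 1)
    stop("invalid DomainSpec: class_balance must lie in [0, 1]")
  if (noise_sd < 0) stop("invalid DomainSpec: noise_sd must be >= 0")
  if (n_accumulations < 1) stop("invalid DomainSpec: n_accumulations must be >= 1")
  if (baseline_amplitude < 0) stop("invalid DomainSpec: baseline_amplitude must be >= 0")
  if (baseline_smoothness <= 0) stop("invalid DomainSpec: baseline_smoothness must be > 0")
  if (cosmic_ray_rate < 0) stop("invalid DomainSpec: cosmic_ray_rate must be >= 0")
  if (patient_effect_sd < 0) stop("invalid DomainSpec: patient_effect_sd must be >= 0")
  stopifnot(is.data.frame(peaks),
            all(c("center", "width", "base_amplitude", "class_effect",
                  "shape") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop("invalid PeakSpec: width must be > 0")
  if (any(peaks$base_amplitude < 0)) stop("invalid PeakSpec: base_amplitude must be >= 0")
  structure(list(name = name, peaks = peaks,
                 baseline_amplitude = baseline_amplitude,
                 baseline_smoothness = baseline_smoothness,
                 noise_sd = noise_sd, cosmic_ray_rate = cosmic_ray_rate,
                 patient_effect_sd = patient_effect_sd,
                 n_accumulations = n_accumulations,
                 class_balance = class_balance),
            class = "domain_spec")
}

# Multiply the amplitudes of the peaks at the given centers; models
# organ-specific relative band intensities on top of the shared signature.
scale_bands <- function(peaks, multipliers) {
  for (ctr in names(multipliers)) {
    i <- which(abs(peaks$center - as.numeric(ctr)) < 0.5)
    peaks$base_amplitude[i] <- peaks$base_amplitude[i] * multipliers[[ctr]]
  }
  peaks
}

#' Preset domains emulating the multi-organ study cohorts
#'
#' Presets share the cancer-versus-normal peak signature (so that learned
#' representations transfer between domains) but differ in their relative
#' band profile (lipid-rich brain, fat-dominated breast, a leaner
#' bacteria-like profile), autofluorescence strength, noise, accumulation
#' count and class balance: an abundant clean bacteria-like source,
#' low-autofluorescence brain and breast cohorts, an imbalanced
#' retrospective prostate cohort, and the strongly autofluorescent
#' prospective prostate target.
#'
#' @param name One of `"bacteria_like"`, `"brain"`, `"breast"`,
#'   `"prostate_retro"`, `"prostate_target"`.
#' @return A [domain_spec()].
#' @export
domain_preset <- function(name = c("bacteria_like", "brain", "breast",
                                   "prostate_retro", "prostate_target")) {
  name <- match.arg(name)
  pk <- default_peak_table()
  switch(name,
    bacteria_like = domain_spec("bacteria_like",
      peaks = scale_bands(pk, list("855" = 0.7, "935" = 0.75, "1245" = 0.85,
                                   "1450" = 0.8, "1655" = 0.8,
                                   "1334" = 1.2, "997" = 1.15)),
      baseline_amplitude = 1.5, baseline_smoothness = 350, noise_sd = 0.04,
      cosmic_ray_rate = 0.02, patient_effect_sd = 0.15,
      n_accumulations = 1, class_balance = 0.5),
    brain = domain_spec("brain",
      peaks = scale_bands(pk, list("1450" = 1.15, "1655" = 1.10,
                                   "855" = 0.85, "935" = 0.85, "1308" = 0.9)),
      baseline_amplitude = 2.5, baseline_smoothness = 320, noise_sd = 0.03,
      cosmic_ray_rate = 0.05, patient_effect_sd = 0.25,
      n_accumulations = 4, class_balance = 0.574),
    breast = domain_spec("breast",
      peaks = scale_bands(pk, list("1450" = 1.25, "1655" = 1.15,
                                   "855" = 0.9, "1245" = 0.9)),
      baseline_amplitude = 2.0, baseline_smoothness = 280, noise_sd = 0.03,
      cosmic_ray_rate = 0.05, patient_effect_sd = 0.25,
      n_accumulations = 4, class_balance = 0.651),
    prostate_retro = domain_spec("prostate_retro",
      peaks = scale_bands(pk, list("1450" = 0.9, "855" = 1.1, "935" = 1.1)),
      baseline_amplitude = 6.0, baseline_smoothness = 300, noise_sd = 0.05,
      cosmic_ray_rate = 0.05, patient_effect_sd = 0.3,
      n_accumulations = 6, class_balance = 0.124),
    prostate_target = domain_spec("prostate_target",
      baseline_amplitude = 8.0, baseline_smoothness = 300, noise_sd = 0.06,
      cosmic_ray_rate = 0.05, patient_effect_sd = 0.3,
      n_accumulations = 10, class_balance = 0.567))
}

peak_profile <- function(wn, center, width, shape) {
  if (shape == "gaussian") exp(-(wn - center)^2 / (2 * width^2))
  else width^2 / ((wn - center)^2 + width^2)
}

# Broad autofluorescence background: three Gaussian lobes whose widths scale
# with baseline_smoothness. `comp_scale` lets patients vary lobe amplitudes.
baseline_profile <- function(wn, amplitude, smoothness, comp_scale = c(1, 1, 1)) {
  span <- max(wn) - min(wn)
  centers <- min(wn) + span * c(0.20, 0.55, 0.85)
  widths  <- smoothness * c(1.0, 1.6, 1.2)
  rel     <- c(1.0, 0.7, 0.5) * comp_scale
  out <- numeric(length(wn))
  for (i in 1:3) out <- out + rel[i] * exp(-(wn - centers[i])^2 / (2 * widths[i]^2))
  amplitude * out
}

# Noise-free expected spectrum for one measurement (before patient factor).
clean_spectrum <- function(wn, spec, label, amp_jitter = NULL) {
  y <- numeric(length(wn))
  pk <- spec$peaks
  if (is.null(amp_jitter)) amp_jitter <- rep(1, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    amp <- pk$base_amplitude[i] * amp_jitter[i]
    if (label == 1) amp <- amp * pk$class_effect[i]
    y <- y + amp * peak_profile(wn, pk$center[i], pk$width[i], pk$shape[i])
  }
  y
}

#' Generate a synthetic patient cohort of raw Raman spectra
#'
#' Draws `n_patients` patients; each contributes a uniformly drawn number of
#' measurement sites. A raw measurement is the per-accumulation sum of the
#' domain's autofluorescence baseline, the class-modulated peak signature and
#' Gaussian noise, scaled by a per-patient log-normal intensity factor, with
#' Poisson-placed cosmic-ray spikes added per accumulation. Stored
#' intensities are the plain accumulation average; raw accumulation matrices
#' are kept so the preprocessing chain can be exercised end to end.
#'
#' @param spec A [domain_spec()].
#' @param n_patients Number of patients.
#' @param spectra_per_patient Length-2 integer range (inclusive) of
#'   measurements per patient.
#' @param seed Integer seed; identical `(spec, n_patients, seed)` give
#'   bit-identical cohorts.
#' @param wavenumbers Acquisition grid (cm^-1), strictly increasing.
#' @param keep_accumulations Keep per-measurement raw accumulation matrices
#'   (needed for cosmic-ray removal and accumulation averaging).
#' @param patient_prefix Prefix for generated patient ids.
#' @return A `raman_cohort`: list with `wavenumbers`, `intensities`
#'   (measurements x points matrix), `meta` (patient_id, sample_id, label,
#'   domain, n_accumulations) and `accumulations`.
#' @export
generate_cohort <- function(spec, n_patients = 10,
                            spectra_per_patient = c(7, 18), seed = 1,
                            wavenumbers = raman_grid(),
                            keep_accumulations = TRUE,
                            patient_prefix = NULL) {
  stopifnot(inherits(spec, "domain_spec"))
  if (n_patients < 1) stop("invalid n_patients: must be >= 1")
  if (length(spectra_per_patient) == 1)
    spectra_per_patient <- rep(spectra_per_patient, 2)
  if (any(spectra_per_patient < 1))
    stop("invalid spectra_per_patient: must be >= 1")
  rng <- range(wavenumbers)
  if (any(spec$peaks$center < rng[1] | spec$peaks$center > rng[2]))
    stop("invalid PeakSpec: center outside the wavenumber grid range")
  if (is.null(patient_prefix)) patient_prefix <- paste0(spec$name, "_P")

  withr::with_seed(seed, {
    p <- length(wavenumbers)
    rows <- list(); acc_list <- list(); meta <- list(); k <- 0
    n_peaks <- nrow(spec$peaks)
    for (pt in seq_len(n_patients)) {
      pid <- sprintf("%s%02d", patient_prefix, pt)
      pfac <- exp(stats::rnorm(1, 0, spec$patient_effect_sd))
      comp_scale <- exp(stats::rnorm(3, 0, 0.15))
      # patient-level biochemical profile: per-peak amplitude multipliers
      # shared by all of the patient's measurements
      pat_peak <- exp(stats::rnorm(n_peaks, 0, 0.12))
      base <- baseline_profile(wavenumbers, spec$baseline_amplitude,
                               spec$baseline_smoothness, comp_scale)
      # right-skewed measurement counts (median near the lower third of the
      # range), matching observed per-patient acquisition counts
      n_meas <- spectra_per_patient[1] +
        stats::rbinom(1, spectra_per_patient[2] - spectra_per_patient[1], 0.31)
      for (m in seq_len(n_meas)) {
        k <- k + 1
        label <- stats::rbinom(1, 1, spec$class_balance)
        amp_jitter <- pat_peak * exp(stats::rnorm(n_peaks, 0, 0.15))
        clean <- pfac * (base + clean_spectrum(wavenumbers, spec, label,
                                               amp_jitter))
        acc <- matrix(0, spec$n_accumulations, p)
        for (a in seq_len(spec$n_accumulations)) {
          y <- clean + stats::rnorm(p, 0, spec$noise_sd)
          n_rays <- stats::rpois(1, spec$cosmic_ray_rate)
          if (n_rays > 0) {
            for (r in seq_len(n_rays)) {
              pos <- sample.int(p, 1)
              amp <- stats::runif(1, 20, 100) * max(spec$noise_sd, 1e-3)
              w <- sample(1:2, 1)
              idx <- pos:min(p, pos + w - 1)
              y[idx] <- y[idx] + amp
            }
          }
          acc[a, ] <- y
        }
        sid <- sprintf("%s_S%03d", pid, m)
        rows[[k]] <- colMeans(acc)
        if (keep_accumulations) acc_list[[sid]] <- acc
        meta[[k]] <- data.frame(patient_id = pid, sample_id = sid,
                                label = label, domain = spec$name,
                                n_accumulations = spec$n_accumulations,
                                stringsAsFactors = FALSE)
      }
    }
    intensities <- do.call(rbind, rows)
    meta <- do.call(rbind, meta)
    rownames(intensities) <- meta$sample_id
    new_cohort(wavenumbers, intensities, meta,
               if (keep_accumulations) acc_list else NULL)
  })
}

new_cohort <- function(wavenumbers, intensities, meta, accumulations = NULL) {
  stopifnot(ncol(intensities) == length(wavenumbers),
            nrow(intensities) == nrow(meta))
  if (any(diff(wavenumbers) <= 0))
    stop("invalid Spectrum: wavenumbers must be strictly increasing")
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = meta, accumulations = accumulations),
            class = "raman_cohort")
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat(sprintf("raman_cohort: %d spectra x %d points [%.0f-%.0f cm^-1]\n",
              nrow(x$intensities), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  domains: %s\n", paste(unique(x$meta$domain), collapse = ", ")))
  cat(sprintf("  patients: %d | labels: %s\n",
              length(unique(x$meta$patient_id)),
              paste(names(table(x$meta$label, useNA = "ifany")),
                    table(x$meta$label, useNA = "ifany"),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Subset a cohort by measurement index
#'
#' @param cohort A `raman_cohort`.
#' @param idx Integer or logical row index.
#' @return The subsetted `raman_cohort`.
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "raman_cohort"))
  meta <- cohort$meta[idx, , drop = FALSE]
  acc <- if (!is.null(cohort$accumulations))
    cohort$accumulations[meta$sample_id] else NULL
  new_cohort(cohort$wavenumbers,
             cohort$intensities[idx, , drop = FALSE], meta, acc)
}

#' Combine cohorts sharing a wavenumber grid
#'
#' @param ... `raman_cohort` objects on identical grids.
#' @return A single merged `raman_cohort`.
#' @export
bind_cohorts <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "raman_cohort")))
  wn <- xs[[1]]$wavenumbers
  for (x in xs) if (!isTRUE(all.equal(x$wavenumbers, wn)))
    stop("cannot bind cohorts: wavenumber grids differ")
  acc <- do.call(c, lapply(xs, function(x) x$accumulations))
  new_cohort(wn, do.call(rbind, lapply(xs, function(x) x$intensities)),
             do.call(rbind, lapply(xs, function(x) x$meta)), acc)
}

#' Apply a covariate shift to a domain
#'
#' Builds the source-to-target shift that test-time adaptation addresses:
#' autofluorescence amplitude scaled by `baseline_scale`, all peak centers
#' translated by `peak_shift` cm^-1, and noise scaled by `1 / snr_scale`.
#'
#' @param spec A [domain_spec()].
#' @param baseline_scale Multiplicative factor on the baseline amplitude (> 0).
#' @param peak_shift Translation of every peak center (cm^-1).
#' @param snr_scale Signal-to-noise scaling; noise SD is divided by it (> 0).
#' @param grid_range Length-2 range the shifted peaks must stay inside.
#' @return A new, independent [domain_spec()]; the input is not modified.
#' @export
shift_domain <- function(spec, baseline_scale = 1, peak_shift = 0,
                         snr_scale = 1, grid_range = c(400, 2000)) {
  stopifnot(inherits(spec, "domain_spec"))
  if (baseline_scale <= 0 || snr_scale <= 0)
    stop("invalid shift: baseline_scale and snr_scale must be > 0")
  out <- spec
  out$baseline_amplitude <- spec$baseline_amplitude * baseline_scale
  out$peaks$center <- spec$peaks$center + peak_shift
  out$noise_sd <- spec$noise_sd / snr_scale
  if (any(out$peaks$center < grid_range[1] | out$peaks$center > grid_range[2]))
    stop("invalid shift: peak center shifted outside the grid range")
  out
}

#' Render the noise-free expected spectrum of a domain
#'
#' Used by tests and fixtures to compare processed spectra against the known
#' generating truth (baseline + peaks, no noise, unit patient factor).
#'
#' @param spec A [domain_spec()].
#' @param label Class label (0 normal, 1 cancer).
#' @param wavenumbers Grid to render on.
#' @param include_baseline Include the autofluorescence background.
#' @return Numeric intensity vector.
#' @export
render_clean <- function(spec, label = 0, wavenumbers = raman_grid(),
                         include_baseline = TRUE) {
  stopifnot(inherits(spec, "domain_spec"))
  y <- clean_spectrum(wavenumbers, spec, label)
  if (include_baseline)
    y <- y + baseline_profile(wavenumbers, spec$baseline_amplitude,
                              spec$baseline_smoothness)
  y
}
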