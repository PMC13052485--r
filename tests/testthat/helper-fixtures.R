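# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small network configuration on a short grid, for fast training tests.
tiny_net <- function(input_length = 256, channels = 6) {
  model_config(input_length = input_length, initial_filters = channels,
               block_channels = rep(as.integer(channels), 6))
}

# A cleanly separable two-peak classification problem: cancer doubles the
# 997 band and halves the 1308 band, almost no noise, no baseline.
separable_spec <- function() {
  peaks <- rbind(
    peak_spec(997, 8, 1.0, 2.0),
    peak_spec(1308, 10, 1.0, 0.5),
    peak_spec(1450, 12, 1.5, 1.0))
  domain_spec("separable", peaks = peaks, baseline_amplitude = 0.2,
              baseline_smoothness = 300, noise_sd = 0.02,
              cosmic_ray_rate = 0, patient_effect_sd = 0.05,
              n_accumulations = 1, class_balance = 0.5)
}

# Separable cohort on a short grid, already normalized (no heavy pipeline).
separable_cohort <- function(n_patients = 20, seed = 1, n_points = 256) {
  co <- generate_cohort(separable_spec(), n_patients, c(8, 12), seed,
                        wavenumbers = raman_grid(n_points = n_points),
                        keep_accumulations = FALSE)
  co$intensities <- t(apply(co$intensities, 1, normalize_spectrum, "minmax"))
  co
}

# Benchmark-scale fixture shared by the adaptation and acceptance tests:
# the synthetic multi-domain study data plus one pre-trained network.
bench_fixture <- function() {
  memo("bench_fixture", function() {
    cfg <- benchmark_config(seed = 42)
    data <- ramanadapt:::benchmark_data(cfg)
    model <- ramanadapt:::benchmark_pretrain("pB+pC", data, cfg, 42017L)
    list(cfg = cfg, data = data, model = model)
  })
}
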