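# ramanadapt

Binary tissue classification from Raman spectra in small-cohort settings:
spectral preprocessing, a 1D residual network, multi-domain pre-training,
efficient (half-frozen) fine-tuning, unsupervised test-time adaptation by
prediction-entropy minimization, classical SVM/random-forest comparators,
and a leave-one-patient-out evaluation harness — with a synthetic Raman
cohort simulator so every stage runs without clinical data.

## The problem and the approach

Intraoperative Raman spectroscopy yields, per deployment, a handful of
patients and ~100 spectra of 1174 points on a 400–2000 cm⁻¹ grid, swamped
by tissue autofluorescence. Training a deep classifier on such a cohort
alone overfits badly. The workflow implemented here:

1. **Preprocess** raw accumulations: cosmic-ray removal by
   across-accumulation medians, averaging, optional instrument-response
   correction, BubbleFill autofluorescence removal (a recursive
   tangent-circle lower envelope), normalization, resampling to the fixed
   grid.
2. **Pre-train** a ResNet-style 1D CNN — stem convolution, six residual
   blocks of four convolutions (kernel 5, stride-2 downsampling in the stem
   and per block, batch norm everywhere, ~1.27 M parameters at the default
   width), softmax head with binary cross-entropy — on larger source
   domains (a bacteria-like corpus, then multi-organ cancer cohorts).
3. **Adapt** to the small target cohort either with labels — *efficient
   fine-tuning*: freeze the stem and first three blocks (~50% of
   parameters), adapt the rest — or without labels — *test-time
   adaptation*: per measurement, minimize the prediction entropy
   H(ŷ) = −Σ_c p(ŷ_c) log p(ŷ_c) for 5 steps over the head and
   batch-norm affine parameters, with per-patient reset so patients never
   influence each other.
4. **Evaluate** by leave-one-patient-out cross-validation, 5 repetitions,
   mean (SD), Welch t-tests, plus univariate per-peak statistics
   (Cohen's d, p-value, mean-difference CI, single-peak AUC).

The network, backpropagation, Adam, and the entropy-minimization adaptation
are implemented in the package (R + RcppArmadillo convolution kernels,
verified against a plain-R reference and finite differences).

## Worked example

```r
library(ramanadapt)

# a synthetic 10-patient prostate cohort with raw accumulations
cohort <- generate_cohort(domain_preset("prostate_target"),
                          n_patients = 10, spectra_per_patient = c(7, 18),
                          seed = 7)
cohort
#> raman_cohort: 110 spectra x 1174 points [400-2000 cm^-1]
#>   domains: prostate_target
#>   patients: 10 | labels: 0=46 1=64

proc <- preprocess_cohort(cohort)          # full chain, 1174-point output

# which literature peaks discriminate cancer from normal?
ua <- univariate_peak_analysis(proc)
head(ua[order(-ua$auc), c("wavenumber", "auc", "p_value")], 3)
#>   wavenumber       auc      p_value
#> 2        994 0.7476223 3.602000e-06
#> 3        997 0.7476223 3.602000e-06
#> 4       1007 0.7387908 1.040915e-05
```

The phenylalanine band near 997 cm⁻¹ carries the strongest single-peak
signal (AUC ≈ 0.75 under the simulator's default cancer signature) — the
994/997 windows overlap, so they share a feature. A model comparison on the
synthetic multi-domain study (pre-training sources, covariate-shifted
target, LOPO, 5 repetitions):

```r
res <- run_benchmark(benchmark_config(seed = 1))
res         # mean (SD) per variant: scratch, p, p+F, p+TTA, svm, rf
res$comparisons   # Welch t-tests vs the SVM baseline
```

## Command line

A thin launcher over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ramanadapt.R", package = "ramanadapt"))')" \
    simulate --domain prostate_target --patients 10 --seed 7 --out cohort
```

Subcommands: `simulate`, `preprocess`, `pretrain`, `finetune`, `tta`,
`baseline`, `evaluate`, `benchmark`. Every run writes a `.runlog.txt` with
the package version and resolved configuration.

## Scope

The simulator emulates the statistical structure of prospective prostate
cohorts (patient heterogeneity, class-dependent literature peaks, strong
autofluorescence, cosmic rays, domain shift); it does not model instrument
optics, and synthetic effect sizes are free parameters — orderings and
contracts, not clinical metric values, are what the test suite asserts.
See the methods vignette (`vignettes/raman-tissue-classification.Rmd`) for
the model, its assumptions, parameter defaults and known limitations.
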