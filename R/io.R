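#' Write a cohort as delimited-text tables
#'
#' Two UTF-8 TSV files: a spectra table (first column `sample_id`, then one
#' column per wavenumber, header = the grid) and a metadata table
#' (`patient_id`, `sample_id`, `label`, `domain`, `n_accumulations`).
#' Intensities and wavenumbers are serialized at full double precision so a
#' write/read round trip is bit-identical. Raw accumulation matrices are not
#' serialized.
#'
#' @param cohort A `raman_cohort`.
#' @param spectra_path Path for the spectra table.
#' @param meta_path Path for the metadata table; defaults to the spectra
#'   path with a `_meta.tsv` suffix.
#' @return Invisibly, the two paths.
#' @export
write_spectra <- function(cohort, spectra_path,
                          meta_path = default_meta_path(spectra_path)) {
  stopifnot(inherits(cohort, "raman_cohort"))
  fmt <- function(x) sprintf("%.17g", x)
  header <- c("sample_id", fmt(cohort$wavenumbers))
  con <- file(spectra_path, "w", encoding = "UTF-8")
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(cohort$intensities))) {
    writeLines(paste(c(cohort$meta$sample_id[i],
                       fmt(cohort$intensities[i, ])), collapse = "\t"), con)
  }
  close(con)
  meta <- cohort$meta
  meta$label <- ifelse(is.na(meta$label), "unknown", as.character(meta$label))
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(spectra = spectra_path, meta = meta_path))
}

default_meta_path <- function(spectra_path)
  paste0(sub("\\.tsv$", "", spectra_path), "_meta.tsv")

#' Read a cohort from delimited-text tables
#'
#' Inverse of [write_spectra()]; malformed input is reported with the
#' offending sample ids or line numbers.
#'
#' @param spectra_path Spectra table path.
#' @param meta_path Metadata table path.
#' @return A `raman_cohort`.
#' @export
read_spectra <- function(spectra_path,
                         meta_path = default_meta_path(spectra_path)) {
  lines <- readLines(spectra_path, encoding = "UTF-8")
  if (length(lines) < 2) stop("spectra table has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "sample_id")
    stop("format error: first column must be sample_id")
  wn <- as.numeric(header[-1])
  if (any(is.na(wn)) || any(diff(wn) <= 0))
    stop("format error: wavenumber header must be numeric and strictly increasing")
  n <- length(lines) - 1
  ints <- matrix(NA_real_, n, length(wn))
  sids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop(sprintf("format error at line %d: expected %d fields, got %d",
                   i + 1, length(header), length(f)))
    sids[i] <- f[1]
    vals <- as.numeric(f[-1])
    if (any(is.na(vals)))
      stop(sprintf("format error at line %d: non-numeric intensity", i + 1))
    ints[i, ] <- vals
  }
  rownames(ints) <- sids
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            colClasses = "character", fileEncoding = "UTF-8")
  need <- c("patient_id", "sample_id", "label", "domain", "n_accumulations")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop(sprintf("metadata table lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  missing_ids <- setdiff(sids, meta$sample_id)
  if (length(missing_ids) > 0)
    stop(sprintf("metadata row missing for sample_id(s): %s",
                 paste(missing_ids, collapse = ", ")))
  meta <- meta[match(sids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  bad <- !meta$label %in% c("0", "1", "unknown")
  if (any(bad))
    stop(sprintf("format error: label must be 0, 1 or unknown (sample %s)",
                 meta$sample_id[which(bad)[1]]))
  lab <- rep(NA_integer_, nrow(meta))
  known <- meta$label != "unknown"
  lab[known] <- as.integer(meta$label[known])
  meta$label <- lab
  meta$n_accumulations <- as.integer(meta$n_accumulations)
  new_cohort(wn, ints, meta)
}

#' Read a structured run configuration
#'
#' YAML file with sections mirroring the module configurations (`simulate`,
#' `preprocess`, `model`, `train`, `finetune`, `tta`, `baseline`,
#' `evaluate`), plus a global `seed` and `output_dir`. Unknown section names
#' are rejected.
#'
#' @param path YAML file path.
#' @return Named list of sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("simulate", "preprocess", "model", "train", "finetune", "tta",
             "baseline", "evaluate", "benchmark", "seed", "output_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop(sprintf("unknown config section(s): %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  cfg
}
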