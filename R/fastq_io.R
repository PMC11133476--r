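#' Read a FASTQ file into a tibble
#'
#' Plain or gzip-compressed FASTQ, Sanger (+33) quality encoding.
#'
#' @param path Path to the FASTQ file.
#' @return A tibble `read_id, dna, quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("FASTQ file not found: %s", path),
                        class = c("biopanr_missing_file", "error")))
  }
  # Biostrings warns that FASTQ metadata columns are dropped; irrelevant here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    dna = as.character(x),
    quality = as.character(Biostrings::quality(x))
  )
}

#' Read a sample sheet
#'
#' A sample sheet is a TSV with columns `file`, `tissue`, `round`,
#' `library`, one row per FASTQ file.
#'
#' @param path Path to the TSV.
#' @param base_dir Directory relative to which `file` entries are resolved
#'   (defaults to the sheet's own directory).
#' @return A tibble with the four required columns, `file` resolved to full
#'   paths.
#' @export
read_sample_sheet <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("sample sheet not found: %s", path),
                        class = c("biopanr_missing_file", "error")))
  }
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("file", "tissue", "round", "library")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    stop(errorCondition(
      sprintf("sample sheet lacks column(s): %s", paste(missing, collapse = ", ")),
      class = c("biopanr_bad_sample_sheet", "error")))
  }
  sheet$round <- as.integer(sheet$round)
  if (anyNA(sheet$round)) {
    stop(errorCondition("sample sheet has non-integer rounds",
                        class = c("biopanr_bad_sample_sheet", "error")))
  }
  abs <- file.path(base_dir, sheet$file)
  sheet$file <- ifelse(file.exists(sheet$file), sheet$file, abs)
  tibble::as_tibble(sheet[, required])
}

#' Extract and count inserts from one FASTQ sample
#'
#' @param path FASTQ file.
#' @param spec [library_spec()] or preset name.
#' @param tissue,round,library Sample labels.
#' @param min_mean_phred Mean-phred read filter threshold (`NULL` disables).
#' @return Raw insert count table (see [count_inserts()]).
#' @export
extract_sample <- function(path, spec, tissue, round, library,
                           min_mean_phred = 20) {
  reads <- read_fastq(path)
  ext <- extract_inserts(reads$dna, spec, quality = reads$quality,
                         min_mean_phred = min_mean_phred,
                         read_id = reads$read_id)
  count_inserts(ext, tissue, round, library)
}

#' Extract inserts for every sample in a sample sheet
#'
#' @param sheet Tibble from [read_sample_sheet()].
#' @param specs Named list of [library_spec()] objects (or preset names)
#'   keyed by the `library` values of the sheet; a single spec is recycled.
#' @param min_mean_phred Mean-phred read filter threshold.
#' @return Combined raw insert count table over all samples.
#' @export
extract_samples <- function(sheet, specs, min_mean_phred = 20) {
  if (inherits(specs, "library_spec") ||
      (is.character(specs) && is.null(names(specs)))) {
    specs <- stats::setNames(
      rep(list(as_library_spec(specs)), length(unique(sheet$library))),
      unique(sheet$library))
  }
  specs <- lapply(specs, as_library_spec)
  unknown <- setdiff(unique(sheet$library), names(specs))
  if (length(unknown) > 0L) {
    stop(errorCondition(
      sprintf("no library spec for: %s", paste(unknown, collapse = ", ")),
      class = c("biopanr_bad_sample_sheet", "error")))
  }
  tabs <- lapply(seq_len(nrow(sheet)), function(i) {
    extract_sample(sheet$file[i], specs[[sheet$library[i]]],
                   sheet$tissue[i], sheet$round[i], sheet$library[i],
                   min_mean_phred = min_mean_phred)
  })
  dplyr::bind_rows(tabs)
}
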