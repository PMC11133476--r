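#' Translate the inserts of a raw insert table
#'
#' Adds a `translation` column (frame 0, standard code; stops as `*`,
#' ambiguous codons as `X`).
#'
#' @param raw_table Tibble with an `insert_dna` column.
#' @return The table with a `translation` column appended.
#' @export
translate_inserts <- function(raw_table) {
  stopifnot(is.data.frame(raw_table), "insert_dna" %in% names(raw_table))
  if (nrow(raw_table) == 0L) {
    raw_table$translation <- character(0)
    return(raw_table)
  }
  uq <- unique(raw_table$insert_dna)
  tr <- stats::setNames(translate_dna(uq), uq)
  raw_table$translation <- unname(tr[raw_table$insert_dna])
  raw_table
}

#' Remove stop-codon and invalid translations
#'
#' Retains exactly the rows whose translation contains neither a stop
#' (`*`) nor a non-residue (`X`, from ambiguous codons).
#'
#' @param translated Tibble with a `translation` column (see
#'   [translate_inserts()]).
#' @return The filtered table.
#' @export
drop_stop_and_invalid <- function(translated) {
  stopifnot("translation" %in% names(translated))
  translated[!grepl("[*X]", translated$translation, fixed = FALSE), ,
             drop = FALSE]
}

#' Enforce library length and linker pattern
#'
#' Keeps rows whose translation is exactly
#' `prefix_residues + peptide + suffix_residues` with the library's peptide
#' length, and strips the linkers, emitting a `peptide` column.
#'
#' @param translated Tibble with a `translation` column, already free of
#'   stops and non-residues.
#' @param spec [library_spec()] or preset name.
#' @return The filtered table with a `peptide` column.
#' @export
pattern_conformity_filter <- function(translated, spec) {
  spec <- as_library_spec(spec)
  stopifnot("translation" %in% names(translated))
  np <- nchar(spec$prefix_residues)
  ns <- nchar(spec$suffix_residues)
  want <- np + spec$peptide_length + ns
  tr <- translated$translation
  ok <- nchar(tr) == want &
    substr(tr, 1L, np) == spec$prefix_residues &
    substr(tr, want - ns + 1L, want) == spec$suffix_residues
  out <- translated[ok, , drop = FALSE]
  out$peptide <- substr(out$translation, np + 1L, np + spec$peptide_length)
  out
}

#' Merge synonymous DNA variants into unique peptides
#'
#' Groups rows by `(peptide, tissue, round, library)`, summing counts and
#' recording how many distinct DNA variants were merged. Merging never
#' crosses tissue, round or library boundaries.
#'
#' @param rows Tibble with `peptide, tissue, round, library, count` and
#'   (optionally) `insert_dna` columns.
#' @return A peptide count table:
#'   `peptide, tissue, round, library, count, n_dna_variants`.
#' @export
merge_duplicate_peptides <- function(rows) {
  stopifnot(all(c("peptide", "tissue", "round", "library", "count") %in%
                  names(rows)))
  if (!"insert_dna" %in% names(rows)) {
    # already-merged rows carry their variant tally; fresh rows count as one
    if (!"n_dna_variants" %in% names(rows)) rows$n_dna_variants <- 1L
    return(rows %>%
      dplyr::group_by(.data$peptide, .data$tissue, .data$round,
                      .data$library) %>%
      dplyr::summarise(count = sum(.data$count),
                       n_dna_variants = sum(.data$n_dna_variants),
                       .groups = "drop") %>%
      dplyr::arrange(.data$library, .data$tissue, .data$round,
                     .data$peptide))
  }
  rows %>%
    dplyr::group_by(.data$peptide, .data$tissue, .data$round, .data$library) %>%
    dplyr::summarise(count = sum(.data$count),
                     n_dna_variants = dplyr::n_distinct(.data$insert_dna),
                     .groups = "drop") %>%
    dplyr::arrange(.data$library, .data$tissue, .data$round, .data$peptide)
}

#' Summarise a filtration cascade
#'
#' Counts unique sequences (and summed reads) remaining after each stage of
#' the cascade, per `(tissue, round, library)`. Stages must descend from the
#' same input: each later stage's keys must be a subset of the earlier
#' stage's.
#'
#' @param input,no_stop,conformant Raw insert tables (with `insert_dna`).
#' @param merged Peptide count table from [merge_duplicate_peptides()].
#' @return A tibble `tissue, round, library, stage, n_unique, n_reads` with
#'   stage one of `input`, `no_stop_or_invalid`, `pattern_conformant`,
#'   `merged_unique_peptides`; `n_unique` is non-increasing across stages.
#' @export
filtration_report <- function(input, no_stop, conformant, merged) {
  key <- function(tab) {
    paste(tab$insert_dna, tab$tissue, tab$round, tab$library)
  }
  if (!all(key(no_stop) %in% key(input)) ||
      !all(key(conformant) %in% key(no_stop)))
    stop("inconsistent provenance: stages do not descend from the same input")
  stage_counts <- function(tab, stage, unit_col) {
    if (nrow(tab) == 0L) {
      return(tibble::tibble(tissue = character(), round = integer(),
                            library = character(), stage = stage,
                            n_unique = integer(), n_reads = integer()))
    }
    tab %>%
      dplyr::group_by(.data$tissue, .data$round, .data$library) %>%
      dplyr::summarise(n_unique = dplyr::n_distinct(.data[[unit_col]]),
                       n_reads = sum(.data$count), .groups = "drop") %>%
      dplyr::mutate(stage = stage)
  }
  out <- dplyr::bind_rows(
    stage_counts(input, "input", "insert_dna"),
    stage_counts(no_stop, "no_stop_or_invalid", "insert_dna"),
    stage_counts(conformant, "pattern_conformant", "insert_dna"),
    stage_counts(merged, "merged_unique_peptides", "peptide")
  )
  stages <- c("input", "no_stop_or_invalid", "pattern_conformant",
              "merged_unique_peptides")
  out$stage <- factor(out$stage, levels = stages)
  out <- out %>%
    dplyr::select("tissue", "round", "library", "stage", "n_unique",
                  "n_reads") %>%
    dplyr::arrange(.data$library, .data$tissue, .data$round, .data$stage)
  # zero-fill stages that lost every sequence of a sample
  out %>%
    tidyr::complete(tidyr::nesting(!!rlang::sym("tissue"),
                                   !!rlang::sym("round"),
                                   !!rlang::sym("library")),
                    stage = factor(stages, levels = stages),
                    fill = list(n_unique = 0L, n_reads = 0L)) %>%
    dplyr::arrange(.data$library, .data$tissue, .data$round, .data$stage)
}

#' Run the full filtration cascade
#'
#' Translate, drop stop-codon/invalid translations, enforce the library
#' pattern and length, and merge synonymous DNA variants — in that order.
#'
#' @param raw_table Raw insert count table (see [count_inserts()]).
#' @param spec [library_spec()] or preset name.
#' @return A list with `peptides` (the peptide count table) and `report`
#'   (the [filtration_report()]).
#' @export
filter_peptides <- function(raw_table, spec) {
  spec <- as_library_spec(spec)
  s0 <- translate_inserts(raw_table)
  s1 <- drop_stop_and_invalid(s0)
  s2 <- pattern_conformity_filter(s1, spec)
  s3 <- merge_duplicate_peptides(s2)
  list(peptides = s3, report = filtration_report(s0, s1, s2, s3))
}
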