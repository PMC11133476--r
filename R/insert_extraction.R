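#' Fuzzy scan for a motif in a DNA sequence
#'
#' Finds the window of `sequence` with the fewest Hamming mismatches to
#' `motif` among all windows with at most `max_mm` mismatches. Ties are
#' broken by the leftmost start. `N` (or any non-matching character) in the
#' sequence counts as a mismatch.
#'
#' @param sequence DNA string to scan.
#' @param motif DNA motif to look for.
#' @param max_mm Maximum number of mismatches allowed.
#' @return A list with `start` (0-based offset) and `mismatches`, or `NULL`
#'   if no window qualifies (including when the motif is longer than the
#'   sequence).
#' @examples
#' mismatch_scan("TTACGTTT", "ACGT", 0)  # start 2, 0 mismatches
#' @export
mismatch_scan <- function(sequence, motif, max_mm) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(motif), length(motif) == 1L, max_mm >= 0)
  hit <- cpp_scan_motif(sequence, motif, as.integer(max_mm))
  if (hit[1] < 0) return(NULL)
  list(start = hit[1], mismatches = hit[2])
}

#' Mean-quality read filter
#'
#' A read passes when the arithmetic mean of its per-base phred scores is at
#' least `min_mean_phred`.
#'
#' @param quality Integer vector of phred scores (one read), or a quality
#'   string in Sanger (+33) encoding.
#' @param min_mean_phred Threshold on the mean phred score.
#' @return `TRUE` or `FALSE`.
#' @export
mean_quality_pass <- function(quality, min_mean_phred = 20) {
  if (is.character(quality)) {
    stopifnot(length(quality) == 1L)
    quality <- phred_scores(quality)
  }
  if (length(quality) == 0L) stop("malformed input: empty read")
  if (any(quality < 0)) stop("malformed input: negative phred score")
  mean(quality) >= min_mean_phred
}

#' Decode a Sanger-encoded quality string into phred scores
#'
#' @param quality Quality string (ASCII offset 33).
#' @return Integer vector of phred scores.
#' @export
phred_scores <- function(quality) {
  utf8ToInt(quality) - 33L
}

# vectorized mean phred over quality strings; fast path for equal lengths
mean_phred <- function(quality) {
  lens <- nchar(quality)
  if (length(quality) > 0L && all(lens == lens[1])) {
    codes <- utf8ToInt(paste(quality, collapse = ""))
    return(colMeans(matrix(codes, nrow = lens[1])) - 33)
  }
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Translate DNA to amino acids (frame 0, standard code)
#'
#' Stop codons translate to `*`; any codon containing an ambiguous base
#' (e.g. `N`) translates to `X`.
#'
#' @param dna Character vector of DNA sequences; every length must be a
#'   multiple of 3.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_dna(c("ATGAAA", "TAA"))
#' @export
translate_dna <- function(dna) {
  if (length(dna) == 0L) return(character(0))
  if (any(nchar(dna) %% 3L != 0L))
    stop("DNA length must be divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     if.fuzzy.codon = "X"))
}

reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
}

#' Extract library inserts from reads
#'
#' Scans each read (and its reverse complement) for the library's 5' flank
#' followed, after exactly the expected insert length, by the 3' flank, each
#' within the library's mismatch tolerance. Among qualifying placements the
#' one with the minimal total number of flank mismatches wins; ties go to
#' the leftmost placement, and the forward strand is preferred over the
#' reverse.
#'
#' @param dna Character vector of read sequences.
#' @param spec A [library_spec()] or preset name.
#' @param quality Optional vector of quality strings (Sanger encoding); when
#'   given together with `min_mean_phred`, low-quality reads are dropped
#'   before scanning.
#' @param min_mean_phred Mean-phred threshold, or `NULL` to skip quality
#'   filtering.
#' @param read_id Optional read identifiers (defaults to `read0001` style).
#' @return A tibble with one row per successfully extracted read:
#'   `read_id`, `insert_dna`, `strand` (`"forward"`/`"reverse"`),
#'   `flank5_mismatches`, `flank3_mismatches`.
#' @export
extract_inserts <- function(dna, spec, quality = NULL, min_mean_phred = NULL,
                            read_id = NULL) {
  spec <- as_library_spec(spec)
  n <- length(dna)
  if (is.null(read_id)) read_id <- sprintf("read%06d", seq_len(n))
  if (!is.null(quality)) {
    stopifnot(length(quality) == n)
    if (any(nchar(quality) != nchar(dna)))
      stop("quality strings must match read lengths")
    if (!is.null(min_mean_phred)) {
      keep <- mean_phred(quality) >= min_mean_phred
      dna <- dna[keep]
      read_id <- read_id[keep]
    }
  }
  if (length(dna) == 0L) {
    return(tibble::tibble(read_id = character(), insert_dna = character(),
                          strand = character(), flank5_mismatches = integer(),
                          flank3_mismatches = integer()))
  }
  ilen <- insert_length(spec)
  mm <- spec$max_flank_mismatch
  fwd <- cpp_scan_inserts(dna, spec$flank5, spec$flank3, ilen, mm)
  rcseq <- reverse_complement(dna)
  rev <- cpp_scan_inserts(rcseq, spec$flank5, spec$flank3, ilen, mm)

  tot_f <- fwd[, 2] + fwd[, 3]
  tot_r <- rev[, 2] + rev[, 3]
  use_f <- fwd[, 1] >= 0 & (rev[, 1] < 0 | tot_f <= tot_r)
  use_r <- rev[, 1] >= 0 & !use_f
  hit <- use_f | use_r

  start0 <- ifelse(use_f, fwd[, 1], rev[, 1])
  seqs <- ifelse(use_f, dna, rcseq)
  off5 <- nchar(spec$flank5)
  out <- tibble::tibble(
    read_id = read_id[hit],
    insert_dna = substr(seqs[hit], start0[hit] + off5 + 1L,
                        start0[hit] + off5 + ilen),
    strand = ifelse(use_f[hit], "forward", "reverse"),
    flank5_mismatches = as.integer(ifelse(use_f, fwd[, 2], rev[, 2]))[hit],
    flank3_mismatches = as.integer(ifelse(use_f, fwd[, 3], rev[, 3]))[hit]
  )
  out
}

#' Extract the insert from a single read
#'
#' Single-read convenience wrapper around [extract_inserts()].
#'
#' @inheritParams extract_inserts
#' @param dna One read sequence.
#' @return A list (`insert_dna`, `strand`, `flank5_mismatches`,
#'   `flank3_mismatches`) or `NULL` when no qualifying placement exists.
#' @export
extract_insert <- function(dna, spec, quality = NULL, min_mean_phred = NULL) {
  res <- extract_inserts(dna, spec, quality = quality,
                         min_mean_phred = min_mean_phred)
  if (nrow(res) == 0L) return(NULL)
  as.list(res[1, c("insert_dna", "strand", "flank5_mismatches",
                   "flank3_mismatches")])
}

#' Count extracted inserts
#'
#' Aggregates a set of insert extractions from one sample into a raw insert
#' count table keyed by distinct insert DNA.
#'
#' @param extractions Tibble from [extract_inserts()] (or anything with an
#'   `insert_dna` column).
#' @param tissue,round,library Sample labels attached to every row.
#' @return A tibble `insert_dna, tissue, round, library, count`; the counts
#'   sum to the number of extractions.
#' @export
count_inserts <- function(extractions, tissue, round, library) {
  stopifnot(is.data.frame(extractions))
  if (nrow(extractions) == 0L) {
    return(tibble::tibble(insert_dna = character(), tissue = character(),
                          round = integer(), library = character(),
                          count = integer()))
  }
  extractions %>%
    dplyr::count(insert_dna = .data$insert_dna, name = "count") %>%
    dplyr::mutate(tissue = tissue, round = as.integer(round),
                  library = library) %>%
    dplyr::select("insert_dna", "tissue", "round", "library", "count") %>%
    dplyr::arrange(.data$insert_dna)
}
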