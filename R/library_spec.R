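#' Describe a phage display library
#'
#' A `library_spec` captures everything needed to recognise and decode one
#' display library in sequencing reads: the length of the random peptide,
#' the fixed linker residues that surround it on the displayed protein, the
#' vector-derived DNA flanks that border the insert in the amplicon, and
#' the per-flank mismatch tolerance used when scanning reads.
#'
#' The two bundled presets (see [library_preset()]) correspond to the
#' commercial naive libraries commonly used for in vivo panning: a 12-mer
#' library displaying `S-<peptide>-GGGS` and a 20-mer library displaying
#' `S-<peptide>-S`, both sharing the amplicon flanks
#' `CCTTTCTATTCTCAC` / `GCCGAAACTGTTGAA`.
#'
#' @param name Identifier for the library.
#' @param peptide_length Length of the random peptide, in amino acids.
#' @param prefix_residues Fixed residues immediately before the peptide
#'   (may be `""`).
#' @param suffix_residues Fixed residues immediately after the peptide.
#' @param flank5,flank3 DNA sequences bordering the insert in the read.
#' @param max_flank_mismatch Maximum mismatches tolerated per flank when
#'   scanning reads (default 2).
#'
#' @return An object of class `library_spec`.
#' @examples
#' phd12 <- library_preset("phd12")
#' insert_length(phd12)  # 3 * (1 + 12 + 4) = 51 nt
#' @export
library_spec <- function(name, peptide_length, prefix_residues, suffix_residues,
                         flank5 = "CCTTTCTATTCTCAC",
                         flank3 = "GCCGAAACTGTTGAA",
                         max_flank_mismatch = 2L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  peptide_length <- as.integer(peptide_length)
  max_flank_mismatch <- as.integer(max_flank_mismatch)
  if (is.na(peptide_length) || peptide_length <= 0L)
    stop("`peptide_length` must be a positive integer")
  if (is.na(max_flank_mismatch) || max_flank_mismatch < 0L)
    stop("`max_flank_mismatch` must be >= 0")
  for (fl in c(flank5, flank3)) {
    if (!nzchar(fl) || grepl("[^ACGT]", fl))
      stop("flanks must be nonempty strings over A/C/G/T")
  }
  for (res in c(prefix_residues, suffix_residues)) {
    if (nchar(res) > 0 && grepl(sprintf("[^%s]", AA_ALPHABET_STR), res))
      stop("linker residues must be canonical amino acids")
  }
  structure(
    list(
      name = name,
      peptide_length = peptide_length,
      prefix_residues = prefix_residues,
      suffix_residues = suffix_residues,
      flank5 = flank5,
      flank3 = flank3,
      max_flank_mismatch = max_flank_mismatch
    ),
    class = "library_spec"
  )
}

# the 20 canonical residues, alphabetical
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_STR <- paste(AA_ALPHABET, collapse = "")

#' Built-in library presets
#'
#' @param name `"phd12"` (12-mer, `S-<peptide>-GGGS` linker) or `"trico20"`
#'   (20-mer, `S-<peptide>-S` linker).
#' @return A [library_spec()].
#' @export
library_preset <- function(name = c("phd12", "trico20")) {
  name <- match.arg(name)
  switch(name,
    phd12 = library_spec("phd12", 12L, "S", "GGGS"),
    trico20 = library_spec("trico20", 20L, "S", "S")
  )
}

#' Expected insert length of a library, in nucleotides
#'
#' Three times the number of encoded residues: prefix linker + peptide +
#' suffix linker.
#'
#' @param spec A [library_spec()].
#' @return Integer number of nucleotides between the flanks.
#' @export
insert_length <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  3L * (nchar(spec$prefix_residues) + spec$peptide_length +
          nchar(spec$suffix_residues))
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf(
    "<library_spec> %s: %d-mer, pattern %s-<peptide>-%s, insert %d nt, <=%d mismatches/flank\n",
    x$name, x$peptide_length, x$prefix_residues, x$suffix_residues,
    insert_length(x), x$max_flank_mismatch))
  invisible(x)
}

# resolve a preset name / spec object into a library_spec
as_library_spec <- function(x) {
  if (inherits(x, "library_spec")) return(x)
  if (is.character(x) && length(x) == 1L) return(library_preset(x))
  stop("expected a library_spec or a preset name")
}
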