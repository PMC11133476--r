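#' Phage titer from UV absorbance
#'
#' Spectrophotometric titer of a purified filamentous phage preparation:
#' `virions/ml = (A269 - A320) * 6e16 / bases_per_virion`.
#'
#' @param a269 Absorbance at 269 nm.
#' @param a320 Absorbance at 320 nm (background).
#' @param bases_per_virion Number of DNA bases per virion.
#' @return Virions per ml.
#' @examples
#' phage_titer(0.2, 0.1, 6000)  # 1e12
#' @export
phage_titer <- function(a269, a320, bases_per_virion) {
  if (any(bases_per_virion <= 0)) stop("bases_per_virion must be positive")
  if (any(a269 < a320))
    stop("invalid spectrophotometry: A269 below A320")
  (a269 - a320) * 6e16 / bases_per_virion
}

write_hits_fasta <- function(hits, path) {
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  headers <- sprintf("%s|cluster%d|count=%d%s", hits$approach,
                     hits$cluster_id, hits$count,
                     if ("category" %in% names(hits))
                       paste0("|", hits$category) else "")
  aa <- Biostrings::AAStringSet(stats::setNames(hits$consensus, headers))
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Extraction, filtration, and the selected hit-identification strategies
#' for every library in a sample sheet; writes all tables, FASTA hit lists
#' and a run manifest into `out_dir`. Re-running with identical inputs and
#' seed reproduces identical outputs.
#'
#' @param samples Path to a sample sheet TSV (see [read_sample_sheet()]) or
#'   an equivalent tibble with resolved file paths.
#' @param library A [library_spec()], preset name, or named list of specs
#'   keyed by the sheet's `library` values.
#' @param out_dir Output directory (created if needed).
#' @param params [specificity_params()].
#' @param cut_height Dendrogram cut height; `NULL` for the per-library
#'   default.
#' @param min_mean_phred Mean-phred read filter threshold.
#' @param top_k Clusters reported by TOPIC.
#' @param approaches Subset of `c("topic20", "topic", "spec", "enrich")`.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list of written file paths.
#' @export
run_pipeline <- function(samples, library, out_dir,
                         params = specificity_params(),
                         cut_height = NULL, min_mean_phred = 20,
                         top_k = 10L,
                         approaches = c("topic20", "topic", "spec",
                                        "enrich"),
                         seed = NULL) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  sheet <- if (is.character(samples)) read_sample_sheet(samples)
           else tibble::as_tibble(samples)
  need_rounds <- seq_len(max(sheet$round))
  for (lib in unique(sheet$library)) {
    gap <- setdiff(need_rounds, sheet$round[sheet$library == lib])
    if ("enrich" %in% approaches && length(gap) > 0L) {
      stop(errorCondition(
        sprintf("sample sheet misses round(s) %s for library %s",
                paste(gap, collapse = ","), lib),
        class = c("biopanr_bad_sample_sheet", "error")))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)

  raw <- extract_samples(sheet, library, min_mean_phred = min_mean_phred)
  if (nrow(raw) == 0L) {
    stop(errorCondition("no inserts could be extracted from any sample",
                        class = c("biopanr_empty_extraction", "error")))
  }
  outputs <- character(0)
  save_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p)
    outputs[name] <<- p
    p
  }
  save_tsv(raw, "raw_inserts.tsv")

  specs <- if (inherits(library, "library_spec") || is.character(library)) {
    stats::setNames(rep(list(as_library_spec(library)),
                        length(unique(sheet$library))),
                    unique(sheet$library))
  } else lapply(library, as_library_spec)

  all_hits <- list()
  for (lib in unique(sheet$library)) {
    spec <- specs[[lib]]
    filt <- filter_peptides(raw[raw$library == lib, , drop = FALSE], spec)
    save_tsv(filt$peptides, sprintf("%s_peptides.tsv", lib))
    save_tsv(filt$report, sprintf("%s_filtration_report.tsv", lib))
    tab <- filt$peptides
    h <- if (is.null(cut_height)) default_cut_height(spec$peptide_length)
         else cut_height

    if ("topic20" %in% approaches) {
      hits <- topic20(tab, params, cut_height = h)
      save_tsv(hits, sprintf("%s_topic20_hits.tsv", lib))
      all_hits[[paste0(lib, "_topic20")]] <- hits
    }
    if ("topic" %in% approaches) {
      hits <- topic(tab, params, cut_height = h, top_k = top_k)
      save_tsv(hits, sprintf("%s_topic_hits.tsv", lib))
      all_hits[[paste0(lib, "_topic")]] <- hits
    }
    if ("spec" %in% approaches) {
      alloc <- spec_cluster_allocation(tab, round = params$round,
                                       cut_height = h)
      hits <- spec_select(alloc, params)
      save_tsv(alloc$assignment, sprintf("%s_spec_clusters.tsv", lib))
      save_tsv(alloc$profiles, sprintf("%s_spec_profiles.tsv", lib))
      save_tsv(hits, sprintf("%s_spec_hits.tsv", lib))
      all_hits[[paste0(lib, "_spec")]] <- hits
    }
    if ("enrich" %in% approaches) {
      assignment <- all_round_clusters(tab, cut_height = h)
      emat <- enrichment_matrix(tab, assignment)
      wide <- tibble::as_tibble(emat, rownames = "cluster_id")
      save_tsv(wide, sprintf("%s_enrichment_matrix.tsv", lib))
      enr <- enriched_clusters(
        emat, target_tissues = params$target_tissue,
        depleting_tissues = setdiff(params$control_tissues, "remote_heart"),
        rounds = sort(unique(tab$round)))
      save_tsv(tibble::tibble(cluster_id = enr),
               sprintf("%s_enriched_clusters.tsv", lib))
    }
    fasta_hits <- dplyr::bind_rows(all_hits[startsWith(names(all_hits), lib)])
    fa <- file.path(out_dir, sprintf("%s_hits.fasta", lib))
    write_hits_fasta(fasta_hits, fa)
    outputs[basename(fa)] <- fa
  }

  manifest <- list(
    package = "biopanr",
    version = as.character(utils::packageVersion("biopanr")),
    seed = seed,
    min_mean_phred = min_mean_phred,
    cut_height = cut_height,
    top_k = top_k,
    approaches = approaches,
    params = unclass(params),
    libraries = lapply(specs, unclass),
    samples = as.list(stats::setNames(basename(sheet$file),
                                      paste(sheet$tissue, sheet$round,
                                            sep = "_r"))),
    outputs = names(outputs))
  mpath <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  outputs["run_manifest.json"] <- mpath
  invisible(as.list(outputs))
}
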