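DNA_BASES <- c("A", "C", "G", "T")

# codons of the standard genetic code grouped by residue
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Configure a biopanning simulation
#'
#' Describes one simulated in vivo panning experiment: a naive display
#' library of distinct random clones with near-uniform log-normal
#' abundances, optional planted families of similar peptides with
#' tissue-specific fitness, the tissues sampled at each round, and the
#' error model used when reads are emitted.
#'
#' @param library [library_spec()] or preset name.
#' @param n_naive_clones Number of distinct background clones.
#' @param naive_meanlog,naive_sdlog Parameters of the log-normal abundance
#'   distribution of the naive library. The default `sdlog = 0.3` models a
#'   naive library that is close to equimolar, as unpanned commercial
#'   libraries are.
#' @param planted_families List of [planted_family()] objects.
#' @param tissues Tissues collected at every round.
#' @param target_tissue Tissue whose recovered phages seed the next round.
#' @param rounds Number of panning rounds (default 3).
#' @param depth Reads sampled per tissue per round.
#' @param error_rate Per-base substitution error rate of emitted reads.
#' @param phred_mean,phred_sd Normal model for per-base phred scores.
#' @param revcomp_fraction Fraction of emitted reads that are
#'   reverse-complemented.
#' @param read_length Emitted read length in nt (default 150).
#' @param seed Random seed; a fixed seed makes every simulator output
#'   byte-identical across runs.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(library = library_preset("phd12"),
                              n_naive_clones = 1000L,
                              naive_meanlog = 0,
                              naive_sdlog = 0.3,
                              planted_families = list(),
                              tissues = c("damaged_lv", "remote_heart",
                                          "kidney", "liver"),
                              target_tissue = "damaged_lv",
                              rounds = 3L,
                              depth = 10000L,
                              error_rate = 0.001,
                              phred_mean = 35,
                              phred_sd = 3,
                              revcomp_fraction = 0.5,
                              read_length = 150L,
                              seed = 1L) {
  library <- as_library_spec(library)
  stopifnot(n_naive_clones >= 1, rounds >= 1, depth >= 1,
            error_rate >= 0, error_rate < 1,
            revcomp_fraction >= 0, revcomp_fraction <= 1,
            target_tissue %in% tissues)
  if (log(n_naive_clones) > library$peptide_length * log(20))
    stop("n_naive_clones exceeds the peptide space of the library")
  total <- nchar(library$flank5) + insert_length(library) +
    nchar(library$flank3)
  if (read_length < total)
    stop("read_length shorter than flank5 + insert + flank3")
  for (f in planted_families) {
    stopifnot(inherits(f, "planted_family"))
    if (nchar(f$seed) != library$peptide_length)
      stop("planted family seed length does not match the library")
    if (!all(tissues %in% names(f$fitness)))
      stop("planted family fitness must name every tissue")
  }
  structure(
    list(library = library, n_naive_clones = as.integer(n_naive_clones),
         naive_meanlog = naive_meanlog, naive_sdlog = naive_sdlog,
         planted_families = planted_families, tissues = tissues,
         target_tissue = target_tissue, rounds = as.integer(rounds),
         depth = as.integer(depth), error_rate = error_rate,
         phred_mean = phred_mean, phred_sd = phred_sd,
         revcomp_fraction = revcomp_fraction,
         read_length = as.integer(read_length), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Declare a planted peptide family
#'
#' A family is a set of near-identical peptides (within `max_subs`
#' substitutions of a seed) sharing one per-tissue fitness profile, used to
#' plant recoverable ground truth into a simulation.
#'
#' @param seed_peptide The family's seed sequence.
#' @param n_variants Family size, including the seed.
#' @param max_subs Maximum substitutions of any member relative to the
#'   seed.
#' @param fitness Named numeric vector of per-tissue fitness multipliers,
#'   all > 0 (see [family_fitness()] for convenient profiles).
#' @return An object of class `planted_family`.
#' @export
planted_family <- function(seed_peptide, n_variants, max_subs, fitness) {
  stopifnot(is.character(seed_peptide), nchar(seed_peptide) >= 1,
            n_variants >= 1, max_subs >= 0,
            max_subs < nchar(seed_peptide),
            is.numeric(fitness), !is.null(names(fitness)), all(fitness > 0))
  structure(list(seed = seed_peptide, n_variants = as.integer(n_variants),
                 max_subs = as.integer(max_subs), fitness = fitness),
            class = "planted_family")
}

#' Fitness profiles for the standard tissue categories
#'
#' `lv_exclusive` binds (essentially) only the target tissue;
#' `whole_heart` binds target and remote heart; `control_enriched` binds
#' the off-target control organs. `background` is the residual fitness in
#' non-binding tissues — kept tiny but positive.
#'
#' @param category One of `"lv_exclusive"`, `"whole_heart"`,
#'   `"control_enriched"`.
#' @param tissues Tissue labels of the simulation.
#' @param target_tissue The target tissue label.
#' @param factor Fitness multiplier in the bound tissues (default 10).
#' @param background Fitness in unbound tissues (default `1e-8`).
#' @return Named numeric vector usable as `fitness` in
#'   [planted_family()].
#' @export
family_fitness <- function(category = c("lv_exclusive", "whole_heart",
                                        "control_enriched"),
                           tissues = c("damaged_lv", "remote_heart",
                                       "kidney", "liver"),
                           target_tissue = "damaged_lv",
                           factor = 10, background = 1e-8) {
  category <- match.arg(category)
  bound <- switch(category,
    lv_exclusive = target_tissue,
    whole_heart = c(target_tissue, "remote_heart"),
    control_enriched = setdiff(tissues, c(target_tissue, "remote_heart")))
  out <- stats::setNames(rep(background, length(tissues)), tissues)
  out[intersect(bound, tissues)] <- factor
  out
}

# n distinct random peptides of length L (uses the current RNG stream)
random_peptides <- function(n, L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- apply(matrix(sample(AA_ALPHABET, need * L, replace = TRUE),
                         nrow = need), 1L, paste, collapse = "")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Sample a naive display library
#'
#' Draws `n_naive_clones` distinct random peptides with abundances from
#' the configured log-normal. Deterministic under the config seed.
#'
#' @param config [simulation_config()].
#' @return Tibble `peptide, abundance`.
#' @export
sample_naive_library <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  peptides <- random_peptides(config$n_naive_clones,
                              config$library$peptide_length)
  tibble::tibble(
    peptide = peptides,
    abundance = stats::rlnorm(length(peptides), config$naive_meanlog,
                              config$naive_sdlog))
}

#' Generate a planted family's member peptides
#'
#' Produces `n_variants` distinct peptides (including the seed), each
#' within `max_subs` substitutions of the seed. Uses the current RNG
#' stream.
#'
#' @param seed_peptide Seed sequence.
#' @param n_variants Family size including the seed.
#' @param max_subs Substitution radius.
#' @return Character vector of member peptides (seed first).
#' @export
plant_family <- function(seed_peptide, n_variants, max_subs) {
  L <- nchar(seed_peptide)
  stopifnot(max_subs >= 0, max_subs < L, n_variants >= 1)
  reachable <- sum(vapply(0:max_subs,
                          function(k) choose(L, k) * 19^k, numeric(1)))
  if (n_variants > reachable)
    stop("n_variants exceeds the reachable substitution neighborhood")
  members <- seed_peptide
  seed_chars <- strsplit(seed_peptide, "")[[1]]
  while (length(members) < n_variants) {
    k <- if (max_subs == 1L) 1L else sample.int(max_subs, 1L)
    pos <- sample.int(L, k)
    cand <- seed_chars
    for (p in pos) {
      cand[p] <- sample(setdiff(AA_ALPHABET, seed_chars[p]), 1L)
    }
    cand <- paste(cand, collapse = "")
    if (!cand %in% members) members <- c(members, cand)
  }
  members
}

#' Simulate a multi-round biopanning experiment
#'
#' Each round, every collected tissue is sequenced as an independent
#' multinomial sample of `depth` reads with probability proportional to
#' the current pool composition times the clone's tissue fitness. Between
#' rounds the pool composition is updated by proportional carryover of the
#' target-tissue binders: the recovered target-tissue population is
#' amplified without bias, so the next round's pool proportions are the
#' previous pool's reweighted by target-tissue fitness. The recovered and
#' amplified phage population is orders of magnitude deeper than the
#' sequencing sample, so the readout does not bottleneck the pool.
#'
#' @param config [simulation_config()].
#' @return A list with `counts` (peptide count table over all tissues and
#'   rounds) and `truth` (planted-family ground truth: members, fitness,
#'   and expected target-tissue proportions per round).
#' @export
simulate_panning <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  naive <- sample_naive_library(config)  # sets the seed

  fam_tbl <- NULL
  fams <- config$planted_families
  members <- lapply(fams, function(f) plant_family(f$seed, f$n_variants,
                                                   f$max_subs))
  if (length(fams) > 0L) {
    fam_tbl <- tibble::tibble(
      family_id = rep(seq_along(fams),
                      vapply(members, length, integer(1))),
      peptide = unlist(members))
    fam_tbl$abundance <- stats::rlnorm(nrow(fam_tbl), config$naive_meanlog,
                                       config$naive_sdlog)
    naive <- naive[!naive$peptide %in% fam_tbl$peptide, , drop = FALSE]
  }

  pool <- dplyr::bind_rows(
    tibble::tibble(peptide = naive$peptide, abundance = naive$abundance,
                   family_id = 0L),
    if (!is.null(fam_tbl))
      fam_tbl[, c("peptide", "abundance", "family_id")])

  tissues <- config$tissues
  fit <- matrix(1, nrow = nrow(pool), ncol = length(tissues),
                dimnames = list(NULL, tissues))
  for (i in seq_along(fams)) {
    fit[pool$family_id == i, ] <-
      matrix(fams[[i]]$fitness[tissues], nrow = sum(pool$family_id == i),
             ncol = length(tissues), byrow = TRUE)
  }

  weights <- pool$abundance
  rows <- list()
  target_col <- match(config$target_tissue, tissues)
  expected <- list()
  exp_w <- pool$abundance
  for (r in seq_len(config$rounds)) {
    round_counts <- matrix(0L, nrow = nrow(pool), ncol = length(tissues))
    for (ti in seq_along(tissues)) {
      prob <- weights * fit[, ti]
      if (sum(prob) <= 0) stop("degenerate pool: all sampling weights zero")
      round_counts[, ti] <- as.integer(stats::rmultinom(1L, config$depth,
                                                        prob))
    }
    for (ti in seq_along(tissues)) {
      nz <- round_counts[, ti] > 0L
      if (any(nz)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          peptide = pool$peptide[nz], tissue = tissues[ti],
          round = r, library = config$library$name,
          count = round_counts[nz, ti])
      }
    }
    weights <- weights * fit[, target_col]  # proportional carryover
    # analytic expectation of the target-tissue composition this round
    p_t <- exp_w * fit[, target_col]
    p_t <- p_t / sum(p_t)
    if (length(fams) > 0L) {
      expected[[r]] <- tibble::tibble(
        family_id = seq_along(fams),
        round = r,
        expected_target_fraction = vapply(
          seq_along(fams),
          function(i) sum(p_t[pool$family_id == i]), numeric(1)))
    }
    exp_w <- p_t
  }

  truth <- list(
    families = if (length(fams) > 0L) tibble::tibble(
      family_id = seq_along(fams),
      seed = vapply(fams, `[[`, character(1), "seed"),
      members = I(members),
      fitness = I(lapply(fams, `[[`, "fitness"))) else NULL,
    expected = if (length(expected) > 0L) dplyr::bind_rows(expected)
               else NULL)

  counts <- dplyr::bind_rows(rows) %>%
    dplyr::mutate(round = as.integer(.data$round),
                  count = as.integer(.data$count)) %>%
    dplyr::arrange(.data$tissue, .data$round, .data$peptide)
  list(counts = counts, truth = truth)
}

#' Emit sequencing reads for a peptide count table
#'
#' For every counted peptide, emits that many reads: a random synonymous
#' codon choice for linker + peptide, the library flanks, a random offset
#' inside a read of the configured length with random sequence context,
#' per-base substitution errors at the configured rate, a configured
#' fraction of reads reverse-complemented, and phred strings from the
#' configured normal model. Uses the current RNG stream; seed via
#' [set.seed()] or use [emit_fastq()] for fully seeded file output.
#'
#' @param count_table Peptide count table (e.g. one (tissue, round) slice
#'   of [simulate_panning()] output).
#' @param config [simulation_config()].
#' @return Tibble `read_id, dna, quality, tissue, round, library,
#'   source_peptide`.
#' @export
simulate_reads <- function(count_table, config) {
  spec <- config$library
  if (nrow(count_table) == 0L) {
    return(tibble::tibble(read_id = character(), dna = character(),
                          quality = character(), tissue = character(),
                          round = integer(), library = character(),
                          source_peptide = character()))
  }
  bad <- nchar(count_table$peptide) != spec$peptide_length |
    grepl(sprintf("[^%s]", AA_ALPHABET_STR), count_table$peptide)
  if (any(bad)) stop("peptide incompatible with the library spec")

  tbl <- dplyr::arrange(count_table, .data$tissue, .data$round,
                        .data$peptide)
  pep <- rep(tbl$peptide, tbl$count)
  tis <- rep(tbl$tissue, tbl$count)
  rnd <- rep(tbl$round, tbl$count)
  n <- length(pep)
  rl <- config$read_length

  # synonymous codon choice, uniform per residue occurrence
  full <- paste0(spec$prefix_residues, pep, spec$suffix_residues)
  m <- nchar(full[1])
  resmat <- matrix(unlist(strsplit(full, "", fixed = TRUE),
                          use.names = FALSE), nrow = n, byrow = TRUE)
  codons <- codon_table()
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    res <- resmat[, j]
    cod <- character(n)
    for (r in unique(res)) {
      idx <- which(res == r)
      cs <- codons[[r]]
      cod[idx] <- cs[sample.int(length(cs), length(idx), replace = TRUE)]
    }
    cols[[j]] <- cod
  }
  insert <- do.call(paste0, cols)
  core <- paste0(spec$flank5, insert, spec$flank3)
  total <- nchar(core[1])
  if (total > rl) stop("read_length shorter than flank5 + insert + flank3")

  # random placement within random context; each read needs exactly
  # rl - total context bases, pooled into one string and sliced
  nctx <- rl - total
  off <- sample.int(nctx + 1L, n, replace = TRUE) - 1L
  ctx_codes <- sample(utf8ToInt("ACGT"), n * nctx, replace = TRUE)
  ctx_all <- rawToChar(as.raw(ctx_codes))
  cb <- (seq_len(n) - 1L) * nctx
  reads <- paste0(substring(ctx_all, cb + 1L, cb + off), core,
                  substring(ctx_all, cb + off + 1L, cb + nctx))

  # per-base substitution errors: a Binomial total over all bases placed
  # uniformly without replacement equals independent per-base flips
  if (config$error_rate > 0) {
    n_err <- stats::rbinom(1L, n * rl, config$error_rate)
    idx <- sort(sample.int(n * rl, n_err, useHash = TRUE))
    if (length(idx) > 0L) {
      ridx <- (idx - 1L) %/% rl + 1L
      pos <- (idx - 1L) %% rl + 1L
      cur <- substr(reads[ridx], pos, pos)
      altm <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                    c("A", "C", "T"), c("A", "C", "G"))
      alt <- altm[cbind(match(cur, DNA_BASES),
                        sample.int(3L, length(ridx), replace = TRUE))]
      # a read can carry several errors; apply one per pass
      ord <- stats::ave(seq_along(ridx), ridx, FUN = seq_along)
      for (k in seq_len(max(ord))) {
        sel <- ord == k
        x <- reads[ridx[sel]]
        substr(x, pos[sel], pos[sel]) <- alt[sel]
        reads[ridx[sel]] <- x
      }
    }
  }

  # strand
  if (config$revcomp_fraction > 0) {
    flip <- stats::runif(n) < config$revcomp_fraction
    if (any(flip)) reads[flip] <- reverse_complement(reads[flip])
  }

  # phred strings: rounded normal clamped to [2, 40], drawn from its
  # discretized distribution in one call and sliced from a pooled string
  vals <- 2:40
  cuts <- stats::pnorm(c(-Inf, vals[-length(vals)] + 0.5, Inf),
                       config$phred_mean, config$phred_sd)
  q <- vals[sample.int(length(vals), n * rl, replace = TRUE,
                       prob = diff(cuts))]
  qual_all <- rawToChar(as.raw(q + 33L))
  base0 <- (seq_len(n) - 1L) * rl
  qual <- substring(qual_all, base0 + 1L, base0 + rl)

  tibble::tibble(
    read_id = sprintf("%s_r%d_%07d", tis, rnd, seq_len(n)),
    dna = reads, quality = qual, tissue = tis, round = as.integer(rnd),
    library = spec$name, source_peptide = pep)
}

#' Write a simulated experiment to FASTQ files
#'
#' Emits one FASTQ per (tissue, round) plus a sample sheet, a read-level
#' ground-truth sidecar mapping read ids to source peptides, and a YAML
#' echo of the configuration. Fully deterministic under the config seed.
#'
#' @param count_table Peptide count table (all tissues/rounds to emit).
#' @param config [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQ files? Default `TRUE`.
#' @return Invisibly, a list with `sample_sheet`, `fastq` (named paths),
#'   `truth` and `config` paths.
#' @export
emit_fastq <- function(count_table, config, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  groups <- count_table %>%
    dplyr::distinct(.data$tissue, .data$round) %>%
    dplyr::arrange(.data$tissue, .data$round)
  sheet <- list()
  paths <- character(0)
  truth_rows <- list()
  for (i in seq_len(nrow(groups))) {
    t <- groups$tissue[i]
    r <- groups$round[i]
    sub <- count_table[count_table$tissue == t & count_table$round == r, ,
                       drop = FALSE]
    rd <- simulate_reads(sub, config)
    fname <- sprintf("%s_round%d.fastq%s", t, r, if (gzip) ".gz" else "")
    fpath <- file.path(dir, fname)
    qs <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(rd$dna, rd$read_id)),
      Biostrings::PhredQuality(rd$quality))
    Biostrings::writeQualityScaledXStringSet(qs, fpath, compress = gzip)
    paths[fname] <- fpath
    sheet[[i]] <- tibble::tibble(file = fname, tissue = t, round = r,
                                 library = config$library$name)
    truth_rows[[i]] <- rd[, c("read_id", "tissue", "round",
                              "source_peptide")]
  }
  sheet_path <- file.path(dir, "samples.tsv")
  readr::write_tsv(dplyr::bind_rows(sheet), sheet_path)
  truth_path <- file.path(dir, "read_truth.tsv")
  readr::write_tsv(dplyr::bind_rows(truth_rows), truth_path)
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config_as_list(config), config_path)
  invisible(list(sample_sheet = sheet_path, fastq = paths,
                 truth = truth_path, config = config_path))
}

# plain-list view of a simulation_config for serialization
config_as_list <- function(config) {
  out <- unclass(config)
  out$library <- unclass(out$library)
  out$planted_families <- lapply(out$planted_families, function(f) {
    f <- unclass(f)
    f$fitness <- as.list(f$fitness)
    f
  })
  out
}
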