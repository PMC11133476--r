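# Independent oracles and fixture builders shared across the test files.

# brute-force motif scan: enumerate every window, minimal mismatches,
# leftmost tie-break
oracle_scan <- function(sequence, motif, max_mm) {
  ls <- nchar(sequence)
  lm <- nchar(motif)
  if (lm > ls) return(NULL)
  sc <- strsplit(sequence, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  best <- NULL
  for (o in 0:(ls - lm)) {
    mm <- sum(sc[(o + 1):(o + lm)] != mc)
    if (mm <= max_mm && (is.null(best) || mm < best$mismatches)) {
      best <- list(start = o, mismatches = mm)
    }
  }
  best
}

# brute-force WPGMA: full matrix rescan at every step, merge into the
# smaller index, same tie rule as the package (smallest row, then column)
oracle_wpgma <- function(d) {
  n <- nrow(d)
  D <- d
  id <- -(1:n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in 1:(n - 1L)) {
    a <- nrow(D)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in 1:(a - 1L)) {
      for (j in (i + 1L):a) {
        if (D[i, j] < best) { best <- D[i, j]; bi <- i; bj <- j }
      }
    }
    merge[s, ] <- c(id[bi], id[bj])
    height[s] <- best
    newrow <- (D[bi, ] + D[bj, ]) / 2
    D[bi, ] <- newrow
    D[, bi] <- newrow
    D[bi, bi] <- 0
    D <- D[-bj, -bj, drop = FALSE]
    id[bi] <- s
    id <- id[-bj]
  }
  list(merge = merge, height = height)
}

# partition of 1..n implied by merges with height <= h (order-free labels)
oracle_partition <- function(tree, h) {
  n <- nrow(tree$merge) + 1L
  g <- seq_len(n)
  rep_leaf <- integer(nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    a <- tree$merge[s, 1L]; b <- tree$merge[s, 2L]
    la <- if (a < 0) -a else rep_leaf[a]
    lb <- if (b < 0) -b else rep_leaf[b]
    rep_leaf[s] <- la
    if (tree$height[s] <= h) g[g == g[lb]] <- g[la]
  }
  match(g, unique(g))
}

# exhaustive per-position count-weighting consensus
oracle_consensus <- function(peptides, counts) {
  L <- nchar(peptides[1])
  chars <- strsplit(peptides, "")
  out <- character(L)
  residues <- sort(unique(unlist(chars)))
  for (p in seq_len(L)) {
    w <- sapply(residues, function(r)
      sum(counts[vapply(chars, function(x) x[p] == r, logical(1))]))
    out[p] <- residues[which.max(w)]  # residues sorted: ties alphabetical
  }
  paste(out, collapse = "")
}

# random metric matrices: Euclidean (continuous) or Manhattan on integer
# points (tie-heavy but still metric)
random_metric <- function(n, ties = FALSE) {
  if (ties) {
    pts <- matrix(sample(0:3, n * 2L, replace = TRUE), ncol = 2L)
    d <- as.matrix(stats::dist(pts, method = "manhattan")) / 6
  } else {
    pts <- matrix(stats::runif(n * 3L), ncol = 3L)
    d <- as.matrix(stats::dist(pts))
  }
  dimnames(d) <- NULL
  d
}

# deterministic reverse translation (first codon of each residue)
FIRST_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  vapply(split(names(gc), unname(gc)), `[`, character(1), 1L)
})

encode_peptide <- function(residues) {
  paste(FIRST_CODON[strsplit(residues, "")[[1]]], collapse = "")
}

# raw insert table from translated sequences (one tissue/round/library)
raw_table <- function(translations, counts = NULL, tissue = "damaged_lv",
                      round = 3L, library = "phd12", dna = NULL) {
  if (is.null(dna)) dna <- vapply(translations, encode_peptide, character(1))
  if (is.null(counts)) counts <- rep(1L, length(dna))
  tibble::tibble(insert_dna = unname(dna), tissue = tissue,
                 round = as.integer(round), library = library,
                 count = as.integer(counts))
}

# peptide count table row builder
pep_rows <- function(peptide, tissue, round, count, library = "phd12") {
  tibble::tibble(peptide = peptide, tissue = tissue,
                 round = as.integer(round), library = library,
                 count = as.integer(count),
                 n_dna_variants = 1L)
}

random_peptide_set <- function(n, L, alphabet = c("A", "C", "D", "E", "F",
                                                  "G", "H", "I", "K", "L")) {
  unique(replicate(n, paste(sample(alphabet, L, replace = TRUE),
                            collapse = "")))
}

# a fixture with exactly 10 unique inserts: 2 stop-codon, 1 pattern-violating,
# and one synonymous pair among the 7 conformant survivors, so the cascade
# report reads (10, 8, 7, 6)
cascade_fixture <- function() {
  peps <- c("NQRTALEVWKAS", "ACDEFGHIKLMN", "MMMMKKKKLLLL",
            "WYVTSRQPNMLK", "CCDDEEFFGGHH")
  good <- vapply(paste0("S", peps, "GGGS"), encode_peptide, character(1))
  syn <- sub("GCT", "GCC", good[2])              # same peptide, new DNA
  stopd <- c(paste0(substr(good[1], 1, 9), "TAA",
                    substr(good[1], 13, 51)),
             paste0(substr(good[3], 1, 21), "TGA",
                    substr(good[3], 25, 51)))
  badp <- encode_peptide(paste0("T", peps[5], "GGGS"))
  extra <- encode_peptide(paste0("S", "HHHHIIIIKKKK", "GGGS"))
  raw_table(character(0),
            dna = c(good, syn, stopd, badp, extra),
            counts = c(5L, 3L, 2L, 2L, 1L, 7L, 1L, 1L, 1L, 4L))
}
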