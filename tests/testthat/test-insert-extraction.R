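phd12 <- library_preset("phd12")
trico20 <- library_preset("trico20")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# read with the insert embedded between the flanks, plus context
embed_read <- function(insert, spec, left = 10L, right = 12L,
                       flank5 = spec$flank5, flank3 = spec$flank3) {
  paste0(random_dna(left), flank5, insert, flank3, random_dna(right))
}

mutate_at <- function(x, pos) {
  for (p in pos) {
    cur <- substr(x, p, p)
    substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  x
}

test_that("mismatch_scan finds the best window with leftmost ties", {
  expect_equal(mismatch_scan("TTACGTTT", "ACGT", 0),
               list(start = 2L, mismatches = 0L))
  expect_equal(mismatch_scan("TTACCTTT", "ACGT", 1),
               list(start = 2L, mismatches = 1L))
  expect_null(mismatch_scan("AAAA", "CCCC", 2))
  # motif longer than the sequence is no match, not an error
  expect_null(mismatch_scan("ACG", "ACGT", 2))
  # N in the read counts as a mismatch
  expect_null(mismatch_scan("TTANGT", "ACGT", 0))
  expect_equal(mismatch_scan("TTANGT", "ACGT", 1)$mismatches, 1L)
})

test_that("mismatch_scan agrees with the all-windows oracle", {
  set.seed(101)
  for (i in 1:1000) {
    ls <- sample(8:40, 1)
    lm <- sample(3:8, 1)
    seqc <- paste(sample(c("A", "C", "G", "T", "N"), ls, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                  collapse = "")
    motif <- random_dna(lm)
    mm <- sample(0:3, 1)
    expect_identical(mismatch_scan(seqc, motif, mm),
                     oracle_scan(seqc, motif, mm))
  }
})

test_that("extract_insert recovers a planted insert with flank errors", {
  set.seed(7)
  insert <- random_dna(insert_length(phd12))  # 3*(1+12+4) = 51 nt
  read <- embed_read(insert, phd12)
  res <- extract_insert(read, phd12)
  expect_equal(res$insert_dna, insert)
  expect_equal(res$strand, "forward")
  expect_equal(res$flank5_mismatches, 0L)
  expect_equal(res$flank3_mismatches, 0L)

  # two substitutions in flank5, one in flank3 (positions inside the read)
  mutread <- mutate_at(read, c(11L, 13L, 10L + 15L + 51L + 2L))
  res2 <- extract_insert(mutread, phd12)
  expect_equal(res2$insert_dna, insert)
  expect_equal(res2$flank5_mismatches, 2L)
  expect_equal(res2$flank3_mismatches, 1L)

  # reverse complement reports the reverse strand, same insert
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  res3 <- extract_insert(rc, phd12)
  expect_equal(res3$insert_dna, insert)
  expect_equal(res3$strand, "reverse")

  # too many flank errors -> no extraction
  badread <- mutate_at(read, c(11L, 13L, 15L))
  expect_null(extract_insert(badread, phd12))

  # read shorter than flank5 + insert + flank3 -> none
  expect_null(extract_insert(substr(read, 1, 60), phd12))
})

test_that("round trip holds for random reads with tolerated flank errors", {
  set.seed(42)
  for (spec in list(phd12, trico20)) {
    for (i in 1:25) {
      insert <- random_dna(insert_length(spec))
      read <- embed_read(insert, spec, left = sample(0:20, 1),
                         right = sample(0:20, 1))
      n5 <- sample(0:2, 1)
      n3 <- sample(0:2, 1)
      f5_start <- regexpr(spec$flank5, read, fixed = TRUE)[1]
      pos5 <- if (n5 > 0) sample(f5_start:(f5_start + 14L), n5) else integer(0)
      f3_start <- f5_start + 15L + nchar(insert)
      pos3 <- if (n3 > 0) sample(f3_start:(f3_start + 14L), n3) else integer(0)
      mut <- mutate_at(read, c(pos5, pos3))
      res <- extract_insert(mut, spec)
      expect_equal(res$insert_dna, insert)
      # strand involution
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mut)))
      res_rc <- extract_insert(rc, spec)
      expect_equal(res_rc$insert_dna, insert)
      expect_true(res_rc$strand != res$strand)
    }
  }
})

test_that("mean-quality filtering follows the arithmetic mean rule", {
  expect_true(mean_quality_pass(rep(30L, 10), 20))
  expect_false(mean_quality_pass(c(10L, 10L, 10L, 10L), 20))
  expect_true(mean_quality_pass(c(10L, 30L), 20))  # mean exactly at threshold
  expect_error(mean_quality_pass(integer(0), 20), "empty")
  # string form (Sanger +33)
  expect_equal(phred_scores("I"), 40L)
  expect_true(mean_quality_pass("IIII", 20))
})

test_that("translation uses the standard code with * and X conventions", {
  expect_equal(translate_dna("ATGAAA"), "MK")
  expect_equal(translate_dna("TAA"), "*")
  expect_equal(translate_dna("ANT"), "X")
  expect_error(translate_dna("ATGA"), "divisible")
})

test_that("count_inserts conserves successful extractions", {
  ext <- tibble::tibble(insert_dna = c("AAA", "AAA", "CCC"))
  tab <- count_inserts(ext, "damaged_lv", 3, "phd12")
  expect_equal(tab$count[tab$insert_dna == "AAA"], 2L)
  expect_equal(tab$count[tab$insert_dna == "CCC"], 1L)
  expect_equal(sum(tab$count), nrow(ext))
  empty <- count_inserts(ext[0, , drop = FALSE], "damaged_lv", 3, "phd12")
  expect_equal(nrow(empty), 0L)
})

test_that("failed extractions drop out of the insert table", {
  set.seed(9)
  inserts <- vapply(1:3, function(i) random_dna(51L), character(1))
  reads <- c(
    vapply(1:40, function(i) embed_read(inserts[1], phd12), character(1)),
    vapply(1:35, function(i) embed_read(inserts[2], phd12), character(1)),
    vapply(1:25, function(i) random_dna(100L), character(1)))  # no flanks
  ext <- extract_inserts(reads, phd12)
  tab <- count_inserts(ext, "damaged_lv", 3, "phd12")
  expect_equal(sum(tab$count), 75L)
  expect_equal(sort(tab$count, decreasing = TRUE), c(40L, 35L))
})
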