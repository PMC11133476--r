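test_that("normalized Hamming distance is the mismatch fraction", {
  expect_equal(normalized_hamming("AAAA", "AAAA"), 0)
  expect_equal(normalized_hamming("AAAA", "AAAT"), 0.25)
  expect_equal(normalized_hamming("ACDE", "WFHK"), 1)
  expect_error(normalized_hamming("AA", "AAA"), "equal length")
})

test_that("the distance matrix is a metric over distinct peptides", {
  d <- build_distance_matrix(c("AA", "AT", "TT"))
  expect_equal(unname(d),
               matrix(c(0, .5, 1, .5, 0, .5, 1, .5, 0), 3, 3))
  expect_equal(unname(build_distance_matrix("ACDE")), matrix(0, 1, 1))
  expect_error(build_distance_matrix(c("AA", "AA")), "distinct")
  expect_error(build_distance_matrix(c("AA", "AAA")), "same length")

  set.seed(3)
  for (i in 1:20) {
    peps <- random_peptide_set(sample(3:12, 1), 8)
    d <- build_distance_matrix(peps)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    n <- nrow(d)
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      expect_true(d[a, cc] <= d[a, b] + d[b, cc] + 1e-12)
    }
  }
})

test_that("wpgma reproduces hand-worked merges", {
  # two leaves merge at their distance
  d2 <- matrix(c(0, .2, .2, 0), 2, 2,
               dimnames = list(c("p1", "p2"), c("p1", "p2")))
  t2 <- wpgma(d2)
  expect_equal(t2$height, 0.2)
  # three leaves: (1,2)@0.1 then average (0.5+0.5)/2 = 0.5
  d3 <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3, 3,
               dimnames = list(paste0("p", 1:3), paste0("p", 1:3)))
  t3 <- wpgma(d3)
  expect_equal(t3$height, c(0.1, 0.5))
  expect_equal(t3$merge[1, ], c(-1L, -2L))
  expect_equal(cut_clusters(t3, 0.3),
               c(p1 = 1L, p2 = 1L, p3 = 2L))
})

test_that("wpgma matches the brute-force reference and hclust/mcquitty", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    d <- random_metric(n, ties = i %% 2 == 0)
    got <- biopanr:::cpp_wpgma(d)
    ref <- oracle_wpgma(d)
    expect_identical(got$merge, ref$merge)
    expect_equal(as.numeric(got$height), ref$height, tolerance = 1e-12)
  }
  # hclust's WPGMA ("mcquitty") as an independent cross-check, tie-free
  for (i in 1:25) {
    n <- 25
    d <- random_metric(n)
    dimnames(d) <- list(paste0("p", 1:n), paste0("p", 1:n))
    t1 <- wpgma(d)
    t2 <- stats::hclust(stats::as.dist(d), method = "mcquitty")
    expect_equal(t1$height, t2$height, tolerance = 1e-12)
    for (h in sample(t1$height, 3)) {
      p1 <- cut_clusters(t1, h)
      p2 <- stats::cutree(t2, h = h)
      # same partition up to label renumbering
      expect_equal(length(unique(p1)), length(unique(p2)))
      expect_true(all(tapply(p2, p1, function(x) length(unique(x))) == 1))
    }
  }
})

test_that("merge heights never decrease on metric inputs", {
  set.seed(13)
  for (i in 1:50) {
    d <- random_metric(sample(3:15, 1), ties = i %% 2 == 0)
    tr <- biopanr:::cpp_wpgma(d)
    expect_true(all(diff(as.numeric(tr$height)) >= -1e-12))
  }
})

test_that("cutting the tree partitions the peptide set", {
  set.seed(17)
  peps <- random_peptide_set(40, 6)
  tr <- wpgma(build_distance_matrix(peps))
  ids0 <- cut_clusters(tr, 0)
  expect_equal(length(unique(ids0)), length(peps))  # all singletons
  expect_equal(unname(ids0[tr$order]), seq_along(peps))  # numbered by leaf order
  expect_true(all(cut_clusters(tr, 1) == 1L))
  for (h in c(0.2, 0.5, 0.8)) {
    ids <- cut_clusters(tr, h)
    expect_equal(length(ids), length(peps))
    expect_setequal(names(ids), peps)
    ref <- oracle_partition(tr, h + 1e-9)
    expect_true(all(tapply(ref, ids, function(x) length(unique(x))) == 1))
    expect_equal(length(unique(ids)), length(unique(ref)))
  }
})

test_that("count weighting decides the consensus residue", {
  expect_equal(weighted_consensus(c("ACD", "ACE"), c(5, 3)),
               list(sequence = "ACD", count = 8))
  expect_equal(weighted_consensus("NQRT", 7),
               list(sequence = "NQRT", count = 7))
  # alphabetical tie-break
  expect_equal(weighted_consensus(c("AD", "CD"), c(2, 2))$sequence, "AD")
  expect_error(weighted_consensus(character(0), numeric(0)), "empty")
})

test_that("consensus matches the exhaustive oracle, dominance holds", {
  set.seed(19)
  for (i in 1:100) {
    k <- sample(1:10, 1)
    peps <- replicate(k, paste(sample(c("A", "C", "D"), 5, replace = TRUE),
                               collapse = ""))
    counts <- sample(1:5, k, replace = TRUE)
    expect_equal(weighted_consensus(peps, counts)$sequence,
                 oracle_consensus(peps, counts))
  }
  # a member holding > 50% of the count mass is the consensus
  for (i in 1:25) {
    k <- sample(2:8, 1)
    peps <- random_peptide_set(k, 7)
    counts <- rep(1L, length(peps))
    counts[1] <- length(peps) + 1L
    expect_equal(weighted_consensus(peps, counts)$sequence, peps[1])
  }
})

test_that("the fused clustering path equals the matrix path", {
  set.seed(23)
  for (i in 1:40) {
    peps <- random_peptide_set(sample(2:60, 1), 6)
    t1 <- wpgma(build_distance_matrix(peps))
    t2 <- cluster_peptides(peps, h = 0.4)$tree
    expect_identical(t1$merge, t2$merge)
    expect_identical(t1$height, t2$height)
  }
})

test_that("default cut heights follow the library peptide length", {
  expect_equal(default_cut_height(12), 0.3)
  expect_equal(default_cut_height(20), 0.7)
})

test_that("a planted family stays in one cluster below the cut", {
  set.seed(29)
  seedpep <- "NQRTALEVWKAS"
  fam <- plant_family(seedpep, 15, 1)
  expect_true(all(vapply(fam, function(p)
    normalized_hamming(p, seedpep), numeric(1)) <= 1 / 12))
  cl <- cluster_peptides(fam, h = 0.3)  # 0.3 > 2 * 1 / 12
  expect_equal(length(unique(cl$assignment$cluster_id)), 1L)
})

test_that("dendrograms export to Newick and read back", {
  peps <- c("AAAA", "AAAT", "TTTT", "TTAA")
  tr <- wpgma(build_distance_matrix(peps))
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, peps)
})
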