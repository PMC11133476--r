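params_default <- specificity_params()

# small multi-tissue table spanning the relative-count boundary
boundary_table <- function() {
  dplyr::bind_rows(
    pep_rows("AAAAAAAAAAAA", "damaged_lv", 3, 100),
    pep_rows("CCCCCCCCCCCC", "damaged_lv", 3, 100),
    pep_rows("DDDDDDDDDDDD", "damaged_lv", 3, 100),
    pep_rows("AAAAAAAAAAAA", "kidney", 3, 5),      # 5 / 10,000 = 0.05%
    pep_rows("KKKKKKKKKKKK", "kidney", 3, 9995),
    pep_rows("CCCCCCCCCCCC", "liver", 3, 1),       # 1 / 1,000,000 = 1e-6
    pep_rows("LLLLLLLLLLLL", "liver", 3, 999999))
}

test_that("relative counts normalize within a tissue and round", {
  tab <- boundary_table()
  rc <- tissue_relative_counts(tab, "kidney", 3)
  expect_equal(rc$fraction[rc$peptide == "AAAAAAAAAAAA"], 5 / 10000)
  expect_equal(sum(rc$fraction), 1)
  solo <- tissue_relative_counts(pep_rows("WWWWWWWWWWWW", "liver", 3, 7),
                                 "liver", 3)
  expect_equal(solo$fraction, 1)
  expect_error(tissue_relative_counts(tab, "spleen", 3), "zero total")
})

test_that("specificity filtering spans the 0.01% boundary correctly", {
  surv <- tissue_specificity_filter(boundary_table(), params_default)
  # 0.05% in kidney -> removed; 1e-6 in liver -> retained; absent -> retained
  expect_setequal(surv$peptide, c("CCCCCCCCCCCC", "DDDDDDDDDDDD"))
})

test_that("raising the threshold never shrinks the survivor set", {
  tab <- boundary_table()
  prev <- character(0)
  for (thr in c(0, 1e-6, 1e-4, 5e-4, 0.9, 1)) {
    p <- specificity_params(relative_threshold = thr)
    surv <- tissue_specificity_filter(tab, p)$peptide
    expect_true(all(prev %in% surv))
    prev <- surv
  }
})

test_that("peptides unique to one tissue always survive", {
  set.seed(31)
  peps <- random_peptide_set(30, 12,
                             alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                 "")[[1]])
  tissues <- sample(c("damaged_lv", "remote_heart", "kidney", "liver"),
                    length(peps), replace = TRUE)
  tab <- pep_rows(peps, tissues, 3, sample(1:100, length(peps), TRUE))
  surv <- tissue_specificity_filter(tab, params_default)
  expect_setequal(surv$peptide, peps[tissues == "damaged_lv"])
})

test_that("topic20 clusters the top survivors into family consensus", {
  set.seed(37)
  fams <- lapply(c("AAAAAAAAAAAA", "HHHHHHHHHHHH", "TTTTTTTTTTTT"),
                 function(s) plant_family(s, 6, 1))
  peps <- unlist(fams)
  tab <- pep_rows(peps, "damaged_lv", 3, sample(50:100, length(peps), TRUE))
  hits <- suppressWarnings(topic20(tab, params_default))  # 18 < top_n
  expect_equal(nrow(hits), 3L)       # three planted families, three hits
  expect_setequal(hits$consensus,
                  c("AAAAAAAAAAAA", "HHHHHHHHHHHH", "TTTTTTTTTTTT"))
  expect_true(all(hits$approach == "TOPIC20"))
  # consensus count equals the member sum
  expect_equal(sum(hits$count), sum(tab$count))

  # at most top_n survivors enter clustering, hits come from survivors
  small <- topic20(tab, specificity_params(top_n = 5))
  members <- unlist(strsplit(small$members, ","))
  expect_true(length(members) <= 5)
  surv <- tissue_specificity_filter(tab, params_default)
  expect_true(all(members %in% surv$peptide))
})

test_that("topic20 handles shortage and emptiness gracefully", {
  one <- pep_rows("GGGGGGGGGGGG", "damaged_lv", 3, 9)
  expect_warning(hits <- topic20(one, params_default), "survivors")
  expect_equal(hits$consensus, "GGGGGGGGGGGG")
  none <- pep_rows("GGGGGGGGGGGG", "kidney", 3, 9)
  expect_equal(nrow(suppressWarnings(topic20(none, params_default))), 0L)
})

test_that("topic lets a family of rare variants outrank a lone peptide", {
  set.seed(41)
  fam <- plant_family("MMMMMMMMMMMM", 30, 1)
  tab <- dplyr::bind_rows(
    pep_rows(fam, "damaged_lv", 3, rep(2, length(fam))),   # 60 in total
    pep_rows("WWWWWWWWWWWW", "damaged_lv", 3, 50))
  hits <- topic(tab, params_default)
  expect_equal(hits$count[1], 60L)
  expect_equal(hits$consensus[1], "MMMMMMMMMMMM")
  expect_equal(hits$count[2], 50L)
  # no survivors -> empty; a single survivor is its own consensus
  expect_equal(nrow(topic(pep_rows("AAAAAAAAAAAA", "liver", 3, 5),
                          params_default)), 0L)
  lone <- topic(pep_rows("AAAAAAAAAAAA", "damaged_lv", 3, 5),
                params_default)
  expect_equal(lone$consensus, "AAAAAAAAAAAA")
})

spec_fixture <- function() {
  # three well-separated clusters with controlled tissue profiles
  dplyr::bind_rows(
    pep_rows("AAAAAAAAAAAA", "damaged_lv", 3, 500),
    pep_rows("HHHHHHHHHHHH", "damaged_lv", 3, 300),
    pep_rows("HHHHHHHHHHHH", "remote_heart", 3, 300),
    pep_rows("HHHHHHHHHHHH", "kidney", 3, 20),
    pep_rows("HHHHHHHHHHHH", "liver", 3, 20),
    pep_rows("TTTTTTTTTTTT", "damaged_lv", 3, 10),
    pep_rows("TTTTTTTTTTTT", "kidney", 3, 900),
    pep_rows("TTTTTTTTTTTT", "liver", 3, 90))
}

test_that("cluster allocation conserves tissue totals", {
  tab <- spec_fixture()
  alloc <- spec_cluster_allocation(tab, round = 3)
  prof <- alloc$profiles
  for (t in unique(tab$tissue)) {
    expect_equal(sum(prof$count[prof$tissue == t]),
                 sum(tab$count[tab$tissue == t]))
  }
  lvonly <- prof[prof$cluster_id ==
                   alloc$assignment$cluster_id[
                     alloc$assignment$peptide == "AAAAAAAAAAAA"], ]
  expect_equal(lvonly$tissue, "damaged_lv")
  expect_equal(lvonly$fraction, 1)
})

test_that("spec_select categorizes exclusive, whole-heart and off-target", {
  alloc <- spec_cluster_allocation(spec_fixture(), round = 3)
  hits <- spec_select(alloc, params_default, include_remote = FALSE)
  a <- hits[hits$category == "A_target_exclusive", ]
  expect_equal(a$consensus, "AAAAAAAAAAAA")   # LV-only cluster
  b <- hits[hits$category == "B_whole_heart", ]
  expect_equal(b$consensus, "HHHHHHHHHHHH")   # 600/640 = 0.9375 >= 0.9
  expect_false("TTTTTTTTTTTT" %in% hits$consensus)  # kidney-dominated
})

test_that("epsilon and the off-target set are honoured", {
  alloc <- spec_cluster_allocation(spec_fixture(), round = 3)
  # with a permissive epsilon the whole-heart cluster becomes "exclusive"
  loose <- spec_select(alloc, specificity_params(epsilon = 0.6),
                       include_remote = FALSE)
  a <- loose[loose$category == "A_target_exclusive", ]
  expect_setequal(a$consensus, c("AAAAAAAAAAAA", "HHHHHHHHHHHH"))
  # excluding remote heart from the off-target set has the same effect
  # only when kidney+liver stay under epsilon (40/640 ~ 6%)
  cfg <- specificity_params(epsilon = 0.1,
                            offtarget_tissues = c("kidney", "liver"))
  a2 <- spec_select(alloc, cfg, include_remote = FALSE)
  a2 <- a2[a2$category == "A_target_exclusive", ]
  expect_setequal(a2$consensus, c("AAAAAAAAAAAA", "HHHHHHHHHHHH"))
})

test_that("log2 enrichment entries and monotone selection behave", {
  tab <- dplyr::bind_rows(
    pep_rows("AAAAAAAAAAAA", "damaged_lv", 1, 1),
    pep_rows("AAAAAAAAAAAA", "damaged_lv", 2, 3),
    pep_rows("AAAAAAAAAAAA", "damaged_lv", 3, 7),
    pep_rows("AAAAAAAAAAAA", "kidney", 1, 7),
    pep_rows("AAAAAAAAAAAA", "kidney", 2, 3),
    pep_rows("AAAAAAAAAAAA", "kidney", 3, 1),
    pep_rows("TTTTTTTTTTTT", "damaged_lv", 1, 1),
    pep_rows("TTTTTTTTTTTT", "damaged_lv", 2, 7),
    pep_rows("TTTTTTTTTTTT", "damaged_lv", 3, 3),
    pep_rows("TTTTTTTTTTTT", "kidney", 2, 1))
  assignment <- all_round_clusters(tab)
  emat <- enrichment_matrix(tab, assignment)
  a_id <- assignment$cluster_id[assignment$peptide == "AAAAAAAAAAAA"]
  t_id <- assignment$cluster_id[assignment$peptide == "TTTTTTTTTTTT"]
  expect_equal(emat[as.character(a_id), "damaged_lv_r3"], 3)  # log2(8)
  expect_equal(emat[as.character(t_id), "kidney_r1"], 0)      # unobserved
  expect_equal(emat[as.character(t_id), "kidney_r3"], 0)

  enr <- enriched_clusters(emat, "damaged_lv", "kidney")
  expect_true(a_id %in% enr)      # strictly up in LV, down in kidney
  expect_false(t_id %in% enr)     # LV trajectory 1,7,3 is not monotone
  # flat control trajectories do not disqualify
  m <- matrix(c(1, 2, 3, 1, 1, 1), nrow = 1,
              dimnames = list("9", c("damaged_lv_r1", "damaged_lv_r2",
                                     "damaged_lv_r3", "kidney_r1",
                                     "kidney_r2", "kidney_r3")))
  expect_equal(enriched_clusters(m, "damaged_lv", "kidney"), 9L)
})
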