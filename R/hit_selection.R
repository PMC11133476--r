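#' Parameters for tissue-specific hit selection
#'
#' Collects the knobs shared by the TOPIC20, TOPIC and SPEC strategies.
#'
#' @param target_tissue Tissue the screen selects for (default
#'   `"damaged_lv"`, the previously ischemic left ventricle).
#' @param control_tissues Tissues used as specificity controls by the
#'   TOPIC20/TOPIC relative-count filter.
#' @param relative_threshold A peptide present in a control tissue above
#'   this fraction of the control's total counts is considered non-specific
#'   (default `1e-4`, i.e. 0.01%).
#' @param round Panning round analysed (default 3, the final round).
#' @param top_n Number of top survivors clustered by TOPIC20 (default 20).
#' @param epsilon SPEC category-A exclusivity tolerance: maximum off-target
#'   count fraction for a cluster to count as target-exclusive (default 0).
#' @param heart_fraction SPEC category-B threshold: minimum fraction of a
#'   cluster's counts that must fall in the whole heart (default 0.9).
#' @param heart_tissues Tissues making up the "whole heart" for category B.
#' @param offtarget_tissues Tissues counted as off-target for category A;
#'   `NULL` (default) means every tissue other than the target, so the
#'   remote heart disqualifies a cluster from strict target exclusivity.
#' @return An object of class `specificity_params`.
#' @export
specificity_params <- function(target_tissue = "damaged_lv",
                               control_tissues = c("remote_heart", "kidney",
                                                   "liver"),
                               relative_threshold = 1e-4,
                               round = 3L,
                               top_n = 20L,
                               epsilon = 0,
                               heart_fraction = 0.9,
                               heart_tissues = c(target_tissue,
                                                 "remote_heart"),
                               offtarget_tissues = NULL) {
  stopifnot(relative_threshold >= 0, relative_threshold <= 1,
            top_n >= 1, epsilon >= 0, epsilon <= 1,
            heart_fraction >= 0, heart_fraction <= 1)
  structure(
    list(target_tissue = target_tissue,
         control_tissues = control_tissues,
         relative_threshold = relative_threshold,
         round = as.integer(round),
         top_n = as.integer(top_n),
         epsilon = epsilon,
         heart_fraction = heart_fraction,
         heart_tissues = unique(heart_tissues),
         offtarget_tissues = offtarget_tissues),
    class = "specificity_params"
  )
}

#' Per-peptide relative counts within a tissue and round
#'
#' @param table Peptide count table.
#' @param tissue,round Sample selector.
#' @return Tibble `peptide, count, fraction`; fractions sum to 1.
#' @export
tissue_relative_counts <- function(table, tissue, round) {
  sub <- table[table$tissue == tissue & table$round == round, , drop = FALSE]
  total <- sum(sub$count)
  if (total <= 0) stop("zero total count for this tissue and round")
  tibble::tibble(peptide = sub$peptide, count = sub$count,
                 fraction = sub$count / total)
}

#' Tissue-specificity filter
#'
#' Keeps peptides present in the target tissue at the analysis round whose
#' relative count in every control tissue at that round is at most the
#' relative threshold (absence counts as zero and passes). This is the
#' shared filtering step of TOPIC20 and TOPIC.
#'
#' @param table Peptide count table.
#' @param params [specificity_params()].
#' @return Tibble of survivors with their target-tissue `peptide, count`.
#' @export
tissue_specificity_filter <- function(table, params) {
  stopifnot(inherits(params, "specificity_params"))
  rnd <- params$round
  target <- table[table$tissue == params$target_tissue & table$round == rnd, ,
                  drop = FALSE]
  if (nrow(target) == 0L) {
    return(tibble::tibble(peptide = character(), count = integer()))
  }
  bad <- character(0)
  for (ct in params$control_tissues) {
    sub <- table[table$tissue == ct & table$round == rnd, , drop = FALSE]
    total <- sum(sub$count)
    if (total <= 0) next
    bad <- c(bad, sub$peptide[sub$count / total > params$relative_threshold])
  }
  keep <- !(target$peptide %in% bad)
  tibble::tibble(peptide = target$peptide[keep],
                 count = as.integer(target$count[keep])) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$peptide)
}

# consensus of each cluster in an assignment, given per-peptide counts;
# returns one row per cluster ranked by consensus count (ties alphabetical)
consensus_by_cluster <- function(assignment, counts) {
  stopifnot(all(assignment$peptide %in% names(counts)))
  split_pep <- split(assignment$peptide, assignment$cluster_id)
  rows <- lapply(names(split_pep), function(cid) {
    members <- split_pep[[cid]]
    cons <- weighted_consensus(members, unname(counts[members]))
    tibble::tibble(cluster_id = as.integer(cid),
                   consensus = cons$sequence,
                   count = as.integer(cons$count),
                   n_members = length(members),
                   members = paste(sort(members), collapse = ","))
  })
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$consensus) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::select("rank", "consensus", "count", "cluster_id", "n_members",
                  "members")
}

#' TOPIC20: specificity filter, top-20 peptides, clustering, consensus
#'
#' Applies the tissue-specificity filter, ranks the survivors by their
#' target-tissue count (ties broken alphabetically), takes the `top_n`
#' (default 20) most abundant, clusters them by WPGMA and emits one
#' count-weighted consensus per resulting cluster, ranked by consensus
#' count.
#'
#' @param table Peptide count table (one library).
#' @param params [specificity_params()].
#' @param cut_height Dendrogram cut height; defaults to
#'   [default_cut_height()] of the peptide length.
#' @return Tibble of consensus hits with columns `approach, rank,
#'   consensus, count, cluster_id, n_members, members`.
#' @export
topic20 <- function(table, params = specificity_params(), cut_height = NULL) {
  surv <- tissue_specificity_filter(table, params)
  if (nrow(surv) == 0L) return(empty_hits("TOPIC20"))
  if (nrow(surv) < params$top_n) {
    warning(sprintf("only %d survivors (< top_n = %d); using all of them",
                    nrow(surv), params$top_n))
  }
  top <- utils::head(surv, params$top_n)
  cl <- cluster_peptides(top$peptide, h = cut_height)
  counts <- stats::setNames(top$count, top$peptide)
  out <- consensus_by_cluster(cl$assignment, counts)
  dplyr::bind_cols(tibble::tibble(approach = rep("TOPIC20", nrow(out))), out)
}

#' TOPIC: specificity filter, clustering of all survivors, consensus
#'
#' Applies the tissue-specificity filter, clusters *all* survivors by
#' WPGMA, ranks the clusters by summed target-tissue count and emits a
#' count-weighted consensus for each of the `top_k` clusters. Families of
#' low-count variants can thereby outrank an isolated high-count peptide.
#'
#' @inheritParams topic20
#' @param top_k Number of top clusters reported (default 10).
#' @return Tibble of consensus hits (see [topic20()]).
#' @export
topic <- function(table, params = specificity_params(), cut_height = NULL,
                  top_k = 10L) {
  surv <- tissue_specificity_filter(table, params)
  if (nrow(surv) == 0L) return(empty_hits("TOPIC"))
  cl <- cluster_peptides(surv$peptide, h = cut_height)
  counts <- stats::setNames(surv$count, surv$peptide)
  # rank clusters by summed count, emit consensus only for the top k
  sums <- cl$assignment %>%
    dplyr::mutate(count = counts[.data$peptide]) %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$total), .data$cluster_id)
  keep_ids <- utils::head(sums$cluster_id, top_k)
  sub <- cl$assignment[cl$assignment$cluster_id %in% keep_ids, , drop = FALSE]
  out <- consensus_by_cluster(sub, counts)
  dplyr::bind_cols(tibble::tibble(approach = rep("TOPIC", nrow(out))), out)
}

empty_hits <- function(approach) {
  tibble::tibble(approach = character(), rank = integer(),
                 consensus = character(), count = integer(),
                 cluster_id = integer(), n_members = integer(),
                 members = character())
}

#' SPEC step 1: cluster all final-round peptides and profile tissues
#'
#' Clusters the union of every peptide observed in any tissue at the
#' analysis round (no specificity pre-filter), then sums each cluster's
#' counts per tissue.
#'
#' @param table Peptide count table (one library).
#' @param round Panning round to analyse (default 3).
#' @param cut_height Dendrogram cut height; defaults to
#'   [default_cut_height()].
#' @return A list with `assignment` (`peptide, cluster_id`), `profiles`
#'   (tibble `cluster_id, tissue, count, fraction, total`), `tree` and `h`.
#' @export
spec_cluster_allocation <- function(table, round = 3L, cut_height = NULL) {
  if (length(unique(table$library)) > 1L)
    stop("allocate one library at a time")
  sub <- table[table$round == round, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no peptides at the requested round")
  peptides <- sort(unique(sub$peptide))
  cl <- cluster_peptides(peptides, h = cut_height)
  cid <- cl$assignment$cluster_id[match(sub$peptide, cl$assignment$peptide)]
  tissues <- sort(unique(sub$tissue))
  clusters <- sort(unique(cl$assignment$cluster_id))
  m <- matrix(0, nrow = length(clusters), ncol = length(tissues),
              dimnames = list(as.character(clusters), tissues))
  for (t in tissues) {
    sel <- sub$tissue == t
    if (any(sel)) {
      r <- rowsum(sub$count[sel], cid[sel])
      m[rownames(r), t] <- r[, 1L]
    }
  }
  total <- rowSums(m)
  prof <- tibble::tibble(
    cluster_id = rep(clusters, times = length(tissues)),
    tissue = rep(tissues, each = length(clusters)),
    count = as.vector(m),
    total = rep(total, times = length(tissues)),
    fraction = as.vector(m / total)) %>%
    dplyr::filter(.data$count > 0)
  list(assignment = cl$assignment, profiles = prof, profile_matrix = m,
       tree = cl$tree, h = cl$h, counts = sub)
}

#' SPEC step 2: select clusters by tissue profile
#'
#' Category A ("target-exclusive"): clusters whose off-target count
#' fraction is at most `epsilon`, ranked by target-tissue count. Category B
#' ("whole heart"): clusters not in A whose heart-count fraction (target +
#' remote heart) is at least `heart_fraction`, ranked by heart count.
#' Category C (optional): the single best remote-heart-dominant cluster not
#' already selected. Each selected cluster is reported as its
#' count-weighted consensus with the cluster's summed count.
#'
#' @param allocation Result of [spec_cluster_allocation()].
#' @param params [specificity_params()].
#' @param include_remote Also report the best remote-heart-dominant cluster
#'   (category C)? Default `TRUE`.
#' @return Tibble of hits: `approach, category, rank, consensus, count,
#'   target_count, heart_count, cluster_id, n_members, members`.
#' @export
spec_select <- function(allocation, params = specificity_params(),
                        include_remote = TRUE) {
  m <- allocation$profile_matrix
  if (is.null(m)) {  # rebuild from the long profiles if needed
    prof <- allocation$profiles
    tissues <- sort(unique(prof$tissue))
    clusters <- sort(unique(prof$cluster_id))
    m <- matrix(0, length(clusters), length(tissues),
                dimnames = list(as.character(clusters), tissues))
    m[cbind(match(prof$cluster_id, clusters),
            match(prof$tissue, tissues))] <- prof$count
  }
  target <- params$target_tissue
  offt <- params$offtarget_tissues
  if (is.null(offt)) offt <- setdiff(colnames(m), target)
  remote <- setdiff(params$heart_tissues, target)
  pick <- function(cols) rowSums(m[, intersect(cols, colnames(m)),
                                   drop = FALSE])
  per_cluster <- tibble::tibble(
    cluster_id = as.integer(rownames(m)),
    total = rowSums(m),
    target_count = pick(target),
    off_count = pick(offt),
    heart_count = pick(params$heart_tissues),
    remote_count = pick(remote)) %>%
    dplyr::mutate(off_fraction = .data$off_count / .data$total,
                  heart_frac = .data$heart_count / .data$total,
                  remote_frac = .data$remote_count / .data$total)

  cat_a <- per_cluster %>%
    dplyr::filter(.data$target_count > 0,
                  .data$off_fraction <= params$epsilon) %>%
    dplyr::arrange(dplyr::desc(.data$target_count), .data$cluster_id)
  cat_b <- per_cluster %>%
    dplyr::filter(!.data$cluster_id %in% cat_a$cluster_id,
                  .data$heart_frac >= params$heart_fraction) %>%
    dplyr::arrange(dplyr::desc(.data$heart_count), .data$cluster_id)
  cat_c <- per_cluster %>%
    dplyr::filter(!.data$cluster_id %in% c(cat_a$cluster_id,
                                           cat_b$cluster_id),
                  .data$remote_frac > 0.5) %>%
    dplyr::arrange(dplyr::desc(.data$remote_count), .data$cluster_id) %>%
    utils::head(if (include_remote) 1L else 0L)

  counts_by_pep <- allocation$counts %>%
    dplyr::group_by(.data$peptide) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  counts <- stats::setNames(counts_by_pep$count, counts_by_pep$peptide)

  one_category <- function(sel, label) {
    if (nrow(sel) == 0L) return(NULL)
    sub <- allocation$assignment[
      allocation$assignment$cluster_id %in% sel$cluster_id, , drop = FALSE]
    cons <- consensus_by_cluster(sub, counts) %>% dplyr::select(-"rank")
    sel %>%
      dplyr::mutate(rank = dplyr::row_number(), category = label) %>%
      dplyr::left_join(cons, by = "cluster_id") %>%
      dplyr::select("category", "rank", "consensus", "count",
                    "target_count", "heart_count", "cluster_id",
                    "n_members", "members")
  }
  out <- dplyr::bind_rows(one_category(cat_a, "A_target_exclusive"),
                          one_category(cat_b, "B_whole_heart"),
                          one_category(cat_c, "C_remote_heart"))
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(approach = character(), category = character(),
                          rank = integer(), consensus = character(),
                          count = integer(), target_count = integer(),
                          heart_count = integer(), cluster_id = integer(),
                          n_members = integer(), members = character()))
  }
  dplyr::bind_cols(tibble::tibble(approach = rep("SPEC", nrow(out))), out)
}

#' Cluster the union of peptides over all rounds
#'
#' Used by the enrichment analysis so a cluster's trajectory can be tracked
#' across rounds.
#'
#' @param table Peptide count table (one library).
#' @param cut_height Cut height; defaults to [default_cut_height()].
#' @return Tibble `peptide, cluster_id` covering every observed peptide.
#' @export
all_round_clusters <- function(table, cut_height = NULL) {
  if (length(unique(table$library)) > 1L)
    stop("cluster one library at a time")
  peptides <- sort(unique(table$peptide))
  cluster_peptides(peptides, h = cut_height)$assignment
}

#' Log2 enrichment matrix of clusters across tissues and rounds
#'
#' Entries are `log2(count + 1)` of the cluster's summed count in each
#' (tissue, round) cell; unobserved cells are 0 (which coincides with a
#' zero count under the +1 pseudocount).
#'
#' @param table Peptide count table (one library, rounds 1..R).
#' @param assignment Cluster assignment covering all peptides of `table`
#'   (e.g. from [all_round_clusters()]).
#' @return Numeric matrix, rows = cluster ids, columns named
#'   `<tissue>_r<round>`.
#' @export
enrichment_matrix <- function(table, assignment) {
  missing <- setdiff(unique(table$peptide), assignment$peptide)
  if (length(missing) > 0L)
    stop("assignment does not cover all observed peptides")
  joined <- table %>%
    dplyr::left_join(assignment, by = "peptide") %>%
    dplyr::group_by(.data$cluster_id, .data$tissue, .data$round) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  tissues <- sort(unique(table$tissue))
  rounds <- sort(unique(table$round))
  clusters <- sort(unique(assignment$cluster_id))
  mat <- matrix(0, nrow = length(clusters),
                ncol = length(tissues) * length(rounds),
                dimnames = list(
                  as.character(clusters),
                  paste0(rep(tissues, each = length(rounds)), "_r",
                         rep(rounds, length(tissues)))))
  idx_row <- match(joined$cluster_id, clusters)
  idx_col <- match(paste0(joined$tissue, "_r", joined$round), colnames(mat))
  mat[cbind(idx_row, idx_col)] <- log2(joined$count + 1)
  mat
}

#' Clusters enriched in target tissues over the panning rounds
#'
#' Returns the clusters whose log2 entries increase strictly across rounds
#' in every target tissue and never increase in any depleting tissue (flat
#' trajectories in depleting tissues are allowed).
#'
#' @param matrix Enrichment matrix from [enrichment_matrix()].
#' @param target_tissues Tissues that must show strict round-over-round
#'   increase.
#' @param depleting_tissues Tissues that must be non-increasing.
#' @param rounds Rounds considered, in order (default 1:3).
#' @return Integer vector of enriched cluster ids.
#' @export
enriched_clusters <- function(matrix, target_tissues, depleting_tissues,
                              rounds = 1:3) {
  cols <- function(tissue) paste0(tissue, "_r", rounds)
  ok <- rep(TRUE, nrow(matrix))
  for (t in target_tissues) {
    m <- matrix[, cols(t), drop = FALSE]
    ok <- ok & apply(m, 1L, function(v) all(diff(v) > 0))
  }
  for (t in depleting_tissues) {
    m <- matrix[, cols(t), drop = FALSE]
    ok <- ok & apply(m, 1L, function(v) all(diff(v) <= 0))
  }
  as.integer(rownames(matrix)[ok])
}
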