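#' Normalized Hamming distance between two equal-length peptides
#'
#' Fraction of positions at which the sequences differ; a metric on
#' fixed-length sequences, in `[0, 1]`.
#'
#' @param a,b Peptide strings of equal length.
#' @return Numeric distance.
#' @export
normalized_hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  mean(utf8ToInt(a) != utf8ToInt(b))
}

#' Pairwise distance matrix over a peptide set
#'
#' Normalized Hamming distances between all pairs of distinct, equal-length
#' peptides.
#'
#' @param peptides Character vector of distinct peptides, equal length.
#' @return A symmetric numeric matrix with zero diagonal and the peptides as
#'   dimnames.
#' @export
build_distance_matrix <- function(peptides) {
  stopifnot(is.character(peptides), length(peptides) >= 1L)
  if (anyDuplicated(peptides)) stop("peptides must be distinct")
  if (length(unique(nchar(peptides))) != 1L)
    stop("peptides must all have the same length")
  d <- cpp_hamming_matrix(peptides)
  dimnames(d) <- list(peptides, peptides)
  d
}

#' WPGMA hierarchical clustering
#'
#' Weighted pair-group agglomeration: at every step the closest pair of
#' clusters is merged at a height equal to their current distance, and the
#' merged cluster's distance to any other cluster is the simple average of
#' its two children's distances, `d(k, i+j) = (d(k,i) + d(k,j)) / 2`
#' (independent of cluster sizes, hence "weighted"). Ties are broken
#' deterministically by the smallest (row, column) index pair in the
#' current matrix ordering, so results are reproducible on the tie-rich
#' distance matrices that Hamming distances produce.
#'
#' @param d Distance matrix (symmetric numeric matrix with peptide
#'   dimnames, e.g. from [build_distance_matrix()]) or a [stats::dist]
#'   object.
#' @return An object of class `hclust` (method `"wpgma"`); merge heights
#'   are non-decreasing.
#' @seealso [cut_clusters()]
#' @export
wpgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d)
  n <- nrow(d)
  if (n == 1L) {
    tree <- list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                 order = 1L, labels = labels, method = "wpgma",
                 call = match.call(), dist.method = "normalized_hamming")
    class(tree) <- "hclust"
    return(tree)
  }
  res <- cpp_wpgma(d)
  tree <- list(merge = res$merge, height = as.numeric(res$height),
               order = leaf_order(res$merge), labels = labels,
               method = "wpgma", call = match.call(),
               dist.method = "normalized_hamming")
  class(tree) <- "hclust"
  tree
}

# leaf ordering by iterative tree traversal (left child first)
leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  if (n == 1L) return(1L)
  out <- integer(n)
  k <- 0L
  stack <- integer(2L * n)  # node indices; negative values are leaves
  stack[1L] <- nrow(merge)
  top <- 1L
  while (top > 0L) {
    node <- stack[top]
    top <- top - 1L
    if (node < 0L) {
      k <- k + 1L
      out[k] <- -node
    } else {
      # push right then left so the left child is visited first
      stack[top + 1L] <- merge[node, 2L]
      stack[top + 2L] <- merge[node, 1L]
      top <- top + 2L
    }
  }
  out
}

#' Cut a dendrogram into clusters at a maximum edge length
#'
#' Two peptides share a cluster iff their merge height is at most `h`
#' (within floating-point tolerance). The defaults used in this package tie
#' the cut height to the peptide length: 0.3 for short (12-mer) libraries,
#' 0.7 for long (20-mer) ones — see [default_cut_height()].
#'
#' @param tree An `hclust` tree from [wpgma()].
#' @param h Cut height (maximum edge length within a cluster).
#' @return Integer vector of cluster ids (1-based, numbered by first
#'   appearance in leaf order), named by peptide when the tree has labels.
#' @export
cut_clusters <- function(tree, h) {
  stopifnot(inherits(tree, "hclust"), h >= 0)
  n <- length(tree$order)
  if (n == 1L) {
    return(stats::setNames(1L, tree$labels))
  }
  roots <- cpp_cut_merges(tree$merge, tree$height, h + 1e-9)
  ids <- match(roots, unique(roots[tree$order]))  # number by leaf order
  names(ids) <- tree$labels
  ids
}

#' Default dendrogram cut height for a peptide length
#'
#' Maps the library's sequence length to the maximum edge length used when
#' cutting the WPGMA tree: 0.3 for peptides up to 15 residues (the 12-mer
#' library), 0.7 for longer ones (the 20-mer library).
#'
#' @param peptide_length Peptide length in residues.
#' @return Numeric cut height.
#' @export
default_cut_height <- function(peptide_length) {
  if (peptide_length <= 15) 0.3 else 0.7
}

#' Count-weighted consensus of a peptide cluster
#'
#' Every residue occurrence is weighted by the read count of the peptide it
#' belongs to; at each position the residue with the largest summed count
#' is chosen (alphabetically first residue on ties). The consensus count is
#' the sum of the member counts.
#'
#' @param peptides Character vector of equal-length cluster members.
#' @param counts Positive member counts, same length as `peptides`.
#' @return A list with `sequence` and `count`.
#' @examples
#' weighted_consensus(c("ACD", "ACE"), c(5, 3))  # "ACD", count 8
#' @export
weighted_consensus <- function(peptides, counts) {
  if (length(peptides) == 0L) stop("empty cluster")
  stopifnot(length(peptides) == length(counts), all(counts >= 1))
  if (length(unique(nchar(peptides))) != 1L)
    stop("cluster members must have equal length")
  if (length(peptides) == 1L) {
    return(list(sequence = peptides, count = sum(counts)))
  }
  chm <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                nrow = length(peptides), byrow = TRUE)
  cons <- vapply(seq_len(ncol(chm)), function(p) {
    w <- rowsum(counts, chm[, p])  # rows sorted by residue -> ties alphabetical
    rownames(w)[which.max(w)]
  }, character(1))
  list(sequence = paste(cons, collapse = ""), count = sum(counts))
}

#' Cluster a set of counted peptides
#'
#' Builds the normalized Hamming distance matrix over the unique peptides,
#' runs [wpgma()] and cuts at `h`.
#'
#' @param peptides Character vector of distinct peptides (equal length).
#' @param h Cut height; defaults to [default_cut_height()] of the peptide
#'   length.
#' @return A list with `assignment` (tibble `peptide, cluster_id`), `tree`
#'   (the `hclust` object) and `h`.
#' @export
cluster_peptides <- function(peptides, h = NULL) {
  stopifnot(length(peptides) >= 1L)
  if (is.null(h)) h <- default_cut_height(nchar(peptides[1]))
  if (length(peptides) == 1L) {
    return(list(
      assignment = tibble::tibble(peptide = peptides, cluster_id = 1L),
      tree = wpgma(build_distance_matrix(peptides)), h = h))
  }
  if (anyDuplicated(peptides)) stop("peptides must be distinct")
  if (length(unique(nchar(peptides))) != 1L)
    stop("peptides must all have the same length")
  # distances and agglomeration fused in C++; identical to
  # wpgma(build_distance_matrix(peptides)) but without the n x n R matrix
  res <- cpp_cluster_peptides(peptides)
  tree <- list(merge = res$merge, height = as.numeric(res$height),
               order = leaf_order(res$merge), labels = peptides,
               method = "wpgma", call = match.call(),
               dist.method = "normalized_hamming")
  class(tree) <- "hclust"
  ids <- cut_clusters(tree, h)
  list(assignment = tibble::tibble(peptide = names(ids),
                                   cluster_id = as.integer(ids)),
       tree = tree, h = h)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param tree An `hclust` tree from [wpgma()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
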