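## Per-lineage Bray-Curtis dissimilarity, cross-lineage matrix averaging
## with a support mask, Ward.D2 agglomerative clustering, cluster
## extraction, and pairwise-dissimilarity distributions.

.new_dissim <- function(values, support, source) {
  structure(list(sample_ids = rownames(values), values = values,
                 support = support, source = source),
            class = "dissim_matrix")
}

#' @export
print.dissim_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$values[upper.tri(x$values)]))
  cat(sprintf("Bray-Curtis matrix (%s): %d samples%s\n", x$source,
              length(x$sample_ids),
              if (nmiss) paste0(", ", nmiss, " unsupported pair(s)") else ""))
  invisible(x)
}

#' Per-lineage Bray-Curtis dissimilarity matrix
#'
#' For samples x and y with per-ASV values a_i and b_i,
#' BC = 1 - 2 * sum(min(a_i, b_i)) / (sum(a_i) + sum(b_i)). With
#' `normalize = TRUE` (default) a and b are within-lineage read
#' proportions, in which case BC equals half the L1 distance between the
#' proportion vectors; proportions guard against the strongly uneven
#' per-sample sequencing depths typical of long-read amplicon runs. Only
#' samples passing the profile's read floor enter the matrix.
#'
#' @param profile A `lineage_profile` with >= 2 included samples.
#' @param normalize Use within-lineage proportions (default TRUE); FALSE
#'   computes BC on raw counts (sensitivity analysis).
#' @return A `dissim_matrix` with per-pair support 1.
#' @export
bray_curtis_matrix <- function(profile, normalize = TRUE) {
  stopifnot(inherits(profile, "lineage_profile"))
  inc <- profile$included_samples
  if (length(inc) < 2L) stop("lineage ", profile$otu_id,
                             " has fewer than 2 included samples")
  m <- t(profile$counts[, inc, drop = FALSE])  # samples x ASVs
  tot <- rowSums(m)
  if (any(tot == 0)) stop("included sample with zero lineage reads: ",
                          inc[tot == 0][1L])
  if (normalize) m <- m / tot
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  sup <- matrix(1L, nrow(d), ncol(d), dimnames = dimnames(d))
  diag(sup) <- 0L
  .new_dissim(d, sup, profile$otu_id)
}

#' Average dissimilarity matrices across lineages
#'
#' Entry (x, y) of the averaged matrix is the arithmetic mean of the
#' per-lineage dissimilarities over the lineages in which BOTH samples
#' pass the read floor; the number of contributing lineages is recorded as
#' per-pair support. Pairs with support below `min_support` are left
#' missing (the clustering step refuses matrices with missing entries, so
#' callers must raise coverage or drop samples).
#'
#' @param matrices List of `dissim_matrix` objects (each may cover a
#'   subset of the sample universe).
#' @param min_support Minimum number of contributing lineages per pair.
#' @return A `dissim_matrix` with source `"averaged"`.
#' @export
average_matrices <- function(matrices, min_support = 1L) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "dissim_matrix")))
  samples <- sort(unique(unlist(lapply(matrices, `[[`, "sample_ids"))))
  n <- length(samples)
  acc <- matrix(0, n, n, dimnames = list(samples, samples))
  sup <- matrix(0L, n, n, dimnames = list(samples, samples))
  for (m in matrices) {
    idx <- match(m$sample_ids, samples)
    acc[idx, idx] <- acc[idx, idx] + m$values
    sup[idx, idx] <- sup[idx, idx] + 1L
  }
  vals <- ifelse(sup >= min_support & sup > 0L, acc / pmax(sup, 1L), NA_real_)
  diag(vals) <- 0
  dimnames(vals) <- list(samples, samples)
  .new_dissim(vals, sup, "averaged")
}

#' Drop samples until a dissimilarity matrix is complete
#'
#' Iteratively removes the sample with the most unsupported (missing)
#' pairs until no missing entries remain (ties: first sample id). Use
#' before [ward_d2_linkage()] when averaging left uncovered pairs.
#'
#' @param m A `dissim_matrix`.
#' @return A complete `dissim_matrix` over the retained samples.
#' @export
drop_unsupported <- function(m) {
  stopifnot(inherits(m, "dissim_matrix"))
  v <- m$values
  sup <- m$support
  while (anyNA(v) && nrow(v) > 1L) {
    worst <- which.max(rowSums(is.na(v)))
    v <- v[-worst, -worst, drop = FALSE]
    sup <- sup[-worst, -worst, drop = FALSE]
  }
  .new_dissim(v, sup, m$source)
}

#' Ward.D2 agglomerative clustering of a dissimilarity matrix
#'
#' Lance-Williams update on squared dissimilarities with square-root merge
#' heights (the `ward.D2` criterion):
#' d(ij,k) = sqrt(((n_i+n_k) d_ik^2 + (n_j+n_k) d_jk^2 - n_k d_ij^2)
#' / (n_i+n_j+n_k)). Delegates to [stats::hclust()].
#'
#' @param m A `dissim_matrix` with no missing entries, >= 2 samples.
#' @return An `hclust` object (merge heights are monotone non-decreasing).
#' @export
ward_d2_linkage <- function(m) {
  stopifnot(inherits(m, "dissim_matrix"))
  if (length(m$sample_ids) < 2L) stop("need at least 2 samples")
  if (anyNA(m$values)) {
    stop("dissimilarity matrix has missing (unsupported) entries; raise ",
         "lineage coverage or drop samples before clustering")
  }
  stats::hclust(stats::as.dist(m$values), method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges; cluster labels are renumbered in
#' dendrogram (first-leaf) order, so cluster 1 contains the leftmost leaf.
#'
#' @param tree An `hclust` object.
#' @param k Number of clusters, 1 <= k <= number of leaves.
#' @return Named integer vector: sample -> cluster label.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "], got ", k)
  raw <- stats::cutree(tree, k = k)
  leaf_order <- tree$labels[tree$order]
  first_seen <- unique(raw[leaf_order])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  out <- relabel[as.character(raw)]
  names(out) <- names(raw)
  out
}

#' Upper-triangle pairwise dissimilarities under a sample filter
#'
#' @param m A `dissim_matrix`.
#' @param sample_filter Either a character vector of sample ids to retain,
#'   a predicate over sample ids, or NULL (keep all).
#' @return Data.frame `sample_a`, `sample_b`, `value` (one row per
#'   retained unordered pair; NA values from unsupported pairs are kept).
#' @export
pairwise_values <- function(m, sample_filter = NULL) {
  stopifnot(inherits(m, "dissim_matrix"))
  keep <- m$sample_ids
  if (is.function(sample_filter)) {
    keep <- keep[vapply(keep, sample_filter, logical(1))]
  } else if (!is.null(sample_filter)) {
    keep <- intersect(keep, sample_filter)
  }
  v <- m$values[keep, keep, drop = FALSE]
  ut <- which(upper.tri(v), arr.ind = TRUE)
  data.frame(sample_a = keep[ut[, 1L]], sample_b = keep[ut[, 2L]],
             value = v[ut])
}
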