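## Greedy centroid clustering of extracted 16S regions at 100% (SSU-ASV)
## and 97% (OTU) identity, consensus representatives, and global
## re-assignment of ASVs to clusters.

#' Greedy centroid clustering
#'
#' Inputs are processed in (length desc, total abundance desc, id asc)
#' order. Each sequence is compared to existing centroids in
#' centroid-creation order and joins the FIRST centroid with identity >=
#' `threshold`; otherwise it founds a new centroid. At `threshold = 1`
#' clustering reduces to exact deduplication (number of clusters = number
#' of distinct sequences) and is computed by hashing.
#'
#' @param seqs Named character vector: asv_id -> 16S-region sequence.
#' @param abundances Named numeric vector: asv_id -> total reads (used only
#'   for ordering; missing ids count as 0).
#' @param threshold Identity fraction in (0, 1].
#' @param prefix Cluster-id prefix (`"OTU"` gives OTU_1, OTU_2, ...).
#' @param scoring Alignment scoring scheme.
#' @return Object of class `cluster_set`: `threshold`, `centroids` (named
#'   character), `assignments` (data.frame asv_id, cluster_id, identity),
#'   `processing_order`.
#' @export
greedy_cluster <- function(seqs, abundances = NULL, threshold = 0.97,
                           prefix = "OTU", scoring = align_scoring()) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(seqs)) {
    return(structure(list(threshold = threshold,
                          centroids = character(),
                          assignments = data.frame(asv_id = character(),
                                                   cluster_id = character(),
                                                   identity = numeric()),
                          processing_order = character()),
                     class = "cluster_set"))
  }
  if (is.null(names(seqs))) stop("seqs must be named by asv_id")
  .check_dna(unlist(seqs))
  ab <- rep(0, length(seqs))
  names(ab) <- names(seqs)
  if (!is.null(abundances)) {
    common <- intersect(names(seqs), names(abundances))
    ab[common] <- abundances[common]
  }
  ord <- order(-nchar(seqs), -ab, names(seqs), method = "radix")
  seqs <- seqs[ord]
  ids <- names(seqs)

  centroid_seq <- character()
  assign_cluster <- character(length(seqs))
  assign_ident <- numeric(length(seqs))

  if (threshold >= 1) {
    first_idx <- match(seqs, seqs)          # index of first occurrence
    cluster_of_first <- integer(length(seqs))
    nclust <- 0L
    for (i in seq_along(seqs)) {
      if (first_idx[i] == i) {
        nclust <- nclust + 1L
        cluster_of_first[i] <- nclust
        centroid_seq[nclust] <- seqs[[i]]
      }
      assign_cluster[i] <- cluster_of_first[first_idx[i]]
      assign_ident[i] <- 1
    }
    cluster_ids <- paste0(prefix, "_", seq_len(nclust))
    names(centroid_seq) <- cluster_ids
    assignments <- data.frame(asv_id = ids,
                              cluster_id = cluster_ids[as.integer(assign_cluster)],
                              identity = assign_ident)
  } else {
    # identical sequences provably receive the identical assignment under
    # first-fit (the centroid list only ever grows by appending), so the
    # scan is memoized by sequence content
    memo <- new.env(parent = emptyenv())
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      hit <- memo[[s]]
      if (!is.null(hit)) {
        assign_cluster[i] <- hit[1L]
        assign_ident[i] <- hit[2L]
        next
      }
      placed <- FALSE
      if (length(centroid_seq)) {
        for (k in seq_along(centroid_seq)) {
          idk <- .identity_many(s, centroid_seq[k], scoring)
          if (idk >= threshold) {
            assign_cluster[i] <- k
            assign_ident[i] <- idk
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) {
        centroid_seq <- c(centroid_seq, s)
        assign_cluster[i] <- length(centroid_seq)
        assign_ident[i] <- 1
      }
      memo[[s]] <- c(assign_cluster[i], assign_ident[i])
    }
    cluster_ids <- paste0(prefix, "_", seq_along(centroid_seq))
    names(centroid_seq) <- cluster_ids
    assignments <- data.frame(asv_id = ids,
                              cluster_id = cluster_ids[as.integer(assign_cluster)],
                              identity = assign_ident)
  }
  structure(list(threshold = threshold, centroids = centroid_seq,
                 assignments = assignments, processing_order = ids),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d sequences -> %d clusters at %.0f%% identity\n",
              nrow(x$assignments), length(x$centroids), 100 * x$threshold))
  invisible(x)
}

#' Validate the invariants of a cluster set
#'
#' Every member's identity to its centroid must be >= threshold and every
#' pair of centroids must be < threshold apart. Intended for tests and
#' post-run checks (quadratic in centroid count).
#'
#' @param cs A `cluster_set`.
#' @param seqs The clustered sequences (asv_id -> sequence).
#' @param scoring Scoring scheme.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_cluster_set <- function(cs, seqs, scoring = align_scoring()) {
  for (i in seq_len(nrow(cs$assignments))) {
    id <- cs$assignments$asv_id[i]
    ident <- .identity_many(seqs[[id]],
                            cs$centroids[[cs$assignments$cluster_id[i]]],
                            scoring)
    if (ident < cs$threshold) {
      stop("member ", id, " below threshold to its centroid (", ident, ")")
    }
  }
  nc <- length(cs$centroids)
  if (nc > 1L && cs$threshold < 1) {
    for (i in seq_len(nc - 1L)) {
      idents <- .identity_many(cs$centroids[[i]],
                               cs$centroids[(i + 1L):nc], scoring)
      if (any(idents >= cs$threshold)) {
        stop("centroids ", i, " and ", i + which(idents >= cs$threshold)[1L],
             " not separated below threshold")
      }
    }
  }
  invisible(TRUE)
}

#' Consensus sequence of a cluster
#'
#' Members are anchored to the most abundant member; each reference column
#' emits the majority state (ties broken alphabetically A<C<G<T; a strict
#' gap majority deletes the column). Insertions present in more than half
#' of the members are retained (most common inserted string; alphabetical
#' tie-break).
#'
#' @param members Named character vector of member sequences.
#' @param abundances Optional named numeric vector used to pick the anchor
#'   (most reads; ties by id); defaults to the first member.
#' @param scoring Scoring scheme.
#' @return Consensus DNA string.
#' @export
cluster_consensus <- function(members, abundances = NULL,
                              scoring = align_scoring()) {
  stopifnot(length(members) >= 1L)
  if (length(members) == 1L) return(unname(members[[1L]]))
  if (is.null(names(members))) names(members) <- paste0("m", seq_along(members))
  anchor_id <- if (!is.null(abundances)) {
    ab <- abundances[names(members)]
    ab[is.na(ab)] <- 0
    names(members)[order(-ab, names(members))][1L]
  } else names(members)[1L]
  msa <- anchored_msa(members[[anchor_id]], members, scoring = scoring,
                      warn_identity = 0)
  n <- nrow(msa$states)
  cons <- character(0)
  ref_len <- ncol(msa$states)
  ins <- msa$insertions
  emit_insertion <- function(after_pos) {
    here <- ins[ins$after_pos == after_pos, , drop = FALSE]
    if (!nrow(here)) return("")
    tab <- table(here$seq)
    if (max(tab) > n / 2) {
      names(tab)[order(-as.integer(tab), names(tab))][1L]
    } else ""
  }
  out <- emit_insertion(0L)
  for (j in seq_len(ref_len)) {
    col <- msa$states[, j]
    ngap <- sum(col == "-")
    if (ngap <= n / 2) {
      bases <- col[col != "-"]
      tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
      out <- c(out, names(tab)[which.max(tab)])  # which.max: first = alphabetical
    }
    out <- c(out, emit_insertion(j))
  }
  paste(out, collapse = "")
}

#' Re-assign sequences to an existing centroid set
#'
#' Unlike greedy clustering (first centroid at or above threshold), global
#' re-assignment picks the centroid with MAXIMUM identity among those >=
#' `threshold` (ties go to the earlier centroid id); sequences below
#' threshold to every centroid are flagged unassigned.
#'
#' @param seqs Named character vector: asv_id -> sequence.
#' @param centroids A `cluster_set` or a named character vector of centroid
#'   sequences (in centroid order).
#' @param threshold Identity fraction. At 1.0, assignment is by exact
#'   sequence match (mirroring that clustering at 1.0 is exact
#'   deduplication); identity is NA for unmatched sequences.
#' @param scoring Scoring scheme.
#' @return Data.frame asv_id, cluster_id (NA when unassigned), identity
#'   (best identity observed against any centroid).
#' @export
map_to_centroids <- function(seqs, centroids, threshold = 0.97,
                             scoring = align_scoring()) {
  cents <- if (inherits(centroids, "cluster_set")) centroids$centroids
  else centroids
  stopifnot(length(cents) >= 1L, !is.null(names(cents)))
  res <- data.frame(asv_id = names(seqs),
                    cluster_id = NA_character_,
                    identity = NA_real_)
  if (threshold >= 1) {
    hit <- match(unlist(seqs), cents)
    res$cluster_id <- names(cents)[hit]
    res$identity[!is.na(hit)] <- 1
    return(res)
  }
  memo <- new.env(parent = emptyenv())  # assignment depends only on content
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    hit <- memo[[s]]
    if (is.null(hit)) {
      idents <- .identity_many(s, cents, scoring)
      best <- which.max(idents)  # first maximum = earlier centroid
      hit <- list(cluster = if (idents[best] >= threshold)
        names(cents)[best] else NA_character_,
        identity = idents[best])
      memo[[s]] <- hit
    }
    res$identity[i] <- hit$identity
    res$cluster_id[i] <- hit$cluster
  }
  res
}
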