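## Per-lineage (per-OTU) ASV composition profiles, inclusion filters, and
## dominance statistics.

#' Build per-lineage composition profiles
#'
#' One profile per OTU: the member-ASV x sample count sub-matrix plus the
#' per-lineage set of included samples (those with at least `min_reads`
#' reads assigned to the OTU). Sample inclusion is computed per OTU — a
#' sample may pass the floor for one lineage and fail it for another.
#'
#' @param table An `asv_table`.
#' @param otu_map Either a `cluster_set`/data.frame with columns `asv_id`,
#'   `cluster_id`, or a named character vector asv_id -> cluster_id. Must
#'   cover every ASV in the table (NA = unassigned, dropped with a warning).
#' @param min_reads Per-sample read floor (default 20): samples with fewer
#'   assigned reads leave all subsequent analysis for that lineage.
#' @return Named list of `lineage_profile` objects.
#' @export
build_profiles <- function(table, otu_map, min_reads = 20L) {
  stopifnot(inherits(table, "asv_table"))
  if (inherits(otu_map, "cluster_set")) otu_map <- otu_map$assignments
  if (is.data.frame(otu_map)) {
    map <- stats::setNames(otu_map$cluster_id, otu_map$asv_id)
  } else map <- otu_map
  missing <- setdiff(table$asv_ids, names(map))
  if (length(missing)) stop("otu_map does not cover ASV: ", missing[1L])
  map <- map[table$asv_ids]
  if (anyNA(map)) {
    warning(sum(is.na(map)), " unassigned ASV(s) dropped from profiles")
    map <- map[!is.na(map)]
  }
  otus <- unique(unname(map))
  profiles <- lapply(otus, function(otu) {
    members <- names(map)[map == otu]
    counts <- table$counts[members, , drop = FALSE]
    csums <- colSums(counts)
    structure(list(otu_id = otu, asv_ids = members, counts = counts,
                   included_samples = colnames(counts)[csums >= min_reads],
                   min_reads_filter = as.integer(min_reads)),
              class = "lineage_profile")
  })
  names(profiles) <- otus
  profiles
}

#' @export
print.lineage_profile <- function(x, ...) {
  cat(sprintf("lineage %s: %d ASVs, %d reads, %d/%d samples pass the %d-read floor\n",
              x$otu_id, length(x$asv_ids), sum(x$counts),
              length(x$included_samples), ncol(x$counts), x$min_reads_filter))
  invisible(x)
}

#' Select dominant lineages
#'
#' A lineage is dominant when it is ubiquitous — detected (>= 1 read,
#' counted before the per-sample read floor) in at least `min_samples`
#' samples — and abundant, with at least `min_total_reads` reads. The
#' defaults encode "detected in more than eight samples" (>= 9) and
#' "> 300 reads" (>= 301).
#'
#' @param profiles Named list from [build_profiles()].
#' @param min_samples Minimum number of samples with >= 1 read (default 9).
#' @param min_total_reads Minimum total reads (default 301).
#' @return Character vector of dominant otu_ids, ordered by total reads
#'   (descending).
#' @export
select_dominant_lineages <- function(profiles, min_samples = 9L,
                                     min_total_reads = 301L) {
  totals <- vapply(profiles, function(p) sum(p$counts), numeric(1))
  detected <- vapply(profiles, function(p) sum(colSums(p$counts) >= 1L),
                     numeric(1))
  sel <- names(profiles)[detected >= min_samples & totals >= min_total_reads]
  sel[order(-totals[sel])]
}

#' Dominance statistics of a lineage
#'
#' Per included sample, member-ASV counts are sorted descending and the
#' top-k read proportion is computed for k = 1, 2, 3 (a lineage with fewer
#' than k ASVs tops out at 1). Means are taken across included samples
#' only.
#'
#' @param profile A `lineage_profile`.
#' @return Object of class `dominance_stats`: `otu_id`, `per_sample`
#'   (data.frame sample_id, top1, top2, top3), `means` (named numeric).
#' @export
dominance_stats <- function(profile) {
  stopifnot(inherits(profile, "lineage_profile"))
  inc <- profile$included_samples
  if (!length(inc)) stop("lineage ", profile$otu_id,
                         " has no sample passing the read floor")
  per <- t(vapply(inc, function(s) {
    v <- sort(profile$counts[, s], decreasing = TRUE)
    tot <- sum(v)
    vapply(1:3, function(k) sum(v[seq_len(min(k, length(v)))]) / tot,
           numeric(1))
  }, numeric(3)))
  colnames(per) <- c("top1", "top2", "top3")
  per_sample <- data.frame(sample_id = inc, per, row.names = NULL)
  structure(list(otu_id = profile$otu_id, per_sample = per_sample,
                 means = colMeans(per)),
            class = "dominance_stats")
}

#' @export
print.dominance_stats <- function(x, ...) {
  cat(sprintf("lineage %s dominance over %d samples: top1 %.1f%%, top2 %.1f%%, top3 %.1f%%\n",
              x$otu_id, nrow(x$per_sample), 100 * x$means[["top1"]],
              100 * x$means[["top2"]], 100 * x$means[["top3"]]))
  invisible(x)
}

#' Pooled ASV composition by sample group
#'
#' Reads of the lineage's included samples are pooled within each group
#' (region, layer or lake) and converted to per-ASV shares; shares sum to
#' one within every non-empty group.
#'
#' @param profile A `lineage_profile`.
#' @param metadata Sample metadata covering the profile's samples.
#' @param grouping One of `"region"`, `"layer"`, `"lake_code"`.
#' @param included_only Pool only samples passing the read floor (default
#'   TRUE).
#' @return Named list: group -> named numeric vector of ASV read shares.
#' @export
regional_composition <- function(profile, metadata,
                                 grouping = c("region", "layer", "lake_code"),
                                 included_only = TRUE) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(profile, "lineage_profile"))
  samples <- if (included_only) profile$included_samples
  else colnames(profile$counts)
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata does not cover sample: ",
                                samples[is.na(md$sample_id)][1L])
  groups <- split(samples, md[[grouping]])
  out <- lapply(groups, function(ss) {
    pooled <- rowSums(profile$counts[, ss, drop = FALSE])
    if (sum(pooled) == 0) return(NULL)
    pooled / sum(pooled)
  })
  out[!vapply(out, is.null, logical(1))]
}
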