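## End-to-end orchestration: region extraction, dual-threshold clustering,
## lineage profiling, dominance statistics, per-lineage and averaged
## Bray-Curtis matrices, Ward.D2 dendrogram, optional SNP concordance,
## plus a reproducibility manifest.

#' Run the full microdiversity / phylogeography pipeline
#'
#' Stages, in order: (1) partition every ASV amplicon into 16S/ITS/23S and
#' extract the 16S region; (2) greedy centroid clustering of 16S regions
#' at `ssu_identity` (SSU-ASVs) and `otu_identity` (OTUs / lineages) with
#' consensus representatives; (3) global re-assignment of all ASVs to the
#' OTU centroids; (4) per-lineage profiles under the per-sample read
#' floor, dominant-lineage selection, dominance statistics; (5)
#' per-lineage Bray-Curtis matrices for the dominant lineages, support-
#' masked averaging, Ward.D2 dendrogram and optional k-cluster cut; (6)
#' optional ASV-vs-pileup SNP concordance for one lineage in one sample.
#'
#' @param table An `asv_table` with sequences attached.
#' @param otu_identity,ssu_identity Clustering identity thresholds
#'   (defaults 0.97 and 1.0).
#' @param min_sample_reads Per-lineage per-sample read floor (default 20).
#' @param dominant_min_samples,dominant_min_reads Dominance filters
#'   (defaults 9 samples, 301 reads).
#' @param normalize Bray-Curtis on within-lineage proportions (default
#'   TRUE).
#' @param min_support Minimum lineages per sample pair in the averaged
#'   matrix.
#' @param n_clusters Optional k for the dendrogram cut.
#' @param ssu_reference,lsu_reference Region references (default bundled).
#' @param pileup Optional `pileup_table` for SNP concordance.
#' @param snp_lineage,snp_sample Lineage (otu id) and sample for the
#'   concordance check; default: the lineage-sample pair with the most
#'   reads.
#' @param snp_min_count,snp_min_freq,snp_min_depth Detection thresholds
#'   (see [detected_variant_sites()]).
#' @param output_dir Optional directory: all intermediates plus a
#'   `manifest.json` are written there.
#' @param scoring Alignment scoring scheme.
#' @return Object of class `ampdiv_result`.
#' @export
run_pipeline <- function(table,
                         otu_identity = 0.97,
                         ssu_identity = 1.0,
                         min_sample_reads = 20L,
                         dominant_min_samples = 9L,
                         dominant_min_reads = 301L,
                         normalize = TRUE,
                         min_support = 1L,
                         n_clusters = NULL,
                         ssu_reference = NULL,
                         lsu_reference = NULL,
                         pileup = NULL,
                         snp_lineage = NULL,
                         snp_sample = NULL,
                         snp_min_count = 2L,
                         snp_min_freq = 0.01,
                         snp_min_depth = 10L,
                         output_dir = NULL,
                         scoring = align_scoring()) {
  stopifnot(inherits(table, "asv_table"))
  if (is.null(table$sequences)) stop("ASV table has no sequences attached")
  cfg <- list(otu_identity = otu_identity, ssu_identity = ssu_identity,
              min_sample_reads = min_sample_reads,
              dominant_min_samples = dominant_min_samples,
              dominant_min_reads = dominant_min_reads,
              normalize = normalize, min_support = min_support,
              n_clusters = n_clusters,
              snp_min_count = snp_min_count, snp_min_freq = snp_min_freq,
              snp_min_depth = snp_min_depth,
              scoring = scoring[c("match", "mismatch", "gap_open",
                                  "gap_extend")])

  if (is.null(ssu_reference) || is.null(lsu_reference)) {
    refs <- ampdiv_references()
    ssu_reference <- ssu_reference %||% refs$ssu
    lsu_reference <- lsu_reference %||% refs$lsu
  }

  # 1. region extraction
  ext <- extract_ssu_regions(table$sequences,
                             ssu_reference = ssu_reference,
                             lsu_reference = lsu_reference,
                             scoring = scoring)
  abundances <- rowSums(table$counts)

  # 2. clustering at both thresholds
  ssu_clusters <- greedy_cluster(ext$regions, abundances,
                                 threshold = ssu_identity,
                                 prefix = "SSUASV", scoring = scoring)
  otu_clusters <- greedy_cluster(ext$regions, abundances,
                                 threshold = otu_identity,
                                 prefix = "OTU", scoring = scoring)
  consensus <- vapply(names(otu_clusters$centroids), function(cid) {
    members <- otu_clusters$assignments$asv_id[
      otu_clusters$assignments$cluster_id == cid]
    cluster_consensus(ext$regions[members], abundances[members], scoring)
  }, character(1))

  # 3. global re-assignment
  otu_map <- map_to_centroids(ext$regions, otu_clusters,
                              threshold = otu_identity, scoring = scoring)
  ssu_map <- map_to_centroids(ext$regions, ssu_clusters,
                              threshold = ssu_identity, scoring = scoring)

  # 4. profiles and dominance
  profiles <- build_profiles(table, otu_map, min_reads = min_sample_reads)
  dominant <- select_dominant_lineages(profiles,
                                       min_samples = dominant_min_samples,
                                       min_total_reads = dominant_min_reads)
  dominance <- lapply(profiles[dominant], function(p) {
    if (length(p$included_samples)) dominance_stats(p) else NULL
  })
  dominance <- dominance[!vapply(dominance, is.null, logical(1))]

  # 5. phylogeography
  usable <- dominant[vapply(profiles[dominant],
                            function(p) length(p$included_samples) >= 2L,
                            logical(1))]
  matrices <- lapply(profiles[usable], bray_curtis_matrix,
                     normalize = normalize)
  averaged <- if (length(matrices)) {
    average_matrices(matrices, min_support = min_support)
  } else NULL
  tree <- NULL
  clusters <- NULL
  if (!is.null(averaged) && length(averaged$sample_ids) >= 2L &&
      !anyNA(averaged$values)) {
    tree <- ward_d2_linkage(averaged)
    if (!is.null(n_clusters)) clusters <- cut_tree(tree, n_clusters)
  }

  # 6. optional SNP concordance
  concordance <- NULL
  if (!is.null(pileup)) {
    if (is.null(snp_lineage) || is.null(snp_sample)) {
      best <- -1L
      for (otu in dominant) {
        cs <- colSums(profiles[[otu]]$counts)
        if (max(cs) > best) {
          best <- max(cs)
          snp_lineage <- otu
          snp_sample <- names(cs)[which.max(cs)]
        }
      }
    }
    p <- profiles[[snp_lineage]]
    in_sample <- p$asv_ids[p$counts[, snp_sample] > 0L]
    ab <- p$counts[in_sample, snp_sample]
    ref_id <- in_sample[order(-ab, in_sample)][1L]
    msa <- anchored_msa(table$sequences[[ref_id]],
                        table$sequences[in_sample], scoring = scoring)
    part <- ext$partitions[[ref_id]]
    expected <- expected_variant_sites(msa, ab, partition = part)
    detected <- detected_variant_sites(pileup, min_count = snp_min_count,
                                       min_freq = snp_min_freq,
                                       min_depth = snp_min_depth)
    concordance <- classify_concordance(expected, detected)
    attr(concordance, "lineage") <- snp_lineage
    attr(concordance, "sample") <- snp_sample
  }

  res <- structure(list(
    config = cfg, table = table, partitions = ext$partitions,
    ssu_regions = ext$regions,
    ssu_clusters = ssu_clusters, otu_clusters = otu_clusters,
    consensus = consensus, otu_map = otu_map, ssu_map = ssu_map,
    profiles = profiles, dominant = dominant, dominance = dominance,
    matrices = matrices, averaged = averaged, tree = tree,
    clusters = clusters, concordance = concordance),
    class = "ampdiv_result")
  if (!is.null(output_dir)) write_result_bundle(res, output_dir)
  res
}

#' @export
print.ampdiv_result <- function(x, ...) {
  cat("ampdiv pipeline result\n")
  cat(sprintf("  %d ASVs x %d samples, %d reads\n", nrow(x$table$counts),
              ncol(x$table$counts), sum(x$table$counts)))
  cat(sprintf("  %d SSU-ASVs (%.0f%%), %d OTUs (%.0f%%)\n",
              length(x$ssu_clusters$centroids), 100 * x$config$ssu_identity,
              length(x$otu_clusters$centroids), 100 * x$config$otu_identity))
  cat(sprintf("  %d dominant lineage(s)\n", length(x$dominant)))
  if (!is.null(x$tree)) {
    cat(sprintf("  averaged Bray-Curtis dendrogram over %d samples\n",
                length(x$averaged$sample_ids)))
  }
  if (!is.null(x$clusters)) {
    cat(sprintf("  cut into %d clusters\n", max(x$clusters)))
  }
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

#' @export
summary.ampdiv_result <- function(object, ...) {
  x <- object
  tot <- sum(x$table$counts)
  dom_reads <- sum(vapply(x$profiles[x$dominant],
                          function(p) sum(p$counts), numeric(1)))
  top1 <- vapply(x$dominance, function(d) d$means[["top1"]], numeric(1))
  out <- list(
    n_asvs = nrow(x$table$counts),
    n_samples = ncol(x$table$counts),
    total_reads = tot,
    n_ssu_asvs = length(x$ssu_clusters$centroids),
    n_otus = length(x$otu_clusters$centroids),
    n_dominant = length(x$dominant),
    dominant_read_share = dom_reads / tot,
    mean_top1_range = if (length(top1)) range(top1) else c(NA, NA))
  class(out) <- "summary.ampdiv_result"
  out
}

#' @export
print.summary.ampdiv_result <- function(x, ...) {
  cat(sprintf("%d ASVs / %d SSU-ASVs / %d OTUs across %d samples (%d reads)\n",
              x$n_asvs, x$n_ssu_asvs, x$n_otus, x$n_samples, x$total_reads))
  cat(sprintf("%d dominant lineage(s) holding %.1f%% of reads\n",
              x$n_dominant, 100 * x$dominant_read_share))
  if (!is.na(x$mean_top1_range[1L])) {
    cat(sprintf("mean top-1 ASV proportion %.1f%%-%.1f%% across dominant lineages\n",
                100 * x$mean_top1_range[1L], 100 * x$mean_top1_range[2L]))
  }
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Emits cluster maps, centroid/consensus FASTA, per-lineage profiles, the
#' dominance report, all Bray-Curtis matrices, the Newick dendrogram,
#' cluster labels, the per-site concordance table, and a `manifest.json`
#' recording the package version, full configuration and md5 checksums of
#' every artifact. Identical inputs and configuration produce
#' byte-identical bundles.
#'
#' @param result An `ampdiv_result`.
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_result_bundle <- function(result, output_dir) {
  stopifnot(inherits(result, "ampdiv_result"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  wr_map <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ampdiv ", .ampdiv_version()), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr_map(result$otu_map, p("otu_map.tsv"))
  wr_map(result$ssu_map, p("ssu_asv_map.tsv"))
  write_fasta(result$otu_clusters$centroids, p("otu_centroids.fasta"))
  write_fasta(result$consensus, p("otu_consensus.fasta"))
  dom <- do.call(rbind, lapply(result$dominance, function(d) {
    data.frame(otu_id = d$otu_id, n_samples = nrow(d$per_sample),
               mean_top1 = d$means[["top1"]], mean_top2 = d$means[["top2"]],
               mean_top3 = d$means[["top3"]])
  }))
  if (is.null(dom)) dom <- data.frame(otu_id = character())
  wr_map(dom, p("dominance.tsv"))
  for (otu in names(result$matrices)) {
    write_matrix(result$matrices[[otu]], p(paste0("bc_", otu, ".tsv")))
  }
  if (!is.null(result$averaged)) {
    write_matrix(result$averaged, p("bc_averaged.tsv"))
  }
  if (!is.null(result$tree)) write_newick(result$tree, p("tree.nwk"))
  if (!is.null(result$clusters)) {
    wr_map(data.frame(sample_id = names(result$clusters),
                      cluster = unname(result$clusters)),
           p("sample_clusters.tsv"))
  }
  if (!is.null(result$concordance)) {
    wr_map(concordance_table(result$concordance), p("snp_concordance.tsv"))
  }
  files <- sort(list.files(output_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(output_dir, files))
  manifest <- list(tool = "ampdiv", version = .ampdiv_version(),
                   config = result$config,
                   checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(p("manifest.json"))
}
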