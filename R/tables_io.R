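## Readers and writers for every external artifact: FASTA, count tables,
## sample metadata, pileups, dissimilarity matrices, Newick trees.
##
## Coordinate conventions: all external positions are 1-based inclusive
## (pileup rows, reported SNP sites); internal region intervals are kept as
## 1-based [start, end] integer pairs in R idiom.

.ampdiv_regions <- c("Honshu-Kyushu", "Hokkaido", "Europe")

#' Read a DNA FASTA file
#'
#' Sequences are uppercased and RNA-style `U` is normalized to `T`. The
#' record identifier is the header token before the first whitespace.
#' IUPAC ambiguity codes are permitted but reported via the
#' `"ambiguous_ids"` attribute so callers can flag them.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids), with
#'   attribute `ambiguous_ids` listing records containing non-ACGT letters.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record: ", ids[!nzchar(seqs)][1L])
  }
  names(seqs) <- ids
  bad <- grepl("[^ACGT]", seqs)
  attr(seqs, "ambiguous_ids") <- ids[bad]
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    writeLines(paste0(">", names(seqs)[i]), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `lake_code`, `region`, `layer`,
#' `year`. `region` and `layer` are validated against the closed
#' vocabularies (`Honshu-Kyushu` / `Hokkaido` / `Europe`;
#' `epilimnion` / `hypolimnion`).
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  needed <- c("sample_id", "lake_code", "region", "layer", "year")
  missing <- setdiff(needed, names(md))
  if (length(missing)) stop("metadata missing column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  }
  bad_region <- setdiff(unique(md$region), .ampdiv_regions)
  if (length(bad_region)) stop("unknown region: ", bad_region[1L])
  bad_layer <- setdiff(unique(md$layer), .ampdiv_layers)
  if (length(bad_layer)) stop("unknown layer: ", bad_layer[1L])
  md$year <- as.integer(md$year)
  md[needed]
}

#' Construct and validate an ASV table
#'
#' The central container: an ASV-by-sample matrix of non-negative integer
#' read counts, optional sequences, and sample metadata.
#'
#' @param counts Integer matrix, rows = ASVs (rownames), cols = samples.
#' @param metadata Data.frame as returned by [read_metadata()].
#' @param sequences Optional named character vector of ASV sequences.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, metadata, sequences = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate asv_id in counts")
  if (any(counts < 0)) stop("negative count in ASV table")
  if (any(counts != round(counts))) stop("non-integer count in ASV table")
  storage.mode(counts) <- "integer"
  unknown <- setdiff(colnames(counts), metadata$sample_id)
  if (length(unknown)) {
    stop("sample in count table but not in metadata: ", unknown[1L])
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  if (!is.null(sequences)) {
    missing <- setdiff(rownames(counts), names(sequences))
    if (length(missing)) stop("no sequence for ASV: ", missing[1L])
    sequences <- sequences[rownames(counts)]
    if (any(!nzchar(sequences))) stop("empty sequence in ASV table")
  }
  structure(list(asv_ids = rownames(counts), counts = counts,
                 metadata = metadata, sequences = sequences),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d ASVs x %d samples, %d reads%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              if (is.null(x$sequences)) " (no sequences attached)" else ""))
  invisible(x)
}

#' Read an ASV count table plus metadata
#'
#' The count table is a TSV whose first column is `asv_id` and whose
#' remaining columns are per-sample integer read counts; the header row
#' carries sample ids. Every sample column must be covered by the metadata.
#'
#' @param path Path to the count TSV.
#' @param metadata_path Path to the metadata TSV (see [read_metadata()]).
#' @param fasta_path Optional FASTA of ASV sequences to attach.
#' @return An `asv_table`.
#' @export
read_count_table <- function(path, metadata_path, fasta_path = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  if (names(tab)[1L] != "asv_id") stop("first column must be 'asv_id', got '",
                                       names(tab)[1L], "'")
  if (anyDuplicated(tab$asv_id)) {
    stop("duplicate asv_id in count table: ",
         tab$asv_id[duplicated(tab$asv_id)][1L])
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad)) {
      stop(sprintf("non-integer count at row %d (asv '%s'), column '%s'",
                   bad[1L], tab$asv_id[bad[1L]], colnames(m)[j]))
    }
  }
  storage.mode(m) <- "integer"
  rownames(m) <- tab$asv_id
  md <- read_metadata(metadata_path)
  seqs <- if (!is.null(fasta_path)) read_fasta(fasta_path) else NULL
  asv_table(m, md, sequences = seqs)
}

#' Write an ASV count table
#'
#' @param table An `asv_table`.
#' @param path Output TSV path.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ampdiv ", .ampdiv_version()), con)
  df <- data.frame(asv_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pileups ----------------------------------------------------------------

.pileup_states <- c("A", "C", "G", "T", "del")

#' Construct a pileup table
#'
#' @param reference_id Reference sequence label.
#' @param pos Integer vector of 1-based reference positions, strictly
#'   increasing.
#' @param counts Matrix with columns `A`, `C`, `G`, `T`, `del`.
#' @return Object of class `pileup_table` (a data.frame with columns
#'   `pos`, `A`, `C`, `G`, `T`, `del`, `depth` and attribute
#'   `reference_id`).
#' @export
pileup_table <- function(reference_id, pos, counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(colnames(counts), .pileup_states) ||
              all(.pileup_states %in% colnames(counts)))
  counts <- counts[, .pileup_states, drop = FALSE]
  if (length(pos) && any(diff(pos) <= 0L)) {
    stop("pileup positions not strictly increasing at row ",
         which(diff(pos) <= 0L)[1L] + 1L)
  }
  if (any(counts < 0)) stop("negative pileup count")
  df <- data.frame(pos = as.integer(pos), counts, check.names = FALSE)
  df$depth <- as.integer(rowSums(counts))
  attr(df, "reference_id") <- reference_id
  class(df) <- c("pileup_table", "data.frame")
  df
}

#' Read a pileup TSV
#'
#' In-repo dialect: columns `ref`, `pos`, `A`, `C`, `G`, `T`, `del`, plus an
#' optional `depth` column which, when present, must equal the sum of the
#' five state counts at every row.
#'
#' @param path Path to the pileup TSV.
#' @return A `pileup_table`. An empty file (header only, or no rows) yields
#'   an empty table.
#' @export
read_pileup <- function(path) {
  first <- tryCatch(readLines(path, n = 50L), error = function(e) character())
  first <- first[!startsWith(first, "#") & nzchar(first)]
  if (!length(first)) {
    return(pileup_table("", integer(), matrix(integer(), 0, 5,
                                              dimnames = list(NULL, .pileup_states))))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  needed <- c("ref", "pos", .pileup_states)
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("pileup missing column(s): ",
                            paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    return(pileup_table("", integer(), matrix(integer(), 0, 5,
                                              dimnames = list(NULL, .pileup_states))))
  }
  if (length(unique(df$ref)) > 1L) {
    stop("pileup contains multiple references: ",
         paste(unique(df$ref), collapse = ", "))
  }
  cm <- as.matrix(df[, .pileup_states])
  if ("depth" %in% names(df)) {
    bad <- which(df$depth != rowSums(cm))
    if (length(bad)) stop("pileup depth mismatch at pos ", df$pos[bad[1L]])
  }
  pileup_table(df$ref[1L], df$pos, cm)
}

#' Write a pileup TSV
#'
#' @param pileup A `pileup_table`.
#' @param path Output path.
#' @export
write_pileup <- function(pileup, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ampdiv ", .ampdiv_version(),
                    " pileup; positions 1-based"), con)
  df <- data.frame(ref = attr(pileup, "reference_id"),
                   as.data.frame(unclass(pileup)), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tally a pileup from a SAM file
#'
#' Per-reference-position base frequencies from an alignment: primary,
#' non-duplicate, non-supplementary reads only (configurable). Deletions
#' spanning a position are counted in the `del` state; insertions have no
#' reference column and are ignored.
#'
#' @param sam_path Path to a SAM file (with header).
#' @param reference_id Reference to tally; defaults to the single reference
#'   present.
#' @param min_mapq Minimum mapping quality (default 0; the upstream read
#'   filters are deliberately configurable).
#' @param include_secondary,include_duplicates Read-filter switches.
#' @return A `pileup_table`.
#' @export
pileup_from_sam <- function(sam_path, reference_id = NULL, min_mapq = 0L,
                            include_secondary = FALSE,
                            include_duplicates = FALSE) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  flags <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = if (include_secondary) NA else FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE,
    isSupplementaryAlignment = FALSE, isUnmappedQuery = FALSE)
  pp <- Rsamtools::PileupParam(max_depth = 1000000L, min_base_quality = 0L,
                               min_mapq = as.integer(min_mapq),
                               min_nucleotide_depth = 0L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = TRUE,
                               include_insertions = FALSE)
  res <- Rsamtools::pileup(bam, scanBamParam = Rsamtools::ScanBamParam(flag = flags),
                           pileupParam = pp)
  if (!is.null(reference_id)) res <- res[res$seqnames == reference_id, ]
  refs <- unique(as.character(res$seqnames))
  if (length(refs) > 1L) stop("SAM covers multiple references; pass reference_id")
  pos <- sort(unique(res$pos))
  cm <- matrix(0L, length(pos), 5L, dimnames = list(NULL, .pileup_states))
  nuc <- as.character(res$nucleotide)
  nuc[nuc == "-"] <- "del"
  keep <- nuc %in% .pileup_states
  idx <- cbind(match(res$pos[keep], pos), match(nuc[keep], .pileup_states))
  for (i in seq_len(nrow(idx))) {
    cm[idx[i, 1L], idx[i, 2L]] <- cm[idx[i, 1L], idx[i, 2L]] + res$count[keep][i]
  }
  pileup_table(if (length(refs)) refs else "", pos, cm)
}

# ---- matrices and trees -----------------------------------------------------

#' Write a dissimilarity matrix as labelled TSV
#'
#' @param matrix A `dissim_matrix` (see [bray_curtis_matrix()]) or a plain
#'   labelled square matrix.
#' @param path Output path.
#' @export
write_matrix <- function(matrix, path) {
  m <- if (inherits(matrix, "dissim_matrix")) matrix$values else matrix
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12) stop("matrix not symmetric")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ampdiv ", .ampdiv_version(), " dissimilarity matrix"),
             con)
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], sprintf("%.15g", m[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a labelled square matrix written by [write_matrix()]
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a dendrogram as Newick
#'
#' Branch lengths follow the standard ultrametric convention for
#' agglomerative trees: leaf-to-root depth equals half the top merge height,
#' so that cophenetic path lengths reproduce merge heights (a two-leaf tree
#' merged at height h is written `(A:h/2,B:h/2);`).
#'
#' @param tree An `hclust` object (see [ward_d2_linkage()]).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
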