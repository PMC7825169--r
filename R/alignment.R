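## Pairwise global / semi-global alignment, identity, degenerate-primer
## matching, reference-anchored multiple alignment, and 16S/ITS/23S region
## partitioning. The affine-gap dynamic program is Biostrings'
## pairwiseAlignment; identity semantics, terminal-gap handling and all
## higher-level constructions are defined here.

#' Alignment scoring scheme
#'
#' Defaults: match +2, mismatch -3, gap open -5, gap extend -2 (a gap of
#' length L costs 5 + 2L). Identity of near-identical amplicons is
#' insensitive to the exact scheme; all values are configurable.
#'
#' @param match,mismatch Substitution scores (mismatch negative).
#' @param gap_open,gap_extend Positive gap costs.
#' @return A scoring list used by the alignment functions.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                          gap_extend = 2L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       submat = Biostrings::nucleotideSubstitutionMatrix(
         match = match, mismatch = mismatch, baseOnly = TRUE))
}

.check_dna <- function(x, what = "sequence") {
  if (!length(x) || any(!nzchar(x))) stop("empty ", what)
  if (any(grepl("[^ACGT]", x))) stop(what, " contains non-ACGT letters")
  invisible(x)
}

# column statistics of a gapped pair of equal-length strings
.aln_stats <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(aligned_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(a) == length(b))
  gap <- a == "-" | b == "-"
  lead <- if (gap[1L]) which.min(gap) - 1L else 0L
  if (all(gap)) lead <- length(gap)
  trail <- if (length(gap) && gap[length(gap)] && lead < length(gap)) {
    rg <- rev(gap)
    which.min(rg) - 1L
  } else 0L
  list(
    matches = sum(a == b & !gap),
    mismatches = sum(a != b & !gap),
    gap_columns = sum(gap),
    internal_gap_columns = sum(gap) - lead - trail,
    terminal_lead = lead, terminal_trail = trail,
    columns = length(a))
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Terminal gaps are penalized (true global mode). The result records the
#' gapped strings, the optimal score and the column tallies used by
#' [pairwise_identity()].
#'
#' @param a,b DNA strings over ACGT.
#' @param scoring Scoring scheme from [align_scoring()].
#' @return Object of class `alignment_result`.
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  .check_dna(a); .check_dna(b)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = scoring$submat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  st <- .aln_stats(aligned_a, aligned_b)
  structure(c(list(aligned_a = unname(aligned_a),
                   aligned_b = unname(aligned_b),
                   score = Biostrings::score(pa)), st),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment: %d columns, %d matches, %d mismatches, %d gap columns, score %g\n",
    x$columns, x$matches, x$mismatches, x$gap_columns, x$score))
  invisible(x)
}

#' Pairwise identity of an alignment
#'
#' Identity = matching columns / alignment columns excluding terminal-gap
#' columns; internal gap columns count against identity. This is the
#' default identity semantics of greedy centroid clustering tools.
#'
#' @param aln An `alignment_result` from [global_align()].
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(aln) {
  stopifnot(inherits(aln, "alignment_result"))
  denom <- aln$columns - aln$terminal_lead - aln$terminal_trail
  if (denom <= 0L) stop("alignment has no non-terminal columns")
  aln$matches / denom
}

# Identity of one query against many references, with exact fast paths:
# (i) byte-identical -> 1;
# (ii) equal length and Hamming mismatch count m small enough that the
#      gapless score provably attains the affine-gap optimum
#      (match*(L-m)+mismatch*m >= match*(L-1) - 2*(open+extend)):
#      identity = (L-m)/L without running the DP.
# Everything else goes through the vectorized Biostrings DP.
.identity_many <- function(query, refs, scoring = align_scoring()) {
  n <- length(refs)
  out <- rep(NA_real_, n)
  if (!n) return(out)
  Lq <- nchar(query)
  hard <- logical(n)
  for (i in seq_len(n)) {
    r <- refs[[i]]
    if (identical(r, query)) { out[i] <- 1; next }
    if (nchar(r) == Lq) {
      qa <- charToRaw(query); ra <- charToRaw(r)
      m <- sum(qa != ra)
      gapless <- scoring$match * (Lq - m) + scoring$mismatch * m
      bound <- scoring$match * (Lq - 1L) -
        2 * (scoring$gap_open + scoring$gap_extend)
      if (gapless >= bound) { out[i] <- (Lq - m) / Lq; next }
    }
    hard[i] <- TRUE
  }
  if (any(hard)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(unlist(refs[hard])), query, type = "global",
      substitutionMatrix = scoring$submat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    sa <- as.character(Biostrings::alignedPattern(pa))
    sb <- as.character(Biostrings::alignedSubject(pa))
    idx <- which(hard)
    for (k in seq_along(idx)) {
      st <- .aln_stats(sa[k], sb[k])
      out[idx[k]] <- st$matches /
        (st$columns - st$terminal_lead - st$terminal_trail)
    }
  }
  out
}

# ---- degenerate primers -----------------------------------------------------

#' Match a degenerate (IUPAC) primer against a sequence
#'
#' A primer letter matches a sequence base when its IUPAC set contains the
#' base (`R` = \{A,G\} matches A or G; the sequence is read literally).
#'
#' @param seq DNA string over ACGT.
#' @param primer IUPAC string.
#' @param max_mismatch Maximum number of mismatching positions.
#' @param orientation `"forward"` to search the primer as given,
#'   `"revcomp"` to search its reverse complement.
#' @return Data.frame with 1-based `position` and `mismatches` per hit;
#'   zero rows when the primer is longer than the sequence.
#' @export
match_degenerate_primer <- function(seq, primer, max_mismatch = 0L,
                                    orientation = c("forward", "revcomp")) {
  orientation <- match.arg(orientation)
  .check_dna(seq)
  pr <- Biostrings::DNAString(primer)
  if (orientation == "revcomp") pr <- Biostrings::reverseComplement(pr)
  if (length(pr) > nchar(seq)) {
    return(data.frame(position = integer(), mismatches = integer()))
  }
  subj <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(pr, subj, max.mismatch = max_mismatch,
                                   with.indels = FALSE, fixed = "subject")
  starts <- Biostrings::start(hits)
  mm <- if (length(starts)) {
    Biostrings::neditStartingAt(pr, subj, starting.at = starts,
                                fixed = "subject")
  } else integer()
  data.frame(position = starts, mismatches = as.integer(mm))
}

# ---- anchored multiple alignment -------------------------------------------

#' Reference-anchored multiple alignment
#'
#' Each member is globally aligned to the reference independently; columns
#' are reference positions (the reference row carries no gaps). Member
#' bases falling into reference gaps (insertions) are kept as insertion
#' records keyed by the reference position they follow (0 = before the
#' first position).
#'
#' @param reference Reference DNA string (typically the most abundant ASV).
#' @param members Named character vector of member sequences (may include
#'   the reference itself).
#' @param scoring Scoring scheme.
#' @param warn_identity Emit a warning when any member's identity to the
#'   reference falls below this value (default 0.9).
#' @return Object of class `anchored_msa`: `reference_id`, `reference`,
#'   `member_ids`, `states` (member x reference-position character matrix
#'   over A/C/G/T/-), and `insertions` (data.frame member, after_pos, seq).
#' @export
anchored_msa <- function(reference, members, scoring = align_scoring(),
                         warn_identity = 0.9) {
  .check_dna(reference, "reference")
  if (is.null(names(members)) && length(members)) {
    names(members) <- paste0("member_", seq_along(members))
  }
  ref_id <- attr(reference, "id") %||% "reference"
  L <- nchar(reference)
  states <- matrix("-", nrow = length(members), ncol = L,
                   dimnames = list(names(members), NULL))
  ins <- list()
  for (i in seq_along(members)) {
    mem <- members[[i]]
    if (identical(mem, reference)) {
      states[i, ] <- strsplit(reference, "")[[1L]]
      next
    }
    aln <- global_align(mem, reference, scoring)
    if (pairwise_identity(aln) < warn_identity) {
      warning("member '", names(members)[i], "' identity to reference below ",
              warn_identity)
    }
    a <- strsplit(aln$aligned_a, "")[[1L]]  # member
    b <- strsplit(aln$aligned_b, "")[[1L]]  # reference
    refpos <- cumsum(b != "-")
    is_ref <- b != "-"
    states[i, refpos[is_ref]] <- a[is_ref]
    if (any(!is_ref)) {
      gcols <- which(!is_ref)
      runs <- split(gcols, cumsum(c(1L, diff(gcols) != 1L)))
      for (run in runs) {
        insseq <- paste(a[run], collapse = "")
        insseq <- gsub("-", "", insseq, fixed = TRUE)
        if (nzchar(insseq)) {
          ins[[length(ins) + 1L]] <- data.frame(
            member = names(members)[i],
            after_pos = if (run[1L] == 1L) 0L else refpos[run[1L] - 1L],
            seq = insseq)
        }
      }
    }
  }
  insertions <- if (length(ins)) do.call(rbind, ins) else
    data.frame(member = character(), after_pos = integer(), seq = character())
  structure(list(reference_id = ref_id, reference = reference,
                 member_ids = names(members), states = states,
                 insertions = insertions),
            class = "anchored_msa")
}

#' @export
print.anchored_msa <- function(x, ...) {
  nvar <- sum(apply(x$states, 2L, function(col) length(unique(col)) > 1L))
  cat(sprintf("anchored MSA: %d members x %d reference positions, %d variant columns, %d insertion records\n",
              nrow(x$states), ncol(x$states), nvar, nrow(x$insertions)))
  invisible(x)
}

# ---- region partitioning ----------------------------------------------------

#' Bundled synthetic region references
#'
#' The package ships a synthetic ~1450-nt 16S reference and a synthetic
#' ~110-nt 23S 5'-fragment reference (user-replaceable) used to partition
#' amplicons into regions. They are synthetic stand-ins generated under a
#' fixed seed, with primer-compatible ends.
#'
#' @return List with elements `ssu` and `lsu` (character sequences).
#' @export
ampdiv_references <- function() {
  ssu <- read_fasta(system.file("extdata", "ssu_reference_synthetic.fasta",
                                package = "ampdiv", mustWork = TRUE))
  lsu <- read_fasta(system.file("extdata", "lsu_fragment_synthetic.fasta",
                                package = "ampdiv", mustWork = TRUE))
  list(ssu = unname(ssu[[1L]]), lsu = unname(lsu[[1L]]))
}

#' Partition an amplicon into 16S / ITS / 23S regions
#'
#' The 16S span is located by semi-global alignment of the 16S reference
#' (whole reference against a substring of the amplicon); the 23S span by
#' the same with the 23S 5'-fragment reference. Because a primer-trimmed
#' amplicon starts inside the 16S gene and ends inside the 23S gene, the
#' 16S region is extended to the amplicon start and the 23S region to the
#' amplicon end; the ITS is everything between. The three intervals tile
#' the amplicon exactly.
#'
#' @param seq Amplicon sequence.
#' @param ssu_reference,lsu_reference Region references; default bundled.
#' @param min_its Minimum ITS length (default 1); shorter or overlapping
#'   spans raise an error flagging a putative unlinked/aberrant operon.
#' @param scoring Scoring scheme.
#' @return Object of class `region_partition`: 1-based inclusive intervals
#'   `ssu`, `its`, `lsu`, plus `length`.
#' @export
partition_regions <- function(seq, ssu_reference = NULL, lsu_reference = NULL,
                              min_its = 1L, scoring = align_scoring()) {
  .check_dna(seq)
  if (is.null(ssu_reference) || is.null(lsu_reference)) {
    refs <- ampdiv_references()
    ssu_reference <- ssu_reference %||% refs$ssu
    lsu_reference <- lsu_reference %||% refs$lsu
  }
  L <- nchar(seq)
  if (L < 0.8 * nchar(ssu_reference)) {
    stop("amplicon shorter than 80% of the 16S reference (",
         L, " < 0.8 * ", nchar(ssu_reference), ")")
  }
  span <- function(ref) {
    pa <- Biostrings::pairwiseAlignment(
      ref, seq, type = "global-local", substitutionMatrix = scoring$submat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    s <- Biostrings::subject(pa)
    c(Biostrings::start(s), Biostrings::end(s))
  }
  ssu_span <- span(ssu_reference)
  lsu_span <- span(lsu_reference)
  ssu_end <- ssu_span[2L]
  lsu_start <- lsu_span[1L]
  if (lsu_start <= ssu_end) {
    stop("16S and 23S spans overlap (16S ends at ", ssu_end,
         ", 23S starts at ", lsu_start,
         "): putative unlinked or aberrant rRNA operon")
  }
  its_len <- lsu_start - ssu_end - 1L
  if (its_len < min_its) {
    stop("ITS shorter than ", min_its, " nt (", its_len,
         "): putative unlinked or aberrant rRNA operon")
  }
  structure(list(ssu = c(1L, ssu_end),
                 its = c(ssu_end + 1L, lsu_start - 1L),
                 lsu = c(lsu_start, L),
                 length = L),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region partition (%d nt): 16S %d-%d, ITS %d-%d, 23S %d-%d\n",
              x$length, x$ssu[1L], x$ssu[2L], x$its[1L], x$its[2L],
              x$lsu[1L], x$lsu[2L]))
  invisible(x)
}

#' Locate an absolute amplicon position within a region partition
#'
#' @param partition A `region_partition`.
#' @param pos 1-based absolute position.
#' @return List with `region` (`"SSU"`, `"ITS"` or `"LSU"`) and
#'   `region_pos` (1-based within the region).
#' @export
locate_position <- function(partition, pos) {
  stopifnot(inherits(partition, "region_partition"),
            pos >= 1L, pos <= partition$length)
  if (pos <= partition$ssu[2L]) {
    list(region = "SSU", region_pos = pos)
  } else if (pos <= partition$its[2L]) {
    list(region = "ITS", region_pos = pos - partition$its[1L] + 1L)
  } else {
    list(region = "LSU", region_pos = pos - partition$lsu[1L] + 1L)
  }
}

#' Extract the 16S region of each amplicon
#'
#' Convenience wrapper: partitions every sequence and returns the 16S
#' substring (used as clustering input).
#'
#' @param seqs Named character vector of amplicons.
#' @param ... Passed to [partition_regions()].
#' @return List with `regions` (named character vector of 16S substrings)
#'   and `partitions` (named list of `region_partition`s).
#' @export
extract_ssu_regions <- function(seqs, ...) {
  parts <- lapply(seqs, partition_regions, ...)
  regions <- vapply(seq_along(seqs), function(i) {
    p <- parts[[i]]
    substring(seqs[[i]], p$ssu[1L], p$ssu[2L])
  }, character(1))
  names(regions) <- names(seqs)
  names(parts) <- names(seqs)
  list(regions = regions, partitions = parts)
}
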