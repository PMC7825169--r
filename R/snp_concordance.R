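## Validation of amplicon-derived variants against metagenomic pileups:
## expected variant sites from within-lineage ASVs, detected variants from
## per-position base counts, per-site concordance status, and base
## proportion comparison.

.snp_states <- c("A", "C", "G", "T", "gap")

#' Expected variant sites from a within-lineage MSA
#'
#' A reference column is expected-variable when at least two distinct
#' states (gap included) occur among the members. Expected state
#' proportions are weighted by member read abundance. ASV insertions
#' relative to the reference have no reference column and are not forced
#' into the site table (they remain in the MSA's insertion records).
#'
#' @param msa An `anchored_msa` whose reference is the most abundant ASV.
#' @param abundances Named numeric vector covering every MSA member.
#' @param partition Optional `region_partition` of the reference amplicon,
#'   used to label sites with region-relative positions.
#' @return Object of class `snp_sites`: list of sites, each with
#'   `position` (1-based on the reference), `region`, `region_pos`, and
#'   `expected_props` (named, sums to 1).
#' @export
expected_variant_sites <- function(msa, abundances, partition = NULL) {
  stopifnot(inherits(msa, "anchored_msa"))
  missing <- setdiff(msa$member_ids, names(abundances))
  if (length(missing)) stop("abundance missing for member: ", missing[1L])
  w <- abundances[msa$member_ids]
  w <- w / sum(w)
  sites <- list()
  for (j in seq_len(ncol(msa$states))) {
    col <- msa$states[, j]
    if (length(unique(col)) < 2L) next
    states <- ifelse(col == "-", "gap", col)
    props <- tapply(w, states, sum)
    props <- props[order(match(names(props), .snp_states))]
    loc <- if (!is.null(partition)) locate_position(partition, j)
    else list(region = NA_character_, region_pos = NA_integer_)
    sites[[length(sites) + 1L]] <- list(
      position = as.integer(j), region = loc$region,
      region_pos = loc$region_pos, expected_props = props)
  }
  structure(sites, class = "snp_sites")
}

#' @export
print.snp_sites <- function(x, ...) {
  cat(sprintf("%d expected variant site(s)\n", length(x)))
  invisible(x)
}

#' Detected variant sites from a pileup
#'
#' A position is detected-variable when, at depth >= `min_depth`, at least
#' two states each pass both thresholds (count >= `min_count` AND
#' frequency >= `min_freq`). Reported frequencies cover passing and
#' non-passing states alike, normalized by depth. The defaults (2 reads,
#' 1%, depth 10) suppress singleton sequencing errors while retaining rare
#' (sub-10%) variants.
#'
#' @param pileup A `pileup_table`.
#' @param min_count Minimum per-state read count (default 2).
#' @param min_freq Minimum per-state frequency (default 0.01).
#' @param min_depth Minimum depth for a position to be assessable
#'   (default 10); shallower positions are reported as uncovered.
#' @return Data.frame with `pos`, `depth`, `covered`, `variable`, and one
#'   frequency column per state (`A`, `C`, `G`, `T`, `gap`).
#' @export
detected_variant_sites <- function(pileup, min_count = 2L, min_freq = 0.01,
                                   min_depth = 10L) {
  stopifnot(inherits(pileup, "pileup_table"))
  cm <- as.matrix(pileup[, c("A", "C", "G", "T", "del")])
  colnames(cm) <- .snp_states
  depth <- pileup$depth
  covered <- depth >= min_depth
  freqs <- cm / ifelse(depth > 0, depth, 1)
  pass <- cm >= min_count & freqs >= min_freq
  variable <- covered & rowSums(pass) >= 2L
  out <- data.frame(pos = pileup$pos, depth = depth, covered = covered,
                    variable = variable, freqs, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify ASV-expected vs pileup-detected variant sites
#'
#' The site universe is the union of expected-variable and
#' detected-variable positions; each site is `both`, `expected_only` or
#' `detected_only`, and the summary proportions partition the union.
#'
#' @param expected `snp_sites` from [expected_variant_sites()].
#' @param detected Data.frame from [detected_variant_sites()].
#' @return Object of class `concordance_summary`: `n_sites`,
#'   `proportions` (named, sums to 1 when sites exist), `sites` (list with
#'   per-site `position`, `region`, `region_pos`, `status`,
#'   `expected_props`, `detected_freqs`).
#' @export
classify_concordance <- function(expected, detected) {
  stopifnot(inherits(expected, "snp_sites"))
  exp_pos <- vapply(expected, function(s) as.integer(s$position), integer(1))
  det_var <- detected$pos[detected$variable]
  universe <- sort(union(exp_pos, det_var))
  det_row <- match(universe, detected$pos)
  sites <- lapply(seq_along(universe), function(i) {
    p <- universe[i]
    is_exp <- p %in% exp_pos
    is_det <- p %in% det_var
    e <- if (is_exp) expected[[which(exp_pos == p)]] else NULL
    freqs <- if (!is.na(det_row[i])) {
      unlist(detected[det_row[i], .snp_states])
    } else NULL
    list(position = p,
         region = if (is_exp) e$region else NA_character_,
         region_pos = if (is_exp) e$region_pos else NA_integer_,
         status = if (is_exp && is_det) "both"
         else if (is_exp) "expected_only" else "detected_only",
         expected_props = if (is_exp) e$expected_props else NULL,
         detected_freqs = freqs)
  })
  status <- vapply(sites, `[[`, character(1), "status")
  props <- c(both = mean(status == "both"),
             expected_only = mean(status == "expected_only"),
             detected_only = mean(status == "detected_only"))
  if (!length(universe)) props[] <- 0
  structure(list(n_sites = length(universe), proportions = props,
                 sites = sites),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("SNP concordance over %d site(s): both %.1f%%, expected-only %.1f%%, detected-only %.1f%%\n",
              x$n_sites, 100 * x$proportions[["both"]],
              100 * x$proportions[["expected_only"]],
              100 * x$proportions[["detected_only"]]))
  invisible(x)
}

#' Per-site concordance table
#'
#' Flat rendering of a concordance summary, one row per site with major
#' expected/detected states and proportions (mirrors a per-site report).
#'
#' @param summary A `concordance_summary`.
#' @return Data.frame.
#' @export
concordance_table <- function(summary) {
  stopifnot(inherits(summary, "concordance_summary"))
  do.call(rbind, lapply(summary$sites, function(s) {
    ep <- s$expected_props
    df <- s$detected_freqs
    data.frame(
      position = s$position, region = s$region, region_pos = s$region_pos,
      status = s$status,
      expected_major = if (!is.null(ep)) names(ep)[which.max(ep)] else NA,
      expected_major_pct = if (!is.null(ep)) 100 * max(ep) else NA,
      detected_major = if (!is.null(df)) names(df)[which.max(df)] else NA,
      detected_major_pct = if (!is.null(df)) 100 * max(df) else NA)
  }))
}

#' Compare expected vs detected base proportions at a concordant site
#'
#' State-aligned proportion pairs plus the total-variation distance
#' between the two distributions (half the L1 distance).
#'
#' @param site One element of a `concordance_summary`'s `sites` with
#'   status `"both"`.
#' @return List with `states`, `expected`, `detected`, `tv`.
#' @export
compare_major_props <- function(site) {
  if (is.null(site$status) || site$status != "both") {
    stop("base-proportion comparison requires a site with status 'both'")
  }
  states <- .snp_states
  e <- stats::setNames(numeric(length(states)), states)
  e[names(site$expected_props)] <- site$expected_props
  d <- stats::setNames(numeric(length(states)), states)
  d[names(site$detected_freqs)] <- site$detected_freqs
  keep <- e > 0 | d > 0
  list(states = states[keep], expected = unname(e[keep]),
       detected = unname(d[keep]), tv = 0.5 * sum(abs(e - d)))
}
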