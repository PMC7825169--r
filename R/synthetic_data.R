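## Ground-truthed simulator of biogeographically structured long-read
## amplicon communities and metagenomic pileups. Defaults emulate the
## study conditions the pipeline targets: 11 lineages more than ~6%
## diverged in 16S, 7-101 intra-lineage genotypes differing by a few
## ITS-biased substitutions and occasional 1-bp indels, three regions of
## lakes sampled in two water layers, and per-sample depths spread
## log-uniformly over 190-4515 reads.

#' Simulation configuration
#'
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   outputs.
#' @param n_lineages Number of lineage templates (default 11).
#' @param inter_lineage_divergence Minimum pairwise 16S divergence between
#'   templates (default 0.08).
#' @param genotypes_per_lineage Inclusive range of genotypes per lineage
#'   (default 7-101).
#' @param snps_per_genotype Inclusive range of substitutions per genotype
#'   (default 1-6).
#' @param its_bias Probability a substitution lands in the ITS
#'   (default 0.8); the remainder land in the 16S region.
#' @param indel_prob Probability a genotype additionally carries a 1-bp
#'   ITS indel (default 0.1).
#' @param regions Region names.
#' @param lakes_per_region Number of lakes per region (default 7/3/2,
#'   giving 24 samples over two layers).
#' @param dispersal Probability in \[0,1\] that a pool-external genotype
#'   leaks into a sample (0 = fully region-private genotype pools).
#' @param layer_overlap Relative abundance weight of a genotype in its
#'   non-preferred water layer (default 0.3; 1 = no layer structure).
#' @param dirichlet_alpha Symmetric Dirichlet concentration of the
#'   region-level genotype mean mixture (small = one dominant genotype).
#' @param sample_concentration Concentration of per-sample mixtures around
#'   the region/layer mean (large = samples within a pool look alike).
#' @param depth_range Per-sample read depth range, drawn log-uniformly
#'   (default 190-4515).
#' @param error_rate Per-base error rate for pileup simulation.
#' @param its_len_range ITS length range per lineage (default 250-500 nt).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_lineages = 11L,
                       inter_lineage_divergence = 0.08,
                       genotypes_per_lineage = c(7L, 101L),
                       snps_per_genotype = c(1L, 6L),
                       its_bias = 0.8,
                       indel_prob = 0.1,
                       regions = c("Honshu-Kyushu", "Hokkaido", "Europe"),
                       lakes_per_region = c(7L, 3L, 2L),
                       dispersal = 0.05,
                       layer_overlap = 0.3,
                       dirichlet_alpha = 0.3,
                       sample_concentration = 10,
                       depth_range = c(190L, 4515L),
                       error_rate = 0.002,
                       its_len_range = c(250L, 500L)) {
  cfg <- list(seed = as.integer(seed), n_lineages = as.integer(n_lineages),
              inter_lineage_divergence = inter_lineage_divergence,
              genotypes_per_lineage = as.integer(genotypes_per_lineage),
              snps_per_genotype = as.integer(snps_per_genotype),
              its_bias = its_bias, indel_prob = indel_prob,
              regions = regions,
              lakes_per_region = as.integer(lakes_per_region),
              dispersal = dispersal, layer_overlap = layer_overlap,
              dirichlet_alpha = dirichlet_alpha,
              sample_concentration = sample_concentration,
              depth_range = as.integer(depth_range),
              error_rate = error_rate,
              its_len_range = as.integer(its_len_range))
  with(cfg, {
    stopifnot(n_lineages >= 1L,
              inter_lineage_divergence > 0, inter_lineage_divergence < 1,
              length(genotypes_per_lineage) == 2L,
              genotypes_per_lineage[1L] <= genotypes_per_lineage[2L],
              genotypes_per_lineage[1L] >= 1L,
              snps_per_genotype[1L] <= snps_per_genotype[2L],
              its_bias >= 0, its_bias <= 1,
              indel_prob >= 0, indel_prob <= 1,
              length(regions) == length(lakes_per_region),
              dispersal >= 0, dispersal <= 1,
              layer_overlap > 0, dirichlet_alpha > 0,
              depth_range[1L] <= depth_range[2L], depth_range[1L] >= 1L,
              error_rate >= 0, error_rate < 1,
              its_len_range[1L] <= its_len_range[2L])
  })
  structure(cfg, class = "sim_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.substitute_at <- function(chars, pos) {
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  chars
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate lineage amplicon templates
#'
#' Each template is a full amplicon: a 16S region derived from the bundled
#' reference with lineage-private substitutions (pairwise 16S divergence
#' at least `inter_lineage_divergence`), a lineage-specific random ITS,
#' and the bundled 23S 5'-fragment. Region boundaries are recorded.
#'
#' @param cfg A `sim_config`.
#' @return List with `templates` (named character), `boundaries` (named
#'   list of `region_partition`-shaped interval lists), and
#'   `ssu_positions_mutated`.
#' @export
simulate_templates <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  refs <- ampdiv_references()
  L <- nchar(refs$ssu)
  r <- ceiling(cfg$inter_lineage_divergence * L / 2)
  protected <- 20L  # keep the primer-compatible 16S start intact
  avail <- (protected + 1L):L
  if (cfg$n_lineages * r > length(avail)) {
    stop("inter-lineage divergence ", cfg$inter_lineage_divergence,
         " infeasible for ", cfg$n_lineages, " lineages on a ", L,
         "-nt 16S reference")
  }
  all_pos <- sample(avail, cfg$n_lineages * r)
  ssu_chars <- strsplit(refs$ssu, "")[[1L]]
  templates <- character(cfg$n_lineages)
  boundaries <- vector("list", cfg$n_lineages)
  mutated <- vector("list", cfg$n_lineages)
  for (l in seq_len(cfg$n_lineages)) {
    pos <- all_pos[((l - 1L) * r + 1L):(l * r)]
    ssu_l <- paste(.substitute_at(ssu_chars, pos), collapse = "")
    its_len <- sample(seq(cfg$its_len_range[1L], cfg$its_len_range[2L]), 1L)
    its_l <- .rand_dna(its_len)
    lsu_l <- refs$lsu
    templates[l] <- paste0(ssu_l, its_l, lsu_l)
    total <- nchar(templates[l])
    boundaries[[l]] <- list(ssu = c(1L, L),
                            its = c(L + 1L, L + its_len),
                            lsu = c(L + its_len + 1L, total),
                            length = total)
    class(boundaries[[l]]) <- "region_partition"
    mutated[[l]] <- sort(pos)
  }
  ids <- sprintf("lineage_%02d", seq_len(cfg$n_lineages))
  names(templates) <- ids
  names(boundaries) <- ids
  names(mutated) <- ids
  list(templates = templates, boundaries = boundaries,
       ssu_positions_mutated = mutated)
}

#' Simulate intra-lineage genotypes from a template
#'
#' Each genotype carries k substitutions (k drawn from
#' `snps_per_genotype`), placed in the ITS with probability `its_bias`
#' and in the 16S otherwise, plus an optional 1-bp ITS indel with
#' probability `indel_prob`. All genotypes are distinct from the template
#' and from each other.
#'
#' @param template Template amplicon string.
#' @param boundaries The template's region intervals (from
#'   [simulate_templates()]).
#' @param cfg A `sim_config`.
#' @param n Number of genotypes.
#' @param seed RNG seed (default `cfg$seed`).
#' @param id_prefix Genotype id prefix.
#' @return List with `seqs` (named character) and `mutations` (named list
#'   of data.frames pos, region, type, from, to).
#' @export
simulate_genotypes <- function(template, boundaries, cfg, n,
                               seed = cfg$seed, id_prefix = "g") {
  stopifnot(inherits(cfg, "sim_config"), n >= 1L)
  set.seed(seed)
  its <- boundaries$its
  ssu <- boundaries$ssu
  seen <- character()
  seqs <- character(n)
  muts <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in 1:100) {
      chars <- strsplit(template, "")[[1L]]
      k <- sample(seq(cfg$snps_per_genotype[1L], cfg$snps_per_genotype[2L]), 1L)
      in_its <- stats::runif(k) < cfg$its_bias
      pos <- integer(k)
      if (any(in_its)) pos[in_its] <- sample(its[1L]:its[2L], sum(in_its))
      if (any(!in_its)) pos[!in_its] <- sample((ssu[1L] + 20L):ssu[2L],
                                               sum(!in_its))
      from <- chars[pos]
      chars <- .substitute_at(chars, pos)
      mut <- data.frame(pos = pos,
                        region = ifelse(in_its, "ITS", "SSU"),
                        type = "substitution", from = from, to = chars[pos])
      if (stats::runif(1) < cfg$indel_prob) {
        ip <- sample(its[1L]:(its[2L] - 1L), 1L)
        if (stats::runif(1) < 0.5) {
          mut <- rbind(mut, data.frame(pos = ip, region = "ITS",
                                       type = "deletion", from = chars[ip],
                                       to = ""))
          chars <- chars[-ip]
        } else {
          base <- sample(c("A", "C", "G", "T"), 1L)
          mut <- rbind(mut, data.frame(pos = ip, region = "ITS",
                                       type = "insertion", from = "",
                                       to = base))
          chars <- append(chars, base, after = ip)
        }
      }
      s <- paste(chars, collapse = "")
      if (!identical(s, template) && !(s %in% seen)) {
        seqs[i] <- s
        muts[[i]] <- mut[order(mut$pos), ]
        seen <- c(seen, s)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not generate ", n,
                  " distinct genotypes; sequence space exhausted")
  }
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  names(seqs) <- ids
  names(muts) <- ids
  list(seqs = seqs, mutations = muts)
}

#' Simulate a biogeographically structured amplicon community
#'
#' Every genotype belongs to one region's pool and prefers one water
#' layer. For each lineage and region a mean genotype mixture is drawn
#' from a symmetric Dirichlet(`dirichlet_alpha`); a sample's mixture is a
#' Dirichlet resample (concentration `sample_concentration`) of that mean
#' tilted towards genotypes preferring the sample's layer, with
#' pool-external genotypes leaking in with probability `dispersal`.
#' Per-sample read counts are multinomial at a log-uniform depth. Only
#' genotypes observed with at least one read enter the emitted ASV table;
#' the full truth is returned alongside.
#'
#' @param cfg A `sim_config`.
#' @return List with `table` (an `asv_table` with sequences), `truth`
#'   (templates, boundaries, genotypes, mutations, lineage/region/layer
#'   assignments, per-sample mixtures and depths) and `config`.
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tpl <- simulate_templates(cfg)
  set.seed(cfg$seed + 2L)
  nreg <- length(cfg$regions)

  # genotypes
  geno_seqs <- character()
  geno_lineage <- character()
  geno_muts <- list()
  for (l in seq_len(cfg$n_lineages)) {
    lid <- names(tpl$templates)[l]
    ng <- sample(seq(cfg$genotypes_per_lineage[1L],
                     cfg$genotypes_per_lineage[2L]), 1L)
    g <- simulate_genotypes(tpl$templates[[l]], tpl$boundaries[[lid]], cfg,
                            n = ng, seed = cfg$seed + 100L + l,
                            id_prefix = paste0(lid, "_g"))
    geno_seqs <- c(geno_seqs, g$seqs)
    geno_lineage <- c(geno_lineage, rep(lid, ng))
    geno_muts <- c(geno_muts, g$mutations)
  }
  names(geno_lineage) <- names(geno_seqs)
  set.seed(cfg$seed + 3L)
  geno_region <- sample(cfg$regions, length(geno_seqs), replace = TRUE,
                        prob = cfg$lakes_per_region / sum(cfg$lakes_per_region))
  geno_layer <- sample(.ampdiv_layers, length(geno_seqs), replace = TRUE)
  names(geno_region) <- names(geno_seqs)
  names(geno_layer) <- names(geno_seqs)

  # samples: lakes x layers
  lake_codes <- character()
  lake_region <- character()
  for (r in seq_len(nreg)) {
    idx <- length(lake_codes) + seq_len(cfg$lakes_per_region[r])
    codes <- paste0(LETTERS[(idx - 1L) %/% 26L + 1L],
                    LETTERS[(idx - 1L) %% 26L + 1L])
    lake_codes <- c(lake_codes, codes)
    lake_region <- c(lake_region, rep(cfg$regions[r], length(codes)))
  }
  metadata <- data.frame(
    sample_id = paste0(rep(lake_codes, each = 2L), c("e", "h")),
    lake_code = rep(lake_codes, each = 2L),
    region = rep(lake_region, each = 2L),
    layer = rep(.ampdiv_layers, times = length(lake_codes)),
    year = ifelse(rep(lake_region, each = 2L) == "Europe", 2017L, 2015L))

  # lineage prominence: global mean, per-sample resample with layer tilt
  lineage_ids <- names(tpl$templates)
  lineage_layer <- sample(.ampdiv_layers, cfg$n_lineages, replace = TRUE)
  names(lineage_layer) <- lineage_ids
  lineage_mean <- .rdirichlet(rep(0.8, cfg$n_lineages))
  names(lineage_mean) <- lineage_ids

  # region-level mean genotype mixture per lineage
  region_mean <- list()
  for (l in lineage_ids) {
    region_mean[[l]] <- list()
    for (r in cfg$regions) {
      pool <- names(geno_seqs)[geno_lineage == l & geno_region == r]
      region_mean[[l]][[r]] <- if (length(pool)) {
        stats::setNames(.rdirichlet(rep(cfg$dirichlet_alpha, length(pool))),
                        pool)
      } else stats::setNames(numeric(), character())
    }
  }

  depths <- as.integer(round(exp(stats::runif(
    nrow(metadata), log(cfg$depth_range[1L]), log(cfg$depth_range[2L])))))
  names(depths) <- metadata$sample_id

  counts <- matrix(0L, nrow = length(geno_seqs), ncol = nrow(metadata),
                   dimnames = list(names(geno_seqs), metadata$sample_id))
  mixtures <- list()
  for (s in seq_len(nrow(metadata))) {
    sm <- metadata[s, ]
    # per-lineage genotype mixture available to this sample
    geno_mix <- list()
    for (l in lineage_ids) {
      mean_in <- region_mean[[l]][[sm$region]]
      w <- stats::setNames(numeric(0), character(0))
      if (length(mean_in)) {
        tilt <- mean_in * ifelse(geno_layer[names(mean_in)] == sm$layer, 1,
                                 cfg$layer_overlap)
        w <- tilt / sum(tilt)
      }
      ext <- names(geno_seqs)[geno_lineage == l & geno_region != sm$region]
      if (length(ext) && cfg$dispersal > 0) {
        leak <- ext[stats::runif(length(ext)) < cfg$dispersal]
        if (length(leak)) {
          wl <- stats::rgamma(length(leak), shape = cfg$dirichlet_alpha)
          w <- c(w, stats::setNames(wl, leak))
          w <- w / sum(w)
        }
      }
      if (length(w)) {
        mix <- .rdirichlet(cfg$sample_concentration * w * length(w))
        names(mix) <- names(w)
        geno_mix[[l]] <- mix
      }
    }
    # lineage prominence, restricted to lineages the sample can draw from
    avail <- names(geno_mix)
    ltilt <- lineage_mean[avail] * ifelse(lineage_layer[avail] == sm$layer, 1,
                                          cfg$layer_overlap)
    lw <- .rdirichlet(cfg$sample_concentration * ltilt / sum(ltilt) *
                        length(avail))
    names(lw) <- avail
    lcounts <- stats::rmultinom(1L, depths[s], lw)[, 1L]
    sample_mix <- stats::setNames(numeric(length(geno_seqs)),
                                  names(geno_seqs))
    for (l in avail) {
      mix <- geno_mix[[l]]
      sample_mix[names(mix)] <- sample_mix[names(mix)] + lw[l] * mix
      if (lcounts[l] == 0L) next
      gcounts <- stats::rmultinom(1L, lcounts[l], mix)[, 1L]
      counts[names(gcounts), s] <- counts[names(gcounts), s] + gcounts
    }
    mixtures[[metadata$sample_id[s]]] <- sample_mix / sum(sample_mix)
  }

  observed <- rowSums(counts) > 0L
  tab <- asv_table(counts[observed, , drop = FALSE], metadata,
                   sequences = geno_seqs[observed])
  truth <- list(templates = tpl$templates, boundaries = tpl$boundaries,
                ssu_positions_mutated = tpl$ssu_positions_mutated,
                genotypes = geno_seqs, mutations = geno_muts,
                lineage = geno_lineage, region = geno_region,
                layer_preference = geno_layer,
                lineage_layer = lineage_layer,
                mixtures = mixtures, depths = depths)
  list(table = tab, truth = truth, config = cfg)
}

#' Simulate a metagenomic pileup from a genotype mixture
#'
#' At every reference position, `depth` reads are drawn: a genotype is
#' chosen from the mixture, its state at the position (base or deletion,
#' via the reference-anchored MSA) is emitted, and bases are flipped
#' uniformly to another base with probability `error_rate`. Deletions are
#' passed through as `del` counts and are not subject to base error.
#'
#' @param true_mixture Named fractions over genotypes (sums to 1); the
#'   most abundant genotype anchors the reference coordinates.
#' @param genotypes Named character vector covering the mixture.
#' @param depth Read depth per position.
#' @param error_rate Per-base error probability.
#' @param seed RNG seed.
#' @return A `pileup_table` on the reference genotype's coordinates.
#' @export
simulate_pileup <- function(true_mixture, genotypes, depth,
                            error_rate = 0, seed = 1L) {
  stopifnot(abs(sum(true_mixture) - 1) < 1e-8,
            all(names(true_mixture) %in% names(genotypes)))
  set.seed(seed)
  genotypes <- genotypes[names(true_mixture)]
  ref_id <- names(true_mixture)[which.max(true_mixture)]
  msa <- anchored_msa(genotypes[[ref_id]], genotypes, warn_identity = 0)
  L <- ncol(msa$states)
  cm <- matrix(0L, L, 5L, dimnames = list(NULL, .pileup_states))
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(L)) {
    gcounts <- stats::rmultinom(1L, depth, true_mixture)[, 1L]
    states <- msa$states[, j]
    for (st in .pileup_states) {
      sel <- if (st == "del") states == "-" else states == st
      cm[j, st] <- sum(gcounts[sel])
    }
    if (error_rate > 0) {
      for (b in bases) {
        n_err <- stats::rbinom(1L, cm[j, b], error_rate)
        if (n_err > 0L) {
          cm[j, b] <- cm[j, b] - n_err
          to <- stats::rmultinom(1L, n_err, rep(1 / 3, 3L))[, 1L]
          cm[j, setdiff(bases, b)] <- cm[j, setdiff(bases, b)] + to
        }
      }
    }
  }
  pileup_table(ref_id, seq_len(L), cm)
}
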