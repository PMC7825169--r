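# tests use deliberately small configurations; the generator's defaults
# encode the full-scale study conditions
small_cfg <- function(seed = 1, depth_range = c(200, 1000), ...) {
  sim_config(seed = seed, n_lineages = 3, genotypes_per_lineage = c(4, 7),
             lakes_per_region = c(2, 2, 2), depth_range = depth_range, ...)
}

test_that("templates respect length bounds, divergence and determinism", {
  cfg <- small_cfg()
  tpl <- simulate_templates(cfg)
  expect_length(tpl$templates, 3)
  lens <- nchar(tpl$templates)
  expect_true(all(lens >= 1800 & lens <= 2100))
  # pairwise 16S identity at most 1 - inter_lineage_divergence
  ssu <- vapply(seq_along(tpl$templates), function(i) {
    b <- tpl$boundaries[[i]]
    substr(tpl$templates[[i]], b$ssu[1], b$ssu[2])
  }, character(1))
  for (i in 1:2) for (j in (i + 1):3) {
    id <- pairwise_identity(global_align(ssu[i], ssu[j]))
    expect_lte(id, 1 - cfg$inter_lineage_divergence)
  }
  # same seed, same bytes
  expect_identical(simulate_templates(cfg)$templates, tpl$templates)
  # infeasible divergence errors
  expect_error(simulate_templates(sim_config(n_lineages = 50,
                                             inter_lineage_divergence = 0.5)),
               "infeasible")
})

test_that("genotypes carry the planted ITS-biased variants and stay distinct", {
  cfg <- small_cfg(its_bias = 1, indel_prob = 0)
  tpl <- simulate_templates(cfg)
  g <- simulate_genotypes(tpl$templates[[1]], tpl$boundaries[[1]], cfg,
                          n = 10, seed = 3)
  expect_length(unique(g$seqs), 10)
  expect_true(all(vapply(g$mutations, function(m) all(m$region == "ITS"),
                         logical(1))))
  # a genotype differing at exactly one ITS position shows one ITS variant
  # column through the anchored MSA
  one <- g$seqs[[which(vapply(g$mutations, nrow, integer(1)) == 1)[1]]]
  msa <- anchored_msa(tpl$templates[[1]],
                      c(t = tpl$templates[[1]], g = one), warn_identity = 0)
  vc <- which(apply(msa$states, 2, function(x) length(unique(x)) > 1))
  expect_length(vc, 1)
  part <- tpl$boundaries[[1]]
  expect_identical(locate_position(part, vc)$region, "ITS")

  # genotypes from distinct templates form distinct 97% clusters
  seqs <- unlist(lapply(1:3, function(l) {
    gs <- simulate_genotypes(tpl$templates[[l]], tpl$boundaries[[l]], cfg,
                             n = 4, seed = 10 + l,
                             id_prefix = paste0("l", l, "_g"))
    gs$seqs
  }))
  ext <- extract_ssu_regions(seqs)
  cs <- greedy_cluster(ext$regions, threshold = 0.97)
  expect_length(cs$centroids, 3)
})

test_that("community simulation is deterministic with valid tables and depths", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_community(cfg)
  expect_s3_class(sim$table, "asv_table")
  expect_identical(ncol(sim$table$counts), 12L)  # 6 lakes x 2 layers
  # column sums equal the drawn depths
  expect_identical(as.integer(colSums(sim$table$counts)),
                   unname(sim$truth$depths)[seq_len(ncol(sim$table$counts))])
  expect_true(all(sim$truth$depths >= 200 & sim$truth$depths <= 1000))
  # every emitted ASV traces to a genotype in the truth
  expect_true(all(rownames(sim$table$counts) %in% names(sim$truth$genotypes)))
  expect_identical(sim$table$sequences[rownames(sim$table$counts)],
                   sim$truth$genotypes[rownames(sim$table$counts)])
  # determinism
  sim2 <- simulate_community(cfg)
  expect_identical(sim2$table$counts, sim$table$counts)
  expect_identical(sim2$truth$genotypes, sim$truth$genotypes)
  # exact depth when the range is degenerate
  cfg100 <- small_cfg(seed = 2, depth_range = c(100, 100))
  expect_true(all(colSums(simulate_community(cfg100)$table$counts) == 100))
})

test_that("planted lineage labels are recovered by 97% clustering", {
  sim <- simulate_community(small_cfg(seed = 13))
  ext <- extract_ssu_regions(sim$table$sequences)
  cs <- greedy_cluster(ext$regions, rowSums(sim$table$counts),
                       threshold = 0.97)
  got <- setNames(cs$assignments$cluster_id, cs$assignments$asv_id)
  truth <- sim$truth$lineage[names(got)]
  expect_equal(ari(truth, got), 1)
})

test_that("single-genotype error-free pileup reproduces the sequence exactly", {
  set.seed(61)
  g <- c(solo = rand_dna(150))
  pl <- simulate_pileup(c(solo = 1), g, depth = 25, error_rate = 0, seed = 4)
  expect_identical(nrow(pl), 150L)
  expect_true(all(pl$depth == 25))
  chars <- strsplit(g[["solo"]], "")[[1]]
  for (b in c("A", "C", "G", "T")) {
    expect_identical(pl[[b]] == 25L, chars == b)
  }
})

test_that("pileup minor-allele frequency stays within binomial bounds", {
  set.seed(62)
  base <- rand_dna(200)
  genos <- c(a = base, b = mutate_seq(base, 2))
  pl <- simulate_pileup(c(a = 0.6, b = 0.4), genos, depth = 10000,
                        error_rate = 0, seed = 8)
  snp_rows <- which(apply(as.matrix(pl[, c("A", "C", "G", "T")]) > 0, 1, sum) > 1)
  expect_length(snp_rows, 2)
  for (r in snp_rows) {
    minor <- sort(as.integer(pl[r, c("A", "C", "G", "T")]), decreasing = TRUE)[2]
    expect_lt(abs(minor / 10000 - 0.4), 0.015)  # 3 sigma
  }
  # error injection: expected non-reference frequency near the error rate
  pl2 <- simulate_pileup(c(a = 1), c(a = base), depth = 20000,
                         error_rate = 0.005, seed = 9)
  nonref <- 1 - vapply(seq_len(nrow(pl2)), function(i) {
    ref_base <- strsplit(base, "")[[1]][i]
    pl2[[ref_base]][i] / pl2$depth[i]
  }, numeric(1))
  expect_lt(abs(mean(nonref) - 0.005), 0.001)
})

test_that("dominance rises as the genotype mixture concentrates", {
  top1_at <- function(alpha) {
    means <- numeric(3)
    for (s in 1:3) {
      sim <- simulate_community(small_cfg(seed = 100 + s,
                                          dirichlet_alpha = alpha))
      map <- sim$truth$lineage[rownames(sim$table$counts)]
      prof <- build_profiles(sim$table, map, min_reads = 20)
      tops <- vapply(prof, function(p) {
        if (length(p$included_samples) == 0) return(NA_real_)
        dominance_stats(p)$means[["top1"]]
      }, numeric(1))
      means[s] <- mean(tops, na.rm = TRUE)
    }
    mean(means)
  }
  expect_gt(top1_at(0.05), top1_at(5))
})
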