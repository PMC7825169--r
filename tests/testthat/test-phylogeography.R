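test_that("Bray-Curtis closed forms: identical 0, disjoint 1, half L1", {
  prof <- toy_profile(list(a = c(AAe = 50L, ABe = 100L),
                           b = c(AAe = 50L, ABe = 100L)))
  bc <- bray_curtis_matrix(prof)
  expect_equal(bc$values["AAe", "ABe"], 0)

  prof <- toy_profile(list(a = c(AAe = 50L, ABe = 0L),
                           b = c(AAe = 0L, ABe = 80L)))
  bc <- bray_curtis_matrix(prof)
  expect_equal(bc$values["AAe", "ABe"], 1)

  # proportions a = (1, 0), b = (0.5, 0.5) -> 0.5
  prof <- toy_profile(list(a = c(AAe = 40L, ABe = 30L),
                           b = c(AAe = 0L, ABe = 30L)))
  bc <- bray_curtis_matrix(prof, normalize = TRUE)
  expect_equal(bc$values["AAe", "ABe"], 0.5)
})

test_that("normalized Bray-Curtis equals half the L1 distance of proportions", {
  set.seed(41)
  for (i in 1:10) {
    counts <- lapply(1:6, function(a) {
      setNames(as.integer(rpois(4, 40)), c("AAe", "ABe", "ACe", "ADe"))
    })
    names(counts) <- paste0("asv", 1:6)
    prof <- toy_profile(counts, min_reads = 1L)
    bc <- bray_curtis_matrix(prof, normalize = TRUE)
    p <- t(prof$counts) / colSums(prof$counts)
    for (x in 1:3) for (y in (x + 1):4) {
      expect_equal(bc$values[x, y], 0.5 * sum(abs(p[x, ] - p[y, ])))
    }
    # bounded semimetric
    expect_true(all(bc$values >= 0 & bc$values <= 1))
    expect_equal(bc$values, t(bc$values))
    expect_true(all(diag(bc$values) == 0))
  }
})

test_that("matrix averaging masks unsupported pairs and records support", {
  mk <- function(samples, vals) {
    v <- matrix(0, length(samples), length(samples),
                dimnames = list(samples, samples))
    v[upper.tri(v)] <- vals
    v <- v + t(v)
    structure(list(sample_ids = samples, values = v,
                   support = (v * 0) + 1, source = "x"),
              class = "dissim_matrix")
  }
  m1 <- mk(c("a", "b"), 0.2)
  m2 <- mk(c("a", "b"), 0.4)
  avg <- average_matrices(list(m1, m2))
  expect_equal(avg$values["a", "b"], 0.3)
  expect_identical(avg$support["a", "b"], 2L)

  # single matrix averages to itself
  avg1 <- average_matrices(list(m1))
  expect_equal(avg1$values, m1$values)

  # permutation invariance in lineage order
  m3 <- mk(c("b", "c"), 0.6)
  expect_equal(average_matrices(list(m1, m2, m3))$values,
               average_matrices(list(m3, m1, m2))$values)

  # pair present in a subset of lineages: mean over that subset
  avg <- average_matrices(list(m1, m2, m3))
  expect_equal(avg$values["b", "c"], 0.6)
  expect_identical(avg$support["b", "c"], 1L)
  expect_true(is.na(avg$values["a", "c"]))  # never co-observed

  # min_support masks low-coverage pairs
  avg <- average_matrices(list(m1, m2, m3), min_support = 2L)
  expect_true(is.na(avg$values["b", "c"]))
  expect_equal(avg$values["a", "b"], 0.3)

  # dropping uncovered samples leaves a complete core
  core <- drop_unsupported(average_matrices(list(m1, m2, m3)))
  expect_false(anyNA(core$values))
  expect_true(all(core$sample_ids %in% c("a", "b", "c")))
  expect_lt(length(core$sample_ids), 3)
})

test_that("Ward.D2 linkage: two-sample merge height and the 3-point formula", {
  mk <- function(v, samples) {
    structure(list(sample_ids = samples, values = v, support = v * 0 + 1,
                   source = "x"), class = "dissim_matrix")
  }
  v <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- ward_d2_linkage(mk(v, c("A", "B")))
  expect_equal(tr$height, 0.4)

  # three equidistant points at d: by the stated update,
  # d(AB,C) = sqrt((2 d^2 + 2 d^2 - d^2) / 3) = d
  d <- 0.3
  v <- matrix(d, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(v) <- 0
  tr <- ward_d2_linkage(mk(v, LETTERS[1:3]))
  expect_equal(tr$height, c(d, d), tolerance = 1e-12)

  # missing entries refuse to cluster
  v[1, 3] <- v[3, 1] <- NA
  expect_error(ward_d2_linkage(mk(v, LETTERS[1:3])), "missing")
})

test_that("Ward.D2 merge heights match the Lance-Williams oracle", {
  set.seed(43)
  for (i in 1:20) {
    n <- 8
    v <- matrix(runif(n * n, 0.05, 1), n)
    v <- (v + t(v)) / 2
    diag(v) <- 0
    dimnames(v) <- list(paste0("s", 1:n), paste0("s", 1:n))
    m <- structure(list(sample_ids = rownames(v), values = v,
                        support = v * 0 + 1, source = "x"),
                   class = "dissim_matrix")
    tr <- ward_d2_linkage(m)
    expect_equal(tr$height, oracle_ward_d2_heights(v), tolerance = 1e-10)
    expect_true(all(diff(tr$height) >= -1e-12))  # monotone heights
  }
})

test_that("tree cutting relabels in dendrogram order and checks bounds", {
  set.seed(44)
  v <- matrix(runif(36, 0.1, 1), 6)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  dimnames(v) <- list(paste0("s", 1:6), paste0("s", 1:6))
  m <- structure(list(sample_ids = rownames(v), values = v,
                      support = v * 0 + 1, source = "x"),
                 class = "dissim_matrix")
  tr <- ward_d2_linkage(m)
  expect_identical(unname(cut_tree(tr, 1)), rep(1L, 6))
  expect_identical(sort(unname(cut_tree(tr, 6))), 1:6)
  labs <- cut_tree(tr, 3)
  # leftmost leaf is in cluster 1, and labels appear in leaf order
  leaf_order <- tr$labels[tr$order]
  expect_identical(unname(labs[leaf_order[1]]), 1L)
  expect_identical(unique(unname(labs[leaf_order])), 1:3)
  expect_error(cut_tree(tr, 0), "k must be")
  expect_error(cut_tree(tr, 7), "k must be")
})

test_that("pairwise value extraction equals the filtered submatrix", {
  set.seed(45)
  v <- matrix(runif(25, 0, 1), 5)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  ids <- paste0("s", 1:5)
  dimnames(v) <- list(ids, ids)
  m <- structure(list(sample_ids = ids, values = v, support = v * 0 + 1,
                      source = "x"), class = "dissim_matrix")
  all_vals <- pairwise_values(m)
  expect_identical(nrow(all_vals), 10L)
  keep <- c("s1", "s3", "s4")
  sub <- pairwise_values(m, keep)
  expect_identical(nrow(sub), 3L)
  expect_setequal(sub$value, v[keep, keep][upper.tri(v[keep, keep])])
  # predicate filter agrees with id filter
  sub2 <- pairwise_values(m, function(s) s %in% keep)
  expect_equal(sub, sub2)
  # 2 retained samples -> a single value
  expect_identical(nrow(pairwise_values(m, c("s2", "s5"))), 1L)
})
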