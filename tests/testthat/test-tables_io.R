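test_that("FASTA reading normalizes case and alphabet and tokenizes headers", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a description here", "acgu", ">b", "GG"), f)
  seqs <- read_fasta(f)
  expect_identical(unname(seqs[["a"]]), "ACGT")
  expect_identical(names(seqs), c("a", "b"))
  expect_length(attr(seqs, "ambiguous_ids"), 0)

  writeLines(c(">x", "ACGT", ">x", "GG"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("FASTA write/read round-trip is identity on random sequences", {
  set.seed(42)
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- setNames(vapply(1:20, function(i) rand_dna(sample(50:300, 1)),
                          character(1)),
                   paste0("asv_", 1:20))
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(as.character(back), as.character(seqs))
  expect_identical(names(back), names(seqs))
})

test_that("count tables parse with metadata and reject contract violations", {
  cf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("asv_id\tAAe\tABh", "asv_1\t5\t0", "asv_2\t1\t7"), cf)
  writeLines(c("sample_id\tlake_code\tregion\tlayer\tyear",
               "AAe\tAA\tHokkaido\tepilimnion\t2015",
               "ABh\tAB\tEurope\thypolimnion\t2017"), mf)
  tab <- read_count_table(cf, mf)
  expect_s3_class(tab, "asv_table")
  expect_identical(dim(tab$counts), c(2L, 2L))
  expect_identical(sum(tab$counts), 13L)
  expect_identical(tab$metadata$sample_id, c("AAe", "ABh"))

  # sample missing from metadata
  writeLines(c("asv_id\tAAe\tZZq", "asv_1\t5\t0"), cf)
  expect_error(read_count_table(cf, mf), "not in metadata")

  # non-integer cell is located
  writeLines(c("asv_id\tAAe\tABh", "asv_1\t5\tx"), cf)
  expect_error(read_count_table(cf, mf), "row 1.*ABh")
})

test_that("count-table write/read round-trip preserves the table", {
  tab <- toy_table(list(a1 = c(AAe = 12L, ABh = 3L), a2 = c(AAe = 0L, ABh = 9L)))
  cf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, cf)
  write.table(tab$metadata, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_count_table(cf, mf)
  expect_identical(back$counts, tab$counts)
})

test_that("pileup TSV honors its invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ref\tpos\tA\tC\tG\tT\tdel", "r1\t10\t5\t0\t0\t0\t0"), f)
  p <- read_pileup(f)
  expect_identical(p$pos, 10L)
  expect_identical(p$depth, 5L)
  expect_identical(p$A, 5L)

  # declared depth must match the five state counts
  writeLines(c("ref\tpos\tA\tC\tG\tT\tdel\tdepth", "r1\t10\t5\t0\t0\t0\t0\t6"), f)
  expect_error(read_pileup(f), "depth mismatch")

  # unsorted positions rejected
  writeLines(c("ref\tpos\tA\tC\tG\tT\tdel", "r1\t10\t5\t0\t0\t0\t0",
               "r1\t9\t1\t0\t0\t0\t0"), f)
  expect_error(read_pileup(f), "strictly increasing")

  # empty file is a valid empty pileup
  writeLines(character(), f)
  expect_identical(nrow(read_pileup(f)), 0L)
})

test_that("SAM tally matches hand counts and the equivalent TSV", {
  sam <- withr::local_tempfile(fileext = ".sam")
  # r1: ACCTA at 1-5; r2: TTACG at 3-7 -> pos 3 sees C (r1) and T (r2)
  # r3: 2M1D2M at 4 -> covers 4,5 then deletion at 6, then 7,8
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ref\tLN:10",
    "r1\t0\tref\t1\t60\t5M\t*\t0\t0\tACCTA\t*",
    "r2\t0\tref\t3\t60\t5M\t*\t0\t0\tTTACG\t*",
    "r3\t0\tref\t4\t60\t2M1D2M\t*\t0\t0\tGGCC\t*"), sam)
  p <- pileup_from_sam(sam)
  row3 <- p[p$pos == 3, ]
  expect_identical(c(row3$C, row3$T, row3$depth), c(1L, 1L, 2L))
  row6 <- p[p$pos == 6, ]
  expect_identical(row6$del, 1L)
  expect_identical(row6$depth, 2L)  # r2 covers pos 6, r3 deletes it

  # same counts via the TSV dialect
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(p, tf)
  back <- read_pileup(tf)
  expect_equal(as.data.frame(unclass(back)), as.data.frame(unclass(p)))
})

test_that("matrix writer emits symmetric labelled TSV and round-trips to 12 decimals", {
  set.seed(7)
  m <- matrix(runif(16), 4)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f)
  expect_true(startsWith(readLines(f, n = 1), "# ampdiv"))
  back <- read_matrix(f)
  expect_equal(back, m, tolerance = 1e-12)

  z <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  write_matrix(z, f)
  expect_true(all(read_matrix(f) == 0))

  asym <- m; asym[1, 2] <- asym[1, 2] + 1
  expect_error(write_matrix(asym, f), "symmetric")
})

test_that("two-leaf dendrogram is written with half-height branches", {
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  hc <- hclust(as.dist(d), method = "ward.D2")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(tr$edge.length, c(1.5, 1.5))
})

test_that("metadata vocabularies are closed", {
  mf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlake_code\tregion\tlayer\tyear",
               "AAe\tAA\tAtlantis\tepilimnion\t2015"), mf)
  expect_error(read_metadata(mf), "unknown region")
  writeLines(c("sample_id\tlake_code\tregion\tlayer\tyear",
               "AAe\tAA\tEurope\tbenthos\t2015"), mf)
  expect_error(read_metadata(mf), "unknown layer")
})
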