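# Independent oracles, kept deliberately separate from the package's code
# paths: a plain-R affine-gap alignment scorer (Gotoh recursion over the
# three gap states), a naive Lance-Williams agglomerator, and small
# fixture builders.

# Optimal global affine-gap alignment score by direct recursion over the
# three alignment states (match/mismatch, gap-in-a, gap-in-b); terminal
# gaps penalized. A gap of length L costs open + L * extend.
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               open = 5, extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last column was substitution
  X <- matrix(NEG, n + 1, m + 1)   # last column consumed b only (gap in a)
  Y <- matrix(NEG, n + 1, m + 1)   # last column consumed a only (gap in b)
  M[1, 1] <- 0
  for (j in seq_len(m)) {
    X[1, j + 1] <- -(open + extend * j)
  }
  for (i in seq_len(n)) {
    Y[i + 1, 1] <- -(open + extend * i)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             X[i + 1, j] - extend,
                             Y[i + 1, j] - open - extend)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - open - extend,
                             Y[i, j + 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Naive Ward.D2 agglomeration: keep the full distance matrix, merge the
# globally closest pair (ties: smallest index pair), update with
# d(ij,k) = sqrt(((ni+nk) dik^2 + (nj+nk) djk^2 - nk dij^2)/(ni+nj+nk)).
oracle_ward_d2_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(NA, NA); bestval <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (d[active[i], active[j]] < bestval - 1e-15) {
          bestval <- d[active[i], active[j]]
          best <- c(i, j)
        }
      }
    }
    ai <- active[best[1]]; aj <- active[best[2]]
    heights[step] <- bestval
    ni <- sizes[ai]; nj <- sizes[aj]
    for (x in active) {
      if (x == ai || x == aj) next
      nk <- sizes[x]
      newd <- sqrt(((ni + nk) * d[ai, x]^2 + (nj + nk) * d[aj, x]^2 -
                      nk * d[ai, aj]^2) / (ni + nj + nk))
      d[ai, x] <- newd; d[x, ai] <- newd
    }
    sizes[ai] <- ni + nj
    active <- setdiff(active, aj)
  }
  heights
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# mutate exactly k positions of a sequence (substitutions only)
mutate_seq <- function(seq, k, protect = integer()) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(setdiff(seq_along(chars), protect), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# small ASV table fixture: counts matrix built from a named list of rows
toy_table <- function(counts, regions = NULL, layers = NULL) {
  m <- do.call(rbind, counts)
  rownames(m) <- names(counts)
  samples <- colnames(m)
  md <- data.frame(
    sample_id = samples,
    lake_code = substr(samples, 1, 2),
    region = regions %||% rep("Hokkaido", length(samples)),
    layer = layers %||% rep("epilimnion", length(samples)),
    year = 2015L)
  asv_table(m, md)
}

toy_profile <- function(counts, otu_id = "OTU_1", min_reads = 20L) {
  tab <- toy_table(counts)
  map <- setNames(rep(otu_id, length(counts)), names(counts))
  build_profiles(tab, map, min_reads = min_reads)[[otu_id]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ari <- function(x, y) mclust::adjustedRandIndex(x, y)
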