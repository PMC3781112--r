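test_that("haplotype collapsing respects gap mode, mask and frequency ordering", {
  aln <- seq_alignment(c("s1", "s2"), c("ACGT", "ACGT"))
  hs <- collapse_haplotypes(aln)
  expect_equal(nrow(hs$seqs), 1L)
  expect_equal(hs$freq, 2L)

  aln2 <- seq_alignment(c("s1", "s2"), c("AC-T", "ACGT"))
  expect_equal(nrow(collapse_haplotypes(aln2, "fifth_state")$seqs), 2L)
  expect_equal(nrow(collapse_haplotypes(aln2, "missing")$seqs), 1L)

  # masked sites are ignored in the comparison
  aln3 <- seq_alignment(c("s1", "s2"), c("ACGT", "TCGT"),
                        mask = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(nrow(collapse_haplotypes(aln3)$seqs), 1L)

  # ordering: descending frequency, ties by first occurrence
  aln4 <- seq_alignment(paste0("s", 1:5),
                        c("AAAA", "CCCC", "AAAA", "GGGG", "AAAA"))
  hs4 <- collapse_haplotypes(aln4)
  expect_equal(hs4$freq, c(3L, 1L, 1L))
  expect_equal(hs4$members$H1, c("s1", "s3", "s5"))
  expect_equal(paste(hs4$seqs[2, ], collapse = ""), "CCCC")

  expect_error(collapse_haplotypes(seq_alignment(character(0),
                                                 matrix("", 0, 4))), "empty")

  # invariant: frequencies sum to sequence count; each sample in one haplotype
  expect_equal(sum(hs4$freq), 5L)
  expect_setequal(unlist(hs4$members), aln4$ids)
})

test_that("median-joining network matches the brute-force Steiner oracle on small cases", {
  # single haplotype
  n1 <- median_joining_network(matrix(c("A", "A", "A"), 1, 3))
  expect_equal(nrow(n1$nodes), 1L)
  expect_equal(nrow(n1$edges), 0L)

  # two haplotypes one step apart
  n2 <- median_joining_network(rbind(c("A", "A", "A"), c("A", "A", "T")))
  expect_equal(nrow(n2$edges), 1L)
  expect_equal(n2$edges$weight, 1L)

  # classic triplet requiring a median vector
  h <- rbind(c("0", "0", "0"), c("1", "1", "0"), c("1", "0", "1"))
  rownames(h) <- paste0("H", 1:3)
  net <- median_joining_network(h)
  expect_true("100" %in% net$nodes$sequence[!net$nodes$observed])
  expect_equal(sum(net$edges$weight), steiner_oracle(h))

  # random small binary haplotype sets: the spanning weight of the final
  # node set equals the Steiner oracle's minimum (the network itself may
  # carry more edges, since it contains every minimum spanning tree), and
  # median vectors have degree >= 3
  set.seed(3)
  mstw <- function(seqm) {
    n <- nrow(seqm)
    if (n == 1) return(0)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(seqm[i, ] != seqm[j, ])
    intree <- c(TRUE, rep(FALSE, n - 1)); mind <- d[1, ]; tot <- 0
    for (s in seq_len(n - 1)) {
      jj <- which(!intree)[which.min(mind[!intree])]
      tot <- tot + mind[jj]; intree[jj] <- TRUE
      mind <- pmin(mind, d[jj, ])
    }
    tot
  }
  for (r in 1:5) {
    hr <- unique(matrix(as.character(rbinom(4 * 4, 1, 0.5)), 4, 4))
    net_r <- median_joining_network(hr)
    final_nodes <- do.call(rbind, strsplit(net_r$nodes$sequence, ""))
    expect_equal(mstw(final_nodes), steiner_oracle(hr))
    if (any(!net_r$nodes$observed)) {
      deg <- table(c(net_r$edges$from, net_r$edges$to))
      med <- net_r$nodes$id[!net_r$nodes$observed]
      expect_true(all(deg[med] >= 3))
    }
  }
})

test_that("network connectivity and path-weight invariants hold", {
  set.seed(11)
  aln <- simulate_expansion_sequences(0.5, 3, 1.5, 12, 200, seed = 8)
  hs <- collapse_haplotypes(aln)
  net <- median_joining_network(hs)
  ids <- net$nodes$id
  # connected
  g <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in seq_len(nrow(net$edges)))
    g[net$edges$from[e], net$edges$to[e]] <-
      g[net$edges$to[e], net$edges$from[e]] <- TRUE
  reach <- ids[1]
  repeat {
    nxt <- unique(c(reach, ids[colSums(g[reach, , drop = FALSE]) > 0]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(reach, ids)
  # path weight between observed haplotypes >= Hamming distance
  obs <- which(net$nodes$observed)
  seqm <- do.call(rbind, strsplit(net$nodes$sequence, ""))
  w <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  diag(w) <- 0
  for (e in seq_len(nrow(net$edges)))
    w[net$edges$from[e], net$edges$to[e]] <-
      w[net$edges$to[e], net$edges$from[e]] <- net$edges$weight[e]
  for (k in ids) for (i in ids) for (j in ids)
    if (w[i, k] + w[k, j] < w[i, j]) w[i, j] <- w[i, k] + w[k, j]
  for (i in obs) for (j in obs) if (i < j) {
    ham <- sum(seqm[i, ] != seqm[j, ])
    expect_gte(w[ids[i], ids[j]] + 1e-12, ham)
  }
})

test_that("network exports are readable", {
  h <- rbind(c("A", "A"), c("A", "T"), c("T", "T"))
  net <- median_joining_network(h)
  f1 <- tempfile(fileext = ".tsv")
  write_network(net, f1)
  el <- read.table(f1, header = TRUE, sep = "\t")
  expect_equal(nrow(el), nrow(net$edges))
  f2 <- tempfile(fileext = ".gml")
  write_network(net, f2, "gml")
  expect_true(any(grepl("^graph \\[", readLines(f2))))
})
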