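# Shared fixtures, all built in code.

# small deterministic marker matrix: two groups with fixed differences plus
# shared polymorphic background
fixture_two_group_matrix <- function(n_per = 4, n_fixed = 20, n_noise = 40,
                                     seed = 1) {
  set.seed(seed)
  block <- rbind(
    matrix(rep(c(rep(1L, n_fixed), rep(0L, n_fixed)), each = n_per),
           nrow = n_per, byrow = FALSE),
    matrix(rep(c(rep(0L, n_fixed), rep(1L, n_fixed)), each = n_per),
           nrow = n_per, byrow = FALSE))
  noise <- matrix(rbinom(2 * n_per * n_noise, 1L, 0.5), nrow = 2 * n_per)
  marker_matrix(cbind(block, noise),
                sample_ids = paste0(rep(c("a", "b"), each = n_per),
                                    seq_len(n_per)),
                species = rep(c("A", "B"), each = n_per),
                warn_monomorphic = FALSE)
}

# additive 4-taxon distance matrix from tree ((A:1,B:1):1,C:1,D:3)
fixture_additive_matrix <- function() {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 2; d["A", "C"] <- 4; d["A", "D"] <- 6
  d["B", "C"] <- 4; d["B", "D"] <- 6; d["C", "D"] <- 4
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# brute-force Steiner-minimal spanning weight over observed haplotypes plus
# every candidate median vertex (exhaustive for small alphabets/lengths)
steiner_oracle <- function(seqs) {
  alphabet <- sort(unique(as.vector(seqs)))
  L <- ncol(seqs)
  grid <- expand.grid(rep(list(alphabet), L), stringsAsFactors = FALSE)
  all_seqs <- unique(rbind(seqs, as.matrix(grid)))
  ham <- function(s) {
    n <- nrow(s)
    d <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(s[i, ] != s[j, ])
    d
  }
  mstw <- function(d) {
    n <- nrow(d)
    intree <- c(TRUE, rep(FALSE, n - 1)); mind <- d[1, ]; tot <- 0
    for (s in seq_len(n - 1)) {
      j <- which(!intree)[which.min(mind[!intree])]
      tot <- tot + mind[j]; intree[j] <- TRUE
      mind <- pmin(mind, d[j, ])
    }
    tot
  }
  n_obs <- nrow(seqs)
  extra <- setdiff(seq_len(nrow(all_seqs)), seq_len(n_obs))
  best <- mstw(ham(seqs))
  # all subsets of candidate medians up to 2 added vertices (enough for the
  # small cases exercised here)
  for (k in 1:min(2, length(extra))) {
    for (comb in utils::combn(extra, k, simplify = FALSE)) {
      w <- mstw(ham(all_seqs[c(seq_len(n_obs), comb), , drop = FALSE]))
      if (w < best) best <- w
    }
  }
  best
}

# exhaustive quartet-based leaf stability for a list of trees
ls_oracle <- function(trees) {
  taxa <- sort(trees[[1]]$tip.label)
  n <- length(taxa)
  qs <- utils::combn(taxa, 4, simplify = FALSE)
  res_of <- function(tree, q) {
    t2 <- tree; t2$edge.length <- rep(1, nrow(t2$edge))
    d <- ape::cophenetic.phylo(t2)
    s <- c(d[q[1], q[2]] + d[q[3], q[4]],
           d[q[1], q[3]] + d[q[2], q[4]],
           d[q[1], q[4]] + d[q[2], q[3]])
    if (sum(s == min(s)) > 1) NA_integer_ else which.min(s)
  }
  maxf <- vapply(qs, function(q) {
    r <- vapply(trees, res_of, 0L, q = q)
    r <- r[!is.na(r)]
    if (!length(r)) return(0)
    max(table(factor(r, levels = 1:3))) / length(trees)
  }, 0)
  out <- vapply(taxa, function(tx)
    mean(maxf[vapply(qs, function(q) tx %in% q, TRUE)]), 0)
  names(out) <- taxa
  out
}
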