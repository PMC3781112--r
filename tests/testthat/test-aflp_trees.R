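test_that("binary distances match hand counts and the link <= jaccard bound", {
  m <- marker_matrix(rbind(c(1, 1, 0), c(0, 1, 1)), c("a", "b"), c("A", "B"),
                     warn_monomorphic = FALSE)
  expect_equal(binary_distance(m, "jaccard")$mat["a", "b"], 1 - 1 / 3)
  expect_equal(binary_distance(m, "link")$mat["a", "b"], 1 - 2 / 4)
  expect_equal(binary_distance(m, "p_distance")$mat["a", "b"], 2 / 3)

  m2 <- marker_matrix(rbind(c(1, 0, 0), c(0, 1, 0)), c("a", "b"), c("A", "B"),
                      warn_monomorphic = FALSE)
  expect_equal(binary_distance(m2, "jaccard")$mat["a", "b"], 1)

  ident <- marker_matrix(rbind(c(1, 0, 1), c(1, 0, 1)), c("a", "b"),
                         c("A", "B"), warn_monomorphic = FALSE)
  for (meth in c("jaccard", "link", "p_distance"))
    expect_equal(binary_distance(ident, meth)$mat["a", "b"], 0)

  allabs <- marker_matrix(rbind(c(0, 0), c(0, 0), c(1, 1)),
                          c("a", "b", "c"), c("A", "A", "B"),
                          warn_monomorphic = FALSE)
  expect_error(binary_distance(allabs, "jaccard"), "all-absent pair")

  # property: link <= jaccard on random matrices
  set.seed(7)
  for (r in 1:5) {
    X <- matrix(rbinom(6 * 30, 1, 0.4), 6)
    X[, 1] <- 1  # avoid all-absent pairs
    mr <- marker_matrix(X, paste0("s", 1:6), rep("A", 6),
                        warn_monomorphic = FALSE)
    dj <- binary_distance(mr, "jaccard")$mat
    dl <- binary_distance(mr, "link")$mat
    expect_true(all(dl <= dj + 1e-12))
  }
})

test_that("NJ recovers additive trees exactly and matches UPGMA on ultrametric input", {
  d <- fixture_additive_matrix()
  tr <- nj_tree(d)
  co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(co, d, tolerance = 1e-9)
  # topology: A,B form the cherry
  expect_true(flockpopgen:::has_split(tr, c("A", "B")))

  # 3 taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  co3 <- ape::cophenetic.phylo(t3)[rownames(d3), colnames(d3)]
  expect_equal(co3, d3, tolerance = 1e-9)

  # ultrametric matrix: NJ topology = UPGMA topology
  du <- matrix(c(0, 2, 8, 8, 2, 0, 8, 8, 8, 8, 0, 4, 8, 8, 4, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tn <- nj_tree(du)
  tu <- ape::as.phylo(stats::hclust(stats::as.dist(du), "average"))
  expect_true(flockpopgen:::has_split(tn, c("A", "B")))
  expect_true(flockpopgen:::has_split(tu, c("A", "B")))
  expect_true(flockpopgen:::has_split(tn, c("C", "D")))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("locus bootstrap is deterministic under seed and certain for fixed divergence", {
  m <- fixture_two_group_matrix()
  bs1 <- bootstrap_support(m, 50, "link", seed = 11)
  bs2 <- bootstrap_support(m, 50, "link", seed = 11)
  expect_identical(bs1$supports, bs2$supports)

  key <- flockpopgen:::bipart_key(paste0("a", 1:4), m$sample_ids)
  expect_equal(unname(bs1$supports[key]), 100)

  # i.i.d. noise: no strongly supported bipartition
  set.seed(5)
  Xn <- matrix(rbinom(8 * 120, 1, 0.5), 8)
  mn <- marker_matrix(Xn, paste0("t", 1:8), rep("A", 8),
                      warn_monomorphic = FALSE)
  bsn <- bootstrap_support(mn, 200, "link", seed = 13)
  expect_true(all(bsn$supports < 70))
})

test_that("leaf stability is 1 on identical trees and matches the quartet oracle", {
  m <- fixture_two_group_matrix()
  bs <- bootstrap_support(m, 30, "link", seed = 2)
  same <- rep(list(bs$tree), 4)
  expect_true(all(abs(leaf_stability(same) - 1) < 1e-12))

  # random small trees: exhaustive quartet tabulation oracle
  set.seed(42)
  trees <- lapply(1:6, function(i) ape::rtree(5, tip.label = paste0("t", 1:5)))
  expect_equal(leaf_stability(trees), ls_oracle(trees), tolerance = 1e-12)

  # a wobbling taxon is less stable than the stable ones
  t1 <- ape::read.tree(text = "(((a1,a2),(b1,b2)),(w,(c1,c2)));")
  t2 <- ape::read.tree(text = "(((a1,a2),(w,(b1,b2))),(c1,c2));")
  ls <- leaf_stability(c(rep(list(t1), 3), rep(list(t2), 3)))
  expect_lt(ls[["w"]], min(ls[c("a1", "a2", "c1", "c2")]))
})

test_that("lineage movement classifies inside/outside/dispersed correctly", {
  t_in <- ape::read.tree(text = "(((q1,q2),r1),r2,(o1,o2));")
  t_out <- ape::read.tree(text = "(((q1,q2),o1),o2,(r1,r2));")
  t_disp <- ape::read.tree(text = "((q1,r1),(q2,r2),(o1,o2));")

  lm_in <- lineage_movement(rep(list(t_in), 5), c("q1", "q2"), c("r1", "r2"))
  expect_equal(unname(lm_in$percent["outside"]), 0)
  expect_equal(unname(lm_in$percent["inside"]), 100)

  lm_mix <- lineage_movement(c(rep(list(t_in), 3), rep(list(t_out), 2)),
                             c("q1", "q2"), c("r1", "r2"))
  expect_equal(unname(lm_mix$percent["outside"]), 40)

  lm_d <- lineage_movement(list(t_disp), c("q1", "q2"), c("r1", "r2"))
  expect_equal(unname(lm_d$percent["dispersed"]), 100)

  expect_error(lineage_movement(list(t_in), c("q1"), c("q1", "r1")), "overlap")
})

test_that("control removals leave supports unchanged within noise; hybrid removal raises parental support", {
  # control: removing an uninvolved taxon from clean two-clade data
  m <- fixture_two_group_matrix(n_per = 5, n_fixed = 40, n_noise = 20)
  he <- homoplasy_excess_scan(m, list(ctrl = "b5"), n_reps = 300, seed = 9)
  key <- flockpopgen:::bipart_key(paste0("a", 1:5), m$sample_ids)
  ctrl <- he[he$clade == key, ]
  expect_true(abs(ctrl$delta) <= 5)

  # synthetic F1 hybrid between two of three species
  cfg <- flock_config(
    n_species = 3, n_per_species = 8, n_loci = 500, frac_outlier = 0,
    fst_neutral = 0.15, introgressed_spec = NULL,
    hybrid_spec = list(list(id = "hyb1", parents = c("astorquii", "chancho"),
                            generation = "F1")),
    seq_len = 600, seed = 99)
  mm <- simulate_flock(cfg)$markers
  he2 <- homoplasy_excess_scan(mm, list(hybrid = "hyb1"), n_reps = 400,
                               seed = 3)
  ids <- mm$sample_ids
  keyA <- flockpopgen:::bipart_key(ids[grepl("^astorquii_", ids)], ids)
  keyB <- flockpopgen:::bipart_key(ids[grepl("^chancho_", ids)], ids)
  dA <- he2$delta[he2$clade == keyA]
  dB <- he2$delta[he2$clade == keyB]
  expect_gt(dA, 0)
  expect_gt(dB, 0)
})
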