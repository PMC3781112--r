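# Scan tests run on reduced problem sizes (600-800 loci) to stay fast; the
# full-scale behaviour is exercised by the acceptance suite.

test_that("per-locus FST estimator is calibrated on island-model data", {
  cfg <- flock_config(n_species = 4, n_per_species = 15, n_loci = 3000,
                      frac_outlier = 0, fst_neutral = 0.2,
                      introgressed_spec = NULL, seq_len = 500, seed = 8)
  m <- simulate_flock(cfg)$markers
  lf <- locus_fst(m)
  expect_lt(abs(attr(lf, "overall_fst") - 0.2), 0.02)
  expect_true(all(lf$het >= 0 & lf$het <= 0.5 + 1e-9))
})

test_that("island-model scan is one-sided and near-nominal on neutral data", {
  cfg <- flock_config(n_species = 6, n_per_species = 15, n_loci = 800,
                      frac_outlier = 0, fst_neutral = 0.10,
                      introgressed_spec = NULL, seq_len = 500, seed = 21)
  m <- simulate_flock(cfg)$markers
  sc <- fdist_scan(m, "average", alpha = 0.95, n_sims = 8000, seed = 5)
  rate <- mean(sc$per_locus$outlier, na.rm = TRUE)
  # within 3 binomial SE of the nominal 5%
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 800))
  # loci below the baseline FST are never flagged
  low <- sc$per_locus$fst <= sc$baseline_fst
  expect_false(any(sc$per_locus$outlier[low], na.rm = TRUE))
})

test_that("island-model scan detects planted high-divergence loci", {
  cfg <- flock_config(n_species = 6, n_per_species = 15, n_loci = 800,
                      frac_outlier = 10 / 800, fst_neutral = 0.10,
                      fst_outlier = 0.55, introgressed_spec = NULL,
                      seq_len = 500, seed = 22)
  s <- simulate_flock(cfg)
  sc <- fdist_scan(s$markers, "trimmed_mean", alpha = 0.99, n_sims = 8000,
                   seed = 6)
  truth <- s$truth$outlier_loci
  flagged <- which(sc$per_locus$outlier)
  expect_gte(sum(truth %in% flagged), 8)
})

test_that("Bayesian scan flags planted outliers decisively with rare false positives", {
  cfg <- flock_config(n_species = 6, n_per_species = 15, n_loci = 600,
                      frac_outlier = 10 / 600, fst_neutral = 0.10,
                      fst_outlier = 0.55, introgressed_spec = NULL,
                      seq_len = 500, seed = 23)
  s <- simulate_flock(cfg)
  sc <- bayes_scan(s$markers, burnin = 1000, iterations = 4000, seed = 7)
  truth <- s$truth$outlier_loci
  pl <- sc$per_locus
  # at this reduced scale every planted locus should carry strong evidence
  # (the strict decisive call at full scale is an acceptance-level check)
  expect_gte(sum(pl$pp[truth] > 0.8), 8)
  expect_true(all(pl$outlier[-truth] == FALSE | pl$pp[-truth] > 0.99))
  expect_lt(mean(pl$outlier[-truth]), 0.01)
  # decisive criterion is the conjunction BF > 100 and PP > 0.99
  expect_true(all(pl$pp[pl$outlier] > 0.99))
  expect_true(all(10^pl$log10_bf[pl$outlier] > 100))
  # concordance with the island-model scan on flagged loci
  sf <- fdist_scan(s$markers, "trimmed_mean", alpha = 0.99, n_sims = 8000,
                   seed = 8)
  both <- which(pl$outlier)
  expect_gte(mean(both %in% which(sf$per_locus$outlier)), 0.9)
})

test_that("single population yields no flags; decisions invariant to column order", {
  m1 <- marker_matrix(matrix(rbinom(10 * 50, 1, 0.5), 10), paste0("s", 1:10),
                      rep("A", 10), warn_monomorphic = FALSE)
  sc1 <- bayes_scan(m1, seed = 1)
  expect_false(any(sc1$per_locus$outlier))

  cfg <- flock_config(n_species = 4, n_per_species = 10, n_loci = 200,
                      frac_outlier = 0.03, fst_neutral = 0.1,
                      fst_outlier = 0.55, introgressed_spec = NULL,
                      seq_len = 500, seed = 9)
  m <- simulate_flock(cfg)$markers
  perm <- sample(seq_len(ncol(m$data)))
  mp <- m
  mp$data <- m$data[, perm]
  mp$locus_ids <- m$locus_ids[perm]
  mp$monomorphic <- m$monomorphic[perm]
  s1 <- fdist_scan(m, "average", alpha = 0.99, n_sims = 4000, seed = 3)
  s2 <- fdist_scan(mp, "average", alpha = 0.99, n_sims = 4000, seed = 3)
  f1 <- s1$per_locus$locus[which(s1$per_locus$outlier)]
  f2 <- s2$per_locus$locus[which(s2$per_locus$outlier)]
  expect_setequal(f1, f2)
})

test_that("matrix partition separates columns and preserves metadata", {
  m <- fixture_two_group_matrix()
  parts <- partition_matrix(m, character(0))
  expect_identical(parts$neutral$data, m$data)
  expect_equal(ncol(parts$outliers$data), 0L)

  out_ids <- m$locus_ids[1:5]
  parts2 <- partition_matrix(m, out_ids)
  expect_equal(ncol(parts2$neutral$data), ncol(m$data) - 5L)
  expect_identical(parts2$outliers$locus_ids, out_ids)
  expect_identical(parts2$neutral$species, m$species)
  expect_error(partition_matrix(m, "nope"), "unknown locus")
  expect_warning(partition_matrix(m, m$locus_ids), "empty")
})

test_that("neutral-partition FST is lower than full-matrix FST when outliers are planted", {
  cfg <- flock_config(n_species = 4, n_per_species = 12, n_loci = 500,
                      frac_outlier = 0.04, fst_neutral = 0.10,
                      fst_outlier = 0.55, introgressed_spec = NULL,
                      seq_len = 500, seed = 30)
  s <- simulate_flock(cfg)
  m <- s$markers
  parts <- partition_matrix(m, m$locus_ids[s$truth$outlier_loci])
  full <- mean(locus_fst(m)$fst, na.rm = TRUE)
  neut <- mean(locus_fst(parts$neutral)$fst, na.rm = TRUE)
  expect_lt(neut, full)
})
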