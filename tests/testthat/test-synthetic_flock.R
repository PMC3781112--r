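test_that("configuration invariants are enforced", {
  expect_error(flock_config(seed = 1, fst_neutral = 0.3, fst_outlier = 0.2),
               "exceed")
  expect_error(flock_config(seed = 1, frac_outlier = 1.5), "\\[0,1\\]")
  expect_error(flock_config(seed = 1, n_loci = 3,
                            introgressed_spec = list(species = "zaliosus",
                                                     n = 2,
                                                     n_fixed_private = 5)),
               "more fixed private")
  expect_error(flock_config(seed = 1,
                            hybrid_spec = list(list(parents = c("a", "b"),
                                                    generation = "F1"))),
               "parents")
  expect_error(flock_config(), "seed")
})

test_that("simulator is deterministic and truth is internally consistent", {
  cfg <- flock_config(n_species = 3, n_per_species = 6, n_loci = 300,
                      frac_outlier = 0.02, introgressed_spec = NULL,
                      seq_len = 500, seed = 5)
  s1 <- simulate_flock(cfg)
  s2 <- simulate_flock(cfg)
  expect_identical(s1$markers$data, s2$markers$data)
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_true(all(abs(rowSums(s1$truth$ancestry) - 1) < 1e-12))
  expect_true(all(s1$truth$outlier_loci >= 1 &
                    s1$truth$outlier_loci <= 300))
})

test_that("panmictic configuration yields near-zero FST; neutral FST converges to target", {
  cfg0 <- flock_config(n_species = 3, n_per_species = 20, n_loci = 2000,
                       frac_outlier = 0, fst_neutral = 0,
                       introgressed_spec = NULL, seq_len = 500, seed = 42)
  s0 <- simulate_flock(cfg0)
  lf0 <- locus_fst(s0$markers)
  expect_lt(abs(mean(lf0$fst, na.rm = TRUE)), 0.02)

  cfg1 <- flock_config(n_species = 6, n_per_species = 20, n_loci = 5000,
                       frac_outlier = 0, fst_neutral = 0.10,
                       introgressed_spec = NULL, seq_len = 500, seed = 7)
  s1 <- simulate_flock(cfg1)
  expect_lt(abs(attr(locus_fst(s1$markers), "overall_fst") - 0.10), 0.01)
})

test_that("introgressed subgroup carries exactly the requested fixed private bands", {
  cfg <- flock_config(seed = 11)   # study-scale defaults
  s <- simulate_flock(cfg)
  X <- s$markers$data
  pl <- s$truth$private_loci
  expect_length(pl, 4L)
  members <- s$markers$sample_ids %in% s$truth$introgressed_ids
  expect_equal(sum(members), 7L)
  expect_true(all(X[members, pl] == 1L))
  expect_true(all(X[!members, pl] == 0L))
  # private-allele accounting recovers them as private to that species
  pa <- private_alleles(s$markers)
  expect_gte(pa$private[pa$species == "zaliosus"], 4)
})

test_that("hybrid individuals draw bands from the ancestry-weighted mixture", {
  cfg <- flock_config(n_species = 2, n_per_species = 30, n_loci = 4000,
                      frac_outlier = 0, fst_neutral = 0.4,
                      introgressed_spec = NULL,
                      hybrid_spec = list(list(id = "f1",
                                              parents = c("astorquii",
                                                          "chancho"),
                                              generation = "F1")),
                      seq_len = 500, seed = 13)
  s <- simulate_flock(cfg)
  expect_equal(unname(s$truth$ancestry["f1", ]), c(0.5, 0.5))
  # the F1's band-sharing should be intermediate between the two species
  d <- binary_distance(s$markers, "link")$mat
  ids <- s$markers$sample_ids
  dA <- mean(d["f1", grepl("^astorquii", ids)])
  dB <- mean(d["f1", grepl("^chancho", ids)])
  within_A <- mean(d[grepl("^astorquii", ids), grepl("^astorquii", ids)])
  between <- mean(d[grepl("^astorquii", ids), grepl("^chancho", ids)])
  expect_gt(dA, within_A)
  expect_lt(dA, between)
  expect_lt(abs(dA - dB), 0.05)
})

test_that("infinite-sites violation fails loudly and flock files round-trip", {
  expect_error(simulate_expansion_sequences(5, 50, 3, 40, 4, seed = 1),
               "infinite-sites")
  cfg <- flock_config(n_species = 3, n_per_species = 5, n_loci = 100,
                      frac_outlier = 0, introgressed_spec = NULL,
                      seq_len = 500, seed = 3)
  s <- simulate_flock(cfg)
  dir <- tempfile()
  paths <- write_flock(s, dir)
  expect_true(all(file.exists(paths)))
  back <- suppressWarnings(read_marker_matrix(paths[["matrix"]],
                                              paths[["metadata"]]))
  expect_identical(back$data, s$markers$data)
  aln <- read_fasta(paths[["fasta"]])
  expect_identical(aln$seq, s$alignment$seq[aln$ids, ])
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(as.integer(unlist(truth$outlier_loci)),
               as.integer(s$truth$outlier_loci))
})
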