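# MCMC tests use reduced matrices and short chains; full study-scale
# behaviour is exercised in the acceptance suite.

test_that("K=1 gives unit ancestry and a finite evidence estimate", {
  m <- fixture_two_group_matrix()
  r <- fit_admixture(m, K = 1, burnin = 50, iterations = 200, seed = 1)[[1]]
  expect_true(all(r$Q == 1))
  expect_true(is.finite(r$lnPD))
})

test_that("well-separated species are recovered with confident assignment", {
  cfg <- flock_config(n_species = 3, n_per_species = 10, n_loci = 2000,
                      frac_outlier = 0, fst_neutral = 0.25,
                      introgressed_spec = NULL, seq_len = 500, seed = 41)
  s <- simulate_flock(cfg)
  r <- fit_admixture(s$markers, K = 3, burnin = 300, iterations = 900,
                     seed = 2)[[1]]
  mc <- match_clusters(r$Q, s$markers$species)
  expect_equal(mc$accuracy, 1)
  expect_gt(mean(apply(r$Q, 1, max)), 0.95)
  # Q rows are distributions
  expect_true(all(abs(rowSums(r$Q) - 1) < 1e-9))
  expect_true(all(r$P >= 0 & r$P <= 1))
})

test_that("an F1 hybrid receives intermediate ancestry from both parents", {
  cfg <- flock_config(n_species = 2, n_per_species = 12, n_loci = 2000,
                      frac_outlier = 0, fst_neutral = 0.25,
                      introgressed_spec = NULL,
                      hybrid_spec = list(list(id = "f1",
                                              parents = c("astorquii",
                                                          "chancho"),
                                              generation = "F1")),
                      seq_len = 500, seed = 43)
  s <- simulate_flock(cfg)
  r <- fit_admixture(s$markers, K = 2, burnin = 300, iterations = 900,
                     seed = 3)[[1]]
  qf1 <- r$Q["f1", ]
  expect_gt(min(qf1), 0.3)
  expect_lt(max(qf1), 0.7)
})

test_that("Evanno delta-K follows its definition and vanishes for linear evidence", {
  # hand example
  df <- data.frame(K = rep(1:4, each = 2),
                   lnPD = c(-101, -99, -51, -49, -46, -44, -45, -43))
  ev <- evanno_deltaK(df)
  sd2 <- sd(c(-51, -49))
  expect_equal(ev$table$deltaK[2], abs(-45 - 2 * -50 + -100) / sd2)
  expect_equal(ev$table$deltaK[3], abs(-44 - 2 * -45 + -50) / sd2)
  expect_true(is.na(ev$table$deltaK[1]))
  expect_true(is.na(ev$table$deltaK[4]))
  expect_equal(ev$best_K, 2)

  # exactly linear mean evidence: interior deltaK all zero
  lin <- data.frame(K = rep(1:5, each = 2),
                    lnPD = rep(-10 * (1:5), each = 2) + c(-0.5, 0.5))
  evl <- evanno_deltaK(lin)
  expect_true(all(evl$table$deltaK[2:4] == 0))

  expect_warning(
    evanno_deltaK(data.frame(K = rep(1:3, each = 2),
                             lnPD = c(-9, -9, -5, -5, -4, -4))),
    "zero SD")
  expect_error(evanno_deltaK(data.frame(K = c(1, 3, 4),
                                        lnPD = c(-1, -2, -3))),
               "consecutive")
})

test_that("ancestry test identifies pure individuals and grandparent ancestry", {
  cfg <- flock_config(n_species = 3, n_per_species = 15, n_loci = 2000,
                      frac_outlier = 0, fst_neutral = 0.25,
                      introgressed_spec = NULL,
                      hybrid_spec = list(list(id = "gp1",
                                              parents = c("astorquii",
                                                          "chancho"),
                                              generation = "grandparent")),
                      seq_len = 500, seed = 51)
  s <- simulate_flock(cfg)
  at <- ancestry_test(s$markers, gb = 2, nu = 0.05)
  sm <- at$summary
  pure <- sm[!(sm$sample_id %in% "gp1"), ]
  expect_gt(mean(pure$p_no_immigrant_ancestry > 0.95), 0.8)
  gp <- sm[sm$sample_id == "gp1", ]
  expect_lt(gp$p_no_immigrant_ancestry, 0.5)
  expect_match(gp$top_alternative, "chancho")
  # posterior rows are distributions over the hypothesis set
  expect_true(all(abs(rowSums(at$posterior) - 1) < 1e-9))

  # stability across the prior nu on clear cases
  at2 <- ancestry_test(s$markers, gb = 2, nu = 0.01)
  at3 <- ancestry_test(s$markers, gb = 2, nu = 0.1)
  clear <- sm$p_no_immigrant_ancestry > 0.99
  drift <- abs(at2$summary$p_no_immigrant_ancestry[clear] -
                 at3$summary$p_no_immigrant_ancestry[clear])
  expect_lt(max(drift), 0.1)
})

test_that("binary PCA separates clusters and respects spectral properties", {
  cfg <- flock_config(n_species = 2, n_per_species = 10, n_loci = 500,
                      frac_outlier = 0, fst_neutral = 0.3,
                      introgressed_spec = NULL, seq_len = 500, seed = 61)
  m <- simulate_flock(cfg)$markers
  p <- pca_binary(m)
  expect_true(all(diff(p$variance_explained) <= 1e-9))
  expect_lte(sum(p$variance_explained), 100 + 1e-6)
  # PC1 separates the two species (sign-invariant)
  pc1 <- p$scores[, 1]
  grp <- m$species
  gap <- abs(mean(pc1[grp == grp[1]]) - mean(pc1[grp != grp[1]]))
  spread <- sd(pc1[grp == grp[1]]) + sd(pc1[grp != grp[1]])
  expect_gt(gap, spread)

  # duplicated individual: identical scores
  X <- rbind(m$data, m$data[1, ])
  m2 <- marker_matrix(X, c(m$sample_ids, "dup"), c(m$species, m$species[1]),
                      warn_monomorphic = FALSE)
  p2 <- pca_binary(m2)
  expect_equal(unname(p2$scores["dup", ]),
               unname(p2$scores[m$sample_ids[1], ]), tolerance = 1e-9)

  expect_error(pca_binary(marker_matrix(matrix(1L, 3, 4), paste0("s", 1:3),
                                        rep("A", 3),
                                        warn_monomorphic = FALSE)),
               "no variance|constant")
})
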