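test_that("two-group statistic is 1 for perfectly separated groups and ~0 under the null", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  pf <- pairwise_fst(d, c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  expect_equal(pf$stat["g2", "g1"], 1)

  # homogeneous data with random labels: statistic near 0, p roughly uniform
  set.seed(4)
  stats <- replicate(30, {
    X <- matrix(rbinom(12 * 80, 1, 0.5), 12)
    X[, 1] <- 1
    m <- marker_matrix(X, paste0("s", 1:12), sample(rep(c("A", "B"), 6)),
                       warn_monomorphic = FALSE)
    dd <- binary_distance(m, "p_distance")
    dd$mat <- dd$mat * 80   # pairwise difference counts
    pf <- pairwise_fst(dd, m$species, n_perm = 60,
                       seed = sample.int(1e8, 1), p_adjust = "none")
    c(pf$stat[2, 1], pf$p[2, 1])
  })
  expect_lt(abs(mean(stats[1, ])), 0.05)
  expect_gt(mean(stats[2, ] > 0.5), 0.25)  # p not concentrated at 0
  ks <- suppressWarnings(ks.test(stats[2, ], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("negative estimates survive unclamped and size-1 groups error", {
  set.seed(9)
  # more variance within than between: expect a small, possibly negative value
  X <- matrix(rbinom(8 * 60, 1, 0.5), 8)
  X[, 1] <- 1
  m <- marker_matrix(X, paste0("s", 1:8), rep(c("A", "B"), 4),
                     warn_monomorphic = FALSE)
  dd <- binary_distance(m, "p_distance")
  pf <- pairwise_fst(dd, m$species, n_perm = 30, seed = 2)
  expect_true(is.finite(pf$stat[2, 1]))  # may be negative; must be reported
  expect_error(pairwise_fst(dd$mat[1:3, 1:3], c("A", "A", "B"),
                            n_perm = 10, seed = 1), "size 1")
})

test_that("one-level AMOVA matches a hand-worked two-population oracle", {
  # 2 pops x 2 individuals; squared distances chosen for hand computation:
  # within pop1: 2, within pop2: 4, between pairs: 10 each
  d2 <- matrix(c(0, 2, 10, 10,
                 2, 0, 10, 10,
                 10, 10, 0, 4,
                 10, 10, 4, 0), 4, byrow = TRUE,
               dimnames = list(paste0("i", 1:4), paste0("i", 1:4)))
  g <- c("p1", "p1", "p2", "p2")
  # SS_total = (2+4+40)/4 = 11.5 ; SS_within = 2/2 + 4/2 = 3
  # SS_among = 8.5 ; df = (1, 2); MS = (8.5, 1.5); n' = 2
  # sigma_a = (8.5 - 1.5)/2 = 3.5 ; sigma_w = 1.5 ; phi = 3.5/5 = 0.7
  a <- amova(d2, g, n_perm = 200, seed = 3)
  expect_equal(a$table$SS, c(8.5, 3), tolerance = 1e-12)
  expect_equal(a$table$sigma, c(3.5, 1.5), tolerance = 1e-12)
  expect_equal(unname(a$phi["phi_ST"]), 0.7, tolerance = 1e-12)
  expect_equal(sum(a$table$percent), 100, tolerance = 1e-9)

  # all individuals identical -> 0% among-group variation
  z <- matrix(0, 4, 4, dimnames = dimnames(d2))
  a0 <- amova(z, g, n_perm = 20, seed = 1)
  expect_equal(a0$table$percent[1], 0)
  expect_error(amova(d2, rep("one", 4), n_perm = 10, seed = 1), "single group")
})

test_that("pairwise statistic equals the two-group AMOVA among-component", {
  set.seed(6)
  cfg <- flock_config(n_species = 2, n_per_species = 10, n_loci = 300,
                      frac_outlier = 0, fst_neutral = 0.15,
                      introgressed_spec = NULL, seq_len = 500, seed = 21)
  m <- simulate_flock(cfg)$markers
  dd <- binary_distance(m, "p_distance")
  dd$mat <- dd$mat * 300
  pf <- pairwise_fst(dd, m$species, n_perm = 10, seed = 4)
  am <- amova(dd, m$species, n_perm = 10, seed = 4)
  expect_equal(pf$stat[2, 1], unname(am$phi["phi_ST"]), tolerance = 1e-12)
})

test_that("nested AMOVA components sum to 100% and detect the levels", {
  cfg <- flock_config(n_species = 3, n_per_species = 8, n_loci = 400,
                      frac_outlier = 0, fst_neutral = 0.2,
                      introgressed_spec = NULL, seq_len = 500, seed = 17)
  m <- simulate_flock(cfg)$markers
  dd <- binary_distance(m, "p_distance")
  dd$mat <- dd$mat * 400
  # locations nested within species (round-robin labels from the simulator
  # are crossed, so construct nested subgroups explicitly)
  sub <- paste(m$species, rep(c("x", "y"), length.out = length(m$species)),
               sep = ".")
  a <- amova(dd, m$species, subgroups = sub, n_perm = 50, seed = 2)
  expect_equal(sum(a$table$percent), 100, tolerance = 0.1)
  expect_gt(a$table$percent[1], 5)        # among species is real
  expect_lt(abs(a$table$percent[2]), 5)   # arbitrary subgroups explain ~0
})

test_that("private and fixed private bands are counted by definition", {
  X <- rbind(c(1, 1, 0, 0),
             c(0, 1, 0, 0),
             c(0, 0, 1, 0),
             c(0, 0, 1, 0))
  m <- marker_matrix(X, paste0("s", 1:4), c("A", "A", "B", "B"),
                     warn_monomorphic = FALSE)
  pa <- private_alleles(m)
  # locus 1: present in one A only -> private, not fixed
  # locus 2: present in all A, no B -> fixed private
  # locus 3: present in all B -> fixed private for B
  expect_equal(pa$private[pa$species == "A"], 2)
  expect_equal(pa$fixed_private[pa$species == "A"], 1)
  expect_equal(pa$fixed_private[pa$species == "B"], 1)
})

test_that("published-table summary reproduces the printed report statistics", {
  tbl <- read_pairwise_fst_table()
  s <- fst_change_summary(tbl)
  expect_equal(s$n_pairs, 15)
  expect_equal(s$phi_excess_mean, 42, tolerance = 0.01)
  expect_equal(s$fst_decrease_mean, 30.8, tolerance = 0.01)
  expect_equal(s$max_decrease, 42.8, tolerance = 0.005)
  # printed as 0.99; the exact value from the table is just under 1
  expect_gte(s$fst_phi_correlation, 0.99)
  expect_lt(s$fst_phi_correlation, 1)
})
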