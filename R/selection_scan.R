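# Detection of loci under divergent selection from dominant binary markers:
# an island-model simulation scan (conditional FST quantiles given
# heterozygosity) and a Bayesian locus/population-effect decomposition of
# FST with posterior inclusion probabilities and Bayes factors.

# Per-locus allele frequencies per species from band frequencies.
# "haploid": bands are haploid Bernoulli characters (band frequency = allele
# frequency), consistent with the generator and the admixture model.
# "sqrt": dominant-marker Hardy-Weinberg correction, q_absent = sqrt(1 -
# band frequency), allele frequency = 1 - q_absent (zero-adjusted).
locus_freqs <- function(m, freq_model = c("haploid", "sqrt")) {
  freq_model <- match.arg(freq_model)
  sps <- sort(unique(m$species))
  counts <- do.call(rbind, lapply(sps, function(s)
    colSums(m$data[m$species == s, , drop = FALSE])))
  sizes <- vapply(sps, function(s) sum(m$species == s), 0L)
  band <- counts / sizes
  p <- if (freq_model == "haploid") band else 1 - sqrt(pmax(1 - band, 0))
  dimnames(p) <- list(sps, m$locus_ids)
  list(p = p, sizes = sizes, species = sps)
}

#' Per-locus FST and heterozygosity
#'
#' Weir-Cockerham-style one-way ANOVA estimator on per-species allele
#' frequencies (haploid formulation), plus the pooled expected
#' heterozygosity per locus used as the conditioning variable in
#' [fdist_scan()].
#'
#' @param m [marker_matrix()]
#' @param freq_model `"haploid"` (default; band = allele) or `"sqrt"`
#'   (dominant-marker Hardy-Weinberg correction)
#' @return data.frame with `locus`, `fst`, `het`, `monomorphic`
#' @export
locus_fst <- function(m, freq_model = "haploid") {
  lf <- locus_freqs(m, freq_model)
  fst_from_freqs(lf$p, lf$sizes)
}

# vectorized over loci; p is species x loci, sizes per species
fst_from_freqs <- function(p, sizes) {
  G <- nrow(p); N <- sum(sizes)
  pbar <- colSums(p * sizes) / N
  msb <- colSums(sizes * (t(t(p) - pbar))^2) / (G - 1)
  # within-group sum of squares; for 0/1 data exactly n * p * (1 - p)
  ssw <- colSums(sizes * p * (1 - p))
  msw <- ssw / (N - G)
  nc <- (N - sum(sizes^2) / N) / (G - 1)
  fst <- (msb - msw) / (msb + (nc - 1) * msw)
  fst[!is.finite(fst)] <- NA_real_
  out <- data.frame(locus = colnames(p) %||% seq_len(ncol(p)),
                    fst = fst, het = pbar * (1 - pbar) * 2,
                    monomorphic = pbar %in% c(0, 1), stringsAsFactors = FALSE)
  # multi-locus ratio-of-sums estimator (less biased than averaging ratios)
  denom <- msb + (nc - 1) * msw
  ok <- is.finite(denom) & denom > 0
  attr(out, "overall_fst") <- sum(msb[ok] - msw[ok]) / sum(denom[ok])
  out
}

#' Island-model FST outlier scan
#'
#' Simulates neutral loci under a symmetric island model calibrated to a
#' baseline FST (the average or the trimmed mean of the observed per-locus
#' FSTs) with the same per-species sample sizes, and flags observed loci
#' whose FST exceeds the conditional `alpha` quantile of the simulated FST
#' distribution given heterozygosity (nearest-neighbour window on the
#' heterozygosity axis). The test is one-sided for directional selection:
#' loci at or below the baseline are never flagged. Monomorphic loci are
#' excluded and reported.
#'
#' @param m [marker_matrix()]
#' @param baseline `"average"` or `"trimmed_mean"` (trims 30% of loci at
#'   each tail, configurable via `trim`)
#' @param alpha quantile level, e.g. `0.95` or `0.99`
#' @param n_sims simulated neutral loci (`>= 1000`)
#' @param seed integer seed
#' @param trim trim fraction per tail for `"trimmed_mean"`
#' @param freq_model passed to [locus_fst()]
#' @param window nearest-neighbour window size for the conditional quantile
#' @return object of class `outlier_result`: per-locus data.frame
#'   (`locus`, `fst`, `het`, `quantile`, `outlier`), `baseline_fst`,
#'   `criteria`, `excluded` (monomorphic loci)
#' @export
fdist_scan <- function(m, baseline = c("average", "trimmed_mean"),
                       alpha = 0.95, n_sims = 20000, seed, trim = 0.3,
                       freq_model = "haploid", window = 500) {
  baseline <- match.arg(baseline)
  if (n_sims < 1000) stop("n_sims must be >= 1000")
  lf <- locus_freqs(m, freq_model)
  if (nrow(lf$p) < 2L) stop("need at least 2 species")
  obs <- fst_from_freqs(lf$p, lf$sizes)
  excluded <- obs$locus[obs$monomorphic]
  keep <- !obs$monomorphic & is.finite(obs$fst)
  fsts <- obs$fst[keep]
  base_fst <- if (baseline == "average") mean(fsts) else {
    qs <- stats::quantile(fsts, c(trim, 1 - trim))
    mean(fsts[fsts >= qs[1L] & fsts <= qs[2L]])
  }
  base_fst <- min(max(base_fst, 1e-4), 0.99)
  sizes <- lf$sizes
  # neutral simulation: ancestral frequencies resampled from the observed
  # pooled frequencies (matches the data's frequency spectrum), species
  # frequencies Balding-Nichols at the baseline FST, haploid sampling
  pooled <- colSums(lf$p[, keep, drop = FALSE] * sizes) / sum(sizes)
  pooled <- sort(pmin(pmax(pooled, 0.02), 0.98))  # order-invariant draws
  sim <- with_seed(seed, {
    p_anc <- sample(pooled, n_sims, replace = TRUE)
    shp <- (1 - base_fst) / base_fst
    pmat <- matrix(stats::rbeta(n_sims * length(sizes),
                                rep(p_anc, each = length(sizes)) * shp,
                                rep(1 - p_anc, each = length(sizes)) * shp),
                   nrow = length(sizes))
    counts <- matrix(stats::rbinom(length(pmat), rep(sizes, n_sims), pmat),
                     nrow = length(sizes))
    phat <- counts / sizes
    fst_from_freqs(phat, sizes)
  })
  sim <- sim[is.finite(sim$fst) & !sim$monomorphic, ]
  ord <- order(sim$het)
  sim_het <- sim$het[ord]; sim_fst <- sim$fst[ord]
  qfun <- function(h) {
    i <- findInterval(h, sim_het)
    lo <- max(1L, i - window %/% 2L)
    hi <- min(length(sim_fst), lo + window - 1L)
    lo <- max(1L, hi - window + 1L)
    stats::quantile(sim_fst[lo:hi], alpha, names = FALSE)
  }
  qs <- rep(NA_real_, nrow(obs))
  qs[keep] <- vapply(obs$het[keep], qfun, 0)
  flag <- rep(FALSE, nrow(obs))
  flag[keep] <- obs$fst[keep] > qs[keep] & obs$fst[keep] > base_fst
  res <- data.frame(locus = obs$locus, fst = obs$fst, het = obs$het,
                    quantile = qs, outlier = flag, stringsAsFactors = FALSE)
  structure(list(per_locus = res, baseline_fst = base_fst,
                 criteria = sprintf("fdist %s baseline, alpha=%.2f",
                                    baseline, alpha),
                 excluded = excluded, alpha = alpha),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat("outlier_result (", x$criteria, "): ",
      sum(x$per_locus$outlier, na.rm = TRUE), " of ",
      nrow(x$per_locus), " loci flagged\n", sep = "")
  invisible(x)
}

#' Bayesian FST outlier scan
#'
#' Logistic decomposition of locus-by-population FST into a locus effect
#' `alpha_i` and a population effect `beta_j`:
#' `logit(FST_ij) = alpha_i + beta_j`. Per-species band counts are
#' beta-binomial given the ancestral frequency `p_i` and
#' `theta_ij = (1 - FST_ij)/FST_ij`. A spike-and-slab indicator on
#' `alpha_i` is sampled by a reversible-jump move with the slab prior as
#' proposal; the posterior inclusion probability gives the Bayes factor
#' `BF = posterior odds / prior odds`. A locus is called under the
#' 'decisive' criterion when `BF > 100` and the posterior probability
#' exceeds 0.99. Split-chain agreement of the inclusion probabilities is
#' reported as a convergence heuristic.
#'
#' @param m [marker_matrix()]
#' @param burnin discarded sweeps
#' @param iterations kept sweeps
#' @param thin thinning interval for stored samples
#' @param seed integer seed
#' @param prior_odds prior odds for neutrality (default 10, i.e. prior
#'   inclusion probability 1/11)
#' @param freq_model passed to [locus_freqs()]
#' @param slab_sd standard deviation of the slab prior on `alpha_i`
#' @return object of class `outlier_result` with per-locus posterior
#'   probability, `log10_bf`, `alpha` (posterior mean locus effect),
#'   decision flag, and `convergence` (max split-chain PP discrepancy)
#' @export
bayes_scan <- function(m, burnin = 2000, iterations = 8000, thin = 5,
                       seed, prior_odds = 10, freq_model = "haploid",
                       slab_sd = 3) {
  lf <- locus_freqs(m, freq_model)
  J <- nrow(lf$p); L <- ncol(lf$p)
  if (J < 2L) {
    res <- data.frame(locus = m$locus_ids, fst = NA_real_, pp = 0,
                      log10_bf = -Inf, outlier = FALSE)
    return(structure(list(per_locus = res, criteria = "bayes (single population)",
                          convergence = NA_real_),
                     class = "outlier_result"))
  }
  sizes <- lf$sizes
  k <- t(lf$p) * rep(sizes, each = L)      # L x J band counts
  nmat <- matrix(rep(sizes, each = L), nrow = L)
  pi_sel <- 1 / (1 + prior_odds)
  ll_cell <- function(eta, p, kv, nv) {
    # beta-binomial log likelihood per cell, vectorized over any shape
    fst <- 1 / (1 + exp(-eta))
    fst <- pmin(pmax(fst, 1e-8), 1 - 1e-8)
    th <- (1 - fst) / fst
    a <- th * p; b <- th * (1 - p)
    lbeta(a + kv, b + nv - kv) - lbeta(a, b)
  }
  loglik <- function(alpha, beta, p) {
    rowSums(ll_cell(outer(alpha, beta, "+"), p, k, nmat))
  }
  loglik_col <- function(alpha, beta_j, p, j) {
    ll_cell(alpha + beta_j, p, k[, j], nmat[, j])
  }
  with_seed(seed, {
    alpha <- rep(0, L); gamma <- rep(0L, L)
    beta <- rep(stats::qlogis(0.1), J)
    p <- pmin(pmax(rowMeans(t(lf$p)), 0.02), 0.98)
    ll <- loglik(alpha, beta, p)
    pp_acc <- numeric(L); alpha_acc <- numeric(L); n_acc <- 0L
    half <- numeric(L); n_half <- 0L
    total <- burnin + iterations
    for (it in seq_len(total)) {
      # ancestral frequencies p_i: random-walk MH per locus (vectorized)
      p_new <- pmin(pmax(p + stats::rnorm(L, 0, 0.05), 1e-3), 1 - 1e-3)
      ll_new <- loglik(alpha, beta, p_new)
      acc <- log(stats::runif(L)) < ll_new - ll
      p[acc] <- p_new[acc]; ll[acc] <- ll_new[acc]
      # locus effects: RJ toggle with slab proposal + RW refinement
      prop_alpha <- ifelse(gamma == 1L, 0, stats::rnorm(L, 0, slab_sd))
      ll_prop <- loglik(prop_alpha, beta, p)
      lr <- ll_prop - ll +
        ifelse(gamma == 1L, log(1 - pi_sel) - log(pi_sel),
               log(pi_sel) - log(1 - pi_sel))
      acc <- log(stats::runif(L)) < lr
      gamma[acc] <- 1L - gamma[acc]
      alpha[acc] <- prop_alpha[acc]; ll[acc] <- ll_prop[acc]
      on_idx <- gamma == 1L
      if (any(on_idx)) {
        a_new <- alpha
        a_new[on_idx] <- alpha[on_idx] + stats::rnorm(sum(on_idx), 0, 0.5)
        ll_new <- loglik(a_new, beta, p)
        pr <- stats::dnorm(a_new, 0, slab_sd, log = TRUE) -
          stats::dnorm(alpha, 0, slab_sd, log = TRUE)
        acc <- on_idx & (log(stats::runif(L)) < ll_new - ll + pr)
        alpha[acc] <- a_new[acc]; ll[acc] <- ll_new[acc]
      }
      # population effects: RW MH; only column j of the likelihood changes
      for (j in seq_len(J)) {
        bj_new <- beta[j] + stats::rnorm(1L, 0, 0.2)
        col_old <- loglik_col(alpha, beta[j], p, j)
        col_new <- loglik_col(alpha, bj_new, p, j)
        pr <- stats::dnorm(bj_new, -1, 1.8, log = TRUE) -
          stats::dnorm(beta[j], -1, 1.8, log = TRUE)
        if (log(stats::runif(1L)) < sum(col_new) - sum(col_old) + pr) {
          beta[j] <- bj_new
          ll <- ll + col_new - col_old
        }
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        pp_acc <- pp_acc + gamma
        alpha_acc <- alpha_acc + alpha
        n_acc <- n_acc + 1L
        if (it - burnin > iterations / 2) { half <- half + gamma; n_half <- n_half + 1L }
      }
    }
    pp <- pp_acc / n_acc
    pp_first <- (pp_acc - half) / (n_acc - n_half)
    pp_second <- half / n_half
    conv <- max(abs(pp_first - pp_second))
    bf <- (pp / pmax(1 - pp, 1 / n_acc)) / (pi_sel / (1 - pi_sel))
    obs <- fst_from_freqs(lf$p, sizes)
    res <- data.frame(locus = m$locus_ids, fst = obs$fst, het = obs$het,
                      pp = pp, log10_bf = log10(bf),
                      alpha = alpha_acc / n_acc,
                      outlier = bf > 100 & pp > 0.99,
                      stringsAsFactors = FALSE)
    structure(list(per_locus = res,
                   criteria = "bayes decisive (BF>100 & PP>0.99)",
                   prior_odds = prior_odds, convergence = conv),
              class = "outlier_result")
  })
}

#' Partition a marker matrix into neutral and outlier loci
#'
#' @param m [marker_matrix()]
#' @param outlier_ids locus ids (or an `outlier_result`, whose flagged loci
#'   are used)
#' @return list with `neutral` and `outliers` marker matrices (sample
#'   metadata preserved in both)
#' @export
partition_matrix <- function(m, outlier_ids) {
  stopifnot(inherits(m, "marker_matrix"))
  if (inherits(outlier_ids, "outlier_result"))
    outlier_ids <- outlier_ids$per_locus$locus[
      which(outlier_ids$per_locus$outlier)]
  unknown <- setdiff(outlier_ids, m$locus_ids)
  if (length(unknown)) stop("unknown locus ids: ",
                            paste(utils::head(unknown, 5L), collapse = ", "))
  is_out <- m$locus_ids %in% outlier_ids
  if (all(is_out)) warning("all loci flagged: neutral matrix is empty")
  mk <- function(sel) {
    structure(list(data = m$data[, sel, drop = FALSE],
                   sample_ids = m$sample_ids, species = m$species,
                   location = m$location, locus_ids = m$locus_ids[sel],
                   monomorphic = m$monomorphic[sel]),
              class = "marker_matrix")
  }
  list(neutral = mk(!is_out), outliers = mk(is_out))
}

#' Write a per-locus outlier report
#'
#' @param res `outlier_result`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_outlier_report <- function(res, path) {
  stopifnot(inherits(res, "outlier_result"))
  utils::write.table(res$per_locus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
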