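# Model-based admixture clustering of binary markers (Gibbs sampler with
# correlated allele frequencies), Evanno's delta-K model choice, the
# immigrant/grandparent ancestry test, and PCA.

#' Fit the admixture model to a binary marker matrix
#'
#' Bands are haploid Bernoulli characters: individual `i` at locus `l`
#' carries a latent cluster-of-origin `z_il` drawn from its ancestry
#' fractions `Q_i ~ Dirichlet(alpha)`, and the band is Bernoulli with the
#' cluster's frequency `P_kl`. Cluster frequencies follow the correlated
#' allele-frequencies prior: `P_kl ~ Beta(p_l (1-F_k)/F_k,
#' (1-p_l)(1-F_k)/F_k)` around an ancestral frequency `p_l ~
#' Beta(lambda, lambda)`, with a per-cluster drift parameter `F_k`. `alpha`,
#' `lambda` and `F_k` are updated by Metropolis steps; `z`, `Q`, `P` by
#' Gibbs. The model log-evidence `lnPD` uses the standard estimator
#' `mean(lnL) - var(lnL)/2` over the post-burn-in likelihood trace.
#' Replicates whose post-burn-in trace still drifts (total fitted drift
#' exceeding `slope_tol` times the trace standard deviation) are flagged
#' non-converged, mirroring the visual log-probability-vs-iteration
#' screening used for such runs.
#'
#' @param m [marker_matrix()]
#' @param K number of clusters (`>= 1`)
#' @param burnin discarded sweeps
#' @param iterations kept sweeps
#' @param n_reps independent replicate runs
#' @param seed integer seed
#' @param slope_tol convergence tolerance on the likelihood-trace slope
#' @param hyper_every update the hyperparameters (`p_l`, `F_k`, `alpha`,
#'   `lambda`) every this many sweeps; they mix slowly, so sparser updates
#'   trade negligible efficiency for substantial speed
#' @param init `"random"` starts each replicate from random ancestry (the
#'   classical behaviour; replicate scatter above the true K is part of
#'   the signal Evanno's delta-K exploits), `"kmeans"` seeds chains from a
#'   k-means partition of PCA scores (faster, for estimating Q at a known K)
#' @return list of `admixture_result` objects (one per replicate), each
#'   with `K`, `Q` (individuals x K), `P` (K x loci), `lnPD`, `alpha`,
#'   `lambda`, `drift`, `lnL_trace`, `converged`, `seed`
#' @export
fit_admixture <- function(m, K, burnin = 500, iterations = 2000, n_reps = 1,
                          seed, slope_tol = 3, hyper_every = 5L,
                          init = c("random", "kmeans")) {
  init <- match.arg(init)
  stopifnot(inherits(m, "marker_matrix"), K >= 1L)
  X <- m$data
  N <- nrow(X); L <- ncol(X)
  if (K > N) stop("K exceeds the number of individuals")
  # PCA scores for cluster-informed chain initialisation (computed once)
  scores <- if (K > 1L && init == "kmeans") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    pc$x[, seq_len(min(K, ncol(pc$x))), drop = FALSE]
  } else NULL
  lapply(seq_len(n_reps), function(rep_i) {
    rep_seed <- derive_seed(seed, rep_i)
    with_seed(rep_seed, {
      alpha <- 1; lambda <- 1
      drift <- rep(0.05, K)
      p_anc <- pmin(pmax(colMeans(X), 0.02), 0.98)
      # initialise ancestry near a k-means partition of the PCA scores;
      # each replicate uses a different random k-means start, so replicates
      # still explore alternative modes
      if (K > 1L && init == "kmeans") {
        km <- tryCatch(stats::kmeans(scores, centers = K, nstart = 1),
                       error = function(e) NULL)
        Q <- matrix(0.2 / K, N, K)
        if (!is.null(km))
          Q[cbind(seq_len(N), km$cluster)] <- Q[cbind(seq_len(N), km$cluster)] + 0.8
        Q <- Q + matrix(stats::rgamma(N * K, 0.5), N, K) * 0.1
        Q <- Q / rowSums(Q)
      } else if (K > 1L) {
        Q <- matrix(stats::rgamma(N * K, 1), N, K)
        Q <- Q / rowSums(Q)
      } else {
        Q <- matrix(1, N, 1L)
      }
      P <- matrix(stats::rbeta(K * L, 1, 1), K, L)
      lnL_trace <- numeric(iterations)   # z-marginalized log likelihood
      z_trace <- numeric(iterations)     # complete-data log likelihood
      Q_acc <- matrix(0, N, K); P_acc <- matrix(0, K, L); n_acc <- 0L
      total <- burnin + iterations
      lnL <- lnLz <- NA_real_
      for (it in seq_len(total)) {
        # z | Q, P sampled in compiled code (the hot loop)
        sw <- admixture_z_sweep(X, Q, P)
        zcount <- sw$zcount
        ones_k <- sw$ones
        tots_k <- sw$tots
        lnL <- sw$loglik
        lnLz <- sw$loglik_z
        # Q | z
        Q <- matrix(stats::rgamma(N * K, alpha + zcount), N, K)
        Q <- Q / rowSums(Q)
        # P | z, x with correlated-frequencies prior
        for (kk in seq_len(K)) {
          sc <- (1 - drift[kk]) / drift[kk]
          P[kk, ] <- stats::rbeta(L, p_anc * sc + ones_k[kk, ],
                                  (1 - p_anc) * sc + tots_k[kk, ] - ones_k[kk, ])
        }
        P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
        if (it %% hyper_every == 0L) {
        # ancestral frequencies p_l: MH against the K cluster Beta priors
        p_new <- pmin(pmax(p_anc + stats::rnorm(L, 0, 0.03), 1e-3), 1 - 1e-3)
        lp <- function(pv) {
          out <- stats::dbeta(pv, lambda, lambda, log = TRUE)
          for (kk in seq_len(K)) {
            sc <- (1 - drift[kk]) / drift[kk]
            out <- out + stats::dbeta(P[kk, ], pv * sc, (1 - pv) * sc, log = TRUE)
          }
          out
        }
        accv <- log(stats::runif(L)) < lp(p_new) - lp(p_anc)
        p_anc[accv] <- p_new[accv]
        # drift F_k: MH on log scale
        for (kk in seq_len(K)) {
          f_new <- exp(log(drift[kk]) + stats::rnorm(1L, 0, 0.3))
          if (f_new < 0.999) {
            sc_o <- (1 - drift[kk]) / drift[kk]; sc_n <- (1 - f_new) / f_new
            lr <- sum(stats::dbeta(P[kk, ], p_anc * sc_n, (1 - p_anc) * sc_n,
                                   log = TRUE) -
                      stats::dbeta(P[kk, ], p_anc * sc_o, (1 - p_anc) * sc_o,
                                   log = TRUE)) +
              stats::dexp(f_new, 10, log = TRUE) -
              stats::dexp(drift[kk], 10, log = TRUE) + log(f_new) - log(drift[kk])
            if (is.finite(lr) && log(stats::runif(1L)) < lr) drift[kk] <- f_new
          }
        }
        # alpha: MH with uniform(0, 10) prior
        a_new <- exp(log(alpha) + stats::rnorm(1L, 0, 0.2))
        if (a_new < 10) {
          lr <- sum(lgamma(K * a_new) - K * lgamma(a_new) +
                      (a_new - 1) * rowSums(log(pmax(Q, 1e-12)))) -
            sum(lgamma(K * alpha) - K * lgamma(alpha) +
                  (alpha - 1) * rowSums(log(pmax(Q, 1e-12)))) +
            log(a_new) - log(alpha)
          if (is.finite(lr) && log(stats::runif(1L)) < lr) alpha <- a_new
        }
        # lambda: MH with uniform(0, 10) prior
        l_new <- exp(log(lambda) + stats::rnorm(1L, 0, 0.2))
        if (l_new < 10) {
          lr <- sum(stats::dbeta(p_anc, l_new, l_new, log = TRUE) -
                      stats::dbeta(p_anc, lambda, lambda, log = TRUE)) +
            log(l_new) - log(lambda)
          if (is.finite(lr) && log(stats::runif(1L)) < lr) lambda <- l_new
        }
        }
        if (it > burnin) {
          lnL_trace[it - burnin] <- lnL
          z_trace[it - burnin] <- lnLz
          Q_acc <- Q_acc + Q; P_acc <- P_acc + P; n_acc <- n_acc + 1L
        }
      }
      # deviance-style evidence estimate on the z-marginalized trace (the
      # complete-data variant is kept in the trace for diagnostics; its
      # sweep-to-sweep variance is dominated by z churn at desk-scale
      # chain lengths, which swamps the fit signal)
      lnPD <- mean(lnL_trace) - stats::var(lnL_trace) / 2
      sl <- stats::coef(stats::lm(lnL_trace ~ seq_along(lnL_trace)))[2L]
      total_drift <- abs(sl) * iterations
      Qm <- Q_acc / n_acc
      rownames(Qm) <- m$sample_ids
      structure(list(K = K, Q = Qm, P = P_acc / n_acc, lnPD = lnPD,
                     alpha = alpha, lambda = lambda, drift = drift,
                     lnL_trace = lnL_trace,
                     converged = total_drift <=
                       slope_tol * max(stats::sd(lnL_trace), 1),
                     burnin = burnin, iterations = iterations,
                     seed = rep_seed),
                class = "admixture_result")
    })
  })
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: K=%d lnPD=%.1f alpha=%.2f converged=%s\n",
              x$K, x$lnPD, x$alpha, x$converged))
  invisible(x)
}

#' Evanno's delta-K from replicate admixture runs
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`
#' over replicate log-evidence estimates. Undefined at the boundary K
#' values; a zero replicate SD yields an infinite delta-K with a warning.
#'
#' @param runs list of `admixture_result` objects (replicates over a range
#'   of K), or a data.frame with columns `K` and `lnPD`
#' @param drop_nonconverged drop replicates flagged non-converged
#' @return object of class `evanno_result`: data.frame with `K`,
#'   `mean_lnPD`, `sd_lnPD`, `n_reps`, `deltaK`; `best_K` = argmax deltaK
#' @export
evanno_deltaK <- function(runs, drop_nonconverged = TRUE) {
  if (is.data.frame(runs)) {
    df <- runs
  } else {
    runs <- unlist(runs, recursive = FALSE)
    if (inherits(runs, "admixture_result")) runs <- list(runs)
    df <- data.frame(K = vapply(runs, function(r) r$K, 0),
                     lnPD = vapply(runs, function(r) r$lnPD, 0),
                     converged = vapply(runs, function(r)
                       isTRUE(r$converged), TRUE))
    if (drop_nonconverged) {
      # drop within each K only while at least two replicates survive
      keep <- unlist(lapply(split(seq_len(nrow(df)), df$K), function(idx) {
        ok <- df$converged[idx]
        if (sum(ok) >= 2L) idx[ok] else idx
      }))
      df <- df[sort(keep), ]
    }
  }
  agg <- do.call(rbind, lapply(split(df, df$K), function(g)
    data.frame(K = g$K[1L], mean_lnPD = mean(g$lnPD),
               sd_lnPD = stats::sd(g$lnPD), n_reps = nrow(g))))
  agg <- agg[order(agg$K), ]
  if (nrow(agg) < 3L) stop("need at least 3 consecutive K values")
  if (any(diff(agg$K) != 1L)) stop("K values must be consecutive")
  dK <- rep(NA_real_, nrow(agg))
  for (i in 2:(nrow(agg) - 1L)) {
    second <- abs(agg$mean_lnPD[i + 1L] - 2 * agg$mean_lnPD[i] +
                    agg$mean_lnPD[i - 1L])
    s <- agg$sd_lnPD[i]
    if (is.na(s)) s <- 0
    if (s == 0) {
      warning("zero SD at K=", agg$K[i], ": deltaK infinite")
      dK[i] <- if (second == 0) 0 else Inf
    } else dK[i] <- second / s
  }
  agg$deltaK <- dK
  best <- agg$K[which.max(ifelse(is.na(dK), -Inf, dK))]
  structure(list(table = agg, best_K = best), class = "evanno_result")
}

#' @export
print.evanno_result <- function(x, ...) {
  print(transform(x$table, mean_lnPD = round(mean_lnPD, 1),
                  deltaK = round(deltaK, 2)))
  cat("best K by deltaK:", x$best_K, "\n")
  invisible(x)
}

#' Immigrant and recent-immigrant-ancestry test
#'
#' With cluster frequencies informed by the labeled individuals, computes
#' for each individual the posterior over the hypothesis set: pure
#' ancestry in its labeled species, or an immigrant ancestor from each
#' other species `s` at generation `g = 0` (the individual itself),
#' `1` (a parent) up to `gb` (e.g. a grandparent at `gb = 2`). Under
#' hypothesis `(s, g)` each unlinked locus derives from `s` with
#' probability `2^-g` and from the labeled species otherwise. The prior
#' assigns `1 - nu` to pure ancestry and splits `nu` equally across source
#' species with weights halving per generation back (documented in the
#' vignette). Species frequencies are posterior-mean estimates with a
#' `Beta(lambda, lambda)` prior; an individual's own band is excluded from
#' its species' frequencies (leave-one-out) to avoid self-assignment bias.
#'
#' @param m [marker_matrix()]
#' @param labels species label per individual (defaults to `m$species`)
#' @param gb generations back tested (0, 1 or 2)
#' @param nu prior probability of misclassified or mixed ancestry
#' @param lambda Beta smoothing parameter for frequency estimation
#' @return object of class `ancestry_test`: `posterior` (individuals x
#'   hypotheses), `summary` data.frame with the pure-ancestry probability
#'   and the modal non-pure hypothesis, `nu`, `gb`
#' @export
ancestry_test <- function(m, labels = NULL, gb = 2, nu = 0.05, lambda = 1) {
  stopifnot(inherits(m, "marker_matrix"))
  labels <- labels %||% m$species
  if (!gb %in% 0:2) stop("gb must be 0, 1 or 2")
  if (nu <= 0 || nu >= 1) stop("nu must be in (0,1)")
  sps <- sort(unique(labels))
  J <- length(sps)
  if (J < 2L) stop("need at least 2 species")
  sizes <- vapply(sps, function(s) sum(labels == s), 0L)
  if (any(sizes < 2L))
    warning("species with < 2 labeled members: frequency estimates unreliable")
  X <- m$data
  N <- nrow(X); L <- ncol(X)
  counts <- do.call(rbind, lapply(sps, function(s)
    colSums(X[labels == s, , drop = FALSE])))
  hyp <- list(list(name = "pure", source = NA, g = NA))
  for (s in sps) for (g in 0:gb)
    hyp[[length(hyp) + 1L]] <- list(
      name = paste0(c("immigrant", "parent", "grandparent")[g + 1L], ":", s),
      source = s, g = g)
  prior <- numeric(length(hyp)); prior[1L] <- 1 - nu
  gw <- 2^(-(0:gb)); gw <- gw / sum(gw)
  for (h in 2:length(hyp))
    prior[h] <- nu / (J - 1) * gw[hyp[[h]]$g + 1L]
  post <- matrix(NA_real_, N, length(hyp),
                 dimnames = list(m$sample_ids,
                                 vapply(hyp, function(h) h$name, "")))
  for (i in seq_len(N)) {
    own <- labels[i]
    own_j <- match(own, sps)
    # leave-one-out frequency for the individual's own species
    fr <- (counts + lambda) / (sizes + 2 * lambda)
    cnt_own <- counts[own_j, ] - X[i, ]
    fr[own_j, ] <- (cnt_own + lambda) / (sizes[own_j] - 1 + 2 * lambda)
    x <- X[i, ]
    loglik_mix <- function(srcj, mix) {
      pl <- mix * fr[srcj, ] + (1 - mix) * fr[own_j, ]
      sum(log(ifelse(x == 1L, pl, 1 - pl)))
    }
    lp <- numeric(length(hyp))
    lp[1L] <- loglik_mix(own_j, 0) + log(prior[1L])
    for (h in 2:length(hyp)) {
      s <- hyp[[h]]$source
      if (s == own) { lp[h] <- -Inf; next }
      lp[h] <- loglik_mix(match(s, sps), 2^(-hyp[[h]]$g)) + log(prior[h])
    }
    lp <- lp - max(lp[is.finite(lp)])
    pr <- exp(lp); pr[!is.finite(pr)] <- 0
    post[i, ] <- pr / sum(pr)
  }
  nonpure <- post[, -1L, drop = FALSE]
  summary <- data.frame(
    sample_id = m$sample_ids, species = labels,
    p_no_immigrant_ancestry = post[, 1L],
    top_alternative = colnames(nonpure)[max.col(nonpure, ties.method = "first")],
    p_top_alternative = nonpure[cbind(seq_len(N),
                                      max.col(nonpure, ties.method = "first"))],
    stringsAsFactors = FALSE)
  structure(list(posterior = post, summary = summary, nu = nu, gb = gb),
            class = "ancestry_test")
}

#' @export
print.ancestry_test <- function(x, ...) {
  cat("ancestry_test (gb=", x$gb, ", nu=", x$nu, "): ",
      sum(x$summary$p_no_immigrant_ancestry < 0.5),
      " of ", nrow(x$summary), " individuals with majority non-pure posterior\n",
      sep = "")
  invisible(x)
}

#' PCA of a binary marker matrix
#'
#' Column-centered covariance PCA; scores per individual and percent
#' variance explained per component.
#'
#' @param m [marker_matrix()]
#' @param n_components components to return (default all)
#' @return list with `scores` (individuals x components) and
#'   `variance_explained` (percent, non-increasing)
#' @export
pca_binary <- function(m, n_components = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  X <- m$data
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need at least 2 samples and 2 loci")
  if (all(apply(X, 2L, function(cl) length(unique(cl)) == 1L)))
    stop("constant matrix: no variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- n_components %||% length(ve)
  k <- min(k, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = ve[seq_len(k)])
}

#' Match inferred clusters to true labels
#'
#' Greedy label matching between a Q matrix and known group labels,
#' handling label switching when scoring recovery on synthetic truth.
#'
#' @param Q individuals x K ancestry matrix
#' @param labels true group label per individual
#' @return list: `assignment` (cluster index per label), `accuracy`
#'   (fraction of individuals whose max-Q cluster matches their label's
#'   cluster)
#' @export
match_clusters <- function(Q, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  K <- ncol(Q)
  mean_q <- do.call(rbind, lapply(groups, function(g)
    colMeans(Q[labels == g, , drop = FALSE])))
  assignment <- integer(length(groups))
  avail <- seq_len(K)
  for (step in order(-apply(mean_q, 1L, max))) {
    pick <- avail[which.max(mean_q[step, avail])]
    assignment[step] <- pick
    avail <- setdiff(avail, pick)
    if (!length(avail)) avail <- seq_len(K)  # more groups than clusters
  }
  names(assignment) <- groups
  maxq <- max.col(Q, ties.method = "first")
  accuracy <- mean(maxq == assignment[labels])
  list(assignment = assignment, accuracy = accuracy)
}

#' Write a Q matrix in a plotter-friendly layout
#'
#' @param res `admixture_result`
#' @param m [marker_matrix()] supplying labels
#' @param path output file
#' @return `path`, invisibly
#' @export
write_q_matrix <- function(res, m, path) {
  df <- data.frame(sample_id = rownames(res$Q), species = m$species,
                   round(res$Q, 4), check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("Q", seq_len(ncol(res$Q)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
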