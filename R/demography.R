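# Mismatch distributions and the sudden-expansion demographic model.
#
# A population of scaled size theta0 = 2*mu*N0 expands instantaneously to
# theta1 = 2*mu*N1 at tau mutational time units before the present
# (tau = 2*u*t with u the per-sequence mutation rate). The expected
# distribution of pairwise differences follows from the pair coalescence
# time: hazard 1/theta1 up to tau (backwards in time), 1/theta0 beyond,
# with the number of differences Poisson(s) given coalescence at time s.
# Integrating gives, with a = (theta1+1)/theta1 and b = (theta0+1)/theta0,
#   F_i = theta1^i/(theta1+1)^(i+1) * P(i+1, a*tau)
#       + exp(tau/theta0 - tau/theta1) * theta0^i/(theta0+1)^(i+1) * Q(i+1, b*tau)
# where P and Q are the regularized lower/upper incomplete gamma functions;
# theta0 = 0 collapses the second term to exp(-tau/theta1) * Pois(i; tau).

#' Observed mismatch distribution
#'
#' Counts of pairwise sequence differences over all unordered pairs.
#' Masked sites are excluded; gaps are compared according to `gap_mode`
#' (fifth state: a gap mismatches any base; missing: sites with a gap or N
#' in either sequence are ignored for that pair).
#'
#' @param aln [seq_alignment()] (or character vector of equal-length strings)
#' @param gap_mode `"fifth_state"` or `"missing"`
#' @return list with `counts` (named vector over 0..max differences),
#'   `mean` (mean pairwise differences) and `n` (number of sequences)
#' @export
mismatch_observed <- function(aln, gap_mode = c("fifth_state", "missing")) {
  gap_mode <- match.arg(gap_mode)
  if (!inherits(aln, "seq_alignment"))
    aln <- seq_alignment(paste0("s", seq_along(aln)), aln)
  s <- aln$seq[, !aln$mask, drop = FALSE]
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 sequences")
  diffs <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    if (gap_mode == "fifth_state") {
      diffs[k] <- sum(s[i, ] != s[j, ])
    } else {
      ok <- !(s[i, ] %in% c("-", "N")) & !(s[j, ] %in% c("-", "N"))
      diffs[k] <- sum(s[i, ok] != s[j, ok])
    }
  }
  mx <- max(diffs)
  counts <- tabulate(diffs + 1L, nbins = mx + 1L)
  names(counts) <- 0:mx
  list(counts = counts, mean = mean(diffs), n = n)
}

#' Expected mismatch distribution under sudden expansion
#'
#' Probability of observing `i = 0..i_max` pairwise differences under the
#' instantaneous-expansion coalescent. Special cases: `tau = 0` gives the
#' geometric equilibrium of `theta0` (a point mass at 0 when `theta0 = 0`);
#' `theta0 = theta1` is the no-expansion equilibrium of that theta. The
#' vector sums to less than one by the tail mass beyond `i_max`.
#'
#' @param tau expansion time in mutational units (`>= 0`)
#' @param theta0 pre-expansion scaled size (`>= 0`)
#' @param theta1 post-expansion scaled size (`> 0` unless `tau = 0`)
#' @param i_max largest difference class computed
#' @return numeric vector of probabilities, names `0..i_max`
#' @export
expected_mismatch <- function(tau, theta0, theta1, i_max) {
  if (!all(is.finite(c(tau, theta0, theta1))) || tau < 0 || theta0 < 0 ||
      theta1 < 0)
    stop("parameters must be finite and non-negative")
  # numerically tiny thetas behave as zero (the general branch overflows)
  if (theta0 < 1e-8) theta0 <- 0
  if (theta1 < 1e-8) theta1 <- 0
  i <- 0:i_max
  geom <- function(th) if (th == 0) c(1, rep(0, i_max)) else
    exp(i * log(th) - (i + 1) * log(th + 1))
  if (tau == 0) {
    p <- geom(theta0)
  } else {
    if (theta1 == 0) {
      p <- c(1, rep(0, i_max))   # full coalescence before any mutation epoch
    } else {
      a <- (theta1 + 1) / theta1
      part1 <- geom(theta1) * stats::pgamma(a * tau, shape = i + 1)
      if (theta0 == 0) {
        part2 <- exp(-tau / theta1) * stats::dpois(i, tau)
      } else {
        # computed in log space: the prefactor exp(tau/theta0) overflows for
        # small theta0 while the gamma tail underformly cancels it
        b <- (theta0 + 1) / theta0
        lg <- i * log(theta0) - (i + 1) * log(theta0 + 1)
        lq <- stats::pgamma(b * tau, shape = i + 1, lower.tail = FALSE,
                            log.p = TRUE)
        part2 <- exp(tau / theta0 - tau / theta1 + lg + lq)
      }
      p <- part1 + part2
    }
  }
  names(p) <- i
  p
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over the relative frequencies
#' `x_0..x_d` of the mismatch distribution, with `x_{d+1} = 0`. Smooth
#' unimodal spectra (expanding populations) give small values.
#'
#' @param freqs relative frequency vector (sums to 1)
#' @return raggedness index
#' @export
raggedness <- function(freqs) {
  if (any(freqs < 0)) stop("negative frequencies")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  x <- c(freqs, 0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to an observed mismatch distribution
#'
#' Least-squares fit of `(tau, theta0, theta1)` minimising the sum of
#' squared deviations (SSD) between observed relative frequencies and
#' [expected_mismatch()], via a coarse grid followed by Nelder-Mead
#' refinement on log-transformed parameters. `theta1` is capped at 99999;
#' fits at the cap are flagged (`theta1_capped`) as effectively unbounded.
#' The goodness-of-fit p-value is a parametric bootstrap: datasets of the
#' same sample size are simulated under the fitted model
#' ([simulate_expansion_sequences()]), refitted, and `p_SSD` is the
#' fraction of simulated SSDs at least as large as the observed SSD (small
#' p rejects the expansion model).
#'
#' @param counts observed counts over difference classes `0..d` (vector)
#' @param n_seq number of sequences behind the counts (needed for the
#'   bootstrap); when `counts` comes from [mismatch_observed()] pass its `n`
#' @param n_boot parametric bootstrap replicates (0 skips the test)
#' @param seed integer seed for the bootstrap
#' @param theta1_cap upper bound for `theta1` (default 99999)
#' @return object of class `mismatch_fit`: `tau`, `theta0`, `theta1`,
#'   `mean_pairwise_diff`, `SSD`, `p_SSD`, `raggedness`, `theta1_capped`,
#'   `n_boot`, `converged`
#' @export
fit_sudden_expansion <- function(counts, n_seq, n_boot = 1000, seed = NULL,
                                 theta1_cap = 99999) {
  if (is.list(counts) && !is.null(counts$counts)) {
    if (missing(n_seq)) n_seq <- counts$n
    counts <- counts$counts
  }
  counts <- as.numeric(counts)
  if (n_seq < 3L) stop("need counts from at least 3 sequences")
  if (sum(counts) <= 0) stop("empty mismatch distribution")
  obs <- counts / sum(counts)
  d <- length(obs) - 1L
  mean_d <- sum((0:d) * obs)
  i_max <- d
  ssd_of <- function(par) {
    e <- expected_mismatch(par[1L], par[2L], par[3L], i_max)
    sum((obs - e)^2)
  }
  fit_once <- function(o, start = NULL) {
    obs_local <- o
    m <- sum((0:(length(o) - 1L)) * o)
    f <- function(p) {
      tau <- min(exp(p[1L]) - 1e-8, 1e6)
      th0 <- exp(p[2L]) - 1e-6
      th1 <- min(exp(p[3L]), theta1_cap)
      if (tau < 0) tau <- 0
      if (th0 < 0) th0 <- 0
      e <- expected_mismatch(tau, th0, th1, length(o) - 1L)
      v <- sum((obs_local - e)^2)
      if (!is.finite(v)) 1e10 else v
    }
    grid_tau <- unique(pmax(0, c(0, 0.25, 0.5, 1, 1.5, 2, 3, m / 2, m, 2 * m)))
    grid_th0 <- unique(c(0, 0.01, 0.1, 0.5, 1, 2, 5, m))
    grid_th1 <- unique(c(0.5, 1, 3, 10, 100, 1000, theta1_cap, max(m, 0.5)))
    best <- NULL; best_v <- Inf
    for (tt in grid_tau) for (t0 in grid_th0) for (t1 in grid_th1) {
      e <- expected_mismatch(tt, t0, t1, length(o) - 1L)
      v <- sum((obs_local - e)^2)
      if (v < best_v) { best_v <- v; best <- c(tt, t0, t1) }
    }
    if (!is.null(start)) {
      e <- expected_mismatch(start[1L], start[2L], start[3L], length(o) - 1L)
      v <- sum((obs_local - e)^2)
      if (v < best_v) { best_v <- v; best <- start }
    }
    p0 <- c(log(best[1L] + 1e-8), log(best[2L] + 1e-6),
            log(min(best[3L], theta1_cap)))
    op <- stats::optim(p0, f, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-9))
    tau <- min(max(0, exp(op$par[1L]) - 1e-8), 1e6)
    th0 <- max(0, exp(op$par[2L]) - 1e-6)
    th1 <- min(exp(op$par[3L]), theta1_cap)
    ssd <- op$value
    # the model is non-identifiable along tau -> Inf (an infinitely old
    # expansion is the theta1 equilibrium); prefer the parsimonious
    # no-expansion fit whenever it explains the spectrum as well
    eq_theta <- grid_th0[-1]
    eq_ssd <- vapply(eq_theta, function(t0)
      sum((obs_local - expected_mismatch(0, t0, t0, length(o) - 1L))^2), 0)
    eq_best <- stats::optimize(function(t0)
      sum((obs_local - expected_mismatch(0, t0, t0, length(o) - 1L))^2),
      interval = c(0, max(eq_theta[which.min(eq_ssd)] * 4, 1)))
    if (eq_best$objective <= ssd + 1e-9) {
      tau <- 0; th0 <- th1 <- eq_best$minimum; ssd <- eq_best$objective
    }
    list(par = c(tau = tau, theta0 = th0, theta1 = th1), ssd = ssd,
         converged = op$convergence == 0L)
  }
  ft <- fit_once(obs)
  if (!ft$converged)
    warning("sudden-expansion optimizer did not report convergence")
  p_ssd <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed required for the parametric bootstrap")
    sims <- with_seed(seed, {
      vapply(seq_len(n_boot), function(r) {
        L <- max(2000L, ceiling(50 * (mean_d + ft$par[["tau"]] + 1)))
        sim <- simulate_expansion_sequences(
          theta0 = ft$par[["theta0"]], theta1 = ft$par[["theta1"]],
          tau = ft$par[["tau"]], n = n_seq, L = L,
          seed = sample.int(2147483646L, 1L))
        mm <- mismatch_observed(sim)
        o <- mm$counts / sum(mm$counts)
        fb <- fit_once(o, start = ft$par)
        fb$ssd
      }, 0)
    })
    p_ssd <- mean(sims >= ft$ssd)
  }
  structure(list(tau = unname(ft$par["tau"]), theta0 = unname(ft$par["theta0"]),
                 theta1 = unname(ft$par["theta1"]),
                 mean_pairwise_diff = mean_d, SSD = ft$ssd, p_SSD = p_ssd,
                 raggedness = raggedness(obs),
                 theta1_capped = ft$par[["theta1"]] >= theta1_cap * (1 - 1e-6),
                 n_boot = n_boot, converged = ft$converged),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf(
    "mismatch_fit: tau=%.3f theta0=%.4f theta1=%s SSD=%.5f p=%.3f r=%.4f\n",
    x$tau, x$theta0,
    if (x$theta1_capped) format(x$theta1) else sprintf("%.3f", x$theta1),
    x$SSD, x$p_SSD, x$raggedness))
  invisible(x)
}

#' Convert expansion time between mutational and calendar units
#'
#' `tau = 2*u*t` with `u` the per-sequence per-year mutation rate, so
#' `t = tau/(2u)` and `u = mu_site * L / 1e6` when `mu_site` is given in
#' substitutions per site per million years per lineage. When rates are
#' supplied per generation instead, multiply by `gen_time` externally; the
#' conversion itself is generation-time free.
#'
#' @param tau expansion time in mutational units
#' @param mu_site substitutions per site per million years per lineage
#' @param L sequence length in sites
#' @return years since expansion
#' @export
expansion_time <- function(tau, mu_site, L) {
  if (mu_site <= 0 || L <= 0) stop("rate and length must be positive")
  u <- mu_site * L / 1e6
  tau / (2 * u)
}

#' Implied per-sequence mutation rate from an expansion time
#'
#' Inverse of [expansion_time()]: `u = tau/(2 t)` per sequence per year.
#' Dividing by a per-site rate gives the implied sequence length, a useful
#' internal-consistency check on published rate/time pairs.
#'
#' @param tau expansion time in mutational units
#' @param t_years years since expansion
#' @return per-sequence per-year mutation rate
#' @export
implied_mu <- function(tau, t_years) {
  if (t_years <= 0) stop("time must be positive")
  tau / (2 * t_years)
}

#' Per-population mismatch report
#'
#' Fits the sudden-expansion model per population and assembles the
#' standard summary rows (sample size, mean pairwise differences, tau,
#' theta0, theta1, SSD with bootstrap p, raggedness).
#'
#' @param aln [seq_alignment()]
#' @param populations factor/character of population labels per sequence
#' @param n_boot bootstrap replicates per population
#' @param seed integer seed
#' @param gap_mode passed to [mismatch_observed()]
#' @return data.frame, one row per population
#' @export
mismatch_report <- function(aln, populations, n_boot = 1000, seed,
                            gap_mode = "fifth_state") {
  stopifnot(inherits(aln, "seq_alignment"))
  pops <- sort(unique(populations))
  rows <- lapply(seq_along(pops), function(k) {
    idx <- populations == pops[k]
    sub <- seq_alignment(aln$ids[idx], aln$seq[idx, , drop = FALSE], aln$mask)
    mm <- mismatch_observed(sub, gap_mode)
    ft <- fit_sudden_expansion(mm$counts, n_seq = mm$n, n_boot = n_boot,
                               seed = derive_seed(seed, k))
    data.frame(population = pops[k], n = mm$n, mean_diff = mm$mean,
               tau = ft$tau, theta0 = ft$theta0, theta1 = ft$theta1,
               SSD = ft$SSD, p_SSD = ft$p_SSD, raggedness = ft$raggedness,
               theta1_capped = ft$theta1_capped, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
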