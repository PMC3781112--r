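# F-statistics and AMOVA on squared molecular distances, permutation tests,
# private-allele accounting, and the summary arithmetic for published
# pairwise FST/PhiST tables.

# Sums of squares for a one-level AMOVA from a squared-distance matrix.
# SS_total = sum_{i<j} d2/N ; SS_within = sum_g sum_{i<j in g} d2/n_g.
amova_ss <- function(d2, groups) {
  N <- nrow(d2)
  ut <- upper.tri(d2)
  ss_total <- sum(d2[ut]) / N
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# One-level AMOVA variance components (Excoffier-style expected mean squares).
amova_components <- function(d2, groups) {
  N <- nrow(d2)
  sizes <- table(groups)
  G <- length(sizes)
  ss <- amova_ss(d2, groups)
  df_among <- G - 1L
  df_within <- N - G
  ms_among <- ss[["among"]] / df_among
  ms_within <- ss[["within"]] / df_within
  n_prime <- (N - sum(sizes^2) / N) / df_among
  sigma_a <- (ms_among - ms_within) / n_prime
  sigma_w <- ms_within
  phi <- if (sigma_a + sigma_w == 0) 0 else sigma_a / (sigma_a + sigma_w)
  list(df = c(among = df_among, within = df_within),
       SS = ss, sigma = c(among = sigma_a, within = sigma_w), phi = phi)
}

#' Pairwise FST/PhiST with permutation tests
#'
#' For every pair of groups the statistic is the among-groups proportion of
#' total molecular variance from a two-group AMOVA on the squared
#' distances. Significance is assessed by permuting individuals between the
#' two groups; p-values are adjusted by sequential Bonferroni (Holm) across
#' pairs by default. Negative estimates (possible when within-group
#' variance exceeds the between-group signal) are reported unclamped.
#'
#' The supplied distances are interpreted as squared molecular distances
#' (`squared = TRUE`), the convention for pairwise-difference counts
#' between binary profiles or haplotypes; set `squared = FALSE` to square a
#' metric distance first.
#'
#' @param d [binary_distance()] result or symmetric matrix with dimnames
#' @param labels group label per individual (matrix order)
#' @param n_perm permutations per pair (default 10100)
#' @param seed integer seed
#' @param squared are the supplied distances already squared?
#' @param p_adjust method for [stats::p.adjust()] (`"holm"` = sequential
#'   Bonferroni; `"none"` to disable)
#' @return object of class `flock_popdiff`: `stat` and `p` matrices,
#'   `method`, `n_perm`, `p_adjust`
#' @export
pairwise_fst <- function(d, labels, n_perm = 10100, seed, squared = TRUE,
                         p_adjust = "holm") {
  mat <- as_dist_matrix(d)
  if (!squared) mat <- mat^2
  labels <- as.character(labels)
  if (length(labels) != nrow(mat)) stop("labels/matrix size mismatch")
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("groups of size 1: ", paste(names(sizes)[sizes < 2L], collapse = ", "))
  G <- length(groups)
  stat <- p <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  pairs <- utils::combn(G, 2L)
  raw_p <- numeric(ncol(pairs))
  with_seed(seed, {
    for (k in seq_len(ncol(pairs))) {
      g1 <- groups[pairs[1L, k]]; g2 <- groups[pairs[2L, k]]
      idx <- which(labels %in% c(g1, g2))
      sub <- mat[idx, idx, drop = FALSE]
      lab <- labels[idx]
      obs <- amova_components(sub, lab)$phi
      if (sum(sub[upper.tri(sub)]) == 0) {
        warning("pair ", g1, "/", g2, " has zero total variance; FST set to 0")
        obs <- 0
      }
      perm <- vapply(seq_len(n_perm), function(r)
        amova_components(sub, sample(lab))$phi, 0)
      stat[g2, g1] <- stat[g1, g2] <- obs
      raw_p[k] <- (sum(perm >= obs) + 1) / (n_perm + 1)
    }
  })
  adj <- stats::p.adjust(raw_p, method = p_adjust)
  for (k in seq_len(ncol(pairs))) {
    g1 <- groups[pairs[1L, k]]; g2 <- groups[pairs[2L, k]]
    p[g2, g1] <- p[g1, g2] <- adj[k]
  }
  structure(list(stat = stat, p = p,
                 method = if (inherits(d, "flock_dist")) d$method else "matrix",
                 n_perm = n_perm, p_adjust = p_adjust),
            class = "flock_popdiff")
}

#' @export
print.flock_popdiff <- function(x, ...) {
  cat("flock_popdiff (", x$method, "), ", x$n_perm, " permutations, ",
      x$p_adjust, "-adjusted p\n", sep = "")
  print(round(x$stat, 3))
  invisible(x)
}

#' Hierarchical AMOVA
#'
#' Analysis of molecular variance on squared distances. With only `groups`,
#' a one-level analysis (among/within groups); with `subgroups` nested in
#' `groups`, the standard three-component nested analysis (among groups,
#' among subgroups within groups, within subgroups). Permutation p-values
#' permute individuals across groups (one-level) or across subgroups
#' within/among as appropriate.
#'
#' @param d distance matrix or [binary_distance()] result
#' @param groups top-level label per individual
#' @param subgroups optional nested label per individual
#' @param n_perm permutations
#' @param seed integer seed
#' @param squared are distances already squared?
#' @return object of class `flock_amova`: data.frame `table` with df, SS,
#'   variance components, percent of variation, p; plus `phi` statistics
#' @export
amova <- function(d, groups, subgroups = NULL, n_perm = 1000, seed,
                  squared = TRUE) {
  mat <- as_dist_matrix(d)
  if (!squared) mat <- mat^2
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L)
    stop("a single group: among-group component undefined")
  if (is.null(subgroups)) {
    comp <- amova_components(mat, groups)
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(r)
      amova_components(mat, sample(groups))$phi, 0))
    p <- (sum(perm >= comp$phi) + 1) / (n_perm + 1)
    tot <- sum(comp$sigma)
    pct <- if (tot == 0) c(0, 100) else 100 * as.numeric(comp$sigma) / tot
    tab <- data.frame(
      source = c("among groups", "within groups"),
      df = as.integer(comp$df),
      SS = c(comp$SS[["among"]], comp$SS[["within"]]),
      sigma = as.numeric(comp$sigma),
      percent = pct,
      p = c(p, NA), stringsAsFactors = FALSE)
    return(structure(list(table = tab, phi = c(phi_ST = comp$phi)),
                     class = "flock_amova"))
  }
  # nested: among groups (AG), among subgroups within groups (ASWG), within
  subgroups <- as.character(subgroups)
  N <- nrow(mat)
  sub_of <- tapply(groups, subgroups, function(g) g[1L])
  nested_components <- function(groups, subgroups) {
    ss_g <- amova_ss(mat, groups)          # among groups / within groups
    ss_s <- amova_ss(mat, subgroups)       # among subgroups / within subgroups
    G <- length(unique(groups)); S <- length(unique(subgroups))
    df_a <- G - 1L; df_b <- S - G; df_w <- N - S
    ss_a <- ss_g[["among"]]
    ss_w <- ss_s[["within"]]
    ss_b <- ss_g[["within"]] - ss_w
    sizes_s <- table(subgroups)
    sizes_g <- table(groups)
    # expected mean squares coefficients (Excoffier 1992)
    sg_by_g <- tapply(subgroups, groups, function(x) table(x))
    n1 <- (N - sum(unlist(lapply(sg_by_g, function(t) sum(t^2))) /
                     as.numeric(sizes_g[names(sg_by_g)]))) / df_b
    n2 <- (sum(unlist(lapply(names(sg_by_g), function(g)
            sum(sg_by_g[[g]]^2) / sizes_g[[g]]))) -
           sum(sizes_s^2) / N) / df_a
    n3 <- (N - sum(sizes_g^2) / N) / df_a
    ms_a <- ss_a / df_a; ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
    sig_w <- ms_w
    sig_b <- (ms_b - sig_w) / n1
    sig_a <- (ms_a - sig_w - n2 * sig_b) / n3
    list(df = c(df_a, df_b, df_w), SS = c(ss_a, ss_b, ss_w),
         sigma = c(sig_a, sig_b, sig_w))
  }
  comp <- nested_components(groups, subgroups)
  tot <- sum(comp$sigma)
  phi_ct <- comp$sigma[1L] / tot
  phi_sc <- comp$sigma[2L] / sum(comp$sigma[2:3])
  phi_st <- sum(comp$sigma[1:2]) / tot
  perms <- with_seed(seed, {
    replicate(n_perm, {
      # permute whole subgroups among groups for the top component
      sg <- unique(subgroups)
      new_g <- sample(as.character(sub_of[sg]))
      g2 <- new_g[match(subgroups, sg)]
      nested_components(g2, subgroups)$sigma[1L]
    })
  })
  p_a <- (sum(perms >= comp$sigma[1L]) + 1) / (n_perm + 1)
  tab <- data.frame(
    source = c("among groups", "among subgroups within groups",
               "within subgroups"),
    df = as.integer(comp$df), SS = comp$SS, sigma = comp$sigma,
    percent = 100 * comp$sigma / tot,
    p = c(p_a, NA, NA), stringsAsFactors = FALSE)
  structure(list(table = tab,
                 phi = c(phi_CT = phi_ct, phi_SC = phi_sc, phi_ST = phi_st)),
            class = "flock_amova")
}

#' @export
print.flock_amova <- function(x, ...) {
  print(transform(x$table, percent = round(percent, 2)))
  cat("Phi:", paste(names(x$phi), round(x$phi, 4), collapse = "  "), "\n")
  invisible(x)
}

#' Private and fixed private bands per species
#'
#' A band is private to a species when present in at least one of its
#' members and absent from all other individuals; fixed private when
#' additionally present in every member of that species.
#'
#' @param m [marker_matrix()]
#' @return data.frame with `species`, `private`, `fixed_private`
#' @export
private_alleles <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  sps <- sort(unique(m$species))
  res <- lapply(sps, function(s) {
    inside <- m$data[m$species == s, , drop = FALSE]
    outside <- m$data[m$species != s, , drop = FALSE]
    priv <- colSums(inside) >= 1L & colSums(outside) == 0L
    fixed <- priv & colSums(inside) == nrow(inside)
    data.frame(species = s, private = sum(priv), fixed_private = sum(fixed),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Summary arithmetic on paired full/neutral FST and PhiST estimates
#'
#' Given per-pair estimates from the complete marker matrix and from the
#' neutral (outlier-free) matrix, computes the report statistics: the mean
#' relative excess of the distance-based PhiST over the
#' pairwise-difference FST (`(Phi - F)/Phi`), the mean relative decrease of
#' each statistic after outlier removal (`(full - neutral)/full`), the
#' maximum per-pair decrease, and the Pearson correlation between the two
#' statistics on the complete matrix.
#'
#' @param tbl data.frame with columns `fst_full`, `phi_full`,
#'   `fst_neutral`, `phi_neutral` (one row per species pair)
#' @return list of summary statistics (percent scales)
#' @export
fst_change_summary <- function(tbl) {
  need <- c("fst_full", "phi_full", "fst_neutral", "phi_neutral")
  if (!all(need %in% names(tbl)))
    stop("table must have columns ", paste(need, collapse = ", "))
  excess <- 100 * (tbl$phi_full - tbl$fst_full) / tbl$phi_full
  dec_f <- 100 * (tbl$fst_full - tbl$fst_neutral) / tbl$fst_full
  dec_p <- 100 * (tbl$phi_full - tbl$phi_neutral) / tbl$phi_full
  list(phi_excess_mean = mean(excess), phi_excess_sd = stats::sd(excess),
       fst_decrease_mean = mean(dec_f), fst_decrease_sd = stats::sd(dec_f),
       phi_decrease_mean = mean(dec_p), phi_decrease_sd = stats::sd(dec_p),
       max_decrease = max(dec_f),
       fst_phi_correlation = stats::cor(tbl$fst_full, tbl$phi_full),
       n_pairs = nrow(tbl))
}

#' Read a published pairwise FST/PhiST table
#'
#' Tab-separated with columns `pair`, `fst_full`, `phi_full`,
#' `fst_neutral`, `phi_neutral`. Comma decimal separators (as printed in
#' some journals) are accepted on input; the package always writes dots.
#'
#' @param path file; defaults to the bundled table of published pairwise
#'   estimates for the six-species Lake Apoyo Midas cichlid flock
#' @return data.frame
#' @export
read_pairwise_fst_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "apoyo_pairwise_fst.tsv",
                        package = "flockpopgen")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  for (col in setdiff(names(tab), "pair")) tab[[col]] <- parse_decimal(tab[[col]])
  tab
}

#' Tab-separated report of a pairwise differentiation analysis
#'
#' Writes the statistic matrix lower-left with p-values upper-right,
#' mirroring the conventional published layout.
#'
#' @param pd [pairwise_fst()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_popdiff_report <- function(pd, path) {
  stopifnot(inherits(pd, "flock_popdiff"))
  out <- pd$stat
  out[upper.tri(out)] <- pd$p[upper.tri(pd$p)]
  df <- data.frame(group = rownames(out), round(out, 4), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "-")
  invisible(path)
}
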