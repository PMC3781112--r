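# Haplotype collapsing and median-joining networks for mtDNA alignments.

#' Collapse aligned sequences into haplotypes
#'
#' Two sequences share a haplotype iff they are identical at all unmasked
#' sites under the chosen gap handling:
#' \describe{
#'   \item{fifth_state}{the gap character `-` is a fifth character state;
#'     comparison is exact identity (`N` is likewise its own state)}
#'   \item{missing}{`-` and `N` are treated as missing data: sites where
#'     either sequence is missing are ignored in the comparison. Matching
#'     under missing data is not transitive, so sequences are assigned
#'     greedily in input order to the first compatible haplotype.}
#' }
#' Haplotypes are ordered by descending frequency, ties broken by first
#' occurrence in the alignment.
#'
#' @param aln [seq_alignment()]
#' @param gap_mode `"fifth_state"` (default) or `"missing"`
#' @return object of class `haplotype_set`: `seqs` (character matrix of
#'   haplotype sequences at unmasked sites), `members` (list of sample ids),
#'   `freq` (counts), `species_table` (haplotype x species counts when the
#'   alignment carries a `species` attribute), `gap_mode`
#' @export
collapse_haplotypes <- function(aln, gap_mode = c("fifth_state", "missing")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(aln, "seq_alignment"))
  if (length(aln$ids) == 0L) stop("empty alignment")
  s <- aln$seq[, !aln$mask, drop = FALSE]
  n <- nrow(s)
  assign_idx <- integer(n)
  reps <- list()   # representative char vectors
  if (gap_mode == "fifth_state") {
    keys <- apply(s, 1L, paste, collapse = "")
    uk <- unique(keys)
    assign_idx <- match(keys, uk)
    reps <- lapply(uk, function(k) strsplit(k, "")[[1L]])
  } else {
    for (i in seq_len(n)) {
      si <- s[i, ]
      hit <- 0L
      for (h in seq_along(reps)) {
        rh <- reps[[h]]
        cmp <- !(si %in% c("-", "N")) & !(rh %in% c("-", "N"))
        if (all(si[cmp] == rh[cmp])) {
          hit <- h
          # refine representative where it was missing
          fill <- (rh %in% c("-", "N")) & !(si %in% c("-", "N"))
          rh[fill] <- si[fill]
          reps[[h]] <- rh
          break
        }
      }
      if (hit == 0L) { reps[[length(reps) + 1L]] <- si; hit <- length(reps) }
      assign_idx[i] <- hit
    }
  }
  freq <- tabulate(assign_idx, nbins = length(reps))
  ord <- order(-freq, vapply(seq_along(reps),
                             function(h) min(which(assign_idx == h)), 0L))
  remap <- match(seq_along(reps), ord)
  assign_idx <- remap[assign_idx]
  reps <- reps[ord]
  freq <- freq[ord]
  members <- split(aln$ids, assign_idx)
  names(members) <- paste0("H", seq_along(reps))
  seqs <- do.call(rbind, reps)
  rownames(seqs) <- names(members)
  species <- attr(aln, "species")
  sp_tab <- NULL
  if (!is.null(species)) {
    sp_tab <- table(haplotype = names(members)[assign_idx], species = species)
  }
  structure(list(seqs = seqs, members = members, freq = freq,
                 species_table = sp_tab, gap_mode = gap_mode),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$seqs), "haplotypes from", sum(x$freq),
      "sequences; modal frequency",
      sprintf("%.2f%%", 100 * max(x$freq) / sum(x$freq)), "\n")
  invisible(x)
}

# --- median-joining machinery ------------------------------------------------

hamming_mat <- function(s) {
  n <- nrow(s)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- sum(s[i, ] != s[j, ])
  d
}

# Union of all minimum spanning trees within epsilon of the MST criterion:
# process weight classes in ascending order; every edge of weight w (<= class
# minimum + epsilon) joining components formed by strictly cheaper classes is
# retained, then components are merged.
msn_links <- function(d, epsilon = 0L) {
  n <- nrow(d)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  edges <- which(upper.tri(d), arr.ind = TRUE)
  ew <- d[edges]
  ord <- order(ew, edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]; ew <- ew[ord]
  keep <- matrix(integer(0), ncol = 3L)
  i <- 1L
  while (i <= length(ew)) {
    w <- ew[i]
    block <- which(ew >= w & ew <= w + epsilon)
    block <- block[block >= i]
    # edges in this class joining distinct current components
    cand <- block[vapply(block, function(k)
      find(edges[k, 1L]) != find(edges[k, 2L]), TRUE)]
    keep <- rbind(keep, cbind(edges[cand, , drop = FALSE], ew[cand]))
    # merge strictly the minimal class only, then advance past it
    cls <- which(ew == w)
    for (k in cls) {
      a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
    i <- max(cls) + 1L
  }
  colnames(keep) <- c("from", "to", "weight")
  unique(keep)
}

mst_weight <- function(d) {
  n <- nrow(d)
  if (n <= 1L) return(0)
  intree <- c(1L, rep(0L, n - 1L))
  mind <- d[1L, ]
  total <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(intree == 0L)
    j <- cand[which.min(mind[cand])]
    total <- total + mind[j]
    intree[j] <- 1L
    mind <- pmin(mind, d[j, ])
  }
  total
}

# Candidate median (consensus) vectors of a sequence triplet: positionwise
# majority; where all three states differ, each of the three states is a
# candidate (quasi-median expansion), capped to avoid blowup.
median_candidates <- function(a, b, c, cap = 81L) {
  L <- length(a)
  states <- rbind(a, b, c)
  cand <- list(character(L))
  cand[[1L]] <- a
  fixed <- character(L)
  free <- integer(0)
  for (p in seq_len(L)) {
    st <- states[, p]
    tab <- table(st)
    if (max(tab) >= 2L) fixed[p] <- names(tab)[which.max(tab)]
    else { fixed[p] <- NA_character_; free <- c(free, p) }
  }
  if (length(free) == 0L) return(list(fixed))
  if (3L^length(free) > cap) return(list())
  grids <- expand.grid(rep(list(1:3), length(free)))
  out <- vector("list", nrow(grids))
  for (g in seq_len(nrow(grids))) {
    v <- fixed
    for (k in seq_along(free)) v[free[k]] <- states[grids[g, k], free[k]]
    out[[g]] <- v
  }
  out
}

#' Median-joining haplotype network
#'
#' Implements the median-joining construction: iterated minimum-spanning
#' network over the current node set (with tolerance `epsilon`), addition of
#' median (consensus) vectors for linked triplets whenever they reduce the
#' total minimum-spanning-tree weight, and removal of obsolete median
#' vectors (unobserved nodes of degree below three). The resulting network
#' contains every minimum spanning tree of the final node set. Gaps are a
#' fifth character state, consistent with [collapse_haplotypes()].
#' Tie-breaking is lexicographic throughout, so the construction is
#' deterministic given the input order.
#'
#' @param hs [collapse_haplotypes()] result, or a character matrix of
#'   haplotype sequences (rows)
#' @param epsilon integer tolerance on the spanning criterion (default 0)
#' @return object of class `haplo_network`: `nodes` (data.frame with `id`,
#'   `sequence`, `observed`, `freq`), `edges` (data.frame `from`, `to`,
#'   `weight` in mutational steps)
#' @export
median_joining_network <- function(hs, epsilon = 0L) {
  seqs <- if (inherits(hs, "haplotype_set")) hs$seqs else as.matrix(hs)
  freq <- if (inherits(hs, "haplotype_set")) hs$freq else rep(1L, nrow(seqs))
  if (nrow(seqs) < 1L) stop("need at least one haplotype")
  n_obs <- nrow(seqs)
  U <- seqs
  labels <- rownames(seqs) %||% paste0("H", seq_len(n_obs))
  rownames(U) <- labels
  repeat {
    if (nrow(U) < 3L) break
    d <- hamming_mat(U)
    base_w <- mst_weight(d)
    in_U <- apply(U, 1L, paste, collapse = "")
    # candidate medians from every sequence triple, deduplicated
    cand <- new.env(hash = TRUE, parent = emptyenv())
    trips <- utils::combn(nrow(U), 3L)
    for (tcol in seq_len(ncol(trips))) {
      for (mv in median_candidates(U[trips[1L, tcol], ], U[trips[2L, tcol], ],
                                   U[trips[3L, tcol], ])) {
        key <- paste(mv, collapse = "")
        if (!key %in% in_U && is.null(cand[[key]])) cand[[key]] <- mv
      }
    }
    keys <- sort(ls(cand))
    best <- NULL; best_w <- base_w
    for (key in keys) {
      mv <- cand[[key]]
      dm <- vapply(seq_len(nrow(U)), function(r) sum(U[r, ] != mv), 0L)
      w <- mst_weight(rbind(cbind(d, dm), c(dm, 0L)))
      if (w < best_w - 1e-9) { best <- mv; best_w <- w }
    }
    if (is.null(best)) break
    U <- rbind(U, best)
    rownames(U)[nrow(U)] <- paste0("mv", nrow(U) - n_obs)
  }
  # final network + pruning of obsolete medians
  repeat {
    d <- hamming_mat(U)
    links <- if (nrow(U) > 1L) msn_links(d, epsilon) else
      matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("from", "to", "weight")))
    deg <- tabulate(c(links[, 1L], links[, 2L]), nbins = nrow(U))
    obsolete <- which(deg < 3L & seq_len(nrow(U)) > n_obs)
    if (!length(obsolete)) break
    U <- U[-obsolete, , drop = FALSE]
  }
  ids <- rownames(U)
  nodes <- data.frame(id = ids,
                      sequence = apply(U, 1L, paste, collapse = ""),
                      observed = seq_len(nrow(U)) <= n_obs,
                      freq = c(freq, rep(0L, nrow(U) - n_obs)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[links[, 1L]], to = ids[links[, 2L]],
                      weight = as.integer(links[, 3L]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", sum(x$nodes$observed), "observed +",
      sum(!x$nodes$observed), "median nodes,", nrow(x$edges),
      "edges (total weight", sum(x$edges$weight), ")\n")
  invisible(x)
}

#' Export a haplotype network as an edge list or GML
#'
#' @param net [median_joining_network()] result
#' @param path output file
#' @param format `"edgelist"` (tab-separated) or `"gml"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("edgelist", "gml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "haplo_network"))
  if (format == "edgelist") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("graph [", con)
    for (i in seq_len(nrow(net$nodes)))
      writeLines(sprintf(
        '  node [ id %d label "%s" observed %d freq %d ]',
        i, net$nodes$id[i], as.integer(net$nodes$observed[i]),
        net$nodes$freq[i]), con)
    idx <- stats::setNames(seq_len(nrow(net$nodes)), net$nodes$id)
    for (e in seq_len(nrow(net$edges)))
      writeLines(sprintf('  edge [ source %d target %d weight %d ]',
                         idx[[net$edges$from[e]]], idx[[net$edges$to[e]]],
                         net$edges$weight[e]), con)
    writeLines("]", con)
  }
  invisible(path)
}
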