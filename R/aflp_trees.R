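# Distances on binary marker matrices, neighbor-joining trees, locus
# bootstrapping, and the tree-based hybridization diagnostics (leaf
# stability, lineage movement, homoplasy-excess removal experiments).

#' Pairwise distances from a binary marker matrix
#'
#' For two individuals let `a` be the number of loci where both show the
#' band, and `b`, `c` the discordant counts. Methods:
#' \describe{
#'   \item{jaccard}{`d = 1 - a/(a+b+c)`}
#'   \item{link}{band-sharing (Dice) distance `d = 1 - 2a/(2a+b+c)`, the
#'     dominant-marker measure of band-sharing similarity}
#'   \item{p_distance}{`(b+c)/L`, the proportion of differing loci}
#' }
#' `link` is never larger than `jaccard` for the same pair. Pairs with no
#' band in either individual (`a+b+c = 0`) are undefined under `jaccard`
#' and `link` and raise an error.
#'
#' @param m [marker_matrix()]
#' @param method one of `"link"`, `"jaccard"`, `"p_distance"`
#' @return object of class `flock_dist`: `ids`, symmetric `mat`, `method`
#' @export
binary_distance <- function(m, method = c("link", "jaccard", "p_distance")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "marker_matrix"))
  x <- m$data
  if (nrow(x) < 2L) stop("need at least 2 samples")
  a <- tcrossprod(x)                       # shared presences
  bc <- tcrossprod(x, 1L - x)              # b (and its transpose is c)
  disc <- bc + t(bc)
  tot <- a + disc
  if (method %in% c("jaccard", "link")) {
    bad <- which(tot == 0 & upper.tri(tot), arr.ind = TRUE)
    if (nrow(bad))
      stop("all-absent pair under ", method, ": ",
           m$sample_ids[bad[1L, 1L]], " / ", m$sample_ids[bad[1L, 2L]])
  }
  d <- switch(method,
    jaccard    = 1 - a / tot,
    link       = 1 - 2 * a / (2 * a + disc),
    p_distance = disc / ncol(x))
  diag(d) <- 0
  dimnames(d) <- list(m$sample_ids, m$sample_ids)
  structure(list(ids = m$sample_ids, mat = d, method = method),
            class = "flock_dist")
}

#' @export
print.flock_dist <- function(x, ...) {
  cat("flock_dist (", x$method, "): ", length(x$ids), " samples\n", sep = "")
  invisible(x)
}

as_dist_matrix <- function(d) {
  if (inherits(d, "flock_dist")) return(d$mat)
  m <- as.matrix(d)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  m
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with the deficit moved to the adjacent branch on the same internal
#' node (smallest node index first, for determinism), preserving path
#' lengths through that node as closely as possible.
#'
#' @param d [binary_distance()] result or symmetric matrix with dimnames
#' @return unrooted `ape::phylo`
#' @export
nj_tree <- function(d) {
  mat <- as_dist_matrix(d)
  if (!isSymmetric(unname(mat), tol = 1e-8)) stop("distance matrix not symmetric")
  if (nrow(mat) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(mat)
  neg <- which(tr$edge.length < 0)
  for (e in sort(neg)) {
    deficit <- tr$edge.length[e]          # negative
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent | tr$edge[, 2L] == parent), e)
    if (length(sib)) {
      s <- sib[1L]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + deficit)
    }
  }
  tr
}

# --- bipartition machinery ---------------------------------------------------

# Canonical key of a bipartition: the side NOT containing the reference
# (lexicographically smallest) taxon, as a sorted, "|"-joined label string.
bipart_key <- function(side, all_taxa) {
  ref <- min(all_taxa)
  if (ref %in% side) side <- setdiff(all_taxa, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' @param tree `ape::phylo`
#' @return named list: canonical key -> character vector of taxa on the side
#'   not containing the reference taxon
#' @keywords internal
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  pp <- ape::prop.part(tree)
  out <- list()
  for (cl in pp) {
    if (length(cl) <= 1L || length(cl) >= n - 1L) next
    side <- tips[cl]
    key <- bipart_key(side, tips)
    if (nchar(key) && !identical(key, paste(sort(tips), collapse = "|")))
      out[[key]] <- strsplit(key, "|", fixed = TRUE)[[1L]]
  }
  # prop.part gives rooted clades; for an unrooted tree the complement of a
  # clade is the same bipartition, which bipart_key already canonicalises.
  out
}

#' Locus bootstrap of the neighbor-joining tree
#'
#' Loci (columns) are resampled with replacement; individuals never are.
#' Each replicate matrix is converted to distances and an NJ tree; clade
#' support is the percentage of replicates containing the bipartition.
#'
#' @param m [marker_matrix()]
#' @param n_reps number of bootstrap replicates
#' @param method distance method passed to [binary_distance()]
#' @param seed integer seed (required; resampling is the only randomness)
#' @return object of class `flock_bootstrap`: `tree` (NJ on the full
#'   matrix, with `node.label` support), `supports` (named % vector over
#'   bipartition keys of the full tree), `trees` (list of replicate trees),
#'   `taxa`, `n_reps`, `method`
#' @export
bootstrap_support <- function(m, n_reps, method = "link", seed) {
  stopifnot(inherits(m, "marker_matrix"), n_reps >= 1L)
  full <- nj_tree(binary_distance(m, method))
  L <- ncol(m$data)
  trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(L, L, replace = TRUE)
      mb <- m
      mb$data <- m$data[, idx, drop = FALSE]
      mb$locus_ids <- m$locus_ids[idx]
      tryCatch(nj_tree(binary_distance(mb, method)),
               error = function(e) stop("bootstrap replicate ", r, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
  })
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in trees) {
    for (key in names(tree_bipartitions(tr))) {
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  full_bip <- tree_bipartitions(full)
  supports <- vapply(names(full_bip),
                     function(k) 100 * (counts[[k]] %||% 0L) / n_reps, 0)
  full <- annotate_supports(full, supports)
  structure(list(tree = full, supports = supports, trees = trees,
                 taxa = m$sample_ids, n_reps = n_reps, method = method,
                 all_counts = counts),
            class = "flock_bootstrap")
}

# write supports onto node labels of the full tree
annotate_supports <- function(tree, supports) {
  tips <- tree$tip.label
  n <- length(tips)
  labs <- character(tree$Nnode)
  pp <- ape::prop.part(tree)
  for (i in seq_along(pp)) {
    cl <- tips[pp[[i]]]
    if (length(cl) <= 1L || length(cl) >= n - 1L) { labs[i] <- ""; next }
    key <- bipart_key(cl, tips)
    labs[i] <- if (key %in% names(supports))
      sprintf("%.0f", supports[[key]]) else ""
  }
  tree$node.label <- labs
  tree
}

#' @export
print.flock_bootstrap <- function(x, ...) {
  cat("flock_bootstrap:", x$n_reps, "replicates,", length(x$taxa), "taxa,",
      length(x$supports), "clades\n")
  invisible(x)
}

# Topological (all edges = 1) cophenetic distances among tips of a tree,
# ordered by the supplied taxa vector.
topo_dist <- function(tree, taxa) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  d <- ape::cophenetic.phylo(t2)
  d[taxa, taxa]
}

#' Leaf-stability index
#'
#' For each taxon, over all quartets containing it, the mean (across
#' quartets) of the maximum relative frequency among the three possible
#' quartet resolutions across the bootstrap trees. Equals 1 exactly when
#' every quartet containing the taxon resolves identically in all trees.
#'
#' @param bs [bootstrap_support()] result (or a list of `phylo` trees over
#'   the same taxa)
#' @param taxa optional taxon subset to report (all by default)
#' @return named numeric vector of LS values in `[0,1]`
#' @export
leaf_stability <- function(bs, taxa = NULL) {
  trees <- if (inherits(bs, "flock_bootstrap")) bs$trees else bs
  all_taxa <- sort(trees[[1L]]$tip.label)
  if (length(all_taxa) < 4L) stop("need at least 4 taxa")
  if (length(trees) < 2L) stop("need at least 2 trees")
  if (is.null(taxa)) taxa <- all_taxa
  n <- length(all_taxa)
  q <- utils::combn(n, 4L)                 # quartets, columns
  nq <- ncol(q)
  # frequency of each of the 3 resolutions per quartet
  freq <- matrix(0L, nrow = 3L, ncol = nq)
  for (tr in trees) {
    d <- topo_dist(tr, all_taxa)
    a <- q[1L, ]; b <- q[2L, ]; cc <- q[3L, ]; dd <- q[4L, ]
    s1 <- d[cbind(a, b)] + d[cbind(cc, dd)]   # ab|cd
    s2 <- d[cbind(a, cc)] + d[cbind(b, dd)]   # ac|bd
    s3 <- d[cbind(a, dd)] + d[cbind(b, cc)]   # ad|bc
    s <- rbind(s1, s2, s3)
    mins <- apply(s, 2L, min)
    resolved <- colSums(s == rep(mins, each = 3L)) == 1L
    pick <- max.col(t(-s), ties.method = "first")
    sel <- which(resolved)
    if (length(sel))
      freq[cbind(pick[sel], sel)] <- freq[cbind(pick[sel], sel)] + 1L
  }
  maxfreq <- apply(freq, 2L, max) / length(trees)
  ls <- vapply(taxa, function(tx) {
    i <- match(tx, all_taxa)
    mean(maxfreq[colSums(q == i) > 0L])
  }, 0)
  names(ls) <- taxa
  ls
}

# Does `side` (character set) occur as one side of a bipartition of `tree`?
has_split <- function(tree, side) {
  tips <- tree$tip.label
  side <- intersect(side, tips)
  if (length(side) < 1L || length(side) > length(tips) - 1L) return(FALSE)
  if (length(side) == 1L || length(side) == length(tips) - 1L) return(TRUE)
  key <- bipart_key(side, tips)
  key %in% names(tree_bipartitions(tree))
}

#' Lineage-movement diagnostics
#'
#' Tabulates, across bootstrap trees, where a query group attaches relative
#' to a reference group. Per tree the query is classified as:
#' \describe{
#'   \item{dispersed}{the query taxa do not form a bipartition}
#'   \item{outside}{some bipartition groups the query exclusively with taxa
#'     outside the reference (to the exclusion of all reference taxa)}
#'   \item{inside}{some bipartition nests the query strictly within
#'     reference taxa}
#'   \item{basal}{monophyletic but attached at a mixed node (neither of the
#'     above)}
#' }
#' A per-alternative breakdown reports, for trees with a monophyletic
#' query, the species signature of the smallest adjacent subtree.
#'
#' @param bs [bootstrap_support()] result or list of trees
#' @param query character vector of query taxa
#' @param reference character vector of reference taxa, disjoint from query
#' @param species optional named vector taxon -> species used to label the
#'   attachment breakdown
#' @return list with `percent` (named: outside, inside, basal, dispersed)
#'   and `attachment` (% table over sister-group signatures)
#' @export
lineage_movement <- function(bs, query, reference, species = NULL) {
  trees <- if (inherits(bs, "flock_bootstrap")) bs$trees else bs
  taxa <- trees[[1L]]$tip.label
  if (length(intersect(query, reference))) stop("query and reference overlap")
  if (!all(query %in% taxa)) stop("query taxa absent from trees")
  if (!all(reference %in% taxa)) stop("reference taxa absent from trees")
  others <- setdiff(taxa, c(query, reference))
  cls <- character(length(trees))
  sisters <- character(0)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (length(query) > 1L && !has_split(tr, query)) { cls[i] <- "dispersed"; next }
    bip <- tree_bipartitions(tr)
    sides <- lapply(bip, function(s) list(s = s, c = setdiff(taxa, s)))
    outside <- inside <- FALSE
    for (sd in sides) {
      for (side in list(sd$s, sd$c)) {
        if (all(query %in% side) && length(side) > length(query)) {
          if (!any(reference %in% side)) outside <- TRUE
          if (!any(others %in% side)) inside <- TRUE
        }
      }
    }
    cls[i] <- if (outside) "outside" else if (inside) "inside" else "basal"
    # sister signature: smallest strict superset side minus query
    best <- NULL
    for (sd in sides) for (side in list(sd$s, sd$c)) {
      if (all(query %in% side) && length(side) > length(query))
        if (is.null(best) || length(side) < length(best)) best <- side
    }
    if (!is.null(best)) {
      sis <- setdiff(best, query)
      lab <- if (!is.null(species)) sort(unique(species[sis])) else sort(sis)
      sisters <- c(sisters, paste(lab, collapse = "+"))
    }
  }
  pct <- 100 * table(factor(cls, levels = c("outside", "inside", "basal",
                                            "dispersed"))) / length(trees)
  att <- if (length(sisters)) sort(100 * table(sisters) / length(trees),
                                   decreasing = TRUE) else table(character(0))
  list(percent = c(pct), attachment = att)
}

#' Homoplasy-excess removal experiments
#'
#' Hybrid taxa introduce homoplasy: removing a hybrid should increase
#' bootstrap support for clades containing its parental lineages, while
#' removing non-hybrids should leave supports unchanged up to Monte-Carlo
#' noise. For each removal set the matrix is reduced, the locus bootstrap
#' recomputed, and every original clade re-evaluated after restricting its
#' bipartition to the retained taxa (clades that become trivial are
#' reported as `NA`).
#'
#' @param m [marker_matrix()]
#' @param removal_sets list of character vectors of sample ids to remove
#' @param n_reps bootstrap replicates per experiment
#' @param method distance method
#' @param seed integer seed
#' @param baseline optional precomputed [bootstrap_support()] on the full
#'   matrix (recomputed when `NULL`)
#' @return object of class `flock_removal`: data.frame with columns
#'   `experiment`, `clade`, `support_before`, `support_after`, `delta`
#' @export
homoplasy_excess_scan <- function(m, removal_sets, n_reps, method = "link",
                                  seed, baseline = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  if (is.null(names(removal_sets)))
    names(removal_sets) <- paste0("rm", seq_along(removal_sets))
  if (is.null(baseline))
    baseline <- bootstrap_support(m, n_reps, method, seed = derive_seed(seed, 0L))
  full_bip <- tree_bipartitions(baseline$tree)
  out <- list()
  for (j in seq_along(removal_sets)) {
    rmset <- removal_sets[[j]]
    keep <- !(m$sample_ids %in% rmset)
    if (sum(keep) < 4L) stop("removal set '", names(removal_sets)[j],
                             "' leaves fewer than 4 taxa")
    mr <- marker_matrix(m$data[keep, , drop = FALSE], m$sample_ids[keep],
                        m$species[keep],
                        location = if (is.null(m$location)) NULL else m$location[keep],
                        locus_ids = m$locus_ids, warn_monomorphic = FALSE)
    bsr <- bootstrap_support(mr, n_reps, method, seed = derive_seed(seed, j))
    kept_taxa <- mr$sample_ids
    counts <- bsr$all_counts
    for (key in names(full_bip)) {
      side <- intersect(full_bip[[key]], kept_taxa)
      comp <- setdiff(kept_taxa, side)
      after <- if (length(side) < 2L || length(comp) < 2L) NA_real_ else {
        rkey <- bipart_key(side, kept_taxa)
        100 * (counts[[rkey]] %||% 0L) / n_reps
      }
      out[[length(out) + 1L]] <- data.frame(
        experiment = names(removal_sets)[j], clade = key,
        support_before = unname(baseline$supports[key]),
        support_after = after,
        delta = after - unname(baseline$supports[key]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("flock_removal", class(res))
  res
}
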