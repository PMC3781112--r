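# Readers/writers for the interchange formats the pipeline touches:
# aligned FASTA, tab-separated binary marker matrices with sample metadata,
# newick trees and NEXUS distance blocks.

#' Construct a sequence alignment object
#'
#' Container for an aligned set of sequences over `{A,C,G,T,-,N}` plus an
#' excluded-site mask. Masked sites are ignored by all downstream comparisons
#' (haplotype collapsing, mismatch distributions). Site indices in the mask
#' are 1-based as reported to the user.
#'
#' @param ids character vector of unique sequence identifiers
#' @param seqs character vector of aligned sequences (equal length) or a
#'   character matrix (rows = sequences)
#' @param mask logical vector, `TRUE` = site excluded; defaults to all-false
#' @return an object of class `seq_alignment` with elements `ids`,
#'   `seq` (character matrix, one row per sequence) and `mask`
#' @export
seq_alignment <- function(ids, seqs, mask = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("unaligned input: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else {
    seqs <- matrix(toupper(seqs), nrow = nrow(seqs))
  }
  if (length(ids) != nrow(seqs)) stop("ids/sequence count mismatch")
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(mask)) mask <- rep(FALSE, ncol(seqs))
  if (length(mask) != ncol(seqs)) stop("mask length must equal alignment length")
  rownames(seqs) <- ids
  structure(list(ids = as.character(ids), seq = seqs, mask = as.logical(mask)),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", length(x$ids), "sequences x", ncol(x$seq), "sites (",
      sum(x$mask), "masked )\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Records must all have the same length (the alignment is assumed to be
#' built upstream). Sequences are uppercased; the excluded-site mask is
#' initialised all-false and can be set afterwards (e.g. to drop
#' unalignable repeat regions).
#'
#' @param path FASTA file
#' @return [seq_alignment()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) > 1L)
    stop("unaligned input: record lengths differ in ", path)
  chars <- lapply(as.character(recs), toupper)   # list of char vectors
  seqs <- do.call(rbind, chars)
  seq_alignment(names(recs), seqs)
}

#' Write an alignment to FASTA
#'
#' Masked sites are written as-is; the mask is analysis state, not data.
#'
#' @param aln [seq_alignment()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"))
  lines <- character(2L * length(aln$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a binary marker matrix
#'
#' Individuals x loci presence/absence matrix (dominant markers such as AFLP
#' bands) with a species label per individual and an optional sampling
#' location. Monomorphic loci are permitted but flagged with a warning, since
#' they carry no information for any downstream statistic.
#'
#' @param data numeric matrix over `{0,1}`, rows = individuals
#' @param sample_ids unique individual identifiers
#' @param species species label per individual
#' @param location optional sampling-location label per individual
#' @param locus_ids locus identifiers; default `L1..Ln`
#' @param warn_monomorphic warn about monomorphic loci (default `TRUE`)
#' @return object of class `marker_matrix`
#' @export
marker_matrix <- function(data, sample_ids, species, location = NULL,
                          locus_ids = NULL, warn_monomorphic = TRUE) {
  data <- as.matrix(data)
  bad <- which(!(data %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(data))
    stop("marker matrix value not in {0,1} at row ", rc[1], " (",
         sample_ids[rc[1]], "), column ", rc[2])
  }
  storage.mode(data) <- "integer"
  if (length(sample_ids) != nrow(data)) stop("sample_ids/rows mismatch")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(species) != nrow(data)) stop("species labels/rows mismatch")
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(data)))
  if (length(locus_ids) != ncol(data)) stop("locus_ids/columns mismatch")
  dimnames(data) <- list(sample_ids, locus_ids)
  mono <- colSums(data) %in% c(0L, nrow(data))
  if (warn_monomorphic && any(mono))
    warning(sum(mono), " monomorphic loci: ",
            paste(utils::head(locus_ids[mono], 5L), collapse = ", "),
            if (sum(mono) > 5L) ", ...")
  structure(list(data = data, sample_ids = as.character(sample_ids),
                 species = as.character(species),
                 location = if (is.null(location)) NULL else as.character(location),
                 locus_ids = as.character(locus_ids),
                 monomorphic = unname(mono)),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$data), "individuals x", ncol(x$data), "loci;",
      length(unique(x$species)), "species\n")
  invisible(x)
}

#' Read a binary marker matrix and its sample metadata
#'
#' The matrix file is tab-separated with a header row of locus ids and sample
#' ids in the first column. The metadata file maps `sample_id` to `species`
#' and (optionally) `location`. Every sample must have a species label;
#' values are coerced strictly from `{0,1}`.
#'
#' @param path matrix file
#' @param metadata_path metadata file with columns `sample_id`, `species`
#'   and optionally `location`
#' @return [marker_matrix()]
#' @export
read_marker_matrix <- function(path, metadata_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE, colClasses = "character")
  md <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "species") %in% names(md)))
    stop("metadata must have columns sample_id and species")
  ids <- rownames(tab)
  missing <- setdiff(ids, md$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  md <- md[match(ids, md$sample_id), , drop = FALSE]
  num <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("value '", tab[bad[1L, 1L], bad[1L, 2L]], "' not in {0,1} at sample ",
         ids[bad[1L, 1L]], ", locus ", colnames(tab)[bad[1L, 2L]])
  marker_matrix(num, sample_ids = ids, species = md$species,
                location = if ("location" %in% names(md)) md$location else NULL,
                locus_ids = colnames(tab))
}

#' Write a binary marker matrix and metadata to tab-separated files
#'
#' @param m [marker_matrix()]
#' @param path output matrix file
#' @param metadata_path output metadata file
#' @return `path`, invisibly
#' @export
write_marker_matrix <- function(m, path, metadata_path) {
  stopifnot(inherits(m, "marker_matrix"))
  df <- as.data.frame(m$data, check.names = FALSE)
  utils::write.table(cbind(sample_id = m$sample_ids, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = m$sample_ids, species = m$species,
                   stringsAsFactors = FALSE)
  if (!is.null(m$location)) md$location <- m$location
  utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a phylogenetic tree to newick
#'
#' Branch lengths are printed with six decimals and internal-node support
#' values (if present as `node.label`) are rendered as internal labels.
#' Output always uses dot decimal separators.
#'
#' @param tree an `ape::phylo` object with labelled leaves
#' @param path optional file; when `NULL` the newick string is returned
#' @return newick string (invisibly when written to file)
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled leaves")
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt_len <- function(e) {
    if (is.null(tree$edge.length)) "" else
      sprintf(":%.6f", tree$edge.length[e])
  }
  rec <- function(node, edge_in) {
    if (node <= n_tip)
      return(paste0(tree$tip.label[node], fmt_len(edge_in)))
    kids <- children[[as.character(node)]]
    inner <- paste(vapply(kids, function(e) rec(tree$edge[e, 2L], e), ""),
                   collapse = ",")
    lab <- if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - n_tip]
      if (is.na(l) || !nzchar(l)) "" else l
    } else ""
    paste0("(", inner, ")", lab, if (is.na(edge_in)) "" else fmt_len(edge_in))
  }
  root <- n_tip + 1L
  txt <- paste0(rec(root, NA_integer_), ";")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Read a newick tree
#'
#' @param path file or a newick string via `text`
#' @param text newick string (alternative to `path`)
#' @return `ape::phylo`
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}

#' Export a distance matrix as a NEXUS distances block
#'
#' For loading into external split-network software (Neighbor-Net viewers).
#'
#' @param d [binary_distance()] result or a plain symmetric matrix with
#'   dimnames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_nexus_distance <- function(d, path) {
  mat <- if (inherits(d, "flock_dist")) d$mat else as.matrix(d)
  ids <- rownames(mat)
  if (is.null(ids)) stop("distance matrix must have row names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", nrow(mat)),
               "  TAXLABELS",
               paste0("    ", ids), "  ;", "END;", "", "BEGIN DISTANCES;",
               sprintf("  DIMENSIONS NTAX=%d;", nrow(mat)),
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;", "  MATRIX"), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste0("    ", ids[i], " ",
                      paste(sprintf("%.6f", mat[i, ]), collapse = " ")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
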