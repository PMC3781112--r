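# End-to-end orchestration: simulate (or load) -> distances/trees/
# diagnostics -> haplotypes/demography -> F-statistics/AMOVA -> outlier
# partition -> admixture/PCA, with per-stage seeds derived from a master
# seed and a manifest of every artifact written.

#' Build a pipeline run configuration
#'
#' Either a simulation source (a [flock_config()]) or input paths
#' (`marker_path` + `metadata_path`, optionally `fasta_path`). Every
#' stochastic stage receives a seed derived deterministically from the
#' master seed, so a rerun with the same configuration reproduces all
#' outputs.
#'
#' @param out_dir output directory
#' @param seed master seed
#' @param sim_config optional [flock_config()] simulation source
#' @param marker_path,metadata_path,fasta_path input files when not
#'   simulating
#' @param stages character vector of stages to run; subset of
#'   `c("simulate", "distance", "tree", "diagnostics", "haplotypes",
#'   "mismatch", "fstats", "amova", "outliers", "partition", "admixture",
#'   "pca")`
#' @param distance_method distance for trees and F-statistics
#' @param n_boot bootstrap replicates (trees)
#' @param n_perm permutations (F-statistics, AMOVA)
#' @param k_range K values for admixture
#' @param n_reps_admixture replicates per K
#' @param mcmc list with `burnin` and `iterations`
#' @param alpha_fdist quantile level of the island-model scan
#' @param nu_list misclassification priors for the ancestry test
#' @param mismatch_boot parametric bootstrap replicates for mismatch fits
#' @return object of class `flock_run_config`
#' @export
flock_run_config <- function(out_dir, seed, sim_config = NULL,
                             marker_path = NULL, metadata_path = NULL,
                             fasta_path = NULL,
                             stages = c("simulate", "distance", "tree",
                                        "diagnostics", "haplotypes",
                                        "mismatch", "fstats", "amova",
                                        "outliers", "partition", "admixture",
                                        "pca"),
                             distance_method = "link",
                             n_boot = 200, n_perm = 500,
                             k_range = NULL, n_reps_admixture = 2,
                             mcmc = list(burnin = 300, iterations = 1200),
                             alpha_fdist = 0.99,
                             nu_list = c(0.1, 0.05, 0.01),
                             mismatch_boot = 100) {
  if (is.null(sim_config) && (is.null(marker_path) || is.null(metadata_path)))
    stop("either sim_config or marker_path + metadata_path required")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 sim_config = sim_config, marker_path = marker_path,
                 metadata_path = metadata_path, fasta_path = fasta_path,
                 stages = stages, distance_method = distance_method,
                 n_boot = n_boot, n_perm = n_perm, k_range = k_range,
                 n_reps_admixture = n_reps_admixture, mcmc = mcmc,
                 alpha_fdist = alpha_fdist, nu_list = nu_list,
                 mismatch_boot = mismatch_boot),
            class = "flock_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order, writing every
#' artifact under `out_dir` together with a JSON manifest recording file
#' checksums, stage parameters and seeds. Stages depending on the outlier
#' partition are skipped with an explicit notice when the outlier scan is
#' not in the stage list. A stage failure halts the run naming the stage.
#'
#' @param cfg [flock_run_config()]
#' @param quiet suppress progress messages
#' @return list of stage results (invisibly contains the manifest path)
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "flock_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[flockpopgen] ", ...)
  manifest <- list(seed = cfg$seed, stages = list(), files = list())
  results <- list()
  t_all <- Sys.time()
  record <- function(stage, files, params) {
    manifest$stages[[stage]] <<- list(params = params,
                                      seed = derive_seed(cfg$seed,
                                                         match(stage, all_stages)))
    for (f in files)
      manifest$files[[basename(f)]] <<- list(stage = stage,
                                             md5 = unname(tools::md5sum(f)))
  }
  all_stages <- c("simulate", "distance", "tree", "diagnostics", "haplotypes",
                  "mismatch", "fstats", "amova", "outliers", "partition",
                  "admixture", "pca")
  run_stage <- function(stage, expr) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    say("stage ", stage)
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage ", stage, " done in ",
        sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  # --- inputs -----------------------------------------------------------
  if (!is.null(cfg$sim_config) && "simulate" %in% cfg$stages) {
    sim <- run_stage("simulate", simulate_flock(cfg$sim_config))
    paths <- write_flock(sim, file.path(cfg$out_dir, "simulated"))
    record("simulate", paths, list(n_loci = cfg$sim_config$n_loci,
                                   seed = cfg$sim_config$seed))
    markers <- sim$markers
    aln <- sim$alignment
    results$simulate <- sim
  } else {
    markers <- read_marker_matrix(cfg$marker_path, cfg$metadata_path)
    aln <- if (!is.null(cfg$fasta_path)) read_fasta(cfg$fasta_path) else NULL
  }
  sp <- markers$species
  # --- distances and trees ---------------------------------------------
  d <- run_stage("distance", binary_distance(markers, cfg$distance_method))
  if (!is.null(d)) {
    f <- file.path(cfg$out_dir, "distances.nex")
    write_nexus_distance(d, f)
    record("distance", f, list(method = cfg$distance_method))
    results$distance <- d
  }
  bs <- run_stage("tree", bootstrap_support(markers, cfg$n_boot,
                                            cfg$distance_method,
                                            seed = derive_seed(cfg$seed, 3L)))
  if (!is.null(bs)) {
    f <- file.path(cfg$out_dir, "nj_tree.nwk")
    write_newick(bs$tree, f)
    record("tree", f, list(n_boot = cfg$n_boot))
    results$tree <- bs
  }
  diag <- run_stage("diagnostics", {
    ls_idx <- leaf_stability(bs)
    f <- file.path(cfg$out_dir, "leaf_stability.tsv")
    utils::write.table(data.frame(sample_id = names(ls_idx),
                                  leaf_stability = ls_idx),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    record("diagnostics", f, list(n_trees = length(bs$trees)))
    ls_idx
  })
  if (!is.null(diag)) results$diagnostics <- diag
  # --- mtDNA ------------------------------------------------------------
  if (!is.null(aln)) {
    hs <- run_stage("haplotypes", {
      hs <- collapse_haplotypes(aln)
      net <- median_joining_network(hs)
      f <- file.path(cfg$out_dir, "haplotype_network.tsv")
      write_network(net, f)
      record("haplotypes", f, list(n_haplotypes = nrow(hs$seqs)))
      list(haplotypes = hs, network = net)
    })
    if (!is.null(hs)) results$haplotypes <- hs
    mfit <- run_stage("mismatch", {
      species_of <- attr(aln, "species") %||%
        sp[match(aln$ids, markers$sample_ids)]
      rep <- mismatch_report(aln, species_of, n_boot = cfg$mismatch_boot,
                             seed = derive_seed(cfg$seed, 5L))
      f <- file.path(cfg$out_dir, "mismatch_report.tsv")
      utils::write.table(rep, f, sep = "\t", quote = FALSE, row.names = FALSE)
      record("mismatch", f, list(n_boot = cfg$mismatch_boot))
      rep
    })
    if (!is.null(mfit)) results$mismatch <- mfit
  }
  # --- population structure --------------------------------------------
  fst <- run_stage("fstats", {
    pd <- pairwise_fst(d, sp, n_perm = cfg$n_perm,
                       seed = derive_seed(cfg$seed, 6L))
    f <- file.path(cfg$out_dir, "pairwise_fst.tsv")
    write_popdiff_report(pd, f)
    record("fstats", f, list(n_perm = cfg$n_perm))
    pd
  })
  if (!is.null(fst)) results$fstats <- fst
  am <- run_stage("amova", {
    a1 <- amova(d, sp, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 7L))
    f <- file.path(cfg$out_dir, "amova_species.tsv")
    utils::write.table(a1$table, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("amova", f, list(n_perm = cfg$n_perm))
    a1
  })
  if (!is.null(am)) results$amova <- am
  # --- outliers and partition ------------------------------------------
  outl <- run_stage("outliers", {
    sc <- bayes_scan(markers, seed = derive_seed(cfg$seed, 8L))
    f <- file.path(cfg$out_dir, "outlier_report.tsv")
    write_outlier_report(sc, f)
    record("outliers", f, list(criteria = sc$criteria))
    sc
  })
  if (!is.null(outl)) results$outliers <- outl
  if ("partition" %in% cfg$stages) {
    if (is.null(outl)) {
      say("stage partition skipped: outlier scan not run; ",
          "downstream neutral-matrix stages unavailable")
    } else {
      parts <- run_stage("partition", partition_matrix(markers, outl))
      results$partition <- parts
      if (!is.null(fst) && ncol(parts$neutral$data) > 0) {
        dn <- binary_distance(parts$neutral, cfg$distance_method)
        pdn <- pairwise_fst(dn, sp, n_perm = cfg$n_perm,
                            seed = derive_seed(cfg$seed, 9L))
        f <- file.path(cfg$out_dir, "pairwise_fst_neutral.tsv")
        write_popdiff_report(pdn, f)
        record("partition", f, list(n_outliers = ncol(parts$outliers$data)))
        results$fstats_neutral <- pdn
      }
    }
  }
  # --- admixture and PCA -----------------------------------------------
  adm <- run_stage("admixture", {
    ks <- cfg$k_range %||% seq_len(min(8L, length(unique(sp)) + 2L))
    runs <- list()
    for (K in ks)
      runs[[as.character(K)]] <- fit_admixture(
        markers, K, burnin = cfg$mcmc$burnin,
        iterations = cfg$mcmc$iterations, n_reps = cfg$n_reps_admixture,
        seed = derive_seed(cfg$seed, 10L + K))
    ev <- if (length(ks) >= 3L) evanno_deltaK(runs) else NULL
    if (!is.null(ev)) {
      f <- file.path(cfg$out_dir, "evanno.tsv")
      utils::write.table(ev$table, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("admixture", f, list(k_range = ks, mcmc = cfg$mcmc))
    }
    best <- if (!is.null(ev)) ev$best_K else max(ks)
    fq <- file.path(cfg$out_dir, sprintf("q_matrix_K%d.tsv", best))
    write_q_matrix(runs[[as.character(best)]][[1L]], markers, fq)
    record("admixture", fq, list(best_K = best))
    list(runs = runs, evanno = ev, best_K = best)
  })
  if (!is.null(adm)) results$admixture <- adm
  pc <- run_stage("pca", {
    p <- pca_binary(markers)
    f <- file.path(cfg$out_dir, "pca_scores.tsv")
    utils::write.table(data.frame(sample_id = rownames(p$scores),
                                  species = sp,
                                  round(p$scores[, 1:min(5, ncol(p$scores))], 4)),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    record("pca", f, list())
    p
  })
  if (!is.null(pc)) results$pca <- pc
  manifest$elapsed_seconds <-
    as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  results$manifest_path <- mf
  invisible(results)
}
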