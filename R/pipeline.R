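#' Pipeline run configuration
#'
#' Collects every setting the pipeline stages read, so a run is fully
#' described by one object: input paths (or a simulation config), thresholds,
#' permutation counts, MCMC settings and the master seed from which each
#' stage's seed is derived deterministically. Defaults follow the published
#' analysis settings where stated: relatedness threshold 0.25, +/-1 bp
#' database matching, rarefaction sizes 15 (sample points) and 56
#' (fermentations), 0.80 membership rule, 1000 accumulation shuffles.
#'
#' @param isolates_path,panel_path input CSV/TSV paths; leave NULL together
#'   with a non-NULL \code{simulate} to generate the inputs.
#' @param simulate optional \code{sim_config}; used when paths are NULL.
#' @param loci a \code{locus_table}.
#' @param classification a \code{classification_config}.
#' @param match_tolerance_bp bp tolerance for database matching (default 1).
#' @param n_permutations permutations for F_ST and R-squared tests.
#' @param rarefaction_g_sample,rarefaction_g_fermentation standard subsample
#'   sizes (defaults 15 and 56).
#' @param accumulation_shuffles locus-subset shuffles (default 1000).
#' @param run_structure run the admixture MCMC stage (default TRUE).
#' @param k_range K values for DIC selection.
#' @param chains_per_k,iterations,burn_in MCMC settings (scaled-down
#'   defaults; raise towards 5 chains x 100000/50000 for full-size runs).
#' @param membership_threshold reporting threshold for cluster membership
#'   (default 0.80).
#' @param align_orders random input orders for run alignment.
#' @param outlier_exclusions declared outlier values for the abundance
#'   t-test (never automatic).
#' @param seed master seed.
#' @param outdir output directory.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(isolates_path = NULL, panel_path = NULL,
                       simulate = NULL, loci = default_loci(),
                       classification = classification_config(),
                       match_tolerance_bp = 1L, n_permutations = 199,
                       rarefaction_g_sample = 15,
                       rarefaction_g_fermentation = 56,
                       accumulation_shuffles = 1000,
                       run_structure = TRUE, k_range = 1:6,
                       chains_per_k = 1, iterations = 20000, burn_in = 5000,
                       membership_threshold = 0.80, align_orders = 100,
                       outlier_exclusions = numeric(), seed = 1,
                       outdir = tempfile("msatpop_run_")) {
  if (is.null(isolates_path) && is.null(simulate))
    stop("either input paths or a simulation config are required")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: input (read or simulate genotypes),
#' classification (Bruvo distances against the panel), population statistics
#' (per-locus summaries, HWE, pairwise F_ST with and without commercial
#' genotypes), diversity (rarefaction, accumulation curve, stage-frequency
#' and overlap tables) and, optionally, admixture inference (DIC selection
#' of K, run alignment, ancestry-profile R-squared). All tables are written
#' under \code{cfg$outdir} together with a manifest recording the package
#' version, derived stage seeds, input checksums and decision flags; the
#' manifest suffices to re-run the analysis bit-identically.
#'
#' @param cfg a \code{run_config}.
#' @return The results list (class \code{msatpop_run}), invisibly written to
#'   \code{cfg$outdir}.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 6)
  names(stage_seeds) <- c("input", "classify", "popgen", "diversity",
                          "structure", "export")
  res <- list(config = cfg, stage_seeds = stage_seeds)

  # --- input ---
  if (!is.null(cfg$isolates_path)) {
    inp <- read_isolate_table(cfg$isolates_path, cfg$loci)
    panel <- read_reference_panel(cfg$panel_path, cfg$loci)
    isolates <- inp$isolates
    mlgs <- inp$mlgs
    checksums <- tools::md5sum(c(cfg$isolates_path, cfg$panel_path))
  } else {
    simcfg <- cfg$simulate
    simcfg$seed <- stage_seeds[["input"]]
    sim <- simulate_dataset(simcfg)
    simdir <- file.path(cfg$outdir, "simulated")
    write_simulated_dataset(sim, simdir)
    inp <- read_isolate_table(file.path(simdir, "isolates.csv"), cfg$loci)
    panel <- read_reference_panel(file.path(simdir, "panel.csv"), cfg$loci)
    isolates <- inp$isolates
    mlgs <- inp$mlgs
    res$sim_truth <- sim$truth
    checksums <- tools::md5sum(file.path(simdir, c("isolates.csv", "panel.csv")))
  }
  names(checksums) <- basename(names(checksums))
  res$isolates <- isolates
  res$mlgs <- mlgs
  res$n_isolates <- nrow(isolates)
  res$n_mlgs <- n_mlg(mlgs)

  # --- classification ---
  matches <- match_commercial(mlgs, panel, tolerance_bp = 0L)
  cls <- classify_mlgs(mlgs, panel, cfg$classification, matches = matches)
  res$classification <- cls$classification
  res$distance_histogram <- cls$histogram
  utils::write.table(cls$classification,
                     file.path(cfg$outdir, "classification.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)

  # --- population statistics (clone-censored by location) ---
  set.seed(stage_seeds[["popgen"]])
  cens <- clone_censor(isolates, by = "location")
  # duplicate MLG rows across locations are intentional after censoring
  cmlgs <- mlg_set(mlgs$alleles[match(cens$mlg_id, mlgs$ids), , , drop = FALSE],
                   paste0(cens$location, ":", cens$mlg_id), mlgs$loci)
  res$population_summary <- population_summary(cmlgs, cens$location)
  cls_cens <- res$classification[match(cens$mlg_id, res$classification$mlg_id), ]
  cls_cens$mlg_id <- cmlgs$ids
  res$fst <- fst_with_without_commercial(cmlgs, cens$location, cls_cens,
                                         n_permutations = cfg$n_permutations)
  utils::write.table(as.data.frame(res$fst$with$matrix),
                     file.path(cfg$outdir, "fst_with_commercial.csv"),
                     sep = ",", quote = FALSE)
  utils::write.table(as.data.frame(res$fst$without$matrix),
                     file.path(cfg$outdir, "fst_without_commercial.csv"),
                     sep = ",", quote = FALSE)

  # --- diversity ---
  set.seed(stage_seeds[["diversity"]])
  counts_by_point <- tapply(isolates$mlg_id,
                            interaction(isolates$location, isolates$vintage,
                                        isolates$fermentation_id,
                                        isolates$stage, drop = TRUE),
                            function(x) as.integer(table(x)))
  rar <- do.call(rbind, lapply(names(counts_by_point), function(k) {
    ab <- counts_by_point[[k]]
    n <- sum(ab)
    g <- min(cfg$rarefaction_g_sample, n)
    data.frame(point = k, n = n, observed = length(ab),
               expected_at_g = rarefy_richness(ab, g), g = g)
  }))
  res$rarefaction <- rar
  utils::write.table(rar, file.path(cfg$outdir, "rarefaction.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  res$accumulation <- genotype_accumulation(
    mlgs, n_shuffles = cfg$accumulation_shuffles)
  res$stage_frequencies <- stage_frequencies(isolates, res$classification)
  utils::write.table(res$stage_frequencies,
                     file.path(cfg$outdir, "stage_frequencies.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  res$overlap <- mlg_overlap(isolates, by = "location",
                             classification = res$classification)
  utils::write.table(res$overlap, file.path(cfg$outdir, "mlg_overlap.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)

  # --- structure ---
  if (isTRUE(cfg$run_structure)) {
    sel <- select_k(cmlgs, cfg$k_range, chains_per_k = cfg$chains_per_k,
                    iterations = cfg$iterations, burn_in = cfg$burn_in,
                    seed = stage_seeds[["structure"]])
    res$structure <- sel
    al <- align_runs(list(sel$best_chain$q), seed = stage_seeds[["structure"]])
    res$obstruct <- obstruct_r2(al$consensus_q, cens$location,
                                n_permutations = cfg$n_permutations,
                                seed = stage_seeds[["structure"]])
    utils::write.table(sel$dic_table, file.path(cfg$outdir, "dic_table.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    write_qmatrix(al$consensus_q, file.path(cfg$outdir, "consensus_q.txt"),
                  groups = cens$location)
  }

  # --- exports ---
  dm <- bruvo_dist(mlgs)
  write_phylip_dm(dm, file.path(cfg$outdir, "bruvo_distance.phy"))
  if (n_mlg(mlgs) >= 3)
    ape::write.tree(nj_tree(dm), file.path(cfg$outdir, "nj_tree.nwk"))

  manifest <- list(
    package = "msatpop",
    version = as.character(utils::packageVersion("msatpop")),
    seed = cfg$seed, stage_seeds = as.list(stage_seeds),
    input_checksums = as.list(checksums),
    n_isolates = res$n_isolates, n_mlgs = res$n_mlgs,
    related_threshold = cfg$classification$related_threshold,
    match_tolerance_bp = cfg$match_tolerance_bp,
    n_permutations = cfg$n_permutations,
    fst_estimator = "Nei Gst (Ht-Hs)/Ht, ratio of locus means",
    hwe_method = "monte_carlo re-pairing",
    alignment_similarity = "1 - ||Q-Q'||_F / sqrt(2N)",
    structure = isTRUE(cfg$run_structure))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  class(res) <- "msatpop_run"
  invisible(res)
}
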