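#' Configuration for the synthetic genotype generator
#'
#' Defines the study design the generator emulates: a typed panel of
#' commercial diploid strains; commercial-related derivatives produced
#' mostly by loss of heterozygosity (LOH) with occasional stepwise repeat
#' mutations; several inbred indigenous subpopulations on repeat-count
#' ranges far from the panel; and isolates sampled from 4 locations x 3
#' replicate fermentations x 3 stages x 2 vintages with location-specific
#' mixture weights over strain classes.
#'
#' @param seed master seed.
#' @param n_commercial commercial panel size (default 72).
#' @param n_related_per_parent derivatives per commercial parent (default 2).
#' @param loh_loci_range range of LOH events per derivative (default 1:4).
#' @param loh_loci_weights sampling weights over that range; the default
#'   favours 1-2 events, with 3-4 occurring in a minority of derivatives.
#' @param stepwise_mut_prob per-allele probability of a +/-1 or +/-2
#'   repeat-unit mutation in a derivative (default 0.02).
#' @param n_indigenous_pops number of indigenous subpopulations (default 3).
#' @param n_indigenous_strains individuals per indigenous population.
#' @param indigenous_f inbreeding coefficient of the indigenous populations
#'   (default 0.6: with probability f both allele copies are one draw).
#' @param min_indigenous_distance minimum Bruvo distance from every
#'   indigenous MLG to the panel (default 0.45, safely above the 0.25
#'   relatedness threshold); enforced by rejection sampling.
#' @param panel_repeat_range repeat-count range for panel alleles.
#' @param panel_het_prob per-locus heterozygosity of panel strains.
#' @param locations named list; each element has \code{class_weights}
#'   (commercial, related, unique; summing to 1) and \code{pop_weights}
#'   (over indigenous populations).
#' @param n_fermentations replicate fermentations per location x vintage.
#' @param n_isolates_per_stage isolates sampled per stage (default 32).
#' @param stages,vintages sampling design.
#' @param class_concentration Dirichlet concentration tying a fermentation's
#'   class weights to its location's (larger = tighter).
#' @param stage_concentration concentration tying each stage's weights to
#'   the fermentation-level draw (stages are correlated, not independent).
#' @param loci a \code{locus_table}.
#' @param noisy_sizes if TRUE, also emit fractional raw sizes with +/-0.3 bp
#'   jitter to exercise allele binning.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_commercial = 72,
                       n_related_per_parent = 2,
                       loh_loci_range = 1:4,
                       loh_loci_weights = c(0.4, 0.3, 0.2, 0.1),
                       stepwise_mut_prob = 0.02,
                       n_indigenous_pops = 3,
                       n_indigenous_strains = 30,
                       indigenous_f = 0.6,
                       min_indigenous_distance = 0.45,
                       panel_repeat_range = c(8L, 28L),
                       panel_het_prob = 0.75,
                       locations = default_locations(),
                       n_fermentations = 3,
                       n_isolates_per_stage = 32,
                       stages = c("early", "mid", "late"),
                       vintages = c(2013L, 2014L),
                       class_concentration = 50,
                       stage_concentration = 200,
                       loci = default_loci(),
                       noisy_sizes = FALSE) {
  stopifnot(stepwise_mut_prob >= 0, stepwise_mut_prob <= 1,
            indigenous_f >= 0, indigenous_f <= 1,
            min_indigenous_distance > 0.25,
            all(loh_loci_range >= 0), all(loh_loci_range <= nrow(loci)),
            length(loh_loci_weights) == length(loh_loci_range))
  for (loc in locations) {
    if (abs(sum(loc$class_weights) - 1) > 1e-9)
      stop("location class weights must sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Default location mixture weights
#'
#' The winery carries a resident commercially derived population, so its
#' weights favour commercial and commercial-related strains; the vineyards
#' are dominated by unique (indigenous) genotypes, each favouring a
#' different indigenous subpopulation so that location carries signal.
#'
#' @return Named list of per-location weights.
#' @export
default_locations <- function() {
  list(
    Winery = list(class_weights = c(commercial = 0.20, related = 0.45, unique = 0.35),
                  pop_weights = c(1, 1, 1) / 3),
    HE     = list(class_weights = c(commercial = 0.05, related = 0.10, unique = 0.85),
                  pop_weights = c(0.70, 0.20, 0.10)),
    HW     = list(class_weights = c(commercial = 0.03, related = 0.07, unique = 0.90),
                  pop_weights = c(0.10, 0.70, 0.20)),
    OG     = list(class_weights = c(commercial = 0.10, related = 0.25, unique = 0.65),
                  pop_weights = c(0.20, 0.10, 0.70))
  )
}

# per-locus base fragment sizes (bp) on which repeat ladders sit
locus_base_sizes <- function(loci) {
  base <- c(120L, 140L, 160L, 185L, 205L, 150L, 175L, 195L)
  rep_len(base, nrow(loci))
}

#' Simulate the commercial reference panel
#'
#' Diploid genotypes on exact repeat ladders: allele size = locus base
#' length + unit length x repeat count, repeat counts uniform on
#' \code{panel_repeat_range}. Profile collisions are resampled so all panel
#' MLGs are mutually distinct.
#'
#' @param cfg a \code{sim_config}.
#' @return An \code{mlg_set} of \code{n_commercial} named strains.
#' @export
simulate_reference_panel <- function(cfg) {
  L <- nrow(cfg$loci)
  base <- locus_base_sizes(cfg$loci)
  unit <- cfg$loci$unit_length
  draw_one <- function() {
    a <- matrix(0L, L, 2)
    for (l in seq_len(L)) {
      r1 <- sample(cfg$panel_repeat_range[1]:cfg$panel_repeat_range[2], 1)
      r2 <- if (stats::runif(1) < cfg$panel_het_prob) {
        sample(setdiff(cfg$panel_repeat_range[1]:cfg$panel_repeat_range[2], r1), 1)
      } else r1
      a[l, ] <- sort(base[l] + unit[l] * c(r1, r2))
    }
    a
  }
  alle <- array(0L, dim = c(cfg$n_commercial, L, 2))
  for (i in seq_len(cfg$n_commercial)) alle[i, , ] <- draw_one()
  for (attempt in 1:100) {
    key <- profile_key(alle)
    dup <- which(duplicated(key))
    if (!length(dup)) break
    for (i in dup) alle[i, , ] <- draw_one()
  }
  ids <- sprintf("COM%03d", seq_len(cfg$n_commercial))
  mlg_set(alle, ids, cfg$loci)
}

#' Derive commercial-related genotypes from the panel
#'
#' Each derivative takes a commercial parent and applies loss of
#' heterozygosity at a sampled number of its heterozygous loci (one allele
#' copied over the other, direction random), then independent stepwise
#' mutations (+/-1 repeat unit, occasionally +/-2) per allele with
#' probability \code{stepwise_mut_prob}. A fully homozygous parent falls
#' back to stepwise-only with at least one forced mutation (flagged).
#'
#' @param panel the commercial \code{mlg_set}.
#' @param cfg a \code{sim_config}.
#' @return List with \code{mlgs} (\code{mlg_set} of derivatives) and
#'   \code{truth} (data frame: strain_id, parent, n_loh, n_mut,
#'   loh_fallback).
#' @export
derive_commercial_related <- function(panel, cfg) {
  L <- nrow(cfg$loci)
  unit <- cfg$loci$unit_length
  n_par <- n_mlg(panel)
  total <- n_par * cfg$n_related_per_parent
  alle <- array(0L, dim = c(total, L, 2))
  truth <- data.frame(strain_id = character(total), parent = character(total),
                      n_loh = integer(total), n_mut = integer(total),
                      loh_fallback = logical(total), stringsAsFactors = FALSE)
  idx <- 0L
  for (pi in seq_len(n_par)) {
    for (d in seq_len(cfg$n_related_per_parent)) {
      idx <- idx + 1L
      a <- panel$alleles[pi, , ]
      het <- which(a[, 1] != a[, 2])
      want <- sample(cfg$loh_loci_range, 1, prob = cfg$loh_loci_weights)
      fallback <- length(het) == 0L
      n_loh <- min(want, length(het))
      if (n_loh > 0) {
        for (l in sample(het, n_loh)) {
          keep <- sample(1:2, 1)
          a[l, ] <- a[l, keep]
        }
      }
      n_mut <- 0L
      for (l in seq_len(L)) for (cp in 1:2) {
        if (stats::runif(1) < cfg$stepwise_mut_prob) {
          step <- sample(c(1L, 2L), 1, prob = c(0.8, 0.2)) *
            sample(c(-1L, 1L), 1)
          a[l, cp] <- a[l, cp] + step * unit[l]
          n_mut <- n_mut + 1L
        }
      }
      if (fallback && n_mut == 0L) {  # force a difference from the parent
        l <- sample(L, 1)
        a[l, 1] <- a[l, 1] + unit[l] * sample(c(-1L, 1L), 1)
        n_mut <- 1L
      }
      alle[idx, , ] <- cbind(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
      truth$strain_id[idx] <- sprintf("REL%03d_%s", idx, panel$ids[pi])
      truth$parent[idx] <- panel$ids[pi]
      truth$n_loh[idx] <- n_loh
      truth$n_mut[idx] <- n_mut
      truth$loh_fallback[idx] <- fallback
    }
  }
  list(mlgs = mlg_set(alle, truth$strain_id, cfg$loci), truth = truth)
}

#' Simulate inbred indigenous subpopulations
#'
#' Each subpopulation draws its allele frequencies over a repeat-count range
#' disjoint from the panel's (and from the other subpopulations'), so every
#' emitted MLG is far from all commercial genotypes; this is verified by
#' rejection sampling against \code{min_indigenous_distance}. Genotypes are
#' drawn with inbreeding f: with probability f both allele copies come from
#' a single draw (identity by descent), otherwise from two independent
#' draws.
#'
#' @param cfg a \code{sim_config}.
#' @param panel the commercial \code{mlg_set} (for the distance check).
#' @return List with \code{mlgs} (all individuals pooled), \code{truth}
#'   (strain_id, pop, f) and \code{freqs} (the generating frequencies).
#' @export
simulate_indigenous <- function(cfg, panel) {
  L <- nrow(cfg$loci)
  base <- locus_base_sizes(cfg$loci)
  unit <- cfg$loci$unit_length
  n_pop <- cfg$n_indigenous_pops
  n_each <- cfg$n_indigenous_strains
  pop_lo <- cfg$panel_repeat_range[2] + 12L + 14L * (seq_len(n_pop) - 1L)
  freqs <- vector("list", n_pop)
  alle <- array(0L, dim = c(n_pop * n_each, L, 2))
  truth <- NULL
  idx <- 0L
  for (p in seq_len(n_pop)) {
    freqs[[p]] <- lapply(seq_len(L), function(l) {
      reps <- sample(pop_lo[p]:(pop_lo[p] + 10L), 5)
      w <- stats::rgamma(5, 1); w <- w / sum(w)
      list(sizes = base[l] + unit[l] * reps, probs = w)
    })
    for (i in seq_len(n_each)) {
      idx <- idx + 1L
      for (attempt in 1:100) {
        a <- matrix(0L, L, 2)
        for (l in seq_len(L)) {
          fr <- freqs[[p]][[l]]
          if (stats::runif(1) < cfg$indigenous_f) {
            a[l, ] <- sample(fr$sizes, 1, prob = fr$probs)
          } else {
            a[l, ] <- sort(sample(fr$sizes, 2, replace = TRUE, prob = fr$probs))
          }
        }
        one <- mlg_set(array(a, dim = c(1, L, 2)), "tmp", cfg$loci)
        if (min(bruvo_dist(one, panel)) > cfg$min_indigenous_distance) break
        if (attempt == 100)
          stop("could not place an indigenous genotype far enough from the panel; ",
               "widen the repeat-range separation")
      }
      alle[idx, , ] <- a
      truth <- rbind(truth, data.frame(strain_id = sprintf("IND%d_%03d", p, i),
                                       pop = p, f = cfg$indigenous_f,
                                       stringsAsFactors = FALSE))
    }
  }
  list(mlgs = mlg_set(alle, truth$strain_id, cfg$loci), truth = truth,
       freqs = freqs)
}

#' Simulate staged fermentation sampling
#'
#' For every location x vintage x replicate fermentation, class abundances
#' are drawn from a Dirichlet centred on the location's class weights; each
#' stage re-perturbs that shared fermentation-level draw (so stages are
#' correlated), and isolates are sampled multinomially: first a strain
#' class, then a strain from the fermentation's within-class abundance
#' draw.
#'
#' @param cfg a \code{sim_config}.
#' @param pools list with \code{commercial}, \code{related},
#'   \code{indigenous} (\code{mlg_set}s) and \code{indigenous_pop} (integer
#'   population label per indigenous strain).
#' @return List with \code{isolates} (data frame) and \code{mix_truth}
#'   (per-fermentation realised class weights).
#' @export
simulate_fermentations <- function(cfg, pools) {
  classes <- c("commercial", "related", "unique")
  rdirich <- function(a) { x <- stats::rgamma(length(a), pmax(a, 1e-6)); x / sum(x) }
  rows <- list()
  mix <- list()
  iso_n <- 0L
  for (loc in names(cfg$locations)) {
    lw <- cfg$locations[[loc]]
    # location-level strain pools: indigenous strains weighted by pop preference
    ind_pop <- pools$indigenous_pop
    ind_base <- lw$pop_weights[ind_pop]
    ind_base <- ind_base / sum(ind_base)
    for (v in cfg$vintages) {
      for (b in seq_len(cfg$n_fermentations)) {
        fid <- sprintf("%s_%d_F%d", loc, v, b)
        ferm_class <- rdirich(cfg$class_concentration * lw$class_weights)
        w_com <- rdirich(rep(1, n_mlg(pools$commercial)))
        w_rel <- rdirich(rep(1, n_mlg(pools$related)))
        w_ind <- rdirich(5 * ind_base * length(ind_base))
        for (st in cfg$stages) {
          stage_class <- rdirich(cfg$stage_concentration * ferm_class)
          cls <- sample(classes, cfg$n_isolates_per_stage, replace = TRUE,
                        prob = stage_class)
          strain <- character(cfg$n_isolates_per_stage)
          for (j in seq_along(cls)) {
            strain[j] <- switch(cls[j],
              commercial = sample(pools$commercial$ids, 1, prob = w_com),
              related    = sample(pools$related$ids, 1, prob = w_rel),
              unique     = sample(pools$indigenous$ids, 1, prob = w_ind))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            isolate_id = sprintf("ISO%05d", iso_n + seq_along(strain)),
            location = loc, vintage = v, fermentation_id = fid, stage = st,
            mlg_id = strain, stringsAsFactors = FALSE)
          iso_n <- iso_n + length(strain)
        }
        mix[[fid]] <- ferm_class
      }
    }
  }
  list(isolates = do.call(rbind, rows),
       mix_truth = do.call(rbind, lapply(names(mix), function(f)
         data.frame(fermentation_id = f, commercial = mix[[f]][1],
                    related = mix[[f]][2], unique = mix[[f]][3]))))
}

#' Simulate a complete dataset with ground truth
#'
#' Runs the full generator under \code{cfg$seed}: commercial panel,
#' commercial-related derivatives, indigenous subpopulations and the staged
#' isolate table. Deterministic: the same config gives a byte-identical
#' dataset.
#'
#' @param cfg a \code{sim_config}.
#' @return List of class \code{sim_dataset}: \code{config}, \code{panel},
#'   \code{strains} (\code{mlg_set} of every candidate strain: panel copies,
#'   derivatives, indigenous individuals), \code{isolates}, \code{truth}
#'   (per-strain true category/parent/population) and \code{mix_truth}. With
#'   \code{noisy_sizes}, also \code{raw_sizes}: fractional allele sizes with
#'   jitter, parallel to \code{strains}.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  panel <- simulate_reference_panel(cfg)
  rel <- derive_commercial_related(panel, cfg)
  ind <- simulate_indigenous(cfg, panel)
  strains <- c_mlg(panel, rel$mlgs, ind$mlgs)
  truth <- rbind(
    data.frame(strain_id = panel$ids, category = "commercial",
               parent = NA_character_, pop = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(strain_id = rel$truth$strain_id, category = "commercial_related",
               parent = rel$truth$parent, pop = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(strain_id = ind$truth$strain_id, category = "unique",
               parent = NA_character_, pop = ind$truth$pop,
               stringsAsFactors = FALSE))
  ferm <- simulate_fermentations(
    cfg, list(commercial = panel, related = rel$mlgs,
              indigenous = ind$mlgs, indigenous_pop = ind$truth$pop))
  out <- list(config = cfg, panel = panel, strains = strains,
              isolates = ferm$isolates, truth = truth,
              mix_truth = ferm$mix_truth,
              related_truth = rel$truth, indigenous_truth = ind$truth)
  if (isTRUE(cfg$noisy_sizes)) {
    out$raw_sizes <- strains$alleles +
      array(stats::runif(length(strains$alleles), -0.3, 0.3),
            dim = dim(strains$alleles))
  }
  class(out) <- "sim_dataset"
  out
}

#' Write a simulated dataset to a directory
#'
#' Emits the same CSV formats the readers accept (\code{isolates.csv},
#' \code{panel.csv}), the ground-truth sidecar (\code{truth.csv}) and the
#' config echoed as JSON, so a round trip through
#' \code{\link{read_isolate_table}} is lossless.
#'
#' @param sim a \code{sim_dataset}.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_isolate_table(sim$isolates, sim$strains, file.path(dir, "isolates.csv"))
  panel_df <- data.frame(strain_name = sim$panel$ids)
  L <- nrow(sim$panel$loci)
  flat <- matrix(sim$panel$alleles, nrow = n_mlg(sim$panel))
  geno <- flat[, as.vector(rbind(seq_len(L), L + seq_len(L))), drop = FALSE]
  colnames(geno) <- as.vector(rbind(paste0(sim$panel$loci$name, ".1"),
                                    paste0(sim$panel$loci$name, ".2")))
  utils::write.table(cbind(panel_df, geno), file.path(dir, "panel.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  cfg <- sim$config
  cfg$loci <- as.data.frame(unclass(cfg$loci))
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
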