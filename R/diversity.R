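#' Rarefied multilocus-genotype richness
#'
#' Expected number of distinct MLGs in a random subsample of size \code{g},
#' \eqn{E[S_g] = \sum_i [1 - C(n - n_i, g)/C(n, g)]} over MLG abundances
#' \eqn{n_i}. Standardised subsample sizes make richness comparable across
#' unevenly sampled fermentation points (typical common sizes: 15 per sample
#' point, 56 per fermentation). Computed via \code{vegan::rarefy}.
#'
#' @param abundances integer vector of per-MLG isolate counts (one group).
#' @param g subsample size, \code{1 <= g <= sum(abundances)}.
#' @return Expected richness (fractional); equals observed richness at
#'   \code{g = n}.
#' @export
rarefy_richness <- function(abundances, g) {
  abundances <- abundances[abundances > 0]
  n <- sum(abundances)
  if (g < 1 || g > n) stop("g must be between 1 and the total count ", n)
  # vegan warns when no abundance equals 1 (a count-vs-incidence heuristic);
  # inputs here are always abundances
  suppressWarnings(
    as.numeric(vegan::rarefy(matrix(abundances, nrow = 1), sample = g)))
}

#' Genotype accumulation curve over locus subsets
#'
#' For each number of loci \code{m} from 1 to L-1, draws \code{n_shuffles}
#' random locus subsets of size m and records how many distinct genotypes the
#' subset distinguishes. A plateau near the full-panel MLG count shows the
#' panel has enough resolving power; the 90\%-of-total reference level is
#' reported alongside.
#'
#' @param mlgs an \code{mlg_set} (>= 2 loci); pass the per-isolate genotypes
#'   (repeats included) or the distinct MLGs depending on the question.
#' @param n_shuffles random subsets per subset size (default 1000).
#' @param seed optional integer seed.
#' @return List with \code{samples} (n_shuffles x (L-1) matrix of distinct
#'   counts), \code{summary} (per m: mean, min, max), \code{total} (full-panel
#'   richness) and \code{ref90} (= 0.9 * total).
#' @export
genotype_accumulation <- function(mlgs, n_shuffles = 1000, seed = NULL) {
  L <- nrow(mlgs$loci)
  if (L < 2L) stop("at least 2 loci required")
  if (!is.null(seed)) set.seed(seed)
  n <- n_mlg(mlgs)
  flat1 <- matrix(mlgs$alleles[, , 1], nrow = n)
  flat2 <- matrix(mlgs$alleles[, , 2], nrow = n)
  count_distinct <- function(loci_idx) {
    key <- do.call(paste, c(as.data.frame(flat1[, loci_idx, drop = FALSE]),
                            as.data.frame(flat2[, loci_idx, drop = FALSE]),
                            sep = "/"))
    length(unique(key))
  }
  samples <- matrix(NA_integer_, n_shuffles, L - 1L,
                    dimnames = list(NULL, paste0("m", seq_len(L - 1L))))
  for (m in seq_len(L - 1L)) {
    for (r in seq_len(n_shuffles)) {
      samples[r, m] <- count_distinct(sample(L, m))
    }
  }
  total <- count_distinct(seq_len(L))
  summ <- data.frame(n_loci = seq_len(L - 1L),
                     mean = colMeans(samples),
                     min = apply(samples, 2, min),
                     max = apply(samples, 2, max))
  list(samples = samples, summary = summ, total = total, ref90 = 0.9 * total)
}

#' Chi-square test of independence with adjusted standardized residuals
#'
#' Pearson chi-square on a contingency table (rows e.g. locations, columns
#' MLG types) with per-cell adjusted standardized residuals
#' \eqn{ASR_{ij} = (O_{ij} - E_{ij}) / \sqrt{E_{ij}(1 - r_i/N)(1 - c_j/N)}}.
#' A cell is flagged significant when the upper-tail probability of
#' \eqn{ASR^2} under chi-square(1) falls below \code{alpha/bonferroni_cells}
#' (Bonferroni over the table's cells, e.g. 0.05/6 ~ 0.008 for a 2x3 table).
#'
#' @param observed matrix of counts; all expected counts must be positive.
#' @param alpha familywise significance level (default 0.05).
#' @param bonferroni_cells divisor for the per-cell level; defaults to the
#'   number of cells.
#' @return List: observed, expected, chi2, df, p_value, asr,
#'   cell_p (per-cell upper-tail probabilities), cell_significant,
#'   alpha_cell.
#' @export
chi_square_asr <- function(observed, alpha = 0.05,
                           bonferroni_cells = length(observed)) {
  observed <- as.matrix(observed)
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  if (any(ct$expected <= 0)) stop("all expected counts must be positive")
  asr <- ct$stdres
  cell_p <- stats::pchisq(asr^2, df = 1, lower.tail = FALSE)
  list(observed = observed, expected = ct$expected,
       chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), asr = asr, cell_p = cell_p,
       cell_significant = cell_p < alpha / bonferroni_cells,
       alpha_cell = alpha / bonferroni_cells)
}

#' Friedman rank test across fermentation stages
#'
#' Nonparametric repeated-measures test: values are ranked within each block
#' (fermentation) across treatments (stages), with average ranks for ties,
#' and the tie-corrected chi-square statistic on df = k - 1 is returned. Used
#' to ask whether rarefied MLG richness changes over the course of
#' fermentation.
#'
#' @param blocks numeric matrix, rows = blocks (fermentations), columns =
#'   treatments (stages); complete (no missing cells).
#' @return Data frame: statistic, df, p_value.
#' @export
friedman_rank_test <- function(blocks) {
  blocks <- as.matrix(blocks)
  b <- nrow(blocks); k <- ncol(blocks)
  if (b < 2L || k < 2L) stop("need >= 2 blocks and >= 2 treatments")
  if (anyNA(blocks)) stop("missing cells are not allowed")
  ranks <- t(apply(blocks, 1, rank))
  Rj <- colSums(ranks)
  A <- sum(ranks^2)
  C <- b * k * (k + 1)^2 / 4
  if (A == C) {  # every block fully tied
    return(data.frame(statistic = 0, df = k - 1, p_value = 1))
  }
  stat <- (k - 1) * (sum(Rj^2) - b * C) / (A - C)
  data.frame(statistic = stat, df = k - 1,
             p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Welch's t-test with declared outlier exclusions
#'
#' Two-sided t-test assuming unequal variances (Satterthwaite df), used for
#' comparing relative strain abundances between locations. Outlier removal is
#' never automatic: values to exclude must be declared explicitly and are
#' echoed in the result, keeping the run auditable.
#'
#' @param a,b numeric samples (e.g. per-fermentation proportions).
#' @param exclude numeric values to remove (exact match, from either sample).
#' @return Data frame: statistic, df, p_value, n_a, n_b; attribute
#'   \code{excluded_points} lists the values actually removed.
#' @export
welch_t_test <- function(a, b, exclude = numeric()) {
  removed <- c(a[a %in% exclude], b[b %in% exclude])
  a <- a[!a %in% exclude]
  b <- b[!b %in% exclude]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs >= 2 values after exclusions")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  out <- data.frame(statistic = unname(tt$statistic),
                    df = unname(tt$parameter),
                    p_value = tt$p.value, n_a = length(a), n_b = length(b))
  attr(out, "excluded_points") <- removed
  out
}
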