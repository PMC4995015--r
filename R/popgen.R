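#' Per-locus summary statistics for one population
#'
#' Allele count, observed heterozygosity (fraction of heterozygous
#' individuals), expected heterozygosity (gene diversity,
#' \eqn{H_e = 1 - \sum p_i^2} over allele frequencies from the 2n allele
#' copies) and the inbreeding coefficient
#' \eqn{F_{IS} = (H_e - H_o)/H_e}, undefined at a monomorphic locus.
#'
#' @param genotypes n x 2 matrix of allele sizes at one locus.
#' @param unbiased if TRUE, apply the small-sample correction
#'   \eqn{2n/(2n-1)} to \eqn{H_e} (default FALSE: plain gene diversity).
#' @return One-row data frame: n, allele_count, Ho, He, Fis (NA when
#'   monomorphic).
#' @export
locus_stats <- function(genotypes, unbiased = FALSE) {
  genotypes <- as.matrix(genotypes)
  stopifnot(ncol(genotypes) == 2L)
  n <- nrow(genotypes)
  if (n < 1L) stop("at least one genotype required")
  p <- table(c(genotypes)) / (2 * n)
  Ho <- mean(genotypes[, 1] != genotypes[, 2])
  He <- 1 - sum(p^2)
  if (unbiased && n > 0) He <- He * 2 * n / (2 * n - 1)
  Fis <- if (He > 0) (He - Ho) / He else NA_real_
  data.frame(n = n, allele_count = length(p), Ho = Ho, He = He, Fis = Fis)
}

#' Population summary across loci
#'
#' Per-locus statistics for each population plus the across-locus mean and
#' standard error of each measure (the usual summary-table layout: mean of
#' each statistic over the 8 loci, +/- SE).
#'
#' @param mlgs an \code{mlg_set} (normally clone-censored).
#' @param populations factor/character of population labels, one per genotype.
#' @param unbiased passed to \code{\link{locus_stats}}.
#' @return List with \code{per_locus} (long data frame) and \code{summary}
#'   (one row per population: mean and SE of allele count, Ho, He, Fis).
#' @export
population_summary <- function(mlgs, populations, unbiased = FALSE) {
  stopifnot(length(populations) == n_mlg(mlgs))
  pops <- unique(as.character(populations))
  per <- do.call(rbind, lapply(pops, function(pp) {
    idx <- which(populations == pp)
    do.call(rbind, lapply(seq_len(nrow(mlgs$loci)), function(l) {
      cbind(population = pp, locus = mlgs$loci$name[l],
            locus_stats(matrix(mlgs$alleles[idx, l, ], ncol = 2),
                        unbiased = unbiased))
    }))
  }))
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  summ <- do.call(rbind, lapply(pops, function(pp) {
    s <- per[per$population == pp, ]
    data.frame(population = pp, n = max(s$n),
               alleles_mean = mean(s$allele_count), alleles_se = se(s$allele_count),
               Ho_mean = mean(s$Ho), Ho_se = se(s$Ho),
               He_mean = mean(s$He), He_se = se(s$He),
               Fis_mean = mean(s$Fis, na.rm = TRUE), Fis_se = se(s$Fis))
  }))
  list(per_locus = per, summary = summ)
}

#' Hardy-Weinberg equilibrium test at one locus
#'
#' Either a chi-square goodness-of-fit of observed genotype counts against
#' HWE expectations (df = number of possible genotypes minus number of
#' alleles), or a Monte Carlo test that re-pairs the pooled allele copies at
#' random \code{n_reps} times and ranks the observed statistic among the
#' simulated ones (the default: robust to the sparse genotype tables typical
#' of multiallelic SSR data).
#'
#' @param genotypes n x 2 matrix of allele sizes at one locus.
#' @param method \code{"monte_carlo"} (default) or \code{"chisq"}.
#' @param n_reps Monte Carlo replicates.
#' @param seed optional integer seed.
#' @return Data frame: statistic, df (NA for Monte Carlo), p_value, method,
#'   defined (FALSE for a monomorphic locus, where the test is undefined).
#' @export
hwe_test <- function(genotypes, method = c("monte_carlo", "chisq"),
                     n_reps = 9999, seed = NULL) {
  method <- match.arg(method)
  genotypes <- as.matrix(genotypes)
  alleles <- sort(unique(c(genotypes)))
  k <- length(alleles)
  if (k < 2L)
    return(data.frame(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                      method = method, defined = FALSE))
  if (!is.null(seed)) set.seed(seed)
  obs <- hwe_chisq_stat(genotypes, alleles)
  if (method == "chisq") {
    df <- k * (k + 1) / 2 - k
    p <- stats::pchisq(obs, df = df, lower.tail = FALSE)
    return(data.frame(statistic = obs, df = df, p_value = p,
                      method = method, defined = TRUE))
  }
  pool <- c(genotypes)
  n <- nrow(genotypes)
  sims <- vapply(seq_len(n_reps), function(r) {
    hwe_chisq_stat(matrix(sample(pool), ncol = 2), alleles)
  }, 0)
  p <- (1 + sum(sims >= obs)) / (n_reps + 1)
  data.frame(statistic = obs, df = NA_real_, p_value = p,
             method = method, defined = TRUE)
}

# chi-square GOF statistic of genotype counts vs HWE expectations
hwe_chisq_stat <- function(genotypes, alleles) {
  n <- nrow(genotypes)
  p <- as.vector(table(factor(c(genotypes), levels = alleles))) / (2 * n)
  k <- length(alleles)
  a1 <- match(pmin(genotypes[, 1], genotypes[, 2]), alleles)
  a2 <- match(pmax(genotypes[, 1], genotypes[, 2]), alleles)
  stat <- 0
  for (i in seq_len(k)) for (j in i:k) {
    e <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
    o <- sum(a1 == i & a2 == j)
    if (e > 0) stat <- stat + (o - e)^2 / e
  }
  stat
}

#' Pairwise F_ST between two populations with a permutation test
#'
#' Nei-style fixation index
#' \eqn{F_{ST} = (\bar H_t - \bar H_s)/\bar H_t}, where per locus
#' \eqn{H_s} is the mean within-population expected heterozygosity and
#' \eqn{H_t} the expected heterozygosity of the unweighted mean allele
#' frequencies of the two populations; the per-locus components are averaged
#' before taking the ratio. Significance comes from shuffling individuals
#' between the populations (sizes preserved): p is the proportion of
#' permuted statistics at least as large as the observed one, with the
#' add-one correction so p is never 0.
#'
#' @param pop_a,pop_b \code{mlg_set}s (normally clone-censored; >= 2
#'   genotypes each).
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer seed.
#' @return Data frame: fst (clamped at 0), fst_raw, p_value, n_permutations.
#' @export
pairwise_fst <- function(pop_a, pop_b, n_permutations = 999, seed = NULL) {
  if (!identical(pop_a$loci$name, pop_b$loci$name)) stop("locus panels differ")
  na <- n_mlg(pop_a); nb <- n_mlg(pop_b)
  if (na < 2L || nb < 2L) stop("each population needs at least 2 genotypes")
  if (!is.null(seed)) set.seed(seed)
  all_a <- abind3(pop_a$alleles, pop_b$alleles)
  obs <- fst_gst(all_a, seq_len(na), na + seq_len(nb))
  hits <- 0L
  for (r in seq_len(n_permutations)) {
    idx <- sample(na + nb)
    s <- fst_gst(all_a, idx[seq_len(na)], idx[na + seq_len(nb)])
    if (s >= obs - 1e-15) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_permutations + 1)
  data.frame(fst = max(0, obs), fst_raw = obs, p_value = p,
             n_permutations = n_permutations)
}

# (mean Ht - mean Hs) / mean Ht over loci; alleles: n x L x 2 array
fst_gst <- function(alleles, idx_a, idx_b) {
  L <- dim(alleles)[2]
  hs <- ht <- numeric(L)
  for (l in seq_len(L)) {
    xa <- c(alleles[idx_a, l, ]); xb <- c(alleles[idx_b, l, ])
    lev <- sort(unique(c(xa, xb)))
    pa <- as.vector(table(factor(xa, levels = lev))) / length(xa)
    pb <- as.vector(table(factor(xb, levels = lev))) / length(xb)
    hs[l] <- mean(c(1 - sum(pa^2), 1 - sum(pb^2)))
    pm <- (pa + pb) / 2
    ht[l] <- 1 - sum(pm^2)
  }
  if (mean(ht) == 0) return(0)
  (mean(ht) - mean(hs)) / mean(ht)
}

#' All pairwise F_ST values between populations
#'
#' @param mlgs \code{mlg_set} of clone-censored genotypes.
#' @param populations label per genotype.
#' @param n_permutations,seed passed to \code{\link{pairwise_fst}}.
#' @return List with \code{pairs} (long data frame) and \code{matrix}
#'   (square: F_ST below the diagonal, permutation p-values above).
#' @export
fst_matrix <- function(mlgs, populations, n_permutations = 999, seed = NULL) {
  pops <- unique(as.character(populations))
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  pairs <- NULL
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i >= j) next
    a <- mlgs[which(populations == pops[i])]
    b <- mlgs[which(populations == pops[j])]
    if (n_mlg(a) < 2L || n_mlg(b) < 2L) {
      pairs <- rbind(pairs, data.frame(pop_a = pops[i], pop_b = pops[j],
                                       fst = NA_real_, fst_raw = NA_real_,
                                       p_value = NA_real_,
                                       n_permutations = n_permutations,
                                       computable = FALSE))
      next
    }
    r <- pairwise_fst(a, b, n_permutations = n_permutations)
    m[j, i] <- r$fst      # estimates lower triangle
    m[i, j] <- r$p_value  # p-values upper triangle
    pairs <- rbind(pairs, cbind(data.frame(pop_a = pops[i], pop_b = pops[j]),
                                r, computable = TRUE))
  }
  list(pairs = pairs, matrix = m)
}

#' F_ST matrices with and without commercial(-related) genotypes
#'
#' Recomputes the pairwise F_ST table after removing every MLG classified
#' commercial or commercial_related, quantifying how much of the
#' between-location differentiation is carried by commercially derived
#' strains. Pairs emptied by the removal are reported as not computable.
#'
#' @param mlgs clone-censored \code{mlg_set}.
#' @param populations label per genotype.
#' @param classification data frame from \code{\link{classify_mlgs}}.
#' @param n_permutations,seed permutation settings.
#' @return List with elements \code{with} and \code{without}, each as
#'   returned by \code{\link{fst_matrix}}.
#' @export
fst_with_without_commercial <- function(mlgs, populations, classification,
                                        n_permutations = 999, seed = NULL) {
  cat_of <- classification$category[match(mlgs$ids, classification$mlg_id)]
  if (anyNA(cat_of)) stop("classification missing for some MLGs")
  if (!is.null(seed)) set.seed(seed)
  with_all <- fst_matrix(mlgs, populations, n_permutations = n_permutations)
  keep <- cat_of == "unique"
  without <- fst_matrix(mlgs[which(keep)], populations[keep],
                        n_permutations = n_permutations)
  list(with = with_all, without = without)
}
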