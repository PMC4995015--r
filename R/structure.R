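#' Genotype log-likelihood under the inbreeding admixture model
#'
#' Probability of one diploid locus-genotype given origin in a population
#' with allele frequencies \code{freqs} and inbreeding coefficient \code{f}:
#' a homozygote \eqn{aa} has probability \eqn{f p_a + (1-f) p_a^2} (the first
#' term is the identity-by-descent route), a heterozygote \eqn{ab} has
#' \eqn{(1-f)\,2 p_a p_b}. Probabilities are floored so an impossible
#' configuration (e.g. a heterozygote under f = 1) never returns -Inf.
#'
#' @param a1,a2 allele indices into \code{freqs} (1-based).
#' @param freqs allele-frequency vector for the locus in one population.
#' @param f inbreeding coefficient in [0, 1].
#' @param floor lower probability bound (default 1e-9).
#' @return log-probability.
#' @export
genotype_log_likelihood <- function(a1, a2, freqs, f, floor = 1e-9) {
  stopifnot(f >= 0, f <= 1, a1 >= 1, a2 >= 1,
            a1 <= length(freqs), a2 <= length(freqs))
  pa <- freqs[a1]
  g <- if (a1 == a2) f * pa + (1 - f) * pa^2 else (1 - f) * 2 * pa * freqs[a2]
  log(max(g, floor))
}

# encode an mlg_set as 0-based allele indices per locus
encode_alleles <- function(mlgs) {
  L <- nrow(mlgs$loci)
  n <- n_mlg(mlgs)
  a1 <- a2 <- matrix(0L, n, L)
  n_alleles <- integer(L)
  levels <- vector("list", L)
  for (l in seq_len(L)) {
    lev <- sort(unique(c(mlgs$alleles[, l, ])))
    levels[[l]] <- lev
    n_alleles[l] <- length(lev)
    a1[, l] <- match(mlgs$alleles[, l, 1], lev) - 1L
    a2[, l] <- match(mlgs$alleles[, l, 2], lev) - 1L
  }
  list(a1 = a1, a2 = a2, n_alleles = n_alleles, levels = levels)
}

#' Run one MCMC chain of the inbreeding admixture model
#'
#' Bayesian clustering of diploid multilocus genotypes into K populations,
#' each with its own allele frequencies and inbreeding coefficient, with
#' proportional (admixed) individual membership. Fitted by an augmented
#' Gibbs sampler (categorical origins per locus-genotype, Dirichlet
#' membership and allele-frequency updates, Beta inbreeding update via an
#' identity-by-descent indicator). Deviance is recorded every \code{thin}
#' post-burn-in sweeps and summarised as DIC = mean deviance + p_D, with
#' p_D = mean deviance - deviance at the posterior means.
#'
#' @param mlgs clone-censored \code{mlg_set}.
#' @param K number of clusters (>= 1; K = 1 gives q identically 1).
#' @param iterations total sweeps (> burn_in).
#' @param burn_in sweeps discarded before recording.
#' @param thin record every thin-th post-burn-in sweep (default 10).
#' @param seed integer seed (chains with equal seeds are identical).
#' @param alpha Dirichlet hyperparameter for membership (default 1/K).
#' @param freq_prior Dirichlet prior mass per allele (default 1).
#' @return Object of class \code{msat_chain}: \code{q} (N x K posterior mean
#'   membership, rows named by MLG id), \code{f} (posterior mean inbreeding
#'   per cluster), \code{p} (per-locus posterior mean allele frequencies),
#'   \code{deviance_samples}, \code{DIC}, \code{p_D}, plus the settings.
#' @export
run_chain <- function(mlgs, K, iterations = 20000, burn_in = 5000,
                      thin = 10, seed = 1, alpha = 1 / K, freq_prior = 1) {
  stopifnot(K >= 1, iterations > burn_in, thin >= 1)
  if (K > n_mlg(mlgs)) stop("K exceeds the number of individuals")
  enc <- encode_alleles(mlgs)
  set.seed(seed)
  fit <- .admixture_gibbs(enc$a1, enc$a2, enc$n_alleles, as.integer(K),
                          as.integer(iterations), as.integer(burn_in),
                          as.integer(thin), alpha, freq_prior)
  mean_dev <- mean(fit$deviance_samples)
  p_D <- mean_dev - fit$deviance_at_mean
  q <- fit$q_mean
  rownames(q) <- mlgs$ids
  colnames(q) <- paste0("K", seq_len(K))
  names(fit$p_mean) <- mlgs$loci$name
  structure(list(K = K, q = q, f = as.numeric(fit$f_mean), p = fit$p_mean,
                 allele_levels = enc$levels,
                 deviance_samples = as.numeric(fit$deviance_samples),
                 DIC = mean_dev + p_D, p_D = p_D, mean_deviance = mean_dev,
                 seed = seed, iterations = iterations, burn_in = burn_in,
                 thin = thin, alpha = alpha),
            class = "msat_chain")
}

#' @export
print.msat_chain <- function(x, ...) {
  cat(sprintf("msat_chain: K = %d, %d individuals, DIC = %.1f (p_D = %.1f), seed %d\n",
              x$K, nrow(x$q), x$DIC, x$p_D, x$seed))
  invisible(x)
}

#' Select the number of clusters by DIC
#'
#' Runs \code{chains_per_k} chains for every K in \code{k_range}, averages
#' the per-chain DIC for each K and reports the K with the lowest mean DIC
#' together with the full table. Per-chain seeds are derived
#' deterministically from \code{seed}.
#'
#' @param mlgs clone-censored \code{mlg_set}.
#' @param k_range integer vector of K values to try.
#' @param chains_per_k chains per K (default 1).
#' @param iterations,burn_in,thin,alpha,freq_prior passed to
#'   \code{\link{run_chain}}.
#' @param seed master seed.
#' @param keep_chains if TRUE, keep every chain object (memory permitting).
#' @return List: \code{best_k}, \code{dic_table} (K, chain, seed, DIC, p_D),
#'   \code{dic_by_k} (mean DIC per K), \code{best_chain} (lowest-DIC chain at
#'   the selected K), and \code{chains} when requested.
#' @export
select_k <- function(mlgs, k_range, chains_per_k = 1, iterations = 20000,
                     burn_in = 5000, thin = 10, seed = 1, alpha = NULL,
                     freq_prior = 1, keep_chains = FALSE) {
  stopifnot(length(k_range) >= 1)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(k_range) * chains_per_k),
                  nrow = length(k_range))
  tab <- NULL
  chains <- list()
  best_per_k <- list()  # lowest-DIC chain at each K
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    for (ci in seq_len(chains_per_k)) {
      ch <- run_chain(mlgs, K, iterations = iterations, burn_in = burn_in,
                      thin = thin, seed = seeds[ki, ci],
                      alpha = if (is.null(alpha)) 1 / K else alpha,
                      freq_prior = freq_prior)
      tab <- rbind(tab, data.frame(K = K, chain = ci, seed = seeds[ki, ci],
                                   DIC = ch$DIC, p_D = ch$p_D))
      if (keep_chains) chains[[length(chains) + 1L]] <- ch
      key <- as.character(K)
      if (is.null(best_per_k[[key]]) || ch$DIC < best_per_k[[key]]$DIC)
        best_per_k[[key]] <- ch
    }
  }
  dic_by_k <- stats::aggregate(DIC ~ K, data = tab, FUN = mean)
  best_k <- dic_by_k$K[which.min(dic_by_k$DIC)]
  best_chain <- best_per_k[[as.character(best_k)]]
  out <- list(best_k = best_k, dic_table = tab, dic_by_k = dic_by_k,
              best_chain = best_chain)
  if (keep_chains) out$chains <- chains
  out
}

#' Write a Q matrix in STRUCTURE/CLUMPP indfile-style format
#'
#' One whitespace-delimited row per individual: id, group label, then the K
#' membership coefficients.
#'
#' @param q N x K matrix with row names.
#' @param path output path.
#' @param groups optional group label per individual.
#' @export
write_qmatrix <- function(q, path, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, nrow(q))
  df <- data.frame(id = rownames(q), group = groups,
                   format(q, digits = 6, trim = TRUE))
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Q matrix written by \code{\link{write_qmatrix}}
#' @param path input path.
#' @param K number of membership columns.
#' @return list with \code{q} (matrix, row names = ids) and \code{groups}.
#' @export
read_qmatrix <- function(path, K) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != K + 2L) stop("expected ", K + 2L, " columns")
  q <- as.matrix(df[, 2L + seq_len(K)])
  rownames(q) <- df[[1]]
  colnames(q) <- paste0("K", seq_len(K))
  list(q = q, groups = df[[2]])
}
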