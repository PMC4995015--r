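#' Align replicate clustering runs (greedy label matching)
#'
#' Cluster labels are arbitrary in each MCMC run, so replicate Q matrices
#' must be aligned before averaging. Runs are taken in a random order; each
#' new run's columns are matched to the running consensus greedily, by
#' repeatedly picking the unmatched (consensus column, run column) pair with
#' the highest similarity (smallest squared distance). The whole procedure is
#' repeated for \code{n_input_orders} random run orders and the result with
#' the highest H is kept. The similarity of two aligned runs is
#' \eqn{1 - \|Q - Q'\|_F / \sqrt{2N}} and H is its mean over run pairs.
#'
#' @param runs list of N x K membership matrices (same individuals, same K).
#' @param n_input_orders random run orders to try (default 100).
#' @param seed optional integer seed.
#' @return List of class \code{alignment_result}: \code{permutations} (per
#'   run, the column permutation applied), \code{aligned} (the permuted
#'   runs), \code{consensus_q} (their mean), \code{H}.
#' @export
align_runs <- function(runs, n_input_orders = 100, seed = NULL) {
  stopifnot(length(runs) >= 1)
  dims <- vapply(runs, dim, c(1L, 1L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all runs must have identical dimensions")
  R <- length(runs)
  K <- ncol(runs[[1]])
  if (!is.null(seed)) set.seed(seed)
  if (R == 1L)
    return(structure(list(permutations = list(seq_len(K)), aligned = runs,
                          consensus_q = runs[[1]], H = 1),
                     class = "alignment_result"))
  best <- NULL
  for (o in seq_len(n_input_orders)) {
    ord <- sample(R)
    perms <- vector("list", R)
    perms[[ord[1]]] <- seq_len(K)
    csum <- runs[[ord[1]]]
    cn <- 1L
    for (ri in ord[-1]) {
      pm <- greedy_match(csum / cn, runs[[ri]])
      perms[[ri]] <- pm
      csum <- csum + runs[[ri]][, pm, drop = FALSE]
      cn <- cn + 1L
    }
    aligned <- lapply(seq_len(R), function(r) runs[[r]][, perms[[r]], drop = FALSE])
    h <- alignment_H(aligned)
    if (is.null(best) || h > best$H)
      best <- list(permutations = perms, aligned = aligned,
                   consensus_q = Reduce(`+`, aligned) / R, H = h)
  }
  structure(best, class = "alignment_result")
}

# greedy assignment: perm[j] = column of run matched to consensus column j
greedy_match <- function(consensus, run) {
  K <- ncol(consensus)
  S <- matrix(0, K, K)
  for (j in seq_len(K)) for (m in seq_len(K))
    S[j, m] <- -sum((consensus[, j] - run[, m])^2)
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- which(S == max(S), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    S[idx[1], ] <- -Inf
    S[, idx[2]] <- -Inf
  }
  perm
}

# mean pairwise similarity 1 - ||Qa - Qb||_F / sqrt(2N)
alignment_H <- function(aligned) {
  R <- length(aligned)
  N <- nrow(aligned[[1]])
  if (R < 2L) return(1)
  tot <- 0; np <- 0L
  for (a in seq_len(R - 1L)) for (b in (a + 1L):R) {
    tot <- tot + 1 - sqrt(sum((aligned[[a]] - aligned[[b]])^2)) / sqrt(2 * N)
    np <- np + 1L
  }
  tot / np
}

#' Ancestry-profile R-squared against a grouping factor
#'
#' Quantifies how much of the total variance of membership coefficients is
#' explained by a grouping (e.g. sampling location):
#' \eqn{R^2 = 1 - SS_{within}/SS_{total}} over all individuals and clusters,
#' with group means per cluster. Significance by permuting group labels.
#' Also reports pairwise group R-squared and leave-one-out values after
#' dropping each group and each cluster column (rows renormalised).
#'
#' @param q N x K consensus membership matrix.
#' @param groups group label per individual (>= 2 distinct groups).
#' @param n_permutations label permutations (default 999).
#' @param seed optional integer seed.
#' @return List of class \code{obstruct_result}: r2, p_value, pairwise_r2
#'   (matrix over group pairs), loo_groups, loo_clusters.
#' @export
obstruct_r2 <- function(q, groups, n_permutations = 999, seed = NULL) {
  q <- as.matrix(q)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(q))
  glev <- unique(groups)
  if (length(glev) < 2L) stop("at least 2 groups required")
  if (!is.null(seed)) set.seed(seed)
  obs <- r2_stat(q, groups)
  hits <- 0L
  for (r in seq_len(n_permutations)) {
    if (r2_stat(q, sample(groups)) >= obs - 1e-15) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_permutations + 1)
  pw <- matrix(NA_real_, length(glev), length(glev), dimnames = list(glev, glev))
  for (i in seq_along(glev)) for (j in seq_along(glev)) {
    if (i >= j) next
    sel <- groups %in% glev[c(i, j)]
    pw[i, j] <- pw[j, i] <- r2_stat(q[sel, , drop = FALSE], groups[sel])
  }
  loo_g <- vapply(glev, function(g) {
    sel <- groups != g
    if (length(unique(groups[sel])) < 2L) return(NA_real_)
    r2_stat(q[sel, , drop = FALSE], groups[sel])
  }, 0)
  loo_c <- vapply(seq_len(ncol(q)), function(k) {
    qq <- q[, -k, drop = FALSE]
    rs <- rowSums(qq)
    rs[rs == 0] <- 1
    r2_stat(qq / rs, groups)
  }, 0)
  names(loo_c) <- colnames(q)
  structure(list(r2 = obs, p_value = p, n_permutations = n_permutations,
                 pairwise_r2 = pw, loo_groups = loo_g, loo_clusters = loo_c),
            class = "obstruct_result")
}

# R2 = 1 - SS_within / SS_total on membership profiles; 0 when SS_total = 0
r2_stat <- function(q, groups) {
  centred <- sweep(q, 2, colMeans(q))
  ss_tot <- sum(centred^2)
  if (ss_tot == 0) return(0)
  ss_w <- 0
  for (g in unique(groups)) {
    sub <- q[groups == g, , drop = FALSE]
    ss_w <- ss_w + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  1 - ss_w / ss_tot
}
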