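# Independent oracles and small fixture builders shared across tests.

# build an mlg_set from an n x 2L matrix of allele sizes (paired columns)
quick_mlgs <- function(mat, ids = sprintf("M%02d", seq_len(nrow(mat))),
                       loci = default_loci()) {
  mlg_set(as.matrix(mat), ids, loci)
}

# a deliberately naive Bruvo implementation: enumerates both diploid
# matchings per locus from the raw definition
oracle_bruvo <- function(a, b, unit_lengths) {
  # a, b: L x 2 matrices
  stopifnot(nrow(a) == nrow(b))
  per_allele <- function(x, y, u) {
    steps <- floor(abs(x - y) / u + 0.5)
    1 - 2^(-steps)
  }
  d <- numeric(nrow(a))
  for (l in seq_len(nrow(a))) {
    u <- unit_lengths[l]
    m1 <- mean(c(per_allele(a[l, 1], b[l, 1], u), per_allele(a[l, 2], b[l, 2], u)))
    m2 <- mean(c(per_allele(a[l, 1], b[l, 2], u), per_allele(a[l, 2], b[l, 1], u)))
    d[l] <- min(m1, m2)
  }
  mean(d)
}

# exhaustive rarefaction: average distinct-species count over all C(n, g)
# subsets of the individual list
oracle_rarefy <- function(abundances, g) {
  pool <- rep(seq_along(abundances), abundances)
  subs <- utils::combn(length(pool), g)
  mean(apply(subs, 2, function(ix) length(unique(pool[ix]))))
}

# all abundance multisets (integer partitions) of n
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - k, k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

# all permutations of 1..k
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    for (p in all_perms(k - 1L)) {
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# exhaustive label alignment of run2 onto run1: best column permutation by
# the Frobenius similarity used for H
oracle_align <- function(q1, q2) {
  K <- ncol(q1)
  best <- -Inf
  best_perm <- seq_len(K)
  for (p in all_perms(K)) {
    s <- 1 - sqrt(sum((q1 - q2[, p, drop = FALSE])^2)) / sqrt(2 * nrow(q1))
    if (s > best) { best <- s; best_perm <- p }
  }
  list(perm = best_perm, similarity = best)
}

# random diploid genotype matrix on the default 8-locus panel
random_genotypes <- function(n, loci = default_loci(),
                             repeat_range = 5:30) {
  L <- nrow(loci)
  base <- rep(150L, L)
  alle <- array(0L, dim = c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    r <- sample(repeat_range, 2, replace = TRUE)
    alle[i, l, ] <- sort(base[l] + loci$unit_length[l] * r)
  }
  mlg_set(alle, sprintf("R%03d", seq_len(n)), loci)
}

# Dirichlet draws (rows sum to 1)
rdirichlet_mat <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), alpha), n, byrow = TRUE)
  x / rowSums(x)
}

# replicate-structured Q runs: a base run plus column-permuted noisy copies
replicate_runs <- function(n_runs, N, K, noise = 20) {
  base <- rdirichlet_mat(N, rep(0.3, K))
  runs <- list(base)
  perms <- list(seq_len(K))
  for (r in seq_len(n_runs - 1L)) {
    pm <- sample(K)
    noisy <- base[, pm, drop = FALSE] * matrix(stats::rgamma(N * K, noise), N)
    runs[[r + 1L]] <- noisy / rowSums(noisy)
    perms[[r + 1L]] <- pm
  }
  list(runs = runs, perms = perms)
}

# tiny isolate data frame around an mlg id vector
quick_isolates <- function(mlg_ids, location = "HE", vintage = 2013,
                           fermentation_id = "F1", stage = "late") {
  n <- length(mlg_ids)
  data.frame(isolate_id = sprintf("I%03d", seq_len(n)),
             location = rep_len(location, n),
             vintage = rep_len(vintage, n),
             fermentation_id = rep_len(fermentation_id, n),
             stage = rep_len(stage, n),
             mlg_id = mlg_ids, stringsAsFactors = FALSE)
}
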