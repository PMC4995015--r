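geno <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

test_that("locus statistics match direct counting", {
  s <- locus_stats(geno(1, 1, 1, 2, 2, 2, 1, 2))  # AA, AB, BB, AB
  expect_equal(s$Ho, 0.5)
  expect_equal(s$He, 0.5)
  expect_equal(s$Fis, 0)
  s2 <- locus_stats(geno(1, 1, 2, 2))             # AA, BB
  expect_equal(s2$Ho, 0)
  expect_equal(s2$He, 0.5)
  expect_equal(s2$Fis, 1)
  s3 <- locus_stats(geno(1, 1, 1, 1))             # monomorphic
  expect_equal(s3$Ho, 0)
  expect_equal(s3$He, 0)
  expect_true(is.na(s3$Fis))
})

test_that("He is bounded by 1 - 1/k and all statistics lie in [0,1]", {
  set.seed(21)
  for (rep in 1:25) {
    g <- matrix(sample(1:5, 40, replace = TRUE), ncol = 2)
    s <- locus_stats(g)
    expect_lte(s$He, 1 - 1 / s$allele_count + 1e-12)
    expect_gte(s$Ho, 0); expect_lte(s$Ho, 1)
    expect_gte(s$He, 0)
  }
})

test_that("HWE test: exact proportions give statistic 0 and p 1", {
  g <- geno(rep(c(1, 1), 25), rep(c(1, 2), 50), rep(c(2, 2), 25))
  r <- hwe_test(g, method = "chisq")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 1)
  r2 <- hwe_test(g, method = "monte_carlo", n_reps = 199, seed = 1)
  expect_equal(r2$p_value, 1)
})

test_that("HWE test: two fixed homozygote classes are strongly rejected", {
  g <- geno(rep(c(1, 1), 50), rep(c(2, 2), 50))
  r <- hwe_test(g, method = "monte_carlo", n_reps = 10000, seed = 2)
  expect_lt(r$p_value, 0.001)
})

test_that("two-allele chi-square matches the closed-form df=1 statistic", {
  set.seed(22)
  g <- matrix(sample(1:2, 60, replace = TRUE, prob = c(0.7, 0.3)), ncol = 2)
  r <- hwe_test(g, method = "chisq")
  n <- nrow(g)
  p <- mean(g == 1)
  obs <- c(sum(g[, 1] == 1 & g[, 2] == 1),
           sum(g[, 1] != g[, 2]),
           sum(g[, 1] == 2 & g[, 2] == 2))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(r$statistic, sum((obs - e)^2 / e))
  expect_equal(r$df, 1)
})

test_that("monomorphic locus yields an undefined-flag result, not an error", {
  r <- hwe_test(geno(1, 1, 1, 1))
  expect_false(r$defined)
  expect_true(is.na(r$p_value))
})

# helper: single-locus mlg_set from explicit genotype rows, padding the other
# loci with a constant (monomorphic) profile
single_locus_set <- function(g, ids = sprintf("i%02d", seq_len(nrow(g)))) {
  loci <- default_loci()
  alle <- array(150L, dim = c(nrow(g), 8, 2))
  alle[, 1, 1] <- as.integer(pmin(g[, 1], g[, 2]))
  alle[, 1, 2] <- as.integer(pmax(g[, 1], g[, 2]))
  mlg_set(alle, ids, loci)
}

test_that("F_ST is 0 for identical populations and 1 for fixed disjoint ones", {
  g <- geno(rep(c(100, 103), 5), rep(c(100, 100), 3), rep(c(103, 103), 2))
  a <- single_locus_set(g)
  b <- single_locus_set(g, ids = sprintf("j%02d", seq_len(nrow(g))))
  r <- pairwise_fst(a, b, n_permutations = 49, seed = 1)
  expect_equal(r$fst, 0)
  fixed_a <- single_locus_set(geno(rep(c(100, 100), 6)))
  fixed_b <- single_locus_set(geno(rep(c(130, 130), 6)),
                              ids = sprintf("j%02d", 1:6))
  # make every locus disjointly fixed so Hs = 0, Ht > 0
  fixed_b$alleles[, , ] <- 130L
  r2 <- pairwise_fst(fixed_a, fixed_b, n_permutations = 49, seed = 1)
  expect_equal(r2$fst, 1)
})

test_that("the (0.8, 0.2) vs (0.2, 0.8) single-locus case gives F_ST 0.36", {
  a <- single_locus_set(geno(rep(c(100, 100), 8), rep(c(103, 103), 2)))
  b <- single_locus_set(geno(rep(c(100, 100), 2), rep(c(103, 103), 8)),
                        ids = sprintf("j%02d", 1:10))
  # restrict to the informative locus by making the others identical anyway
  r <- pairwise_fst(a, b, n_permutations = 99, seed = 3)
  # 7 monomorphic loci contribute Hs = Ht = 0; means over loci keep the ratio
  expect_equal(r$fst_raw, 0.36, tolerance = 1e-12)
})

abind_test <- function(ga, gb) {
  n <- nrow(ga) + nrow(gb)
  arr <- array(0L, dim = c(n, 1, 2))
  arr[, 1, ] <- rbind(ga, gb)
  arr
}

test_that("F_ST is invariant under allele relabelling", {
  set.seed(23)
  ga <- matrix(sample(1:4, 40, replace = TRUE), ncol = 2)
  gb <- matrix(sample(1:4, 40, replace = TRUE, prob = c(4, 3, 2, 1)), ncol = 2)
  f1 <- msatpop:::fst_gst(abind_test(ga, gb), 1:20, 21:40)
  relab <- c(7, 5, 9, 2)  # bijective relabelling
  f2 <- msatpop:::fst_gst(abind_test(matrix(relab[ga], ncol = 2),
                                     matrix(relab[gb], ncol = 2)), 1:20, 21:40)
  expect_equal(f1, f2)
})

test_that("permutation p-values are deterministic under a fixed seed", {
  set.seed(24)
  a <- single_locus_set(matrix(sample(c(100, 103, 106), 20, replace = TRUE), ncol = 2))
  b <- single_locus_set(matrix(sample(c(100, 103, 106), 20, replace = TRUE), ncol = 2),
                        ids = sprintf("j%02d", 1:10))
  r1 <- pairwise_fst(a, b, n_permutations = 99, seed = 42)
  r2 <- pairwise_fst(a, b, n_permutations = 99, seed = 42)
  expect_identical(r1, r2)
})

test_that("removal of commercial-derived strains lowers every pairwise F_ST", {
  set.seed(25)
  shared <- random_genotypes(12, repeat_range = 40:60)
  com_a <- random_genotypes(8, repeat_range = 5:12)
  com_b <- random_genotypes(8, repeat_range = 20:27)
  com_a$ids <- paste0("CA", 1:8); dimnames(com_a$alleles)[[1]] <- com_a$ids
  com_b$ids <- paste0("CB", 1:8); dimnames(com_b$alleles)[[1]] <- com_b$ids
  all_m <- c_mlg(shared, com_a, com_b)
  # both locations carry the same shared uniques; the commercial-derived
  # strains are location-specific and carry all the differentiation
  loc_a_ids <- c(shared$ids, com_a$ids)
  loc_b_ids <- c(paste0("b_", shared$ids), com_b$ids)
  dup <- mlg_set(all_m$alleles[c(seq_len(12), 13:20,
                                 seq_len(12), 21:28), , , drop = FALSE],
                 c(loc_a_ids, loc_b_ids), shared$loci)
  pops <- rep(c("A", "B"), each = 20)
  cls <- data.frame(mlg_id = dup$ids,
                    category = rep(c("unique", "commercial_related",
                                     "unique", "commercial_related"),
                                   c(12, 8, 12, 8)))
  res <- fst_with_without_commercial(dup, pops, cls, n_permutations = 29,
                                     seed = 5)
  f_with <- res$with$pairs$fst
  f_without <- res$without$pairs$fst
  expect_true(all(f_without < f_with))
  expect_equal(f_without, 0)  # identical unique sets remain
})

test_that("population summary reports per-locus rows and across-locus SE", {
  set.seed(26)
  g <- random_genotypes(20)
  pops <- rep(c("HE", "OG"), each = 10)
  ps <- population_summary(g, pops)
  expect_equal(nrow(ps$per_locus), 16)  # 2 pops x 8 loci
  expect_equal(nrow(ps$summary), 2)
  he_rows <- ps$per_locus$He[ps$per_locus$population == "HE"]
  expect_equal(ps$summary$He_mean[ps$summary$population == "HE"], mean(he_rows))
  expect_equal(ps$summary$He_se[ps$summary$population == "HE"],
               sd(he_rows) / sqrt(8))
})
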