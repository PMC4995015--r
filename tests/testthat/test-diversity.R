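test_that("rarefied richness matches exhaustive enumeration on small sets", {
  expect_equal(rarefy_richness(c(2, 1, 1), 2), 11 / 6, tolerance = 1e-12)
  ab <- c(3, 2, 1, 1)
  for (g in 1:sum(ab))
    expect_equal(rarefy_richness(ab, g), oracle_rarefy(ab, g), tolerance = 1e-12)
})

test_that("rarefaction boundary cases: g = n and a single MLG", {
  expect_equal(rarefy_richness(c(4, 3, 2), 9), 3)
  expect_equal(rarefy_richness(7, 3), 1)
  expect_error(rarefy_richness(c(2, 2), 5), "between")
})

test_that("rarefaction is monotone non-decreasing in g", {
  ab <- c(5, 3, 2, 2, 1)
  vals <- vapply(1:sum(ab), function(g) rarefy_richness(ab, g), 0)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("accumulation curve is constant at 1 for identical isolates", {
  loci <- default_loci()
  a <- array(rep(150L, 5 * 8 * 2), dim = c(5, 8, 2))
  g <- mlg_set(a, paste0("i", 1:5), loci)
  res <- genotype_accumulation(g, n_shuffles = 30, seed = 1)
  expect_true(all(res$samples == 1))
  expect_equal(res$total, 1)
})

test_that("a single fully-resolving locus yields total richness when present", {
  loci <- default_loci()
  a <- array(150L, dim = c(6, 8, 2))
  a[, 1, 1] <- a[, 1, 2] <- 150L + 3L * (1:6)  # locus 1 separates everything
  g <- mlg_set(a, paste0("i", 1:6), loci)
  res <- genotype_accumulation(g, n_shuffles = 200, seed = 2)
  # every subset of >= 1 locus either contains locus 1 (richness 6) or not (1)
  expect_true(all(res$samples %in% c(1L, 6L)))
  expect_equal(res$total, 6)
})

test_that("3-locus fixture matches exhaustive subset enumeration", {
  loci <- locus_table(c("A", "B", "C"), c("TA", "TA", "TA"), c(2, 2, 2))
  a <- array(0L, dim = c(4, 3, 2))
  a[, 1, ] <- c(100L, 100L, 102L, 102L)   # locus A splits {1,2} vs {3,4}
  a[, 2, ] <- c(100L, 102L, 100L, 102L)   # locus B splits odd/even
  a[, 3, ] <- 100L                        # locus C uninformative
  g <- mlg_set(a, paste0("i", 1:4), loci)
  res <- genotype_accumulation(g, n_shuffles = 300, seed = 3)
  distinct_for <- function(loci_idx) {
    key <- apply(matrix(a[, loci_idx, ], nrow = 4), 1, paste, collapse = "/")
    length(unique(key))
  }
  enum1 <- vapply(1:3, function(l) distinct_for(l), 0)            # m = 1
  enum2 <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), distinct_for, 0) # m = 2
  expect_setequal(unique(res$samples[, 1]), unique(enum1))
  expect_setequal(unique(res$samples[, 2]), unique(enum2))
  expect_equal(mean(res$samples[, 1]), mean(enum1), tolerance = 0.15)
  expect_equal(mean(res$samples[, 2]), mean(enum2), tolerance = 0.15)
})

test_that("chi-square with ASRs: flat table gives zero everywhere", {
  r <- chi_square_asr(matrix(10, 2, 2))
  expect_equal(r$chi2, 0)
  expect_equal(unname(r$asr), matrix(0, 2, 2))
  expect_false(any(r$cell_significant))
})

test_that("2x2 chi-square equals the closed-form N(ad-bc)^2/(r1 r2 c1 c2)", {
  o <- matrix(c(12, 7, 5, 9), 2, 2)
  r <- chi_square_asr(o)
  closed <- sum(o) * (o[1, 1] * o[2, 2] - o[1, 2] * o[2, 1])^2 /
    prod(rowSums(o), colSums(o))
  expect_equal(r$chi2, closed, tolerance = 1e-12)
  expect_equal(r$chi2, 2.431, tolerance = 1e-3)
})

test_that("ASR-squared path reproduces the chi-square on 2x2 tables", {
  set.seed(31)
  for (rep in 1:10) {
    o <- matrix(rpois(4, 20) + 1, 2, 2)
    r <- chi_square_asr(o)
    # on a 2x2 all four ASRs are equal in magnitude and ASR^2 = chi2
    expect_equal(unname(r$asr[1, 1]^2), r$chi2, tolerance = 1e-10)
  }
})

test_that("Bonferroni cell flags are a subset of unadjusted flags", {
  set.seed(32)
  o <- matrix(rpois(6, 30) + 1, 2, 3)
  r <- chi_square_asr(o)
  unadj <- r$cell_p < 0.05
  expect_true(all(!r$cell_significant | unadj))
})

test_that("zero marginals are a hard error", {
  expect_error(chi_square_asr(matrix(c(0, 0, 5, 6), 2, 2)), "marginal")
})

test_that("Friedman test handles complete ties and strong orderings", {
  all_equal <- matrix(5, nrow = 6, ncol = 3)
  r <- friedman_rank_test(all_equal)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(33)
  strong <- cbind(rnorm(10, 0), rnorm(10, 0), rnorm(10, 10))
  r2 <- friedman_rank_test(strong)
  expect_lt(r2$p_value, 0.01)
})

test_that("Friedman statistic is rank-based (monotone-transform invariant)", {
  set.seed(34)
  x <- matrix(runif(18), 6, 3)
  r1 <- friedman_rank_test(x)
  r2 <- friedman_rank_test(exp(3 * x))
  expect_equal(r1$statistic, r2$statistic)
})

test_that("tie-free Friedman equals the base-R implementation", {
  set.seed(35)
  x <- matrix(rnorm(24), 8, 3)
  ours <- friedman_rank_test(x)
  base <- stats::friedman.test(x)
  expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
})

test_that("Welch t-test: identical samples, shifted samples, exclusions", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- welch_t_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(r2$p_value, 0.05)
  tt <- stats::t.test(c(1, 2, 3), c(11, 12, 13), var.equal = FALSE)
  expect_equal(r2$statistic, unname(tt$statistic))
  expect_equal(r2$df, unname(tt$parameter))
  r3 <- welch_t_test(c(0.1, 0.2, 0.3, 0.55), c(0.5, 0.6, 0.7),
                     exclude = 0.55)
  expect_equal(r3$n_a, 3)
  expect_equal(attr(r3, "excluded_points"), 0.55)
  expect_error(welch_t_test(c(1, 2), c(3, 4), exclude = c(1, 2)), ">= 2")
})
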