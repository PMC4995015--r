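test_that("allele distance follows the stepwise-mutation formula", {
  expect_equal(bruvo_allele_distance(150, 150, 3), 0)
  expect_equal(bruvo_allele_distance(150, 153, 3), 0.5)
  expect_equal(bruvo_allele_distance(150, 156, 3), 0.75)
  # non-integer repeat differences round to nearest, ties away from zero
  expect_equal(bruvo_allele_distance(150, 151, 2), 0.5)   # 0.5 -> 1 step
  expect_equal(bruvo_allele_distance(150, 151, 3), 0)     # 0.33 -> 0 steps
  expect_true(all(bruvo_allele_distance(100, 100 + 0:50, 2) < 1))
})

test_that("locus distance is the minimum over diploid matchings", {
  expect_equal(bruvo_locus_distance(c(150, 156), c(150, 153), 3), 0.25)
  expect_equal(bruvo_locus_distance(c(150, 153), c(150, 153), 3), 0)
  expect_equal(bruvo_locus_distance(c(150, 150), c(153, 153), 3), 0.5)
})

test_that("MLG distance is the mean of locus distances", {
  loci <- default_loci()
  a <- matrix(rep(c(150L, 150L), 8), nrow = 8, byrow = TRUE)
  m1 <- mlg_set(array(a, dim = c(1, 8, 2)), "A", loci)
  b <- a; b[1, ] <- b[1, ] + loci$unit_length[1]  # one repeat unit, one locus
  m2 <- mlg_set(array(b, dim = c(1, 8, 2)), "B", loci)
  expect_equal(bruvo_mlg_distance(c_mlg(m1, m2)), 0.5 / 8)
  expect_equal(bruvo_mlg_distance(m1, m1), 0)
})

test_that("vectorised distances equal the brute-force matching oracle", {
  set.seed(11)
  g <- random_genotypes(40)
  dm <- bruvo_dist(g)
  u <- g$loci$unit_length
  for (rep in 1:60) {
    ij <- sample(40, 2)
    expect_equal(dm[ij[1], ij[2]],
                 oracle_bruvo(g$alleles[ij[1], , ], g$alleles[ij[2], , ], u),
                 tolerance = 1e-14)
  }
})

test_that("distance matrix is symmetric, bounded, zero iff identical", {
  set.seed(12)
  extra <- random_genotypes(1)
  extra$ids <- "X001"; dimnames(extra$alleles)[[1]] <- "X001"
  g <- c_mlg(random_genotypes(20), extra)
  g$alleles[21, , ] <- g$alleles[1, , ]  # planted duplicate profile
  dm <- bruvo_dist(g)
  expect_equal(dm, t(dm))
  expect_true(all(dm >= 0 & dm < 1))
  expect_equal(unname(diag(dm)), rep(0, 21))
  keys <- apply(matrix(g$alleles, nrow = 21), 1, paste, collapse = "/")
  same <- outer(keys, keys, "==")
  expect_equal(unname(dm == 0), unname(same))
})

test_that("classification applies the strictly-below threshold rule", {
  set.seed(13)
  panel <- random_genotypes(10, repeat_range = 5:15)
  # exact copy -> commercial
  q_com <- panel[2]
  q_com$ids <- "copy"; dimnames(q_com$alleles)[[1]] <- "copy"
  # one repeat unit off at one locus -> distance 0.0625 -> related
  a <- panel$alleles[3, , ]
  a[4, ] <- a[4, ] + panel$loci$unit_length[4]
  q_rel <- mlg_set(array(a, dim = c(1, 8, 2)), "rel", panel$loci)
  # far genotype -> unique
  q_far <- random_genotypes(1, repeat_range = 200:220)
  q_far$ids <- "far"; dimnames(q_far$alleles)[[1]] <- "far"
  res <- classify_mlgs(c_mlg(q_com, q_rel, q_far), panel)
  cls <- res$classification
  expect_equal(cls$category, c("commercial", "commercial_related", "unique"))
  expect_equal(cls$min_distance[1], 0)
  expect_equal(cls$derived_label[2], paste0("SB_", cls$nearest_commercial[2]))
  expect_true(cls$min_distance[3] > 0.43)
  expect_equal(sum(res$histogram$count), 3)
})

test_that("a genotype exactly at the threshold classifies unique", {
  loci <- default_loci()
  base <- matrix(rep(150L, 16), nrow = 8)
  panel <- mlg_set(array(base, dim = c(1, 8, 2)), "P", loci)
  # distance exactly 0.25: two loci fully one-repeat-off homozygous (0.5 each)
  q <- base
  q[1, ] <- q[1, ] + loci$unit_length[1] * 30L  # d ~ 1, locus ~ (1-2^-30)
  q2 <- base
  q2[1, ] <- q2[1, ] + loci$unit_length[1]      # 0.5
  q2[2, ] <- q2[2, ] + loci$unit_length[2]      # 0.5
  q2[3, ] <- q2[3, ] + loci$unit_length[3]      # 0.5
  q2[4, ] <- q2[4, ] + loci$unit_length[4]      # 0.5
  m <- mlg_set(array(q2, dim = c(1, 8, 2)), "Q", loci)
  d <- bruvo_dist(m, panel)[1, 1]
  expect_equal(d, 0.25)
  cls <- classify_mlgs(m, panel)$classification
  expect_equal(cls$category, "unique")
})

test_that("classification is invariant to input order", {
  set.seed(14)
  panel <- random_genotypes(8)
  q <- random_genotypes(15, repeat_range = 5:40)
  r1 <- classify_mlgs(q, panel)$classification
  ord <- sample(15)
  r2 <- classify_mlgs(q[ord], panel)$classification
  expect_equal(r1[match(r2$mlg_id, r1$mlg_id), "category"], r2$category)
  expect_equal(r1[match(r2$mlg_id, r1$mlg_id), "min_distance"], r2$min_distance)
})

test_that("empty panel is a hard error", {
  set.seed(15)
  q <- random_genotypes(3)
  empty <- q[integer(0)]
  expect_error(classify_mlgs(q, empty), "empty")
})
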