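test_that("3-taxon NJ solves the three-point formulas", {
  dm <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  # x + y = d(ab), x + z = d(ac), y + z = d(bc)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
})

test_that("additive 4-taxon distances are recovered exactly", {
  # tree: (a:1, b:2):1 vs (c:3, d:4)
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  bl <- c(a = 1, b = 2, c = 3, d = 4)
  side <- c(a = 0, b = 0, c = 1, d = 1)
  for (i in letters[1:4]) for (j in letters[1:4]) {
    if (i == j) next
    dm[i, j] <- bl[i] + bl[j] + (side[i] != side[j]) * 1
  }
  tr <- nj_tree(dm)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
  # topology: a,b form a cherry
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("a", "b")))
})

test_that("NJ output round-trips through Newick text", {
  set.seed(61)
  g <- random_genotypes(8)
  tr <- nj_tree(bruvo_dist(g))
  expect_true(all(tr$edge.length >= 0))
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  d1 <- ape::cophenetic.phylo(tr)
  d2 <- ape::cophenetic.phylo(back)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-6)
})

test_that("fewer than 3 labels is a hard error", {
  dm <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(dm), "3 labels")
})

test_that("PHYLIP export writes a readable square matrix", {
  set.seed(62)
  g <- random_genotypes(5)
  dm <- bruvo_dist(g)
  path <- tempfile(fileext = ".phy")
  write_phylip_dm(dm, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 5)
  row1 <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]][-1])
  expect_equal(row1, unname(dm[1, ]), tolerance = 1e-6)
})

cls_for <- function(ids, category) {
  data.frame(mlg_id = ids, category = category,
             nearest_commercial = NA, min_distance = NA,
             derived_label = ids, stringsAsFactors = FALSE)
}

test_that("stage frequencies: pure stages, the <10-isolate exclusion rule", {
  iso <- quick_isolates(rep("U1", 20), stage = "late")
  sf <- stage_frequencies(iso, cls_for("U1", "unique"))
  expect_equal(sf$freq_unique, 1)
  expect_equal(sf$freq_commercial, 0)
  expect_false(sf$excluded)
  iso9 <- quick_isolates(rep("U1", 9), stage = "early")
  sf9 <- stage_frequencies(iso9, cls_for("U1", "unique"))
  expect_true(sf9$excluded)
})

test_that("stage frequency rows sum to 1 and order stages early<mid<late", {
  set.seed(63)
  ids <- c("C1", "R1", "U1")
  iso <- rbind(quick_isolates(sample(ids, 15, replace = TRUE), stage = "mid"),
               quick_isolates(sample(ids, 15, replace = TRUE), stage = "late"),
               quick_isolates(sample(ids, 15, replace = TRUE), stage = "early"))
  sf <- stage_frequencies(iso, cls_for(ids, c("commercial", "commercial_related",
                                              "unique")))
  expect_equal(sf$freq_commercial + sf$freq_commercial_related + sf$freq_unique,
               rep(1, 3), tolerance = 1e-9)
  expect_equal(as.character(sf$stage), c("early", "mid", "late"))
})

test_that("MLG overlap uses exclusive Venn regions", {
  iso <- rbind(quick_isolates(c("A", "B"), location = "HE"),
               quick_isolates(c("A", "C"), location = "HW"),
               quick_isolates(c("A"), location = "OG"),
               quick_isolates(c("A", "D"), location = "Winery"))
  ov <- mlg_overlap(iso, by = "location")
  four_way <- ov[ov$region == "HE+HW+OG+Winery", ]
  expect_equal(four_way$n_mlgs, 1)           # A only, counted once
  expect_equal(sum(ov$n_mlgs), 4)            # regions partition the MLGs
  # disjoint sets produce only singleton regions
  iso2 <- rbind(quick_isolates(c("X"), location = "HE"),
                quick_isolates(c("Y"), location = "OG"))
  ov2 <- mlg_overlap(iso2, by = "location")
  expect_true(all(ov2$n_groups == 1))
})

test_that("planted shared MLGs land in the full intersection region", {
  set.seed(64)
  shared <- paste0("S", 1:5)
  locs <- c("HE", "HW", "OG", "Winery")
  iso <- do.call(rbind, lapply(locs, function(lc)
    quick_isolates(c(shared, paste0(lc, "_", 1:3)), location = lc)))
  ov <- mlg_overlap(iso, by = "location")
  expect_equal(ov$n_mlgs[ov$region == paste(sort(locs), collapse = "+")], 5)
  expect_equal(sum(ov$n_mlgs), 5 + 4 * 3)
})
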