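test_that("hand-evaluated dissimilarity examples hold", {
  m <- rbind(x = c(1, 2, 3), y = c(3, 2, 1))
  expect_equal(beta_distance(m, "bray")["x", "y"], 4 / 12, tolerance = 1e-10)
  m2 <- rbind(x = c(1, 0), y = c(0, 1))
  expect_equal(beta_distance(m2, "canberra")["x", "y"], 1, tolerance = 1e-10)
  m3 <- rbind(x = c(1, 2, 3, 4), y = 2 * c(1, 2, 3, 4) + 1, z = c(4, 1, 3, 2))
  expect_equal(beta_distance(m3, "pearson")["x", "y"], 0, tolerance = 1e-10)
  # two-tip star tree, each sample fully on one tip: every branch is unique
  tree <- ape::read.tree(text = "(T1:1,T2:1);")
  m4 <- rbind(a = c(1, 0), b = c(0, 1))
  colnames(m4) <- c("T1", "T2")
  expect_equal(beta_distance(m4, "w_unifrac", tree = tree)["a", "b"], 1,
               tolerance = 1e-10)
  # identical samples are at distance zero for every index
  ds <- toy_dataset(41, n = 8, p = 20)
  dup <- transform_counts(ds$counts, "prop")
  dup[2, ] <- dup[1, ]
  ann <- simulate_taxa_annotations(20, 40, seed = 4,
                                   taxon_ids = colnames(ds$counts))
  for (ix in setdiff(beta_indices(), c("chao", "rf_proximity"))) {
    d <- beta_distance(dup, ix, tree = ann$tree, seed = 1)
    expect_lt(d[1, 2], 1e-8)
  }
})

test_that("formula-based indices match brute-force double-loop oracles", {
  x <- rand_counts(77, 6, 10, lambda = 9, zero_frac = 0.3)
  pr <- transform_counts(x, "prop")
  ann <- simulate_taxa_annotations(10, 60, seed = 6, taxon_ids = colnames(x))
  tol <- 1e-8
  expect_equal(beta_distance(pr, "euclidean"),
               pairloop(pr, function(a, b) sqrt(sum((a - b)^2))),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "bray"), oracle_bray(pr),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "canberra"), oracle_canberra(pr),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "kulczynski"), oracle_kulczynski(pr),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "horn"), oracle_horn(pr),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "gower"), oracle_gower(pr),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "alt_gower"), oracle_alt_gower(pr),
               tolerance = tol, ignore_attr = TRUE)
  ra <- transform_counts(x, "rarefy", seed = 3)
  expect_equal(beta_distance(ra, "chao"), oracle_chao(ra),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "pearson"), oracle_cor_dist(pr, "pearson"),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "spearman"), oracle_cor_dist(pr, "spearman"),
               tolerance = tol, ignore_attr = TRUE)
  A <- taxon_association(pr, "abundance")
  expect_equal(beta_distance(pr, "tina_w"), oracle_iaw(pr, A),
               tolerance = tol, ignore_attr = TRUE)
  P <- taxon_association(pr, "phylogenetic", tree = ann$tree)
  expect_equal(beta_distance(pr, "pina_w", tree = ann$tree),
               oracle_iaw(pr, P), tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "w_unifrac", tree = ann$tree),
               oracle_unifrac(pr, ann$tree, "weighted"),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "g_unifrac_05", tree = ann$tree),
               oracle_unifrac(pr, ann$tree, "generalized", 0.5),
               tolerance = tol, ignore_attr = TRUE)
  expect_equal(beta_distance(pr, "vaw_unifrac", tree = ann$tree),
               oracle_unifrac(pr, ann$tree, "vaw"),
               tolerance = tol, ignore_attr = TRUE)
})

test_that("all sixteen indices yield valid bounded distance matrices", {
  ds <- toy_dataset(42, n = 10, p = 25)
  ann <- simulate_taxa_annotations(25, 50, seed = 5,
                                   taxon_ids = colnames(ds$counts))
  pr <- transform_counts(ds$counts, "prop")
  ra <- transform_counts(ds$counts, "rarefy", seed = 2)
  bounded <- c("bray", "canberra", "kulczynski", "horn", "chao", "tina_w",
               "pina_w", "w_unifrac", "g_unifrac_05", "vaw_unifrac")
  for (ix in beta_indices()) {
    mat <- if (ix == "chao") ra else pr
    d <- beta_distance(mat, ix, tree = ann$tree, seed = 9, rf_trees = 100)
    expect_true(all(is.finite(d)), info = ix)
    expect_equal(d, t(d), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(diag(d) == 0), info = ix)
    expect_true(all(d >= 0), info = ix)
    if (ix %in% bounded) expect_lte(max(d), 1 + 1e-9)
  }
})

test_that("UniFrac family degenerates correctly", {
  ds <- toy_dataset(43, n = 8, p = 15)
  ann <- simulate_taxa_annotations(15, 40, seed = 7,
                                   taxon_ids = colnames(ds$counts))
  pr <- transform_counts(ds$counts, "prop")
  # generalized UniFrac at alpha = 1 reduces to weighted UniFrac
  g1 <- beta_distance(pr, "g_unifrac_05", tree = ann$tree, gunifrac_alpha = 1)
  w <- beta_distance(pr, "w_unifrac", tree = ann$tree)
  expect_equal(g1, w, tolerance = 1e-8, ignore_attr = TRUE)
  # identical relative-abundance rows: zero for all variants
  same <- matrix(rep(pr[1, ], 4), 4, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4), colnames(pr)))
  for (v in c("w_unifrac", "g_unifrac_05", "vaw_unifrac"))
    expect_lt(max(beta_distance(same, v, tree = ann$tree)), 1e-10)
  expect_error(beta_distance(pr[, 1:10], "w_unifrac",
                             tree = ape::drop.tip(ann$tree, "T0001")),
               "T0001")
})

test_that("taxon associations have the declared structure", {
  ds <- toy_dataset(44, n = 12, p = 10)
  pr <- transform_counts(ds$counts, "prop")
  A <- taxon_association(pr, "abundance")
  expect_true(all(diag(A) == 1))
  expect_equal(A, t(A), tolerance = 1e-12)
  expect_true(all(A >= 0 & A <= 1))
  dup <- cbind(pr, dup_taxon = pr[, 1])
  expect_equal(taxon_association(dup, "abundance")[1, "dup_taxon"], 1,
               tolerance = 1e-12, ignore_attr = TRUE)
  const <- pr; const[, 2] <- 0.1
  expect_warning(Ac <- taxon_association(const, "abundance"), "constant")
  expect_true(all(Ac[2, -2] == 0.5))
  ann <- simulate_taxa_annotations(10, 40, seed = 3,
                                   taxon_ids = colnames(pr))
  P <- taxon_association(pr, "phylogenetic", tree = ann$tree)
  coph <- stats::cophenetic(ann$tree)
  far <- which(coph == max(coph), arr.ind = TRUE)[1, ]
  expect_equal(P[rownames(coph)[far[1]], colnames(coph)[far[2]]], 0,
               tolerance = 1e-12)
})

test_that("TINA with an identity association separates disjoint communities", {
  m <- rbind(a = c(1, 2, 0, 0), b = c(0, 0, 3, 1), c = c(1, 1, 1, 1))
  colnames(m) <- paste0("T", 1:4)
  d <- beta_distance(m, "tina_w", association = diag(4))
  expect_equal(d["a", "b"], 1, tolerance = 1e-10)
  expect_lt(d["a", "c"], 1)
})

test_that("random-forest proximity distance is seed-deterministic", {
  ds <- toy_dataset(45, n = 12, p = 20)
  pr <- transform_counts(ds$counts, "prop")
  d1 <- beta_distance(pr, "rf_proximity", seed = 5, rf_trees = 100)
  d2 <- beta_distance(pr, "rf_proximity", seed = 5, rf_trees = 100)
  expect_identical(d1, d2)
  d3 <- beta_distance(pr, "rf_proximity", seed = 6, rf_trees = 100)
  expect_false(identical(d1, d3))
})

test_that("the compatibility table rules out invalid pairings", {
  expect_false(combo_compatible("clr", "bray")$ok)
  expect_false(combo_compatible("vst", "w_unifrac")$ok)
  expect_false(combo_compatible("prop", "chao")$ok)
  expect_true(combo_compatible("rarefy", "chao")$ok)
  expect_false(combo_compatible("kmer", "w_unifrac")$ok)
  expect_false(combo_compatible("kmer", "tina_w")$ok)
  expect_true(combo_compatible("clr", "euclidean")$ok)
  expect_true(combo_compatible("hellinger", "bray")$ok)
  # signed input is refused at run time too
  x <- rand_counts(1, 5, 8)
  cl <- transform_counts(x, "clr")
  expect_error(beta_distance(cl, "bray"), "nonnegative")
})
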