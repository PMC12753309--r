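test_that("hand-checkable transform examples hold", {
  x <- matrix(c(2L, 3L, 5L, 1L, 3L, 6L), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  expect_equal(unname(transform_counts(x, "prop")["a", ]), c(0.2, 0.3, 0.5))
  h <- transform_counts(matrix(c(1L, 3L), 1, 2,
                               dimnames = list("a", c("t1", "t2"))), "hellinger")
  expect_equal(unname(h[1, ]), c(0.5, sqrt(0.75)), tolerance = 1e-6)
  cl <- transform_counts(matrix(c(1L, 10L, 100L), 1, 3,
                                dimnames = list("a", c("t1", "t2", "t3"))),
                         "clr", clr_pseudocount = 0)
  expect_equal(unname(cl[1, ]), c(-log(10), 0, log(10)), tolerance = 1e-6)
  r <- transform_counts(rand_counts(1, 5, 8), "rarefy", rarefy_depth = 20,
                        seed = 1)
  expect_true(all(rowSums(r) == 20))
})

test_that("every transform matches its independent brute-force oracle", {
  for (seed in c(101, 202)) {
    for (dims in list(c(5, 8), c(6, 10))) {
      x <- rand_counts(seed, dims[1], dims[2], lambda = 12, zero_frac = 0.25)
      expect_equal(transform_counts(x, "prop"), oracle_prop(x),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "hellinger"), oracle_hellinger(x),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "chi_square"), oracle_chi_square(x),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "clr"), oracle_clr(x, 1),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "rclr"), oracle_rclr(x),
                   tolerance = 1e-8, ignore_attr = TRUE)
      tc <- transform_counts(x, "css")
      expect_equal(tc, oracle_css(x, attr(tc, "css_quantile")),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "vst"), oracle_vst(x),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "tmm"),
                   oracle_logcpm(x, oracle_tmm_factors(x)),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "tmmwsp"),
                   oracle_logcpm(x, oracle_tmmwsp_factors(x)),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "wrench"), oracle_wrench(x),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(transform_counts(x, "gmpr"),
                   x / oracle_gmpr_factors(x),
                   tolerance = 1e-8, ignore_attr = TRUE)
      ann <- simulate_taxa_annotations(dims[2], 40, seed = seed,
                                       taxon_ids = colnames(x))
      km <- transform_counts(x, "kmer", sequences = ann$sequences, kmer_k = 3)
      ko <- oracle_kmer(x, ann$sequences, 3)
      expect_equal(km[, colnames(ko)], ko, tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_true(all(km[, setdiff(colnames(km), colnames(ko))] == 0))
      # rarefaction: same seed, same draw; always a valid subsample
      r1 <- transform_counts(x, "rarefy", seed = seed)
      r2 <- transform_counts(x, "rarefy", seed = seed)
      expect_identical(r1, r2)
      expect_true(all(r1 <= x))
      expect_true(all(rowSums(r1) == min(rowSums(x))))
    }
  }
})

test_that("compositional transforms are scale-invariant and log-ratios centred", {
  x <- rand_counts(7, 6, 10, lambda = 15)
  for (m in c("clr", "rclr")) {
    tm <- transform_counts(x, m)
    included <- if (m == "clr") matrix(TRUE, nrow(x), ncol(x)) else x > 0
    expect_true(all(abs(rowSums(tm * included)) < 1e-9))
  }
  xs <- x; xs[3, ] <- xs[3, ] * 7L
  for (m in c("prop", "hellinger")) {
    expect_equal(transform_counts(x, m)[3, ], transform_counts(xs, m)[3, ],
                 tolerance = 1e-12)
  }
  expect_equal(transform_counts(x, "chi_square"),
               transform_counts(x * 3L, "chi_square"), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rarefaction at the common depth returns the sample unchanged", {
  x <- rand_counts(3, 5, 8, lambda = 10)
  eq <- x
  tot <- rowSums(eq)
  for (i in seq_len(nrow(eq))) eq[i, 1] <- eq[i, 1] + max(tot) - tot[i]
  r <- transform_counts(eq, "rarefy", rarefy_depth = max(tot), seed = 1)
  expect_equal(unname(r), unname(eq * 1.0), ignore_attr = TRUE)
})

test_that("gmpr factors are equivariant and equal for identical samples", {
  x <- rand_counts(9, 6, 12, lambda = 10, zero_frac = 0.2)
  x[2, ] <- x[1, ]
  f <- oracle_gmpr_factors(x)
  expect_equal(f[1], f[2], tolerance = 1e-10)
  xs <- x; xs[4, ] <- xs[4, ] * 5L
  fs <- oracle_gmpr_factors(xs)
  expect_equal(fs[4] / f[4], 5, tolerance = 1e-10)
  expect_equal(transform_counts(x, "gmpr"), x / f, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("k-mer profiles are proportions and respect duplicate sequences", {
  x <- rand_counts(4, 5, 6, lambda = 10)
  ann <- simulate_taxa_annotations(6, 50, seed = 2, taxon_ids = colnames(x))
  seqs <- ann$sequences
  seqs[2] <- seqs[1]
  km <- transform_counts(x, "kmer", sequences = seqs, kmer_k = 4)
  expect_equal(unname(rowSums(km)), rep(1, 5), tolerance = 1e-12)
  x2 <- x
  x2[, 1] <- x[, 1] + 3L; x2[, 2] <- x[, 2] - pmin(x[, 2], 3L) + 3L
  # moving counts between taxa with identical sequences leaves profiles alone
  xa <- x; xa[1, 1] <- xa[1, 1] + 5L
  xb <- x; xb[1, 2] <- xb[1, 2] + 5L
  expect_equal(transform_counts(xa, "kmer", sequences = seqs, kmer_k = 4)[1, ],
               transform_counts(xb, "kmer", sequences = seqs, kmer_k = 4)[1, ],
               tolerance = 1e-12)
})

test_that("wrench honours group structure and stays positive", {
  x <- rand_counts(12, 8, 15, lambda = 10, zero_frac = 0.3)
  g <- rep(c("A", "B"), each = 4)
  w <- transform_counts(x, "wrench", wrench_groups = g)
  expect_true(all(is.finite(w)) && all(w >= 0))
  expect_equal(w, oracle_wrench(x, g), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the closed-form VST agrees qualitatively with DESeq2's", {
  skip_if_not_installed("DESeq2")
  x <- rand_counts(5, 20, 60, lambda = 30, zero_frac = 0.2)
  v <- transform_counts(x, "vst")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    t(x), S4Vectors::DataFrame(row.names = rownames(x)), ~1)
  dds <- DESeq2::estimateSizeFactors(dds, type = "poscounts")
  ref <- t(SummarizedExperiment::assay(
    DESeq2::varianceStabilizingTransformation(dds, blind = TRUE)))
  expect_gt(stats::cor(as.vector(v), as.vector(ref), method = "spearman"),
            0.95)
})

test_that("transform error contracts fire", {
  x <- rand_counts(2, 5, 8)
  expect_error(transform_counts(x, "rarefy", rarefy_depth = 1e6), "S00")
  x0 <- x; x0[1, 1] <- 0L
  expect_error(transform_counts(x0, "clr", clr_pseudocount = 0), "pseudocount")
  expect_error(transform_counts(x, "kmer"), "sequences")
  xn <- x; xn[1, 1] <- -1L
  expect_error(transform_counts(xn, "prop"), "nonnegative")
})
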