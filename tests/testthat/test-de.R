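test_that("median-of-ratios size factors match hand evaluations", {
  sheet <- sample_sheet(c("a", "b"), c("HI", "HI"), c("N1", "N1"), 1:2)
  eq <- count_matrix(matrix(c(3, 8, 3, 8), 2,
                            dimnames = list(c("g1", "g2"), c("a", "b"))),
                     sheet)
  expect_equal(unname(size_factors(eq)), c(1, 1))

  doub <- count_matrix(matrix(c(2, 10, 4, 20), 2,
                              dimnames = list(c("g1", "g2"), c("a", "b"))),
                       sheet)
  sf <- size_factors(doub)
  expect_equal(unname(sf[2] / sf[1]), 2)

  single <- count_matrix(matrix(c(4, 9), 1,
                                dimnames = list("g1", c("a", "b"))), sheet)
  sfs <- size_factors(single)
  expect_equal(unname(sfs[2] / sfs[1]), 9 / 4)

  # no gene positive everywhere -> column-sum fallback with a warning
  fb <- count_matrix(matrix(c(4, 0, 0, 8), 2,
                            dimnames = list(c("g1", "g2"), c("a", "b"))),
                     sheet)
  expect_warning(sff <- size_factors(fb), "fall")
  expect_equal(unname(sff), c(4, 8) / 6)
})

test_that("size factors agree with the reference median-of-ratios engine", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(simulation_config(
    list(archetype_spec("null", 150),
         archetype_spec("constitutive_difference", 50)),
    depth_factors = "lognormal", seed = 21))
  sf <- size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts$counts)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("BH adjustment matches hand evaluations and rejects bad input", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the literal step-up rule on random vectors", {
  for (s in 1:100) {
    set.seed(s)
    p <- round(runif(sample(1:20, 1)), 3)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("BH adjustment is monotone and bounded by [p, 1]", {
  set.seed(1)
  p <- runif(500)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("identical groups give log2fc 0 and no DEGs", {
  m <- exact_counts(list(g1 = c(50, 50, 80, 90), g2 = c(7, 7, 3, 1)))
  r <- de_test(m, contrast_spec(c("HI", "N0"), c("HI", "N1")),
               sf = rep(1, 12))
  expect_equal(r$log2fc, c(0, 0))
  expect_false(any(r$is_deg))
  expect_equal(r$p, c(1, 1))
})

test_that("swapping numerator and denominator negates log2fc, keeps p", {
  sim <- simulate_counts(simulation_config(
    list(archetype_spec("shared_response", 40),
         archetype_spec("null", 60)), seed = 12))
  sf <- size_factors(sim$counts)
  a <- de_test(sim$counts, contrast_spec(c("HI", "N0"), c("HI", "N1")),
               sf = sf)
  b <- de_test(sim$counts, contrast_spec(c("HI", "N1"), c("HI", "N0")),
               sf = sf)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
  expect_equal(a$mean_num, b$mean_den)
  # and reverse_contrast reproduces the swapped test
  rb <- reverse_contrast(a)
  expect_equal(rb$log2fc, b$log2fc)
  expect_equal(rb$direction, b$direction)
})

test_that("a strong planted response is detected as upregulated", {
  # frontloaded-in-HI genes respond 100 -> 1600 in LO
  sim <- simulate_counts(simulation_config(
    list(archetype_spec("frontloaded_in_HI", 20),
         archetype_spec("null", 180)), seed = 3))
  r <- de_test(sim$counts, contrast_spec(c("LO", "N0"), c("LO", "N1")))
  planted <- grepl("^frontloaded_in_HI", r$gene_id)
  expect_true(all(r$is_deg[planted]))
  expect_true(all(r$direction[planted] == "up"))
})

test_that("de_test is invariant to replicate order within groups", {
  sim <- simulate_counts(simulation_config(
    list(archetype_spec("shared_response", 30),
         archetype_spec("null", 70)), seed = 14))
  m <- sim$counts
  perm <- c(3, 1, 2, 4:12)  # permute HI_N1 replicates
  m2 <- count_matrix(m$counts[, perm],
                     sample_sheet(m$samples$sample_id[perm],
                                  m$samples$genotype[perm],
                                  m$samples$treatment[perm],
                                  m$samples$replicate[perm]))
  sf <- size_factors(m)
  r1 <- de_test(m, contrast_spec(c("HI", "N1"), c("HI", "N0")), sf = sf)
  r2 <- de_test(m2, contrast_spec(c("HI", "N1"), c("HI", "N0")),
                sf = size_factors(m2))
  expect_equal(r1$p, r2$p)
  expect_equal(r1$log2fc, r2$log2fc)
})

test_that("null simulations keep the discovery fraction under control", {
  frac <- vapply(1:10, function(s) {
    sim <- simulate_counts(null_sim_config(seed = s, n_genes = 1000))
    r <- de_test(sim$counts, contrast_spec(c("HI", "N0"), c("HI", "N1")))
    mean(r$padj < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("missing contrast groups and thin designs are refused", {
  m <- exact_counts(list(g1 = c(5, 5, 5, 5)), reps = 3)
  keep <- m$samples$genotype == "HI"
  mhi <- count_matrix(m$counts[, keep, drop = FALSE],
                      sample_sheet(m$samples$sample_id[keep],
                                   rep("HI", sum(keep)),
                                   m$samples$treatment[keep],
                                   m$samples$replicate[keep]))
  expect_error(de_test(mhi, contrast_spec(c("LO", "N0"), c("HI", "N1"))),
               "absent")
  m1 <- exact_counts(list(g1 = c(5, 5, 5, 5)), reps = 1)
  expect_error(de_test(m1, contrast_spec(c("HI", "N0"), c("HI", "N1"))),
               "replicates")
})

test_that("external DE tables honor or recompute padj and re-flag", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("a", "b", "c"),
                   log2fc = c(1.0, -2.5, 0.2),
                   p = c(0.001, 0.02, 0.5),
                   padj = c(0.04, 0.06, 0.9))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  r <- read_contrast_table(path)
  # file's padj honored; |log2fc| = 1 inclusive at the boundary
  expect_equal(r$padj, df$padj)
  expect_equal(r$is_deg, c(TRUE, FALSE, FALSE))
  expect_equal(r$direction, c("up", "none", "none"))

  write.table(df[, 1:3], path, sep = "\t", quote = FALSE, row.names = FALSE)
  r2 <- read_contrast_table(path)
  expect_equal(r2$padj, bh_adjust(df$p))

  write.table(df[, c(1, 3)], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_contrast_table(path), "log2fc")
})

test_that("contrast tables round-trip through TSV", {
  m <- exact_counts(list(g1 = c(400, 400, 100, 1600),
                         g2 = c(10, 10, 10, 10)))
  r <- de_test(m, contrast_spec(c("HI", "N1"), c("LO", "N1")),
               sf = rep(1, 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast_table(r, path)
  r2 <- read_contrast_table(path)
  expect_equal(r2$log2fc, r$log2fc)
  expect_equal(r2$is_deg, r$is_deg)
})
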