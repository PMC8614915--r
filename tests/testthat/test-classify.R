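test_that("genotype-specific response is the directed set difference", {
  mk <- function(ids, dirs, degs) {
    r <- data.frame(gene_id = ids, mean_num = 10, mean_den = 10,
                    log2fc = ifelse(dirs == "up", 2, -2),
                    p = 0.001, padj = 0.001, is_deg = degs,
                    direction = ifelse(degs, dirs, "none"),
                    stringsAsFactors = FALSE)
    class(r) <- c("contrast_result", "data.frame")
    r
  }
  other <- mk(c("a", "b", "c"), c("up", "down", "up"), c(TRUE, TRUE, TRUE))
  focal <- mk(c("a", "b", "c"), c("up", "up", "up"),
              c(FALSE, FALSE, TRUE))
  out <- genotype_specific_response(other, focal)
  expect_equal(out$gene_id, c("a", "b"))
  expect_equal(out$direction, c("up", "down"))
  # identical DEG sets -> empty
  expect_equal(nrow(genotype_specific_response(other, other)), 0)
})

test_that("expression filter drops genes silent in the focal genotype", {
  m <- exact_counts(list(g_silent = c(0, 0, 100, 400),
                         g_low = c(0, 3, 100, 400),
                         g_expr = c(50, 0, 100, 400)))
  f <- expression_filter(c("g_silent", "g_low", "g_expr"), m, "HI",
                         sf = rep(1, 12))
  expect_setequal(f$kept, c("g_low", "g_expr"))
  expect_equal(f$removed, 1)
  expect_equal(f$removed_ids, "g_silent")
  # floor 0 keeps everything
  f0 <- expression_filter(c("g_silent", "g_expr"), m, "HI",
                          cfg = classifier_config(expression_floor = 0),
                          sf = rep(1, 12))
  expect_equal(f0$removed, 0)
})

test_that("trend filter removes sign conflicts and undefined ratios", {
  mk <- function(ids, lfc, mnum, mden) {
    r <- data.frame(gene_id = ids, mean_num = mnum, mean_den = mden,
                    log2fc = lfc, p = 0.01, padj = 0.01,
                    is_deg = TRUE,
                    direction = ifelse(lfc > 0, "up", "down"),
                    stringsAsFactors = FALSE)
    class(r) <- c("contrast_result", "data.frame")
    r
  }
  ids <- c("ok", "conflict_n1", "zero_other")
  # 'conflict_n1': positive table log2fc but lower raw mean in N1
  bn1 <- mk(ids, lfc = c(1.5, 1.5, 1.5),
            mnum = c(30, 10, 5), mden = c(10, 30, 0))
  bn0 <- mk(ids, lfc = c(-1.5, -1.5, 1.5),
            mnum = c(10, 10, 5), mden = c(30, 30, 0))
  out <- trend_filter(ids, bn1, bn0)
  expect_equal(out$kept, "ok")
  expect_setequal(out$removed_ids, c("conflict_n1", "zero_other"))
})

test_that("the six-gene fixture classifies exactly as hand-derived", {
  fx <- fixture_six_gene()
  res <- classify_frontloaded(fx$m, fx$quartet, "HI", sf = fx$sf)
  lab <- setNames(res$table$label, res$table$gene_id)
  expect_false("g_shared" %in% names(lab))  # responds in both genotypes
  expect_equal(lab[["g_front"]], "frontloaded")
  expect_equal(lab[["g_relup"]], "relatively_upregulated")
  expect_equal(lab[["g_failn0"]], "candidate_unclassified")
  expect_equal(lab[["g_nodeg"]], "not_candidate")
  expect_equal(lab[["g_notexpr"]], "excluded_not_expressed")

  bk <- res$bookkeeping
  expect_equal(bk$n_specific, 5)
  expect_equal(bk$n_not_expressed, 1)
  expect_equal(bk$n_trend_inconsistent, 0)
  expect_equal(bk$n_classifiable, 4)
  expect_equal(c(bk$n_up, bk$n_down), c(3, 1))
  expect_equal(c(bk$n_candidate_front, bk$n_candidate_relup), c(2, 1))
  expect_equal(c(bk$n_front, bk$n_relup), c(1, 1))

  # hand-checkable ratios with pseudocount 1 and unit size factors
  tab <- res$table
  expect_equal(tab$r_n1[tab$gene_id == "g_front"], 401 / 101)
  expect_equal(tab$r_n0[tab$gene_id == "g_front"], 401 / 1601)
  expect_equal(tab$r_n0[tab$gene_id == "g_failn0"], 0.5)  # not < 0.5
})

test_that("an all-null simulation yields no classified genes", {
  sim <- simulate_counts(null_sim_config(seed = 41, n_genes = 500))
  res <- classify_frontloaded(sim$counts,
                              contrast_quartet(sim$counts, "HI"), "HI")
  expect_equal(res$bookkeeping$n_front, 0)
  expect_equal(res$bookkeeping$n_relup, 0)
})

test_that("planted classes are recovered with high sensitivity/precision", {
  sim <- simulate_counts(default_sim_config(seed = 101))
  m <- sim$counts
  sf <- size_factors(m)
  for (focal in c("HI", "LO")) {
    res <- classify_frontloaded(m, contrast_quartet(m, focal, sf = sf),
                                focal, sf = sf)
    ev <- evaluate_classification(res, sim$truth)
    expect_true(all(ev$sensitivity >= 0.8))
    expect_true(all(ev$precision >= 0.8))
  }
})

test_that("swapping genotype labels swaps the two focal results", {
  sim <- simulate_counts(default_sim_config(seed = 55))
  m <- sim$counts
  swap <- c(HI = "LO", LO = "HI")
  sheet2 <- sample_sheet(m$samples$sample_id,
                         unname(swap[m$samples$genotype]),
                         m$samples$treatment, m$samples$replicate)
  m2 <- count_matrix(m$counts, sheet2)
  resHI <- classify_frontloaded(m, contrast_quartet(m, "HI"), "HI")
  resLO2 <- classify_frontloaded(m2, contrast_quartet(m2, "LO"), "LO")
  o1 <- order(resHI$table$gene_id)
  o2 <- order(resLO2$table$gene_id)
  expect_equal(resHI$table[o1, ], resLO2$table[o2, ],
               ignore_attr = TRUE)
  expect_equal(unclass(resHI$bookkeeping), unclass(resLO2$bookkeeping))
})

test_that("classification is invariant to joint count/size-factor scaling", {
  fx <- fixture_six_gene()
  res1 <- classify_frontloaded(fx$m, fx$quartet, "HI", sf = fx$sf)
  m2 <- count_matrix(fx$m$counts * 3, fx$m$samples)
  q2 <- contrast_quartet(m2, "HI", sf = rep(3, 12))
  res2 <- classify_frontloaded(m2, q2, "HI", sf = rep(3, 12))
  expect_equal(res1$table, res2$table)
})

test_that("raising ratio_high can only shrink the frontloaded set", {
  sim <- simulate_counts(default_sim_config(seed = 77))
  m <- sim$counts
  sf <- size_factors(m)
  q <- contrast_quartet(m, "HI", sf = sf)
  loose <- classify_frontloaded(m, q, "HI",
                                classifier_config(2, 0.5), sf = sf)
  tight <- classify_frontloaded(m, q, "HI",
                                classifier_config(4, 0.25), sf = sf)
  front_loose <- loose$table$gene_id[loose$table$label == "frontloaded"]
  front_tight <- tight$table$gene_id[tight$table$label == "frontloaded"]
  expect_true(all(front_tight %in% front_loose))
  expect_lte(tight$bookkeeping$n_front, loose$bookkeeping$n_front)
})

test_that("classified sets are disjoint subsets of the specific set", {
  sim <- simulate_counts(default_sim_config(seed = 88))
  m <- sim$counts
  q <- contrast_quartet(m, "HI")
  res <- classify_frontloaded(m, q, "HI")
  tab <- res$table
  front <- tab$gene_id[tab$label == "frontloaded"]
  relup <- tab$gene_id[tab$label == "relatively_upregulated"]
  expect_length(intersect(front, relup), 0)
  spec <- genotype_specific_response(q$other_response, q$focal_response)
  expect_true(all(c(front, relup) %in% spec$gene_id))
})

test_that("bookkeeping enforces the count-chain invariants", {
  bk <- bookkeeping(4789, 25, 39, n_up = 2584, n_down = 2141)
  expect_equal(bk$n_classifiable, 4725)
  expect_error(bookkeeping(100, 80, 30), "exceed")
  expect_error(bookkeeping(100, 10, 10, n_up = 50, n_down = 40),
               "n_up \\+ n_down")
  expect_error(bookkeeping(100, 0, 0, n_up = 60, n_down = 40,
                           n_candidate_front = 70), "candidates exceed")
  expect_error(bookkeeping(100, 0, 0, n_up = 60, n_down = 40,
                           n_candidate_front = 20, n_front = 30),
               "frontloaded exceed")
})

test_that("summary ratio divides frontloaded counts and guards zero", {
  expect_equal(summary_ratio(10, 4), 2.5)
  expect_equal(summary_ratio(7, 7), 1)
  expect_error(summary_ratio(5, 0), "zero")
  fx <- fixture_six_gene()
  res <- classify_frontloaded(fx$m, fx$quartet, "HI", sf = fx$sf)
  expect_equal(summary_ratio(res, res), 1)
})

test_that("classification tables serialize to TSV", {
  fx <- fixture_six_gene()
  res <- classify_frontloaded(fx$m, fx$quartet, "HI", sf = fx$sf)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification(res, path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 5)
  expect_true(all(c("gene_id", "other_direction", "r_n1", "r_n0",
                    "label") %in% names(df)))
})
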