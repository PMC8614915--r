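# Fixture builders and brute-force oracles shared across the suite.

# 2x2 design sheet: groups ordered HI_N1, HI_N0, LO_N1, LO_N0
make_sheet <- function(reps = 3) {
  cells <- c("HI_N1", "HI_N0", "LO_N1", "LO_N0")
  grid <- expand.grid(r = seq_len(reps), cell = cells,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$cell, cells), grid$r), ]
  parts <- strsplit(grid$cell, "_")
  sample_sheet(paste0(grid$cell, "_r", grid$r),
               vapply(parts, `[`, "", 1),
               vapply(parts, `[`, "", 2),
               grid$r)
}

# counts with EXACT replicate values per cell: gene_mus is a named list
# gene_id -> c(HI_N1, HI_N0, LO_N1, LO_N0).  Zero within-group variance
# makes every p-value exactly 0 or 1 and group means hand-computable.
exact_counts <- function(gene_mus, reps = 3) {
  sheet <- make_sheet(reps)
  cell <- paste(sheet$genotype, sheet$treatment, sep = "_")
  mat <- t(vapply(gene_mus, function(mu) {
    names(mu) <- c("HI_N1", "HI_N0", "LO_N1", "LO_N0")
    unname(mu[cell])
  }, numeric(nrow(sheet))))
  rownames(mat) <- names(gene_mus)
  colnames(mat) <- sheet$sample_id
  count_matrix(mat, sheet)
}

# hand-designed 6-gene fixture exercising every classifier rule (focal HI):
#   g_front    frontloaded: ratios 401/101 > 2 and 401/1601 < 0.5
#   g_relup    relatively upregulated: 26/101 < 0.5, 26/7 > 2
#   g_failn0   candidate whose N0 ratio is exactly 0.5 (not < 0.5)
#   g_nodeg    LO-specific responder, below the between-genotype DEG bar
#   g_notexpr  zero counts in HI -> expression filter
#   g_shared   responds in both genotypes -> not genotype-specific
fixture_six_gene <- function() {
  m <- exact_counts(list(
    g_front   = c(400, 400, 100, 1600),
    g_relup   = c(25, 25, 100, 6),
    g_failn0  = c(400, 400, 100, 801),
    g_nodeg   = c(150, 150, 100, 250),
    g_notexpr = c(0, 0, 100, 400),
    g_shared  = c(100, 400, 100, 400)
  ))
  sf <- rep(1, 12)
  quartet <- contrast_quartet(m, "HI", sf = sf)
  list(m = m, sf = sf, quartet = quartet)
}

# literal BH step-up enumeration (independent of stats::p.adjust)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m),
                function(i) min(1, min(m * ps[i:m] / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force two-set Venn by per-gene membership loops
venn_brute <- function(a, b) {
  all_ids <- union(c(a$up, a$down), c(b$up, b$down))
  common <- unique_a <- unique_b <- inconsistent <- 0L
  for (g in all_ids) {
    in_a <- g %in% c(a$up, a$down)
    in_b <- g %in% c(b$up, b$down)
    if (in_a && in_b) {
      common <- common + 1L
      opposite <- (g %in% a$up && g %in% b$down) ||
        (g %in% a$down && g %in% b$up)
      if (opposite) inconsistent <- inconsistent + 1L
    } else if (in_a) unique_a <- unique_a + 1L
    else unique_b <- unique_b + 1L
  }
  list(common = common, unique_a = unique_a, unique_b = unique_b,
       inconsistent_common = inconsistent)
}

# upper-tail hypergeometric by direct enumeration of choose() terms
hyper_brute <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

random_deg_set <- function(name, genes, p_up = 0.3, p_down = 0.3) {
  r <- runif(length(genes))
  deg_set(name, up = genes[r < p_up],
          down = genes[r >= p_up & r < p_up + p_down])
}
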