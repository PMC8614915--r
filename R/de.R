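#' Median-of-ratios size factors
#'
#' For each sample j, `factor_j = median_g(count_gj / geomean_g)` over genes
#' with strictly positive counts in every sample.  When no gene is positive
#' in all samples, falls back (with a warning) to column sums divided by the
#' mean column sum.
#'
#' @param m a [count_matrix()] or a bare counts matrix.
#' @return Positive numeric vector, one factor per sample.
#' @examples
#' sh <- sample_sheet(c("a", "b"), c("HI", "HI"), c("N1", "N1"), 1:2)
#' m <- count_matrix(matrix(c(2, 10, 4, 20), 2,
#'                          dimnames = list(c("g1", "g2"), c("a", "b"))), sh)
#' size_factors(m)  # proportional to (1, 2)
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  if (ncol(counts) == 0) return(numeric(0))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("size_factors: no gene has positive counts in every sample; ",
            "falling back to column-sum normalization", call. = FALSE)
    cs <- colSums(counts)
    if (any(cs == 0))
      stop("size_factors: a sample has zero total counts", call. = FALSE)
    return(cs / mean(cs))
  }
  lc <- log(counts[allpos, , drop = FALSE])
  gm <- rowMeans(lc)
  # median = midpoint of the two central order statistics for even n
  apply(lc, 2, function(col) exp(stats::median(col - gm)))
}

#' Size-factor-normalized counts
#'
#' @param m a [count_matrix()].
#' @param sf size factors; default [size_factors()] of `m`.
#' @return Numeric matrix `counts / sf` (columns divided by their factor).
#' @export
normalize_counts <- function(m, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(m)
  if (any(sf <= 0)) stop("normalize_counts: size factors must be > 0",
                         call. = FALSE)
  sweep(m$counts, 2, sf, "/")
}

#' Name one contrast between two (genotype, treatment) groups
#'
#' The numerator is the first-listed condition; e.g. the within-genotype
#' nitrogen response of HI is `contrast_spec(c("HI", "N0"), c("HI", "N1"))`,
#' named `"N0_HI_vs_N1_HI"`.
#'
#' @param numerator,denominator length-2 character vectors
#'   `c(genotype, treatment)`.
#' @param name optional contrast label; default
#'   `"<treat>_<geno>_vs_<treat>_<geno>"`.
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(numerator, denominator, name = NULL) {
  grp <- function(x) {
    if (length(x) != 2 || !(x[1] %in% GENOTYPES) || !(x[2] %in% TREATMENTS))
      stop("contrast_spec: groups are c(genotype, treatment) with genotype ",
           "in HI/LO and treatment in N1/N0", call. = FALSE)
    list(genotype = x[1], treatment = x[2])
  }
  num <- grp(numerator); den <- grp(denominator)
  if (identical(num, den))
    stop("contrast_spec: numerator and denominator are the same group",
         call. = FALSE)
  if (is.null(name))
    name <- paste0(num$treatment, "_", num$genotype, "_vs_",
                   den$treatment, "_", den$genotype)
  structure(list(name = name, numerator = num, denominator = den),
            class = "contrast_spec")
}

group_index <- function(sheet, group) {
  which(sheet$genotype == group$genotype & sheet$treatment == group$treatment)
}

rowvars <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

# Welch two-sided t on the rows of two matrices (log2 scale)
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowvars(x1); v2 <- rowvars(x2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
}

# moderated pooled t with mean-variance trend (limma-trend) on two groups
limma_rows <- function(x1, x2) {
  grp <- factor(rep(c("den", "num"), c(ncol(x2), ncol(x1))),
                levels = c("den", "num"))
  design <- stats::model.matrix(~grp)
  # zero-variance rows are re-decided exactly by the caller, so limma's
  # offset warning for them carries no information here
  suppressWarnings(tryCatch({
    fit <- limma::lmFit(cbind(x2, x1), design)
    fit <- tryCatch(limma::eBayes(fit, trend = TRUE),
                    error = function(e) limma::eBayes(fit))
    fit$p.value[, 2]
  }, error = function(e) rep(NA_real_, nrow(x1))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values (FDR), order-preserving on the input indexing.
#' @examples
#' bh_adjust(c(0.005, 0.1))  # 0.01 0.10
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression for one contrast
#'
#' Group means are means of size-factor-normalized counts;
#' `log2fc = log2((mean_num + eps) / (mean_den + eps))`; p-values come from
#' a two-sided t on `log2(normalized count + 1)` per gene, BH-adjusted.
#' A gene is flagged differentially expressed when `padj < alpha` and
#' `|log2fc| >= fc_min` (or `> fc_min` with `strict_fc = TRUE`).
#'
#' The default engine `"limma_trend"` is limma's moderated pooled t with a
#' mean-variance trend, which shares variance information across genes — at
#' two or three replicates per group an unmoderated per-gene t has so few
#' residual degrees of freedom that moderate fold changes are unrecoverable.
#' `"welch"` gives the plain per-gene Welch t.  Under either engine a gene
#' whose two groups both have zero sample variance is decided exactly:
#' p = 1 when the group means are equal, 0 otherwise.
#'
#' The engine is pluggable: externally computed tables (e.g. from a
#' negative-binomial engine) enter through [read_contrast_table()] and flow
#' through the identical downstream contracts.
#'
#' @param m a [count_matrix()].
#' @param contrast a [contrast_spec()].
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param fc_min absolute log2 fold-change threshold (default 1).
#' @param pseudocount added to both group means before the ratio (default 1).
#' @param sf size factors; default computed from `m` (pass shared factors
#'   when testing several contrasts of one matrix).
#' @param strict_fc if `TRUE` require `|log2fc| > fc_min` strictly.
#' @param engine `"limma_trend"` (default) or `"welch"`.
#' @return A `data.frame` of class `contrast_result` with columns `gene_id`,
#'   `mean_num`, `mean_den`, `log2fc`, `p`, `padj`, `is_deg`, `direction`,
#'   and attributes `contrast`, `alpha`, `fc_min`, `pseudocount`.
#' @export
de_test <- function(m, contrast, alpha = 0.05, fc_min = 1, pseudocount = 1,
                    sf = NULL, strict_fc = FALSE,
                    engine = c("limma_trend", "welch")) {
  engine <- match.arg(engine)
  stopifnot(inherits(m, "count_matrix"), inherits(contrast, "contrast_spec"))
  idx_num <- group_index(m$samples, contrast$numerator)
  idx_den <- group_index(m$samples, contrast$denominator)
  if (length(idx_num) == 0 || length(idx_den) == 0)
    stop("de_test: contrast group absent from the sample sheet", call. = FALSE)
  if (length(idx_num) < 2 || length(idx_den) < 2)
    stop("de_test: at least 2 replicates per side are required", call. = FALSE)
  norm <- normalize_counts(m, sf)
  mean_num <- rowMeans(norm[, idx_num, drop = FALSE])
  mean_den <- rowMeans(norm[, idx_den, drop = FALSE])
  log2fc <- log2((mean_num + pseudocount) / (mean_den + pseudocount))
  lx <- log2(norm + 1)
  x1 <- lx[, idx_num, drop = FALSE]
  x2 <- lx[, idx_den, drop = FALSE]
  p <- switch(engine, limma_trend = limma_rows(x1, x2),
              welch = welch_rows(x1, x2))
  # rows where both groups are constant are decided exactly
  zero <- rowvars(x1) + rowvars(x2) == 0
  p[zero] <- ifelse(rowMeans(x1)[zero] == rowMeans(x2)[zero], 1, 0)
  p[is.na(p)] <- 1
  p <- pmin(pmax(p, 0), 1)
  padj <- bh_adjust(p)
  pass_fc <- if (strict_fc) abs(log2fc) > fc_min else abs(log2fc) >= fc_min
  is_deg <- padj < alpha & pass_fc
  direction <- ifelse(!is_deg, "none", ifelse(log2fc > 0, "up", "down"))
  out <- data.frame(gene_id = rownames(m$counts), mean_num = mean_num,
                    mean_den = mean_den, log2fc = log2fc, p = p, padj = padj,
                    is_deg = is_deg, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast$name
  attr(out, "alpha") <- alpha
  attr(out, "fc_min") <- fc_min
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Reverse a contrast result (swap numerator and denominator)
#'
#' Means swap, log2fc negates, p-values and significance are unchanged,
#' directions flip.
#'
#' @param r a `contrast_result`.
#' @param name optional new contrast label.
#' @return A `contrast_result`.
#' @export
reverse_contrast <- function(r, name = NULL) {
  stopifnot(inherits(r, "contrast_result"))
  out <- r
  out$mean_num <- r$mean_den
  out$mean_den <- r$mean_num
  out$log2fc <- -r$log2fc
  out$direction <- c(up = "down", down = "up", none = "none")[r$direction]
  names(out$direction) <- NULL
  if (is.null(name)) {
    nm <- attr(r, "contrast")
    parts <- strsplit(nm, "_vs_", fixed = TRUE)[[1]]
    name <- if (length(parts) == 2) paste0(parts[2], "_vs_", parts[1])
            else paste0("rev_", nm)
  }
  attr(out, "contrast") <- name
  out
}

#' Read an externally computed DE table
#'
#' Required columns: `gene_id`, `log2fc`, `p`.  If `padj` is absent it is
#' recomputed by [bh_adjust()]; `mean_num`/`mean_den` are kept when present
#' (else `NA`).  The `is_deg`/`direction` flags are always recomputed from
#' the thresholds given here, regardless of any flags in the file.
#'
#' @param path TSV path.
#' @inheritParams de_test
#' @param name contrast label (default the file name).
#' @return A `contrast_result`.
#' @export
read_contrast_table <- function(path, alpha = 0.05, fc_min = 1,
                                strict_fc = FALSE, name = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  padj <- if ("padj" %in% names(df)) df$padj else bh_adjust(df$p)
  pass_fc <- if (strict_fc) abs(df$log2fc) > fc_min else abs(df$log2fc) >= fc_min
  is_deg <- padj < alpha & pass_fc
  out <- data.frame(
    gene_id = as.character(df$gene_id),
    mean_num = if ("mean_num" %in% names(df)) df$mean_num else NA_real_,
    mean_den = if ("mean_den" %in% names(df)) df$mean_den else NA_real_,
    log2fc = df$log2fc, p = df$p, padj = padj, is_deg = is_deg,
    direction = ifelse(!is_deg, "none", ifelse(df$log2fc > 0, "up", "down")),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- if (is.null(name)) basename(path) else name
  attr(out, "alpha") <- alpha
  attr(out, "fc_min") <- fc_min
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' @rdname read_contrast_table
#' @param r a `contrast_result` to serialize.
#' @export
write_contrast_table <- function(r, path) {
  utils::write.table(as.data.frame(r), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the four study contrasts for one focal genotype
#'
#' Builds the contrast quartet used by the classifier, all oriented from the
#' focal genotype's perspective:
#' * `focal_response`: `N0_focal vs N1_focal`
#' * `other_response`: `N0_other vs N1_other`
#' * `between_n1`: `N1_focal vs N1_other`
#' * `between_n0`: `N0_focal vs N0_other`
#'
#' @param m a [count_matrix()] covering all four groups.
#' @param focal `"HI"` or `"LO"`.
#' @inheritParams de_test
#' @return Named list of four `contrast_result`s, class `contrast_quartet`.
#' @export
contrast_quartet <- function(m, focal = c("HI", "LO"), alpha = 0.05,
                             fc_min = 1, pseudocount = 1, sf = NULL,
                             strict_fc = FALSE,
                             engine = c("limma_trend", "welch")) {
  focal <- match.arg(focal)
  engine <- match.arg(engine)
  other <- setdiff(GENOTYPES, focal)
  if (is.null(sf)) sf <- size_factors(m)
  run <- function(num, den) de_test(m, contrast_spec(num, den), alpha = alpha,
                                    fc_min = fc_min, pseudocount = pseudocount,
                                    sf = sf, strict_fc = strict_fc,
                                    engine = engine)
  structure(list(
    focal_response = run(c(focal, "N0"), c(focal, "N1")),
    other_response = run(c(other, "N0"), c(other, "N1")),
    between_n1     = run(c(focal, "N1"), c(other, "N1")),
    between_n0     = run(c(focal, "N0"), c(other, "N0"))
  ), class = "contrast_quartet", focal = focal)
}
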