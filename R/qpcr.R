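#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_reference) - (Ct_target_cal - Ct_reference_cal)`
#' and relative expression is `2^-ddCt`.  All arguments are vectorized.
#'
#' @param ct_t,ct_r target and reference-gene Ct in the sample of interest.
#' @param ct_t_cal,ct_r_cal the same Cts in the calibrator condition.
#' @return Relative expression (1 when ddCt is 0).
#' @examples
#' ddct(22, 18, 24, 18)  # 4
#' @export
ddct <- function(ct_t, ct_r, ct_t_cal, ct_r_cal) {
  vals <- c(ct_t, ct_r, ct_t_cal, ct_r_cal)
  if (!all(is.finite(vals)))
    stop("ddct: all Ct inputs must be finite", call. = FALSE)
  2^-((ct_t - ct_r) - (ct_t_cal - ct_r_cal))
}

#' Read a Ct table TSV
#'
#' Columns: `gene`, `sample`, `ct_target`, `ct_reference`, `is_calibrator`
#' (logical / 0-1).  Replicate rows per (gene, sample) are allowed and are
#' averaged by [relative_expression()].
#'
#' @param path TSV path.
#' @return A `data.frame` of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "ct_target", "ct_reference", "is_calibrator")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct table ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$is_calibrator <- as.logical(df$is_calibrator)
  if (!all(is.finite(df$ct_target)) || !all(is.finite(df$ct_reference)))
    stop("Ct table ", path, ": Ct values must be finite", call. = FALSE)
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Relative expression per gene and sample from a Ct table
#'
#' Technical-replicate Cts are averaged per (gene, sample) first; each
#' gene's calibrator is the mean over its `is_calibrator` rows, and every
#' sample's relative expression is computed against it by [ddct()].
#' The calibrator condition itself gets relative expression 1.
#'
#' @param ct a [read_ct_table()] result (or equivalent `data.frame`).
#' @return `data.frame` with `gene`, `sample`, `rel_expr`, `log2_rel_expr`.
#' @export
relative_expression <- function(ct) {
  need <- c("gene", "sample", "ct_target", "ct_reference", "is_calibrator")
  stopifnot(all(need %in% names(ct)))
  agg <- stats::aggregate(ct[c("ct_target", "ct_reference")],
                          by = ct[c("gene", "sample", "is_calibrator")],
                          FUN = mean)
  out <- lapply(split(agg, agg$gene), function(g) {
    cal <- g[g$is_calibrator, , drop = FALSE]
    if (nrow(cal) == 0)
      stop("relative_expression: gene '", g$gene[1],
           "' has no calibrator rows", call. = FALSE)
    ct_t_cal <- mean(cal$ct_target)
    ct_r_cal <- mean(cal$ct_reference)
    data.frame(gene = g$gene, sample = g$sample,
               rel_expr = ddct(g$ct_target, g$ct_reference,
                               ct_t_cal, ct_r_cal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$log2_rel_expr <- log2(out$rel_expr)
  rownames(out) <- NULL
  out
}

#' Squared Pearson correlation between qPCR and RNA-seq fold changes
#'
#' @param x,y numeric vectors (e.g. log2 fold changes from the two assays),
#'   equal length of at least 3, each with nonzero variance.
#' @return R-squared, the squared Pearson correlation.
#' @examples
#' concordance(c(1, 2, 3), c(1, 2, 4))  # 0.9643
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("concordance: x and y must have equal length >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("concordance: zero variance makes the correlation undefined",
         call. = FALSE)
  stats::cor(x, y)^2
}
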