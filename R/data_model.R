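#' @keywords internal
"_PACKAGE"

GENOTYPES  <- c("HI", "LO")
TREATMENTS <- c("N1", "N0")

# round half-up, the convention used for reported percentages
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Construct and validate a sample sheet
#'
#' A sample sheet describes the 2-genotype x 2-treatment design: each row is
#' one sequenced library.  Genotypes are coded `"HI"` (the high-NUE line,
#' e.g. 1Y) and `"LO"` (the low-NUE line, e.g. 1W); treatments are `"N1"`
#' (normal nitrogen) and `"N0"` (nitrogen deficiency).
#'
#' @param sample_id character, unique library identifiers.
#' @param genotype character, `"HI"` or `"LO"` per sample.
#' @param treatment character, `"N1"` or `"N0"` per sample.
#' @param replicate positive integer, biological replicate index within its
#'   (genotype, treatment) group.
#' @return A `data.frame` of class `sample_sheet` with the four columns.
#' @examples
#' sample_sheet(
#'   sample_id = c("a", "b", "c", "d"),
#'   genotype  = c("HI", "HI", "LO", "LO"),
#'   treatment = c("N1", "N0", "N1", "N0"),
#'   replicate = c(1, 1, 1, 1)
#' )
#' @export
sample_sheet <- function(sample_id, genotype, treatment, replicate) {
  sample_id <- as.character(sample_id)
  genotype  <- as.character(genotype)
  treatment <- as.character(treatment)
  n <- length(sample_id)
  if (length(genotype) != n || length(treatment) != n || length(replicate) != n)
    stop("sample_sheet: all columns must have the same length", call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("sample_sheet: duplicated sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  bad_g <- setdiff(unique(genotype), GENOTYPES)
  if (length(bad_g))
    stop("sample_sheet: genotype must be one of ",
         paste(GENOTYPES, collapse = "/"), "; got: ",
         paste(bad_g, collapse = ", "), call. = FALSE)
  bad_t <- setdiff(unique(treatment), TREATMENTS)
  if (length(bad_t))
    stop("sample_sheet: treatment must be one of ",
         paste(TREATMENTS, collapse = "/"), "; got: ",
         paste(bad_t, collapse = ", "), call. = FALSE)
  replicate <- as.integer(replicate)
  if (anyNA(replicate) || any(replicate < 1))
    stop("sample_sheet: replicate must be a positive integer", call. = FALSE)
  out <- data.frame(sample_id = sample_id, genotype = genotype,
                    treatment = treatment, replicate = replicate,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Read / write a sample sheet TSV
#'
#' Columns: `sample_id`, `genotype`, `treatment`, `replicate`.
#'
#' @param path file path.
#' @return `read_sample_sheet` returns a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "genotype", "treatment", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sample_sheet(df$sample_id, df$genotype, df$treatment, df$replicate)
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count matrix bound to its sample sheet
#'
#' @param counts integer matrix, genes x samples, with unique rownames
#'   (gene IDs) and colnames equal to `samples$sample_id` in order.
#' @param samples a [sample_sheet()].
#' @return A list of class `count_matrix` with elements `counts` and
#'   `samples`.
#' @export
count_matrix <- function(counts, samples) {
  if (!inherits(samples, "sample_sheet"))
    samples <- sample_sheet(samples$sample_id, samples$genotype,
                            samples$treatment, samples$replicate)
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(samples))
    stop("count_matrix: ", ncol(counts), " columns but ",
         nrow(samples), " sample-sheet rows", call. = FALSE)
  if (nrow(counts) > 0 &&
      (is.null(rownames(counts)) || anyDuplicated(rownames(counts))))
    stop("count_matrix: rownames must be unique gene IDs", call. = FALSE)
  if (is.null(colnames(counts))) {
    colnames(counts) <- samples$sample_id
  } else if (!identical(colnames(counts), samples$sample_id)) {
    stop("count_matrix: colnames must match sample sheet order", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "double"   # holds integral values; avoids int overflow
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(x$samples$genotype, x$samples$treatment)
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene-level count TSV against a sample sheet
#'
#' The file must have a header row whose names (after the first, gene-ID,
#' column) contain exactly the sheet's sample IDs; columns are re-ordered to
#' the sheet order.  Cells must be non-negative integers.
#'
#' @param path counts TSV (first column gene IDs, then one column per sample).
#' @param sheet a [sample_sheet()].
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, sheet) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2)
    stop("counts file ", path, ": needs a gene-ID column plus sample columns",
         call. = FALSE)
  gene_ids <- as.character(df[[1]])
  have <- names(df)[-1]
  missing_s <- setdiff(sheet$sample_id, have)
  extra_s   <- setdiff(have, sheet$sample_id)
  if (length(missing_s) || length(extra_s))
    stop("counts file ", path, ": sample columns do not match the sheet",
         if (length(missing_s)) paste0("; missing: ",
                                       paste(missing_s, collapse = ", ")),
         if (length(extra_s))   paste0("; extra: ",
                                       paste(extra_s, collapse = ", ")),
         call. = FALSE)
  mat <- as.matrix(df[, sheet$sample_id, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("counts file ", path, ": non-integer or negative count at gene '",
         gene_ids[bad[1, 1]], "', sample '", colnames(mat)[bad[1, 2]], "'",
         call. = FALSE)
  }
  rownames(mat) <- gene_ids
  count_matrix(mat, sheet)
}

#' @rdname read_counts
#' @param m a [count_matrix()].
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table (gene_id, length_bp)
#'
#' @param path TSV with columns `gene_id` and `length_bp`.
#' @return Named numeric vector of lengths in base pairs.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene-length file ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  len <- as.numeric(df$length_bp)
  if (anyNA(len) || any(len <= 0))
    stop("gene-length file ", path, ": lengths must be positive", call. = FALSE)
  stats::setNames(len, df$gene_id)
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length_bp * library_size)`.  By default the library
#' size is the per-sample column sum of the count matrix; pass explicit
#' mapped-fragment totals to reproduce report-style semantics where the
#' denominator is the mapped-read total.
#'
#' @param m a [count_matrix()].
#' @param lengths named numeric vector of gene lengths in bp (must cover
#'   every gene of `m`), as from [read_gene_lengths()].
#' @param library_sizes optional per-sample positive totals; default
#'   `colSums(counts)`.
#' @return Numeric matrix of FPKM values, genes x samples.
#' @examples
#' sh <- sample_sheet("s1", "HI", "N1", 1)
#' m  <- count_matrix(matrix(10, 1, 1, dimnames = list("g1", "s1")), sh)
#' compute_fpkm(m, c(g1 = 1000), library_sizes = 1e6)  # 10
#' @export
compute_fpkm <- function(m, lengths, library_sizes = NULL) {
  counts <- m$counts
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("compute_fpkm: no length for gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...", call. = FALSE)
  len <- lengths[rownames(counts)]
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0))
    stop("compute_fpkm: library_sizes must be positive, one per sample",
         call. = FALSE)
  counts * 1e9 / outer(len, library_sizes)
}

#' Sequencing QC percentage arithmetic
#'
#' Reproduces the standard read-accounting summary: clean% = clean/raw,
#' total-mapped% = total_mapped/clean, uniquely-mapped% =
#' uniquely_mapped/total_mapped, each as a percentage rounded half-up to two
#' decimals.
#'
#' @param raw,clean,total_mapped,uniquely_mapped read counts (vectorized).
#' @param sample_id optional sample labels.
#' @return `data.frame` with the counts and the three percentages
#'   (`clean_pct`, `total_mapped_pct`, `uniquely_mapped_pct`).
#' @examples
#' qc_summary(42598731, 42364637, 40389624, 38025789)
#' @export
qc_summary <- function(raw, clean, total_mapped, uniquely_mapped,
                       sample_id = NULL) {
  n <- length(raw)
  if (is.null(sample_id)) sample_id <- paste0("sample", seq_len(n))
  if (any(uniquely_mapped > total_mapped) || any(total_mapped > clean) ||
      any(clean > raw) || any(uniquely_mapped < 0))
    stop("qc_summary: requires uniquely_mapped <= total_mapped <= clean <= raw",
         call. = FALSE)
  if (any(raw == 0) || any(clean == 0) || any(total_mapped == 0))
    stop("qc_summary: zero denominator makes a percentage undefined",
         call. = FALSE)
  data.frame(
    sample_id = sample_id,
    raw_reads = raw, clean_reads = clean,
    total_mapped = total_mapped, uniquely_mapped = uniquely_mapped,
    clean_pct = round_half_up(100 * clean / raw),
    total_mapped_pct = round_half_up(100 * total_mapped / clean),
    uniquely_mapped_pct = round_half_up(100 * uniquely_mapped / total_mapped),
    stringsAsFactors = FALSE
  )
}

#' Read / write a QC table TSV
#'
#' Input columns: `sample_id`, `raw_reads`, `clean_reads`, `total_mapped`,
#' `uniquely_mapped`; percentages are recomputed on read.
#' @param path file path.
#' @export
read_qc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "raw_reads", "clean_reads", "total_mapped",
            "uniquely_mapped")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("QC file ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  qc_summary(df$raw_reads, df$clean_reads, df$total_mapped,
             df$uniquely_mapped, sample_id = df$sample_id)
}

#' @rdname read_qc_table
#' @param qc a QC `data.frame` from [qc_summary()].
#' @export
write_qc_table <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
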