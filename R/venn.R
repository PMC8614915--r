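#' Build a directional DEG set
#'
#' @param x a `contrast_result` (membership from the `direction` flags), or
#'   a character contrast name when `up`/`down` are given explicitly.
#' @param up,down character gene-ID vectors (ignored when `x` is a
#'   `contrast_result`); must be disjoint.
#' @param name optional label overriding the contrast name.
#' @return A list of class `deg_set` with elements `name`, `up`, `down`.
#' @export
deg_set <- function(x, up = NULL, down = NULL, name = NULL) {
  if (inherits(x, "contrast_result")) {
    up <- x$gene_id[x$direction == "up"]
    down <- x$gene_id[x$direction == "down"]
    if (is.null(name)) name <- attr(x, "contrast")
  } else {
    if (is.null(name)) name <- as.character(x)
    up <- as.character(up %||% character(0))
    down <- as.character(down %||% character(0))
  }
  up <- unique(up); down <- unique(down)
  both <- intersect(up, down)
  if (length(both))
    stop("deg_set: gene(s) both up and down: ",
         paste(utils::head(both, 5), collapse = ", "), call. = FALSE)
  structure(list(name = name, up = up, down = down), class = "deg_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deg_ids <- function(s) c(s$up, s$down)

#' @export
length.deg_set <- function(x) length(x$up) + length(x$down)

#' @export
print.deg_set <- function(x, ...) {
  cat("deg_set '", x$name, "': ", length(x$up), " up + ", length(x$down),
      " down = ", length(x), " genes\n", sep = "")
  invisible(x)
}

#' Pairwise Venn summary of two directional DEG sets
#'
#' Computes common and unique gene counts, and flags "inconsistent" common
#' genes — significant in both contrasts but with opposite direction (the
#' parenthetical bookkeeping convention of two-set DEG Venn reports).  By
#' default inconsistent genes stay inside the common count; with
#' `drop_inconsistent = TRUE` they are removed from both sets before the
#' arithmetic, which preserves `|A| = common + unique_a`.
#'
#' @param a,b [deg_set()]s.
#' @param drop_inconsistent drop direction-inconsistent genes entirely
#'   (default `FALSE`: keep in `common`, report in `inconsistent_common`).
#' @return A list of class `venn_summary` with counts (`common`, `unique_a`,
#'   `unique_b`, `inconsistent_common`, up/down splits) and the underlying
#'   ID lists in `$ids`.
#' @export
venn_pairwise <- function(a, b, drop_inconsistent = FALSE) {
  stopifnot(inherits(a, "deg_set"), inherits(b, "deg_set"))
  inconsistent <- c(intersect(a$up, b$down), intersect(a$down, b$up))
  if (drop_inconsistent) {
    a <- deg_set(a$name, up = setdiff(a$up, inconsistent),
                 down = setdiff(a$down, inconsistent))
    b <- deg_set(b$name, up = setdiff(b$up, inconsistent),
                 down = setdiff(b$down, inconsistent))
    inconsistent <- character(0)
  }
  ids_a <- deg_ids(a); ids_b <- deg_ids(b)
  common <- intersect(ids_a, ids_b)
  uniq_a <- setdiff(ids_a, ids_b)
  uniq_b <- setdiff(ids_b, ids_a)
  structure(list(
    name_a = a$name, name_b = b$name,
    common = length(common),
    unique_a = length(uniq_a), unique_b = length(uniq_b),
    inconsistent_common = length(inconsistent),
    common_up = length(intersect(a$up, b$up)),
    common_down = length(intersect(a$down, b$down)),
    unique_a_up = length(intersect(uniq_a, a$up)),
    unique_a_down = length(intersect(uniq_a, a$down)),
    unique_b_up = length(intersect(uniq_b, b$up)),
    unique_b_down = length(intersect(uniq_b, b$down)),
    ids = list(common = common, unique_a = uniq_a, unique_b = uniq_b,
               inconsistent = inconsistent)
  ), class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("venn: ", x$name_a, " | ", x$name_b, "\n",
      "  unique A: ", x$unique_a, "  common: ", x$common,
      " (", x$inconsistent_common, " direction-inconsistent)",
      "  unique B: ", x$unique_b, "\n", sep = "")
  invisible(x)
}

#' Ratio of unique DEG counts between two contrasts
#'
#' `(|A| - common) / (|B| - common)`; e.g. the ratio of condition-unique
#' DEGs between the normal-nitrogen and deficiency between-genotype
#' comparisons.
#'
#' @param a,b [deg_set()]s, or bare numeric totals `|A|` and `|B|`.
#' @param common size of the intersection; defaults to the computed
#'   intersection when `a` and `b` are `deg_set`s.
#' @return The ratio as a single numeric.
#' @examples
#' unique_ratio(7023, 3290, common = 1398)  # 2.97...
#' @export
unique_ratio <- function(a, b, common = NULL) {
  size_a <- if (inherits(a, "deg_set")) length(a) else as.numeric(a)
  size_b <- if (inherits(b, "deg_set")) length(b) else as.numeric(b)
  if (is.null(common)) {
    if (!inherits(a, "deg_set") || !inherits(b, "deg_set"))
      stop("unique_ratio: 'common' is required with numeric totals",
           call. = FALSE)
    common <- length(intersect(deg_ids(a), deg_ids(b)))
  }
  if (common > min(size_a, size_b))
    stop("unique_ratio: common exceeds a set size", call. = FALSE)
  den <- size_b - common
  if (den == 0)
    stop("unique_ratio: zero unique genes in the denominator set",
         call. = FALSE)
  (size_a - common) / den
}

#' Write a Venn summary as a region TSV
#'
#' One row per region (`unique_a`, `common`, `unique_b`, `inconsistent`)
#' with its count and comma-separated gene IDs.
#'
#' @param v a [venn_pairwise()] result.
#' @param path output TSV path.
#' @export
write_venn <- function(v, path) {
  stopifnot(inherits(v, "venn_summary"))
  df <- data.frame(
    region = c("unique_a", "common", "unique_b", "inconsistent"),
    count = c(v$unique_a, v$common, v$unique_b, v$inconsistent_common),
    gene_ids = vapply(v$ids[c("unique_a", "common", "unique_b",
                              "inconsistent")],
                      paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal two-circle Venn figure
#'
#' @param x a `venn_summary`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.venn_summary <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 10), ylim = c(0, 6), axes = FALSE,
                 xlab = "", ylab = "", asp = 1, ...)
  graphics::symbols(c(4, 6), c(3, 3), circles = c(2.2, 2.2), inches = FALSE,
                    add = TRUE, fg = c("firebrick", "steelblue"))
  lab_common <- if (x$inconsistent_common > 0)
    paste0(x$common, "\n(", x$inconsistent_common, ")") else x$common
  graphics::text(c(2.9, 5, 7.1), c(3, 3, 3),
                 labels = c(x$unique_a, lab_common, x$unique_b))
  graphics::text(c(3, 7), c(5.6, 5.6), labels = c(x$name_a, x$name_b))
  invisible(x)
}
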