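#' Read a gene-to-term map TSV
#'
#' Columns: `gene_id`, `term_id`, and optionally `label`.
#'
#' @param path TSV path.
#' @return A list of class `term_map`: `terms` (named list of gene-ID
#'   vectors) and `labels` (named character).
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "term_id"), names(df))
  if (length(miss))
    stop("term map ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  term_map(df$gene_id, df$term_id,
           labels = if ("label" %in% names(df)) df$label else NULL)
}

#' Build a term map from parallel vectors
#'
#' @param gene_id,term_id character vectors of gene-term memberships.
#' @param labels optional per-row term labels (first seen per term wins).
#' @return A `term_map`.
#' @export
term_map <- function(gene_id, term_id, labels = NULL) {
  terms <- lapply(split(as.character(gene_id), as.character(term_id)), unique)
  terms <- terms[lengths(terms) > 0]
  lab <- if (is.null(labels)) stats::setNames(names(terms), names(terms))
         else {
           first <- !duplicated(term_id)
           stats::setNames(as.character(labels)[first],
                           as.character(term_id)[first])[names(terms)]
         }
  structure(list(terms = terms, labels = lab), class = "term_map")
}

#' Hypergeometric over-representation test
#'
#' For each term: with population size `N`, term size `K` (after restricting
#' the term to the population), study size `n`, and overlap `k`, the
#' enrichment p-value is the upper tail `P(X >= k)` of the hypergeometric
#' distribution.  A term is flagged enriched when the raw `p < alpha`
#' (BH-adjusted values are reported alongside).
#'
#' @param study character gene IDs (must be a subset of `population`).
#' @param population character gene IDs (the universe).
#' @param terms a [term_map()].
#' @param alpha raw-p significance threshold (default 0.05).
#' @return `data.frame` with one row per term: `term_id`, `label`, `k`, `K`,
#'   `n`, `N`, `p`, `padj`, `enriched`, `genes` (comma-separated overlap).
#' @export
hypergeom_enrich <- function(study, population, terms, alpha = 0.05) {
  stopifnot(inherits(terms, "term_map"))
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  outside <- setdiff(study, population)
  if (length(outside))
    stop("hypergeom_enrich: study gene(s) outside the population: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) " ...", call. = FALSE)
  N <- length(population)
  n <- length(study)
  rows <- lapply(names(terms$terms), function(tid) {
    tg <- intersect(terms$terms[[tid]], population)
    K <- length(tg)
    if (K == 0) return(NULL)
    hits <- intersect(study, tg)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, label = unname(terms$labels[tid]),
               k = k, K = K, n = n, N = N, p = p,
               genes = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), label = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), padj = numeric(0),
                      enriched = logical(0), genes = character(0)))
  out$padj <- bh_adjust(out$p)
  out$enriched <- out$p < alpha
  out <- out[order(out$p), c("term_id", "label", "k", "K", "n", "N",
                             "p", "padj", "enriched", "genes")]
  rownames(out) <- NULL
  out
}

#' @rdname hypergeom_enrich
#' @param res an enrichment `data.frame` to serialize.
#' @param path output TSV.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
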