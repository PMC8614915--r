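CLASS_LABELS <- c("frontloaded", "relatively_upregulated",
                  "candidate_unclassified", "excluded_not_expressed",
                  "excluded_trend", "not_candidate")

#' Classifier configuration
#'
#' Thresholds for the frontloaded / relatively-upregulated classification.
#' A candidate is *frontloaded* in the focal genotype when its focal/other
#' expression ratio exceeds `ratio_high` under normal nitrogen (N1) and
#' falls below `ratio_low` under deficiency (N0); *relatively upregulated*
#' is the mirror.  Comparisons are strict (`>` / `<`).
#'
#' @param ratio_high upper fold-change-ratio threshold (default 2).
#' @param ratio_low lower threshold (default 0.5); must satisfy
#'   `ratio_low < 1 < ratio_high`.
#' @param expression_floor a gene counts as expressed in the focal genotype
#'   when its mean normalized count reaches this floor in at least one
#'   treatment (default 1).
#' @param alpha,fc_min,pseudocount DE-stage thresholds shared with
#'   [de_test()].
#' @param trend_filter apply the direction-consistency exclusion
#'   (default `TRUE`).
#' @param ratio_source `"normalized_means"` (default) computes the
#'   focal/other ratios from pseudocounted normalized group means;
#'   `"log2fc"` uses `2^log2fc` from the between-genotype DE tables
#'   (useful with externally estimated fold changes).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(ratio_high = 2, ratio_low = 0.5,
                              expression_floor = 1, alpha = 0.05,
                              fc_min = 1, pseudocount = 1,
                              trend_filter = TRUE,
                              ratio_source = c("normalized_means", "log2fc")) {
  if (!(ratio_low < 1 && 1 < ratio_high))
    stop("classifier_config: need ratio_low < 1 < ratio_high", call. = FALSE)
  structure(list(ratio_high = ratio_high, ratio_low = ratio_low,
                 expression_floor = expression_floor, alpha = alpha,
                 fc_min = fc_min, pseudocount = pseudocount,
                 trend_filter = trend_filter,
                 ratio_source = match.arg(ratio_source)),
            class = "classifier_config")
}

#' Genes responding to nitrogen deficiency in the other genotype only
#'
#' The set difference of within-genotype response DEG sets: genes
#' significantly N-responsive in the *other* genotype but not in the focal
#' one, each tagged with its direction in the other genotype.
#'
#' @param other_response,focal_response `contrast_result`s for the two
#'   within-genotype N0-vs-N1 contrasts.
#' @return `data.frame` with columns `gene_id`, `direction`.
#' @export
genotype_specific_response <- function(other_response, focal_response) {
  stopifnot(inherits(other_response, "contrast_result"),
            inherits(focal_response, "contrast_result"))
  other_deg <- other_response[other_response$is_deg, c("gene_id", "direction")]
  focal_ids <- focal_response$gene_id[focal_response$is_deg]
  out <- other_deg[!(other_deg$gene_id %in% focal_ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop genes not expressed in the focal genotype
#'
#' A gene is kept when its mean normalized count in the focal genotype
#' reaches `cfg$expression_floor` in at least one treatment.
#'
#' @param genes character gene IDs, or a `data.frame` with a `gene_id`
#'   column.
#' @param m a [count_matrix()].
#' @param focal `"HI"` or `"LO"`.
#' @param cfg a [classifier_config()].
#' @param sf size factors (default computed from `m`).
#' @return List with `kept` (same shape as `genes`), `removed` (count), and
#'   `removed_ids`.
#' @export
expression_filter <- function(genes, m, focal, cfg = classifier_config(),
                              sf = NULL) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  stopifnot(all(ids %in% rownames(m$counts)))
  if (length(ids) == 0)
    return(list(kept = genes, removed = 0L, removed_ids = character(0)))
  norm <- normalize_counts(m, sf)
  mu_tr <- sapply(TREATMENTS, function(tr) {
    idx <- which(m$samples$genotype == focal & m$samples$treatment == tr)
    rowMeans(norm[ids, idx, drop = FALSE])
  })
  mu_tr <- matrix(mu_tr, nrow = length(ids))
  keep_flag <- rowSums(mu_tr >= cfg$expression_floor) > 0
  kept <- if (is.data.frame(genes)) genes[keep_flag, , drop = FALSE]
          else ids[keep_flag]
  if (is.data.frame(kept)) rownames(kept) <- NULL
  list(kept = kept, removed = sum(!keep_flag), removed_ids = ids[!keep_flag])
}

#' Drop genes with inconsistent expression trends
#'
#' A gene is removed when, in either between-genotype contrast, the sign of
#' the table's `log2fc` disagrees with the sign of the raw normalized-mean
#' difference `mean_num - mean_den` (possible when fold changes were
#' estimated or shrunk externally), or when the other-genotype normalized
#' mean is zero under both treatments so the expression ratio would be
#' undefined without a pseudocount.
#'
#' @param genes character gene IDs or `data.frame` with `gene_id`.
#' @param between_n1,between_n0 `contrast_result`s oriented focal-vs-other.
#' @return List with `kept`, `removed`, `removed_ids`.
#' @export
trend_filter <- function(genes, between_n1, between_n0) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  sign_conflict <- function(r) {
    i <- match(ids, r$gene_id)
    lfc <- r$log2fc[i]
    diff <- r$mean_num[i] - r$mean_den[i]
    !is.na(diff) & (sign(lfc) * sign(diff) < 0)
  }
  other_zero <- function(r) {
    i <- match(ids, r$gene_id)
    md <- r$mean_den[i]
    !is.na(md) & md == 0
  }
  bad <- sign_conflict(between_n1) | sign_conflict(between_n0) |
    (other_zero(between_n1) & other_zero(between_n0))
  kept <- if (is.data.frame(genes)) genes[!bad, , drop = FALSE] else ids[!bad]
  if (is.data.frame(kept)) rownames(kept) <- NULL
  list(kept = kept, removed = sum(bad), removed_ids = ids[bad])
}

#' Stage-by-stage classification bookkeeping
#'
#' Validates and completes the count chain of the classification pipeline:
#' `n_classifiable = n_specific - n_not_expressed - n_trend_inconsistent`,
#' which must equal `n_up + n_down` when the split is supplied;
#' `n_front <= n_candidate_front <= n_up` and likewise for the
#' relatively-upregulated side.
#'
#' @param n_specific genes N-responsive only in the other genotype.
#' @param n_not_expressed removed by the expression filter.
#' @param n_trend_inconsistent removed by the trend filter.
#' @param n_up,n_down split of the classifiable genes by other-genotype
#'   direction (optional).
#' @param n_candidate_front,n_candidate_relup candidates significant in both
#'   between-genotype contrasts (optional).
#' @param n_front,n_relup final class sizes (optional).
#' @return A list of class `bookkeeping` including the derived
#'   `n_classifiable`.
#' @examples
#' bookkeeping(4789, 25, 39, n_up = 2584, n_down = 2141)$n_classifiable
#' @export
bookkeeping <- function(n_specific, n_not_expressed, n_trend_inconsistent,
                        n_up = NULL, n_down = NULL,
                        n_candidate_front = NULL, n_candidate_relup = NULL,
                        n_front = NULL, n_relup = NULL) {
  n_classifiable <- n_specific - n_not_expressed - n_trend_inconsistent
  if (n_classifiable < 0)
    stop("bookkeeping: exclusions exceed the specific set", call. = FALSE)
  if (!is.null(n_up) && !is.null(n_down) &&
      n_up + n_down != n_classifiable)
    stop("bookkeeping: n_up + n_down must equal n_classifiable (",
         n_up, " + ", n_down, " != ", n_classifiable, ")", call. = FALSE)
  chk <- function(lo, hi, what) {
    if (!is.null(lo) && !is.null(hi) && lo > hi)
      stop("bookkeeping: ", what, call. = FALSE)
  }
  chk(n_candidate_front, n_up, "candidates exceed upregulated genes")
  chk(n_front, n_candidate_front, "frontloaded exceed candidates")
  chk(n_candidate_relup, n_down, "candidates exceed downregulated genes")
  chk(n_relup, n_candidate_relup, "relatively-upregulated exceed candidates")
  structure(list(n_specific = n_specific, n_not_expressed = n_not_expressed,
                 n_trend_inconsistent = n_trend_inconsistent,
                 n_classifiable = n_classifiable,
                 n_up = n_up, n_down = n_down,
                 n_candidate_front = n_candidate_front,
                 n_candidate_relup = n_candidate_relup,
                 n_front = n_front, n_relup = n_relup),
            class = "bookkeeping")
}

#' @export
print.bookkeeping <- function(x, ...) {
  cat("specific ", x$n_specific,
      " - not-expressed ", x$n_not_expressed,
      " - trend-inconsistent ", x$n_trend_inconsistent,
      " = classifiable ", x$n_classifiable, "\n", sep = "")
  if (!is.null(x$n_up))
    cat("  up ", x$n_up, " -> candidates ", x$n_candidate_front %||% NA,
        " -> frontloaded ", x$n_front %||% NA, "\n",
        "  down ", x$n_down, " -> candidates ", x$n_candidate_relup %||% NA,
        " -> relatively upregulated ", x$n_relup %||% NA, "\n", sep = "")
  invisible(x)
}

#' Classify genotype-specific N-responsive genes
#'
#' The full classification pipeline for one focal genotype:
#'
#' 1. take genes significantly N-responsive in the *other* genotype but not
#'    in the focal one ([genotype_specific_response()]), tagged with the
#'    other-genotype direction;
#' 2. drop genes not expressed in the focal genotype
#'    ([expression_filter()]);
#' 3. drop genes with inconsistent expression trends ([trend_filter()],
#'    optional);
#' 4. split the remainder by other-genotype direction: upregulated genes are
#'    frontload candidates, downregulated genes are relative-upregulation
#'    candidates;
#' 5. keep candidates that are significant DEGs in **both** between-genotype
#'    contrasts (N1 and N0);
#' 6. label *frontloaded* the candidates with focal/other ratio
#'    `> ratio_high` under N1 and `< ratio_low` under N0, and *relatively
#'    upregulated* the mirror; candidates failing a ratio rule stay
#'    `candidate_unclassified`.
#'
#' Ratios default to `(focal mean + eps) / (other mean + eps)` on
#' size-factor-normalized counts, so they are defined for every gene; see
#' [classifier_config()] for the `log2fc`-based alternative.
#'
#' @param m a [count_matrix()].
#' @param quartet a [contrast_quartet()] (or a named list of four
#'   `contrast_result`s: `focal_response`, `other_response`, `between_n1`,
#'   `between_n0`, the between contrasts oriented focal-vs-other).
#' @param focal `"HI"` or `"LO"`.
#' @param cfg a [classifier_config()].
#' @param sf size factors shared across the stages (default computed from
#'   `m`).
#' @return A list of class `classification_result`: `focal`, `table`
#'   (per-gene `gene_id`, `other_direction`, `r_n1`, `r_n0`, `label` over
#'   the genotype-specific set), `bookkeeping`, and `config`.
#' @export
classify_frontloaded <- function(m, quartet, focal = c("HI", "LO"),
                                 cfg = classifier_config(), sf = NULL) {
  focal <- match.arg(focal)
  other <- setdiff(GENOTYPES, focal)
  need <- c("focal_response", "other_response", "between_n1", "between_n0")
  miss <- setdiff(need, names(quartet))
  if (length(miss))
    stop("classify_frontloaded: quartet lacks contrast(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (nm in need)
    if (!inherits(quartet[[nm]], "contrast_result"))
      stop("classify_frontloaded: quartet$", nm,
           " is not a contrast_result", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(m)

  spec_df <- genotype_specific_response(quartet$other_response,
                                        quartet$focal_response)
  n_specific <- nrow(spec_df)

  ef <- expression_filter(spec_df, m, focal, cfg, sf = sf)
  tf <- if (cfg$trend_filter)
    trend_filter(ef$kept, quartet$between_n1, quartet$between_n0)
  else list(kept = ef$kept, removed = 0L, removed_ids = character(0))
  classifiable <- tf$kept

  up_ids   <- classifiable$gene_id[classifiable$direction == "up"]
  down_ids <- classifiable$gene_id[classifiable$direction == "down"]

  deg_both <- intersect(quartet$between_n1$gene_id[quartet$between_n1$is_deg],
                        quartet$between_n0$gene_id[quartet$between_n0$is_deg])
  cand_front <- intersect(up_ids, deg_both)
  cand_relup <- intersect(down_ids, deg_both)

  # focal/other expression ratios per treatment
  all_ids <- spec_df$gene_id
  if (cfg$ratio_source == "normalized_means") {
    norm <- normalize_counts(m, sf)
    grp_mean <- function(g, tr) {
      idx <- which(m$samples$genotype == g & m$samples$treatment == tr)
      rowMeans(norm[all_ids, idx, drop = FALSE])
    }
    eps <- cfg$pseudocount
    r_n1 <- (grp_mean(focal, "N1") + eps) / (grp_mean(other, "N1") + eps)
    r_n0 <- (grp_mean(focal, "N0") + eps) / (grp_mean(other, "N0") + eps)
  } else {
    r_n1 <- 2^quartet$between_n1$log2fc[match(all_ids,
                                              quartet$between_n1$gene_id)]
    r_n0 <- 2^quartet$between_n0$log2fc[match(all_ids,
                                              quartet$between_n0$gene_id)]
    names(r_n1) <- names(r_n0) <- all_ids
  }

  front <- cand_front[r_n1[cand_front] > cfg$ratio_high &
                      r_n0[cand_front] < cfg$ratio_low]
  relup <- cand_relup[r_n1[cand_relup] < cfg$ratio_low &
                      r_n0[cand_relup] > cfg$ratio_high]

  label <- rep("not_candidate", length(all_ids))
  names(label) <- all_ids
  label[ef$removed_ids] <- "excluded_not_expressed"
  label[tf$removed_ids] <- "excluded_trend"
  label[c(cand_front, cand_relup)] <- "candidate_unclassified"
  label[front] <- "frontloaded"
  label[relup] <- "relatively_upregulated"

  bk <- bookkeeping(
    n_specific = n_specific,
    n_not_expressed = ef$removed,
    n_trend_inconsistent = tf$removed,
    n_up = length(up_ids), n_down = length(down_ids),
    n_candidate_front = length(cand_front),
    n_candidate_relup = length(cand_relup),
    n_front = length(front), n_relup = length(relup)
  )
  tab <- data.frame(gene_id = all_ids,
                    other_direction = spec_df$direction,
                    r_n1 = unname(r_n1[all_ids]), r_n0 = unname(r_n0[all_ids]),
                    label = unname(label[all_ids]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(focal = focal, table = tab, bookkeeping = bk, config = cfg),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification (focal = ", x$focal, ")\n", sep = "")
  print(x$bookkeeping)
  invisible(x)
}

#' Ratio of frontloaded gene counts between the two focal genotypes
#'
#' @param res_a,res_b `classification_result`s for the two focal genotypes
#'   (or bare numeric frontloaded counts).
#' @return `n_front(a) / n_front(b)`.
#' @examples
#' summary_ratio(103, 45)  # 2.288...
#' @export
summary_ratio <- function(res_a, res_b) {
  n <- function(x) {
    if (inherits(x, "classification_result")) x$bookkeeping$n_front
    else as.numeric(x)
  }
  na <- n(res_a); nb <- n(res_b)
  if (nb == 0)
    stop("summary_ratio: zero frontloaded genes in the denominator",
         call. = FALSE)
  na / nb
}

#' Write a classification table TSV
#'
#' @param res a `classification_result`.
#' @param path output TSV.
#' @export
write_classification <- function(res, path) {
  stopifnot(inherits(res, "classification_result"))
  utils::write.table(res$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare a classification against planted truth
#'
#' For the focal genotype of `res`, the planted positives of class
#' `frontloaded` are truth rows with archetype `frontloaded_in_<focal>`, and
#' likewise `relatively_up_in_<focal>` for `relatively_upregulated`.
#' Sensitivity is recovered/planted; precision is recovered/labeled.
#'
#' @param res a `classification_result`.
#' @param truth truth `data.frame` (`gene_id`, `archetype`) from
#'   [simulate_counts()] or [read_truth()].
#' @return `data.frame` with one row per class: `class`, `n_planted`,
#'   `n_labeled`, `tp`, `sensitivity`, `precision`.
#' @export
evaluate_classification <- function(res, truth) {
  stopifnot(inherits(res, "classification_result"))
  focal <- res$focal
  classes <- c(frontloaded = paste0("frontloaded_in_", focal),
               relatively_upregulated = paste0("relatively_up_in_", focal))
  out <- lapply(names(classes), function(lb) {
    planted <- truth$gene_id[truth$archetype == classes[[lb]]]
    labeled <- res$table$gene_id[res$table$label == lb]
    tp <- length(intersect(planted, labeled))
    data.frame(class = lb, n_planted = length(planted),
               n_labeled = length(labeled), tp = tp,
               sensitivity = if (length(planted)) tp / length(planted) else NA,
               precision = if (length(labeled)) tp / length(labeled) else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
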