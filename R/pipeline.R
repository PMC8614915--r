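#' Run the full dual-genotype analysis
#'
#' Executes the whole pipeline on one count matrix: size factors, the four
#' study contrasts, DEG sets and pairwise Venn summaries (the within-
#' genotype response pair and the between-genotype pair), the frontloaded /
#' relatively-upregulated classification for both focal genotypes, the
#' frontloaded-count summary ratio, and optionally term enrichment of each
#' frontloaded set.  When `output_dir` is given, every stage's table is
#' written as TSV plus a `summary.json`.
#'
#' @param m a [count_matrix()] covering the 2x2 design.
#' @param cfg a [classifier_config()] (its `alpha`, `fc_min`, `pseudocount`
#'   drive the DE stage too).
#' @param term_map optional [term_map()]; when given, each focal genotype's
#'   frontloaded set is tested for term over-representation against all
#'   genes of `m`.
#' @param output_dir optional directory for the report bundle.
#' @param seed recorded in the summary for provenance (the pipeline itself
#'   is deterministic).
#' @return A list of class `frontload_report`; see Details.
#' @details The report carries: `size_factors`; `contrasts` (the four
#'   `contrast_result`s keyed `response_HI`, `response_LO`, `between_N1`,
#'   `between_N0`, each oriented as named); `deg_counts` (per-contrast
#'   up/down/total); `venn_response` (response-pair summary),
#'   `venn_between`; `unique_ratio_between` (N1-unique over N0-unique);
#'   `classification` (list `HI`, `LO`); `summary_ratio_front`
#'   (frontloaded HI over LO, `NA` when the LO count is zero);
#'   `enrichment` (optional); `thresholds`; `seed`.
#' @export
run_pipeline <- function(m, cfg = classifier_config(), term_map = NULL,
                         output_dir = NULL, seed = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  sf <- size_factors(m)
  qHI <- contrast_quartet(m, "HI", alpha = cfg$alpha, fc_min = cfg$fc_min,
                          pseudocount = cfg$pseudocount, sf = sf)
  # the LO-focal quartet reuses the same four tests, reoriented
  qLO <- structure(list(
    focal_response = qHI$other_response,
    other_response = qHI$focal_response,
    between_n1     = reverse_contrast(qHI$between_n1),
    between_n0     = reverse_contrast(qHI$between_n0)
  ), class = "contrast_quartet", focal = "LO")

  contrasts <- list(response_HI = qHI$focal_response,
                    response_LO = qHI$other_response,
                    between_N1 = qHI$between_n1,
                    between_N0 = qHI$between_n0)
  sets <- lapply(contrasts, deg_set)
  deg_counts <- data.frame(
    contrast = vapply(contrasts, attr, "", "contrast"),
    up = vapply(sets, function(s) length(s$up), 0L),
    down = vapply(sets, function(s) length(s$down), 0L),
    total = vapply(sets, length, 0L),
    row.names = NULL, stringsAsFactors = FALSE)

  venn_response <- venn_pairwise(sets$response_LO, sets$response_HI)
  venn_between <- venn_pairwise(sets$between_N1, sets$between_N0)
  ur <- tryCatch(unique_ratio(sets$between_N1, sets$between_N0),
                 error = function(e) NA_real_)

  cls <- list(HI = classify_frontloaded(m, qHI, "HI", cfg, sf = sf),
              LO = classify_frontloaded(m, qLO, "LO", cfg, sf = sf))
  sr <- tryCatch(summary_ratio(cls$HI, cls$LO), error = function(e) NA_real_)

  enr <- NULL
  if (!is.null(term_map)) {
    population <- rownames(m$counts)
    enr <- lapply(cls, function(res) {
      front <- res$table$gene_id[res$table$label == "frontloaded"]
      if (length(front) == 0) return(NULL)
      hypergeom_enrich(front, population, term_map, alpha = cfg$alpha)
    })
  }

  report <- structure(list(
    size_factors = sf, contrasts = contrasts, deg_counts = deg_counts,
    venn_response = venn_response, venn_between = venn_between,
    unique_ratio_between = ur, classification = cls,
    summary_ratio_front = sr, enrichment = enr,
    thresholds = cfg, seed = seed
  ), class = "frontload_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.frontload_report <- function(x, ...) {
  cat("frontload_report\n\nDEG counts per contrast:\n")
  print(x$deg_counts)
  cat("\nResponse-pair Venn:\n"); print(x$venn_response)
  cat("Between-pair Venn:\n"); print(x$venn_between)
  cat("N1-unique / N0-unique ratio: ",
      formatC(x$unique_ratio_between, digits = 3), "\n\n", sep = "")
  for (g in names(x$classification)) print(x$classification[[g]])
  cat("\nfrontloaded HI / LO ratio: ",
      formatC(x$summary_ratio_front, digits = 3), "\n", sep = "")
  invisible(x)
}

report_summary_list <- function(report) {
  bk <- lapply(report$classification, function(res)
    Filter(Negate(is.null), unclass(res$bookkeeping)))
  venn_list <- function(v)
    list(common = v$common, unique_a = v$unique_a, unique_b = v$unique_b,
         inconsistent_common = v$inconsistent_common)
  list(
    deg_counts = report$deg_counts,
    venn_response = venn_list(report$venn_response),
    venn_between = venn_list(report$venn_between),
    unique_ratio_between = report$unique_ratio_between,
    bookkeeping = bk,
    summary_ratio_front = report$summary_ratio_front,
    thresholds = Filter(Negate(is.null), unclass(report$thresholds)),
    seed = report$seed
  )
}

#' Write a report bundle to disk
#'
#' Emits per-contrast DE TSVs, Venn region TSVs, classification TSVs for
#' both focal genotypes, optional enrichment TSVs, and `summary.json`.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "frontload_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$contrasts))
    write_contrast_table(report$contrasts[[nm]],
                         file.path(dir, paste0("de_", nm, ".tsv")))
  write_venn(report$venn_response, file.path(dir, "venn_response.tsv"))
  write_venn(report$venn_between, file.path(dir, "venn_between.tsv"))
  for (g in names(report$classification))
    write_classification(report$classification[[g]],
                         file.path(dir, paste0("classification_", g, ".tsv")))
  if (!is.null(report$enrichment)) {
    for (g in names(report$enrichment))
      if (!is.null(report$enrichment[[g]]))
        write_enrichment(report$enrichment[[g]],
                         file.path(dir, paste0("enrichment_front_", g,
                                               ".tsv")))
  }
  jsonlite::write_json(report_summary_list(report),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Run the pipeline from a YAML run configuration
#'
#' The YAML may carry either a `simulate` block (passed to
#' [simulation_config()] via [default_sim_config()] fields: `seed`,
#' `baseline_mean`, `between_genotype_fold`, `response_fold`, `dispersion`)
#' or `counts` + `samples` paths; optional keys: `lengths`, `term_map`,
#' `output_dir`, and a `thresholds` block with [classifier_config()]
#' fields.
#'
#' @param path YAML file path.
#' @return A `frontload_report` (with attribute `sim` when simulated).
#' @export
run_pipeline_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- do.call(classifier_config, cfg$thresholds %||% list())
  tm <- if (!is.null(cfg$term_map)) read_term_map(cfg$term_map)
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- simulate_counts(do.call(default_sim_config, cfg$simulate))
    m <- sim$counts
    seed <- cfg$simulate$seed %||% 1L
  } else {
    if (is.null(cfg$counts) || is.null(cfg$samples))
      stop("run config ", path, ": needs either a 'simulate' block or ",
           "'counts' + 'samples' paths", call. = FALSE)
    sheet <- read_sample_sheet(cfg$samples)
    m <- read_counts(cfg$counts, sheet)
    seed <- cfg$seed
  }
  report <- run_pipeline(m, cfg = thr, term_map = tm,
                         output_dir = cfg$output_dir, seed = seed)
  attr(report, "sim") <- sim
  report
}
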