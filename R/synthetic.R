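ARCHETYPES <- c("frontloaded_in_HI", "relatively_up_in_HI",
                "frontloaded_in_LO", "relatively_up_in_LO",
                "shared_response", "constitutive_difference", "null")

GROUP_CELLS <- c("HI_N1", "HI_N0", "LO_N1", "LO_N0")

#' Describe one planted gene archetype
#'
#' An archetype fixes the expected expression of a block of simulated genes
#' in the four genotype x treatment cells.  The two interesting classes are:
#'
#' * `frontloaded_in_HI` — elevated in HI vs LO under normal nitrogen
#'   (`between_genotype_fold`), depressed relative to LO under deficiency,
#'   with the nitrogen response (`response_fold`) confined to LO.
#' * `relatively_up_in_HI` — the mirror: depressed vs LO under normal
#'   nitrogen, elevated under deficiency, response (downward) confined to LO.
#'
#' `*_in_LO` swap the genotype roles.  `shared_response` responds to
#' deficiency identically in both genotypes; `constitutive_difference`
#' differs between genotypes identically in both treatments; `null` is flat.
#'
#' @param name one of
#'   `r paste0('\x60', ARCHETYPES, '\x60', collapse = ", ")`.
#' @param n_genes number of genes of this archetype.
#' @param baseline_mean expected fragment count at unit size factor for the
#'   reference cell (default 100).
#' @param between_genotype_fold fold difference between genotypes (default 4).
#' @param response_fold nitrogen-response fold in the responding genotype
#'   (default 16).
#' @return A list of class `archetype_spec`.
#' @export
archetype_spec <- function(name, n_genes, baseline_mean = 100,
                           between_genotype_fold = 4, response_fold = 16) {
  name <- match.arg(name, ARCHETYPES)
  if (n_genes < 0) stop("archetype_spec: n_genes must be >= 0", call. = FALSE)
  if (baseline_mean <= 0)
    stop("archetype_spec: baseline_mean must be > 0", call. = FALSE)
  if (name != "null" &&
      (between_genotype_fold <= 1 || response_fold <= 1))
    stop("archetype_spec: folds must be > 1 for non-null archetypes",
         call. = FALSE)
  structure(list(name = name, n_genes = as.integer(n_genes),
                 baseline_mean = baseline_mean,
                 between_genotype_fold = between_genotype_fold,
                 response_fold = response_fold),
            class = "archetype_spec")
}

#' Expected group means for one archetype
#'
#' Returns the four cell means in the order `HI_N1, HI_N0, LO_N1, LO_N0`.
#' For `frontloaded_in_HI` with baseline `m` and folds `(b, r)` the means are
#' `(b*m, b*m, m, r*m)`: the HI/LO ratio is `b` under N1 and `b/r` under N0,
#' and only LO responds to deficiency (log2FC `log2(r)`).
#' `relatively_up_in_HI` gives `(m/b, m/b, m, m/r)`.
#'
#' @param spec an [archetype_spec()].
#' @return Named numeric vector of length 4.
#' @examples
#' plant_means(archetype_spec("frontloaded_in_HI", 1))  # 400 400 100 1600
#' @export
plant_means <- function(spec) {
  stopifnot(inherits(spec, "archetype_spec"))
  m <- spec$baseline_mean
  b <- spec$between_genotype_fold
  r <- spec$response_fold
  mu <- switch(spec$name,
    null                    = c(m, m, m, m),
    frontloaded_in_HI       = c(b * m, b * m, m, r * m),
    relatively_up_in_HI     = c(m / b, m / b, m, m / r),
    frontloaded_in_LO       = c(m, r * m, b * m, b * m),
    relatively_up_in_LO     = c(m, m / r, m / b, m / b),
    shared_response         = c(m, r * m, m, r * m),
    constitutive_difference = c(b * m, b * m, m, m)
  )
  stats::setNames(mu, GROUP_CELLS)
}

#' Simulation configuration
#'
#' @param archetypes list of [archetype_spec()]s.
#' @param replicates_per_group biological replicates per genotype x treatment
#'   cell (default 3, the emulated design).
#' @param dispersion negative-binomial dispersion phi, so that
#'   `Var = mu + phi * mu^2` (default 0.05); a single value shared across
#'   genes, or one value per gene.
#' @param depth_factors per-sample positive depth multipliers (default all 1),
#'   or the string `"lognormal"` for log-normal factors with sdlog 0.2.
#' @param seed integer RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(archetypes, replicates_per_group = 3,
                              dispersion = 0.05, depth_factors = NULL,
                              seed = 1L) {
  if (inherits(archetypes, "archetype_spec")) archetypes <- list(archetypes)
  stopifnot(all(vapply(archetypes, inherits, TRUE, "archetype_spec")))
  if (replicates_per_group < 2)
    stop("simulation_config: replicates_per_group must be >= 2", call. = FALSE)
  if (any(dispersion <= 0))
    stop("simulation_config: dispersion must be > 0", call. = FALSE)
  structure(list(archetypes = archetypes,
                 replicates_per_group = as.integer(replicates_per_group),
                 dispersion = dispersion,
                 depth_factors = depth_factors,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' The default planted-class study configuration
#'
#' 2000 genes: 120 `frontloaded_in_HI`, 80 `relatively_up_in_HI`, 120/80
#' mirrored in LO, 300 `shared_response`, 300 `constitutive_difference`, and
#' 1000 `null`; 3 replicates per group, dispersion 0.05, folds (4, 16),
#' baseline mean 100.
#'
#' @param seed integer RNG seed.
#' @param baseline_mean,between_genotype_fold,response_fold,dispersion
#'   forwarded to every archetype / the config.
#' @return A [simulation_config()].
#' @export
default_sim_config <- function(seed = 1L, baseline_mean = 100,
                               between_genotype_fold = 4, response_fold = 16,
                               dispersion = 0.05) {
  sizes <- c(frontloaded_in_HI = 120, relatively_up_in_HI = 80,
             frontloaded_in_LO = 120, relatively_up_in_LO = 80,
             shared_response = 300, constitutive_difference = 300,
             null = 1000)
  arch <- lapply(names(sizes), function(nm)
    archetype_spec(nm, sizes[[nm]], baseline_mean = baseline_mean,
                   between_genotype_fold = between_genotype_fold,
                   response_fold = response_fold))
  simulation_config(arch, replicates_per_group = 3, dispersion = dispersion,
                    seed = seed)
}

#' All-null configuration for false-positive control checks
#'
#' @param n_genes number of null genes (default 2000).
#' @inheritParams default_sim_config
#' @return A [simulation_config()].
#' @export
null_sim_config <- function(seed = 1L, n_genes = 2000, baseline_mean = 100,
                            dispersion = 0.05) {
  simulation_config(list(archetype_spec("null", n_genes,
                                        baseline_mean = baseline_mean)),
                    replicates_per_group = 3, dispersion = dispersion,
                    seed = seed)
}

#' Simulate a two-genotype x two-treatment count matrix with ground truth
#'
#' Counts are drawn independently per gene and sample from a negative
#' binomial with mean `mu_cell * depth_factor` and variance
#' `mu + phi * mu^2`.  Gene IDs are `"<archetype>_<index>"` so the truth is
#' self-describing; the full truth table (archetype and the four planted
#' cell means per gene) is returned alongside.
#'
#' @param config a [simulation_config()].
#' @return A list of class `frontload_sim` with elements `counts` (a
#'   [count_matrix()]) and `truth` (`data.frame`: `gene_id`, `archetype`,
#'   `mu_HI_N1`, `mu_HI_N0`, `mu_LO_N1`, `mu_LO_N0`).
#' @examples
#' sim <- simulate_counts(default_sim_config(seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  reps <- config$replicates_per_group
  grid <- expand.grid(replicate = seq_len(reps), cell = GROUP_CELLS,
                      stringsAsFactors = FALSE)
  # samples ordered HI_N1, HI_N0, LO_N1, LO_N0, replicates within cell
  grid <- grid[order(match(grid$cell, GROUP_CELLS), grid$replicate), ]
  parts <- strsplit(grid$cell, "_")
  sheet <- sample_sheet(
    sample_id = paste0(grid$cell, "_r", grid$replicate),
    genotype  = vapply(parts, `[`, "", 1),
    treatment = vapply(parts, `[`, "", 2),
    replicate = grid$replicate
  )
  n_samples <- nrow(sheet)

  mu_list <- lapply(config$archetypes, function(sp) {
    if (sp$n_genes == 0) return(NULL)
    mu <- matrix(rep(plant_means(sp), each = sp$n_genes), nrow = sp$n_genes,
                 dimnames = list(sprintf("%s_%04d", sp$name,
                                         seq_len(sp$n_genes)), GROUP_CELLS))
    mu
  })
  mu <- do.call(rbind, mu_list)
  if (is.null(mu)) mu <- matrix(0, 0, 4, dimnames = list(NULL, GROUP_CELLS))
  n_genes <- nrow(mu)

  set.seed(config$seed)
  depth <- config$depth_factors
  if (is.null(depth)) {
    depth <- rep(1, n_samples)
  } else if (identical(depth, "lognormal")) {
    depth <- stats::rlnorm(n_samples, meanlog = 0, sdlog = 0.2)
  } else if (length(depth) != n_samples || any(depth <= 0)) {
    stop("simulate_counts: depth_factors must be positive, one per sample",
         call. = FALSE)
  }

  cell_of_sample <- paste(sheet$genotype, sheet$treatment, sep = "_")
  mu_samples <- mu[, cell_of_sample, drop = FALSE] *
    rep(depth, each = n_genes)
  phi <- config$dispersion
  counts <- matrix(
    stats::rnbinom(n_genes * n_samples, mu = as.vector(mu_samples),
                   size = 1 / phi),
    nrow = n_genes, ncol = n_samples,
    dimnames = list(rownames(mu), sheet$sample_id)
  )
  truth <- data.frame(gene_id = rownames(mu), archetype = sub("_[0-9]+$", "",
                                                              rownames(mu)),
                      mu_HI_N1 = mu[, "HI_N1"], mu_HI_N0 = mu[, "HI_N0"],
                      mu_LO_N1 = mu[, "LO_N1"], mu_LO_N0 = mu[, "LO_N0"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(counts = count_matrix(counts, sheet), truth = truth,
                 seed = config$seed),
            class = "frontload_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits `counts.tsv`, `samples.tsv`, `truth.tsv`, and `metadata.json`
#' (recording the seed) into `dir`.
#'
#' @param sim a `frontload_sim` from [simulate_counts()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "frontload_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$counts$samples, file.path(dir, "samples.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = sim$seed), file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a planted-truth table
#'
#' @param path `truth.tsv` as written by [write_simulation()].
#' @return `data.frame` with at least `gene_id` and `archetype`.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "archetype"), names(df))
  if (length(miss))
    stop("truth file ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}
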