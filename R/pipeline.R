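# End-to-end orchestration on synthetic data: simulate -> collapse ->
# characteristic genes -> paired differential expression -> enrichment.
# Every artifact carries a header with the package version, a config hash and
# the seed, so a run is reproducible and self-describing.

#' Default pipeline configuration
#'
#' @param seed Integer seed controlling every random stage.
#' @param ... Named overrides of any default (see Details).
#' @details Components: `dev` (arguments of [simulate_dev_timeseries()]),
#'   `cohort` ([simulate_paired_cohort()]), `probes`
#'   ([simulate_probe_map()]: `max_probes_per_gene`), `top_fraction`, `pcs`,
#'   `alpha`, `ci_level`, `smooth` (`span`, `degree`, applied when
#'   `smooth$enabled`).
#' @return A named list; round-trips losslessly through YAML.
#' @export
pipeline_config <- function(seed, ...) {
  if (missing(seed)) abort("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    dev = list(n_genes = 2000, n_characteristic = 100,
               effect_amp = 1.5, noise_sd = 0.5),
    cohort = list(n_genes = 2000, n_pairs = 95, de_fraction = 0.05,
                  effect_log2 = 1.0, noise_sd = 0.4),
    probes = list(max_probes_per_gene = 3),
    top_fraction = 0.05,
    pcs = 1:3,
    alpha = 0.05,
    ci_level = 0.95,
    smooth = list(enabled = FALSE, span = 0.7, degree = 1)
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return `read_config()`: the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) abort("config must carry a seed")
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$pcs)) cfg$pcs <- as.integer(cfg$pcs)
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Stages: simulate a duplicated developmental series and a paired cohort;
#' expand the series to probe level and collapse it back by replicate
#' correlation; standardize and extract the characteristic gene set from
#' PC1-3 loadings; run paired Wilcoxon differential expression on the
#' cohort; test the characteristic set for over-representation among the
#' significant genes. Re-running with an identical configuration reproduces
#' identical artifact files.
#'
#' @param config Configuration list from [pipeline_config()] or
#'   [read_config()], or a path to a YAML file.
#' @param output_dir Directory for artifacts (created if needed).
#' @return Invisibly, a list with `char_set`, `diffexpr`, `enrichment`,
#'   `files` (paths written) and `config`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  if (is.null(config$seed)) abort("config must carry a seed")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- artifact_header(config)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    readr::write_lines(stamp, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
    files[[name]] <<- path
    path
  }

  seeds <- config$seed + base::c(dev = 0L, probes = 1L, expand = 2L, cohort = 3L)

  # --- developmental series: simulate, probe expansion, collapse ------------
  dev <- do.call(simulate_dev_timeseries,
                 base::c(config$dev, list(seed = unname(seeds["dev"]))))
  probe_map <- simulate_probe_map(
    dev$truth$gene_id,
    max_probes_per_gene = config$probes$max_probes_per_gene,
    seed = unname(seeds["probes"])
  )
  probe_expr <- expand_probe_matrix(dev$expression, probe_map,
                                    seed = unname(seeds["expand"]))
  expr <- probe_expr
  if (isTRUE(config$smooth$enabled)) {
    expr <- smooth_expression(expr, dev$metadata,
                              span = config$smooth$span,
                              degree = config$smooth$degree)
  }
  corr <- replicate_correlation(expr, dev$metadata)
  gene_expr <- collapse_max_correlation(expr, probe_map, corr)
  emit(dev$metadata, "dev_metadata.tsv")
  emit(corr, "replicate_correlation.tsv")

  # --- characteristic genes -------------------------------------------------
  pca <- pca_loadings(standardize_samples(gene_expr),
                      n_components = max(config$pcs))
  char_set <- characteristic_genes(pca, top_fraction = config$top_fraction,
                                   pcs = config$pcs)
  emit(dplyr::select(tidy(pca), "gene_id", pc = "pc", "loading", "rank"),
       "loadings.tsv")
  emit(glance(pca), "explained_variance.tsv")
  char_path <- file.path(output_dir, "characteristic_genes.txt")
  readr::write_lines(base::c(stamp, char_set$gene_ids), char_path)
  files[["characteristic_genes.txt"]] <- char_path

  # --- paired differential expression ---------------------------------------
  cohort <- do.call(simulate_paired_cohort,
                    base::c(config$cohort, list(seed = unname(seeds["cohort"]))))
  de <- differential_table(cohort$expression, cohort$design,
                           alpha = config$alpha)
  emit(dplyr::select(de, "feature_id", "n_pairs_used", W = "statistic",
                     "p", "p_bh", "log2fc"),
       "differential_expression.tsv")
  sig_path <- file.path(output_dir, "significant_genes.txt")
  readr::write_lines(base::c(stamp, significant_features(de)), sig_path)
  files[["significant_genes.txt"]] <- sig_path

  # --- enrichment: characteristic set among significant genes ---------------
  universe <- cohort$truth$gene_id
  enr <- enrich(char_set$gene_ids, significant_features(de), universe,
                level = config$ci_level)
  enr_path <- file.path(output_dir, "enrichment.json")
  write_enrich_json(enr, enr_path)
  files[["enrichment.json"]] <- enr_path
  emit(tidy(enr), "enrichment.tsv")

  invisible(list(char_set = char_set, diffexpr = de, enrichment = enr,
                 files = files, config = config))
}

artifact_header <- function(config) {
  ver <- as.character(utils::packageVersion("chargenes"))
  sprintf("# chargenes %s | config %s | seed %d",
          ver, rlang::hash(config), config$seed)
}
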