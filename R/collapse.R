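# Probe-to-gene collapse. Array platforms measure a gene with one or more
# probe sets; a single representative probe is chosen per gene, either by
# replicate-profile reproducibility (time series) or by smallest signed-rank
# p value (paired designs).

#' Correlation between replicate time-series profiles
#'
#' For a duplicated developmental series, computes for each feature the
#' Pearson correlation between its two replicate expression profiles ordered
#' by age. High correlation means the temporal profile is reproducible.
#'
#' @param expr Expression tibble (features x samples).
#' @param meta Metadata tibble with `sample_id`, `age_days`, `replicate_id`;
#'   exactly two replicate series over a common age grid, each age present
#'   once per replicate.
#' @return Tibble `(feature_id, correlation)`; `correlation` is `NA` when
#'   either profile has zero variance.
#' @export
replicate_correlation <- function(expr, meta) {
  m <- expr_matrix(expr)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (any(is.na(meta$sample_id))) abort("metadata missing some samples of the expression table")
  reps <- sort(unique(meta$replicate_id))
  if (length(reps) != 2) {
    abort(sprintf("replicate_correlation needs exactly 2 replicates, found %d", length(reps)))
  }
  split_ages <- split(meta$age_days, meta$replicate_id)
  a1 <- sort(split_ages[[reps[1]]]); a2 <- sort(split_ages[[reps[2]]])
  if (length(a1) != length(a2) || any(a1 != a2)) abort("replicate age grids do not match")
  if (anyDuplicated(a1)) abort("an age occurs more than once within a replicate")
  idx1 <- meta$sample_id[meta$replicate_id == reps[1]][order(meta$age_days[meta$replicate_id == reps[1]])]
  idx2 <- meta$sample_id[meta$replicate_id == reps[2]][order(meta$age_days[meta$replicate_id == reps[2]])]
  x <- m[, idx1, drop = FALSE]
  y <- m[, idx2, drop = FALSE]
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sxx <- rowSums(xc^2); syy <- rowSums(yc^2)
  r <- rowSums(xc * yc) / sqrt(sxx * syy)
  r[sxx == 0 | syy == 0] <- NA_real_
  tibble::tibble(feature_id = rownames(m), correlation = as.numeric(r))
}

#' Collapse probes to genes by maximum replicate correlation
#'
#' Each gene measured by more than one probe set is represented by the probe
#' whose replicate time-series profiles correlate most strongly; ties (and
#' all-undefined correlations) are broken by the lexicographically smallest
#' probe id. Probes absent from the map are excluded with a message.
#'
#' @param expr Probe-level expression tibble.
#' @param probe_map Tibble `(probe_id, gene_id)`.
#' @param corr Tibble `(feature_id, correlation)` from
#'   [replicate_correlation()], covering every mapped probe in `expr`.
#' @return Gene-level expression tibble, one row per distinct gene, rows the
#'   selected probes' rows; `feature_id` becomes the gene id.
#' @export
collapse_max_correlation <- function(expr, probe_map, corr) {
  validate_expression(expr)
  probe_map <- probe_map[, base::c("probe_id", "gene_id")]
  unmapped <- setdiff(expr$feature_id, probe_map$probe_id)
  if (length(unmapped) > 0) {
    inform(sprintf("excluded %d probe(s) absent from the probe map", length(unmapped)))
  }
  joined <- expr |>
    dplyr::inner_join(probe_map, by = c(feature_id = "probe_id")) |>
    dplyr::left_join(corr, by = "feature_id")
  missing_corr <- joined$feature_id[is.na(match(joined$feature_id, corr$feature_id))]
  if (length(missing_corr) > 0) {
    abort(sprintf("no correlation supplied for probe '%s'", missing_corr[1]))
  }
  picked <- joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$correlation, -Inf)),
                   .data$feature_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id)
  picked |>
    dplyr::mutate(feature_id = .data$gene_id) |>
    dplyr::select(-"gene_id", -"correlation")
}

#' Collapse a differential-expression table to genes by minimum p
#'
#' For each gene the probe row with the smallest p value is retained; ties are
#' broken by the lexicographically smallest probe id.
#'
#' @param de Tibble with at least `feature_id` and `p` (probe-level).
#' @param probe_map Tibble `(probe_id, gene_id)`.
#' @return The selected rows keyed by `gene_id` (original probe id kept as
#'   `probe_id`).
#' @export
collapse_min_p <- function(de, probe_map) {
  if (!all(c("feature_id", "p") %in% names(de))) abort("`de` needs columns feature_id and p")
  if (any(de$p < 0 | de$p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1]")
  probe_map <- probe_map[, base::c("probe_id", "gene_id")]
  unmapped <- setdiff(de$feature_id, probe_map$probe_id)
  if (length(unmapped) > 0) {
    inform(sprintf("excluded %d probe(s) absent from the probe map", length(unmapped)))
  }
  de |>
    dplyr::inner_join(probe_map, by = c(feature_id = "probe_id")) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$p, .data$feature_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::rename(probe_id = "feature_id") |>
    dplyr::relocate("gene_id") |>
    dplyr::arrange(.data$gene_id)
}
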