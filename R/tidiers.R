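# broom-style methods for the package's result objects

#' Tidy a gene-space PCA
#'
#' @param x A `dev_pca` object.
#' @param ... Unused.
#' @return The ranked loading table: tibble `(gene_id, pc, loading, rank)`.
#' @method tidy dev_pca
#' @export
tidy.dev_pca <- function(x, ...) x$loadings

#' @rdname tidy.dev_pca
#' @return `glance()`: one row per component with its variance and the
#'   fraction of total sample variance explained.
#' @method glance dev_pca
#' @export
glance.dev_pca <- function(x, ...) x$explained_variance

#' Tidy a characteristic gene set
#'
#' @param x A `char_gene_set` object.
#' @param ... Unused.
#' @return Tibble `(gene_id, pc)`, one row per gene per component in which it
#'   is characteristic.
#' @method tidy char_gene_set
#' @export
tidy.char_gene_set <- function(x, ...) {
  purrr::imap(x$per_pc, function(genes, nm) {
    tibble::tibble(gene_id = genes, pc = as.integer(sub("^PC", "", nm)))
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$pc, .data$gene_id)
}

#' @rdname tidy.char_gene_set
#' @method glance char_gene_set
#' @export
glance.char_gene_set <- function(x, ...) {
  tibble::tibble(
    n_genes_set = length(x$gene_ids),
    n_genes_total = x$n_genes,
    n_per_pc = x$n_per_pc,
    top_fraction = x$top_fraction,
    n_pcs = length(x$per_pc)
  )
}

#' Tidy an enrichment result
#'
#' @param x An `enrich_result` object.
#' @param ... Unused.
#' @return One-row tibble with the table cells, p-value, both odds-ratio
#'   estimates and the confidence bounds.
#' @method tidy enrich_result
#' @export
tidy.enrich_result <- function(x, ...) {
  tibble::tibble(
    a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    p = x$p, or_sample = x$or_sample, or_cmle = x$or_cmle,
    ci_lower = x$ci[["lower"]], ci_upper = x$ci[["upper"]],
    level = x$level, universe_size = x$universe_size
  )
}

#' @rdname tidy.enrich_result
#' @method glance enrich_result
#' @export
glance.enrich_result <- function(x, ...) tidy.enrich_result(x)

#' Tidy a gene set
#'
#' @param x A `gene_set` object.
#' @param ... Unused.
#' @return The provenance tibble `(gene_id, supervised, unsupervised)`.
#' @method tidy gene_set
#' @export
tidy.gene_set <- function(x, ...) x$provenance
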