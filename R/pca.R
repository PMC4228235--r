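# Characteristic genes of a developmental series: PCA of sample time points
# in gene space; a gene's loading-coefficient magnitude in a component
# measures its contribution to sample variation along that component.

#' Principal components of samples in gene space, with gene loadings
#'
#' Decomposes a column-standardized expression matrix so that each component
#' is a direction in gene space of maximal sample variance. By default each
#' gene is centered across samples first, so the components describe the
#' variation of the sample cloud about its centroid; `center_genes = FALSE`
#' is available for sensitivity analysis with the uncentered decomposition.
#'
#' @param expr Column-standardized expression tibble (features x samples);
#'   see [standardize_samples()]. A warning is issued if columns do not look
#'   standardized.
#' @param n_components Number of leading components to return (default 3).
#' @param center_genes Center each gene across samples before decomposition.
#' @return An object of class `dev_pca`: a list with
#'   \describe{
#'     \item{loadings}{tibble `(gene_id, pc, loading, rank)`, rank 1 = largest
#'       loading magnitude within its component, ties broken by gene id;}
#'     \item{scores}{tibble `(sample_id, pc, score)`;}
#'     \item{explained_variance}{tibble `(pc, variance, proportion)` over the
#'       retained components, proportions relative to total variance;}
#'     \item{n_genes, n_samples, center_genes}{decomposition metadata.}
#'   }
#' @export
pca_loadings <- function(expr, n_components = 3, center_genes = TRUE) {
  m <- expr_matrix(expr)
  if (any(!is.finite(m))) abort("expression values must be finite")
  cm <- colMeans(m); cv <- apply(m, 2, var)
  if (max(abs(cm)) > 1e-6 || max(abs(cv - 1)) > 1e-6) {
    warn("columns do not appear standardized (mean 0, variance 1); see standardize_samples()")
  }
  x <- if (center_genes) m - rowMeans(m) else m
  max_rank <- min(nrow(x), ncol(x) - if (center_genes) 1L else 0L)
  if (n_components < 1 || n_components > max_rank) {
    abort(sprintf("n_components must be in 1..%d for this matrix", max_rank))
  }
  sv <- svd(x)
  pos <- sv$d > max(sv$d[1] * 1e-12, 0)
  if (n_components > sum(pos)) {
    abort(sprintf("matrix rank is %d, cannot extract %d components", sum(pos), n_components))
  }
  d <- sv$d[seq_len(n_components)]
  u <- sv$u[, seq_len(n_components), drop = FALSE]
  v <- sv$v[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|loading| gene positive in each component
  for (j in seq_len(n_components)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  loadings <- tidyr::expand_grid(pc = seq_len(n_components), gene_id = rownames(m)) |>
    dplyr::arrange(.data$pc) |>
    dplyr::mutate(loading = as.numeric(u[cbind(
      match(.data$gene_id, rownames(m)), .data$pc)])) |>
    dplyr::select("gene_id", "pc", "loading")
  scores <- tidyr::expand_grid(pc = seq_len(n_components), sample_id = colnames(m)) |>
    dplyr::mutate(score = as.numeric(t(v * rep(d, each = nrow(v)))[cbind(
      .data$pc, match(.data$sample_id, colnames(m)))])) |>
    dplyr::select("sample_id", "pc", "score")
  total_var <- sum(sv$d^2)
  ev <- tibble::tibble(
    pc = seq_len(n_components),
    variance = d^2,
    proportion = d^2 / total_var
  )
  structure(
    list(
      loadings = rank_loadings(loadings),
      scores = scores,
      explained_variance = ev,
      n_genes = nrow(m), n_samples = ncol(m), center_genes = center_genes
    ),
    class = "dev_pca"
  )
}

#' Rank genes by loading magnitude within each component
#'
#' Within each component, rank 1 is assigned to the largest absolute loading;
#' ties are broken by gene id so ranking is deterministic.
#'
#' @param loadings Tibble `(gene_id, pc, loading)`.
#' @return The same tibble with a `rank` column; within each `pc` the ranks
#'   are a permutation of `1..n_genes`.
#' @export
rank_loadings <- function(loadings) {
  loadings |>
    dplyr::group_by(.data$pc) |>
    dplyr::arrange(dplyr::desc(abs(.data$loading)), .data$gene_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$pc, .data$rank)
}

#' Characteristic gene set from loading ranks
#'
#' The characteristic genes of a component are the top `top_fraction`
#' (default 5%) of genes by loading magnitude; a gene characteristic in any
#' of the requested components belongs to the characteristic set of the
#' dataset. The per-component count is `round(top_fraction * n_genes)`
#' (half-up).
#'
#' @param x A `dev_pca` object or a ranked loading tibble
#'   (see [rank_loadings()]).
#' @param top_fraction Fraction of genes kept per component, in (0, 1).
#' @param pcs Integer vector of components to use (default `1:3`).
#' @return An object of class `char_gene_set`: list with `gene_ids` (the
#'   union, sorted), `per_pc` (named list of per-component subsets),
#'   `top_fraction`, `n_genes`, `n_per_pc`.
#' @export
characteristic_genes <- function(x, top_fraction = 0.05, pcs = 1:3) {
  lt <- if (inherits(x, "dev_pca")) x$loadings else x
  if (!all(c("gene_id", "pc", "loading", "rank") %in% names(lt))) {
    abort("input must be a dev_pca object or a ranked loading tibble")
  }
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1) {
    abort("top_fraction must lie strictly between 0 and 1")
  }
  missing_pcs <- setdiff(pcs, unique(lt$pc))
  if (length(missing_pcs)) {
    abort(sprintf("component %d not present in the loading table", missing_pcs[1]))
  }
  n_genes <- length(unique(lt$gene_id))
  n_top <- round_half_up(top_fraction * n_genes)
  per_pc <- lapply(pcs, function(k) {
    sub <- lt[lt$pc == k & lt$rank <= n_top, ]
    sort(sub$gene_id)
  })
  names(per_pc) <- paste0("PC", pcs)
  structure(
    list(
      gene_ids = sort(unique(unlist(per_pc))),
      per_pc = per_pc,
      top_fraction = top_fraction,
      n_genes = n_genes,
      n_per_pc = n_top
    ),
    class = "char_gene_set"
  )
}

#' @export
print.char_gene_set <- function(x, ...) {
  cat(sprintf(
    "Characteristic gene set: %d genes (top %.1f%% of %d per component; %s)\n",
    length(x$gene_ids), 100 * x$top_fraction, x$n_genes,
    paste(names(x$per_pc), collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.dev_pca <- function(x, ...) {
  cat(sprintf(
    "PCA of %d samples in %d-gene space (%d components)\n",
    x$n_samples, x$n_genes, nrow(x$explained_variance)
  ))
  print(x$explained_variance)
  invisible(x)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
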