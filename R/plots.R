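# ggplot2 methods for result objects

#' Scree and score plots for a gene-space PCA
#'
#' @param object A `dev_pca` object.
#' @param meta Optional metadata tibble with `sample_id` and `age_days`;
#'   when supplied, component scores are drawn against age, otherwise a
#'   scree plot of explained-variance fractions is drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dev_pca
#' @export
autoplot.dev_pca <- function(object, meta = NULL, ...) {
  if (is.null(meta)) {
    return(
      ggplot2::ggplot(object$explained_variance,
                      ggplot2::aes(x = factor(.data$pc), y = .data$proportion)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "principal component",
                      y = "fraction of sample variance explained") +
        ggplot2::theme_minimal()
    )
  }
  df <- dplyr::left_join(object$scores, meta, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_days, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate_id),
                       alpha = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~pc, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "age (days)", y = "component score") +
    ggplot2::theme_minimal()
}

#' Odds-ratio plot for enrichment results
#'
#' Draws the sample odds ratio with its confidence interval on a log scale;
#' accepts a single result or a named list of results.
#'
#' @param object An `enrich_result` or a list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrich_result
#' @export
autoplot.enrich_result <- function(object, ...) {
  results <- if (inherits(object, "enrich_result")) list(result = object) else object
  df <- purrr::imap(results, function(r, nm) {
    dplyr::mutate(tidy(r), analysis = nm)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or_sample, y = .data$analysis)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a paired differential-expression table
#'
#' @param de Output of [differential_table()].
#' @param alpha Significance threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_differential <- function(de, alpha = 0.05) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = base::c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (A - B)", y = "-log10 p") +
    ggplot2::theme_minimal()
}
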