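# Paired two-condition differential expression: Wilcoxon signed-rank test on
# within-pair differences plus log2 fold change (values already on log2
# scale, so a difference of means IS the log2 fold change).

#' Build a paired design from sample metadata
#'
#' @param meta Metadata tibble with `sample_id`, `group`, `pair_id`; each
#'   pair id must occur exactly twice with distinct group labels.
#' @param condition_a,condition_b Group labels defining the A and B arms of
#'   the comparison (fold changes are A minus B). Default: the two group
#'   labels in sort order.
#' @return Tibble `(pair_id, sample_a, sample_b)` with attributes
#'   `condition_a`, `condition_b`.
#' @export
paired_design <- function(meta, condition_a = NULL, condition_b = NULL) {
  need <- c("sample_id", "group", "pair_id")
  if (!all(need %in% names(meta))) abort("metadata needs sample_id, group, pair_id")
  meta <- meta[!is.na(meta$pair_id), ]
  groups <- sort(unique(meta$group))
  if (length(groups) != 2) abort(sprintf("paired design needs exactly 2 groups, found %d", length(groups)))
  condition_a <- condition_a %||% groups[1]
  condition_b <- condition_b %||% groups[2]
  if (!all(c(condition_a, condition_b) %in% groups)) abort("condition labels not present in metadata")
  counts <- table(meta$pair_id)
  if (any(counts != 2)) {
    abort(sprintf("pair_id '%s' occurs %d time(s); must be exactly 2", names(counts)[counts != 2][1],
                  counts[counts != 2][1]))
  }
  wide <- meta |>
    dplyr::select("sample_id", "group", "pair_id") |>
    tidyr::pivot_wider(names_from = "group", values_from = "sample_id")
  if (anyNA(wide[[condition_a]]) || anyNA(wide[[condition_b]])) {
    abort("each pair must contain one sample of each group")
  }
  out <- tibble::tibble(
    pair_id = wide$pair_id,
    sample_a = wide[[condition_a]],
    sample_b = wide[[condition_b]]
  )
  attr(out, "condition_a") <- condition_a
  attr(out, "condition_b") <- condition_b
  out
}

#' Log2 fold change between the two arms of a paired design
#'
#' The expression values are log2-scale, so the fold change of a feature in A
#' relative to B is the arithmetic average over the A samples minus the
#' arithmetic average over the B samples.
#'
#' @param expr Expression tibble.
#' @param design Paired design from [paired_design()].
#' @return Tibble `(feature_id, log2fc)`.
#' @export
log2_fold_change <- function(expr, design) {
  m <- expr_matrix(expr)
  check_design(m, design)
  if (nrow(design) == 0) abort("empty design")
  fc <- rowMeans(m[, design$sample_a, drop = FALSE]) -
    rowMeans(m[, design$sample_b, drop = FALSE])
  tibble::tibble(feature_id = rownames(m), log2fc = as.numeric(fc))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Computes the signed-rank statistic W (sum of the ranks of the positive
#' differences after ranking the absolute differences with midranks for ties)
#' and a two-sided p-value. Zero differences are discarded before ranking by
#' default (`zero_handling = "drop"`); the number retained is reported.
#' The p-value is exact (from the signed-rank null distribution) when the
#' retained sample size is at most `exact_threshold` and there are no tied
#' magnitudes; otherwise a normal approximation with tie-corrected variance
#' and a 0.5 continuity correction is used. The mode used is recorded in the
#' result so outputs are self-describing.
#'
#' @param diffs Numeric vector of within-pair differences (A minus B).
#' @param zero_handling `"drop"` (discard zero differences, the classical
#'   convention) or `"keep"` (retain them in the ranking, drop their rank
#'   contribution from W, and always use the normal approximation).
#' @param exact_threshold Largest tie-free sample size for which the exact
#'   null distribution is used (default 25).
#' @return List with `statistic` (W), `p`, `n_used`, `exact` (logical), and
#'   `degenerate` (`TRUE` when every difference is zero; then `p = 1`).
#' @export
wilcoxon_signed_rank <- function(diffs, zero_handling = c("drop", "keep"),
                                 exact_threshold = 25) {
  zero_handling <- match.arg(zero_handling)
  if (length(diffs) < 1) abort("need at least one difference")
  if (any(!is.finite(diffs))) abort("differences must be finite")
  nz <- diffs != 0
  if (!any(nz)) {
    return(list(statistic = 0, p = 1, n_used = 0L, exact = FALSE, degenerate = TRUE))
  }
  if (zero_handling == "drop") {
    d <- diffs[nz]
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    n <- length(d)
    ties <- table(r)
    has_ties <- any(ties > 1)
    if (n <= exact_threshold && !has_ties) {
      p_lo <- psignrank(w, n)            # P(W <= w)
      p_hi <- psignrank(w - 1, n, lower.tail = FALSE)  # P(W >= w)
      p <- min(1, 2 * min(p_lo, p_hi))
      return(list(statistic = w, p = p, n_used = n, exact = TRUE, degenerate = FALSE))
    }
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  } else {
    # Pratt: zeros ranked with the rest, their ranks removed from both tails
    r <- rank(abs(diffs))
    w <- sum(r[diffs > 0])
    n <- sum(nz)
    n0 <- sum(!nz)
    ties <- table(r[nz])
    N <- length(diffs)
    mu <- (N * (N + 1) - n0 * (n0 + 1)) / 4
    sigma2 <- (N * (N + 1) * (2 * N + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
  }
  if (sigma2 <= 0) {
    return(list(statistic = w, p = 1, n_used = as.integer(n), exact = FALSE, degenerate = TRUE))
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = w, p = max(p, .Machine$double.xmin), n_used = as.integer(n),
       exact = FALSE, degenerate = FALSE)
}

#' Per-feature paired differential expression table
#'
#' Runs [wilcoxon_signed_rank()] on each feature's within-pair differences
#' and attaches the log2 fold change. Significance is raw `p < alpha`
#' (strict); no multiplicity adjustment enters the significance call, but a
#' Benjamini-Hochberg column `p_bh` is reported for context.
#'
#' @param expr Expression tibble.
#' @param design Paired design from [paired_design()].
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @inheritParams wilcoxon_signed_rank
#' @return Tibble `(feature_id, n_pairs_used, statistic, p, p_bh, log2fc,
#'   significant)`, one row per feature in input order, with attribute
#'   `methods` recording the conventions used.
#' @export
differential_table <- function(expr, design, alpha = 0.05,
                               zero_handling = "drop", exact_threshold = 25) {
  m <- expr_matrix(expr)
  check_design(m, design)
  d <- m[, design$sample_a, drop = FALSE] - m[, design$sample_b, drop = FALSE]
  res <- apply(d, 1, wilcoxon_signed_rank,
               zero_handling = zero_handling, exact_threshold = exact_threshold)
  fc <- log2_fold_change(expr, design)
  pvals <- unname(vapply(res, `[[`, numeric(1), "p"))
  out <- tibble::tibble(
    feature_id = rownames(m),
    n_pairs_used = unname(vapply(res, `[[`, integer(1), "n_used")),
    statistic = unname(vapply(res, `[[`, numeric(1), "statistic")),
    p = pvals,
    p_bh = p.adjust(pvals, method = "BH"),
    log2fc = fc$log2fc
  ) |>
    dplyr::mutate(significant = .data$p < alpha)
  attr(out, "methods") <- list(
    test = "wilcoxon_signed_rank", alpha = alpha, strict = TRUE,
    zero_handling = zero_handling, exact_threshold = exact_threshold,
    tie_break = "lexicographic probe_id (collapse)",
    adjustment = "none (BH reported for context only)"
  )
  out
}

#' Significant feature set of a differential table
#' @param de Output of [differential_table()].
#' @return Character vector of significant feature ids.
#' @export
significant_features <- function(de) {
  if (!all(c("feature_id", "significant") %in% names(de))) {
    abort("input must be a differential_table() result")
  }
  de$feature_id[de$significant]
}

check_design <- function(m, design) {
  if (!all(c("sample_a", "sample_b") %in% names(design))) {
    abort("design needs sample_a and sample_b columns (see paired_design())")
  }
  samples <- c(design$sample_a, design$sample_b)
  if (anyDuplicated(samples)) abort("a sample appears in more than one pair")
  missing <- setdiff(samples, colnames(m))
  if (length(missing)) abort(sprintf("design sample '%s' absent from the expression table", missing[1]))
  invisible(TRUE)
}
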