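# fixtures and independent oracles used across the suite

make_expr <- function(m, feature_ids = NULL, sample_ids = NULL) {
  if (is.null(feature_ids)) feature_ids <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(ncol(m)))
  rownames(m) <- feature_ids
  colnames(m) <- sample_ids
  dplyr::bind_cols(
    tibble::tibble(feature_id = feature_ids),
    tibble::as_tibble(as.data.frame(m))
  )
}

expr_to_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$feature_id
  m
}

# metadata for a duplicated time series over `ages`
series_meta <- function(ages, reps = c("r1", "r2")) {
  tibble::tibble(
    sample_id = as.vector(vapply(reps, function(r) paste0(r, "_", seq_along(ages)), character(length(ages)))),
    age_days = rep(ages, times = length(reps)),
    replicate_id = rep(reps, each = length(ages)),
    group = NA_character_,
    pair_id = NA_character_
  )
}

# duplicated-series expression table from two feature x time matrices
series_expr <- function(x1, x2, feature_ids = NULL) {
  stopifnot(all(dim(x1) == dim(x2)))
  meta <- series_meta(seq_len(ncol(x1)))
  m <- cbind(x1, x2)
  colnames(m) <- meta$sample_id
  list(expr = make_expr(m, feature_ids, meta$sample_id), meta = meta)
}

# brute-force Pearson correlation from the covariance/variance definition
pearson_direct <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / sqrt(var(x) * var(y))
}

# exhaustive 2^n sign-flip null of the signed-rank statistic; two-sided p of
# the observed configuration
wilcoxon_enum_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# direct-summation Fisher two-sided p over the conditional support, with
# probabilities from lchoose (independent of dhyper)
fisher_enum_p <- function(a, b, c, d, rel_err = 1 + 1e-7) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  lp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(lp)
  p_obs <- p[a - lo + 1]
  sum(p[p <= p_obs * rel_err])
}

# noncentral hypergeometric tail by direct summation (independent path used
# to audit confidence bounds)
nchg_tail_direct <- function(psi, a, m, n, k, upper = TRUE) {
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  lw <- lchoose(m, x) + lchoose(n, k - x) + x * log(psi)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  if (upper) sum(w[x >= a]) else sum(w[x <= a])
}

random_table <- function(max_cell = 40) {
  contingency_table(
    sample.int(max_cell, 1), sample.int(max_cell, 1),
    sample.int(max_cell, 1), sample.int(max_cell, 1)
  )
}
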