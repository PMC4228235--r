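# Seeded simulators producing inputs with the statistical structure the
# pipeline assumes: (i) duplicated developmental time series whose dominant
# sample-variation axes are driven by a planted minority of genes, and
# (ii) paired two-condition cohorts with a planted fraction of differentially
# expressed genes. All values are log2 scale with additive Gaussian noise
# (the conventional error model for log-transformed array intensities).

# default age grid: a C57BL6-style whole-organ series, E9.5..P56 expressed on
# one monotone axis in days (prenatal = days post conception; postnatal =
# gestation length 19.5 d + postnatal day)
dev_default_timepoints <- function() {
  base::c(9.5, 12.5, 14.5, 16.5, 18.5,
          19.5 + base::c(0, 2, 4, 7, 11, 13, 18, 24, 30, 56))
}

#' Simulate a duplicated developmental expression time series
#'
#' Background genes are a gene-specific baseline plus Gaussian noise; planted
#' ("characteristic") genes additionally carry a temporal program shared
#' across both replicates, with independent noise per replicate:
#' \describe{
#'   \item{monotone}{logistic ramp over age (75% rising, 25% falling, so most
#'     planted genes are higher late in development);}
#'   \item{switch}{smooth stage-switch step at a random interior timepoint
#'     (75% up);}
#'   \item{transient}{Gaussian pulse of random sign centred inside the
#'     series.}
#' }
#' Program midpoints fall in the central 60% of the age window so every
#' program acts within the sampled interval. Identical seeds give identical
#' output.
#'
#' @param n_genes Number of genes (default 2000).
#' @param timepoints Strictly increasing ages in days; default a 15-point
#'   E9.5-P56 mouse-style grid.
#' @param n_characteristic Number of planted genes (default 100, i.e. 5% of
#'   the default `n_genes`, matching the top-5% selection rule).
#' @param program_types Subset of `c("monotone", "switch", "transient")`.
#' @param effect_amp Program amplitude in log2 units (default 1.5).
#' @param noise_sd Additive noise standard deviation in log2 units
#'   (default 0.5).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @param seed Integer seed (mandatory).
#' @return List with `expression` (wide tibble, 2 x `length(timepoints)`
#'   sample columns), `metadata` (`sample_id, age_days, replicate_id, group,
#'   pair_id`), and `truth` (`gene_id, characteristic, program`).
#' @export
simulate_dev_timeseries <- function(n_genes = 2000,
                                    timepoints = dev_default_timepoints(),
                                    n_characteristic = 100,
                                    program_types = base::c("monotone", "switch", "transient"),
                                    effect_amp = 1.5,
                                    noise_sd = 0.5,
                                    baseline_mean = 7,
                                    baseline_sd = 1,
                                    seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_characteristic >= n_genes) abort("n_characteristic must be below n_genes")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (is.unsorted(timepoints, strictly = TRUE)) abort("timepoints must be strictly increasing")
  program_types <- match.arg(program_types, several.ok = TRUE)
  withr::with_seed(seed, {
    tp <- timepoints
    n_t <- length(tp)
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    planted <- sort(sample.int(n_genes, n_characteristic))
    program <- rep(NA_character_, n_genes)
    program[planted] <- sample(program_types, n_characteristic, replace = TRUE)

    range_t <- range(tp)
    span_t <- diff(range_t)
    mid_lo <- range_t[1] + 0.2 * span_t
    mid_hi <- range_t[2] - 0.2 * span_t

    signal <- matrix(0, n_genes, n_t)
    for (i in planted) {
      t0 <- runif(1, mid_lo, mid_hi)
      shape <- switch(program[i],
        monotone = {
          tau <- span_t / 8
          s <- if (runif(1) < 0.75) 1 else -1
          s / (1 + exp(-(tp - t0) / tau))
        },
        switch = {
          tau <- span_t / 40   # sharp but smooth stage switch
          s <- if (runif(1) < 0.75) 1 else -1
          s / (1 + exp(-(tp - t0) / tau))
        },
        transient = {
          w <- span_t / 6
          s <- if (runif(1) < 0.5) 1 else -1
          s * exp(-(tp - t0)^2 / (2 * w^2))
        }
      )
      signal[i, ] <- effect_amp * shape
    }
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    make_rep <- function() {
      baseline + signal + matrix(rnorm(n_genes * n_t, 0, noise_sd), n_genes, n_t)
    }
    m <- cbind(make_rep(), make_rep())
    sample_ids <- base::c(sprintf("r1_t%02d", seq_len(n_t)), sprintf("r2_t%02d", seq_len(n_t)))
    colnames(m) <- sample_ids
    rownames(m) <- gene_ids
    list(
      expression = as_expression(m),
      metadata = tibble::tibble(
        sample_id = sample_ids,
        age_days = rep(tp, 2),
        replicate_id = rep(base::c("r1", "r2"), each = n_t),
        group = NA_character_,
        pair_id = NA_character_
      ),
      truth = tibble::tibble(
        gene_id = gene_ids,
        characteristic = seq_len(n_genes) %in% planted,
        program = program
      )
    )
  })
}

#' Simulate a paired two-condition cohort
#'
#' Each pair shares a random per-gene baseline shift (`pair_sd`), inducing
#' the within-pair correlation of a matched design; condition A of a planted
#' differentially expressed gene is shifted by `effect_log2` (A higher).
#' Noise is additive Gaussian on the log2 scale; identical seeds give
#' identical output.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_pairs Number of sample pairs (default 95, a sibling-pair-study
#'   scale cohort).
#' @param de_fraction Fraction of genes planted as differentially expressed
#'   (default 0.05, matching the nominal test level).
#' @param effect_log2 Planted log2 effect, condition A minus B (default 1).
#' @param noise_sd Additive noise sd in log2 units (default 0.4).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @param pair_sd Sd of the shared within-pair shift (default 0.5).
#' @param group_labels Length-2 character vector, A then B.
#' @param seed Integer seed (mandatory).
#' @return List with `expression`, `metadata`, `design` (see
#'   [paired_design()]) and `truth` (`gene_id, de`).
#' @export
simulate_paired_cohort <- function(n_genes = 2000, n_pairs = 95,
                                   de_fraction = 0.05, effect_log2 = 1.0,
                                   noise_sd = 0.4, baseline_mean = 7,
                                   baseline_sd = 1, pair_sd = 0.5,
                                   group_labels = base::c("affected", "unaffected"),
                                   seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (de_fraction <= 0 || de_fraction >= 1) abort("de_fraction must be in (0, 1)")
  n_de <- round_half_up(de_fraction * n_genes)
  if (n_de < 1) abort("de_fraction * n_genes must be at least 1")
  withr::with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    de_idx <- sort(sample.int(n_genes, n_de))
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    pair_shift <- matrix(rnorm(n_genes * n_pairs, 0, pair_sd), n_genes, n_pairs)
    noise_a <- matrix(rnorm(n_genes * n_pairs, 0, noise_sd), n_genes, n_pairs)
    noise_b <- matrix(rnorm(n_genes * n_pairs, 0, noise_sd), n_genes, n_pairs)
    effect <- numeric(n_genes)
    effect[de_idx] <- effect_log2
    ma <- baseline + pair_shift + effect + noise_a
    mb <- baseline + pair_shift + noise_b
    ids_a <- sprintf("p%03d_a", seq_len(n_pairs))
    ids_b <- sprintf("p%03d_b", seq_len(n_pairs))
    m <- cbind(ma, mb)
    colnames(m) <- base::c(ids_a, ids_b)
    rownames(m) <- gene_ids
    meta <- tibble::tibble(
      sample_id = base::c(ids_a, ids_b),
      age_days = NA_real_,
      replicate_id = NA_character_,
      group = rep(group_labels, each = n_pairs),
      pair_id = rep(sprintf("p%03d", seq_len(n_pairs)), 2)
    )
    design <- paired_design(meta, condition_a = group_labels[1],
                            condition_b = group_labels[2])
    list(
      expression = as_expression(m),
      metadata = meta,
      design = design,
      truth = tibble::tibble(gene_id = gene_ids, de = seq_len(n_genes) %in% de_idx)
    )
  })
}

#' Simulate a probe-to-gene map and probe-level expansion
#'
#' `simulate_probe_map()` assigns each gene 1 to `max_probes_per_gene`
#' probes; one designated "good" probe per gene carries low measurement
#' noise (`good_sd`), the rest are noisier (`bad_sd`), so replicate-
#' correlation collapse has a well-defined best probe.
#' `expand_probe_matrix()` turns a gene-level matrix into a probe-level one
#' by adding independent per-probe noise at each probe's sd.
#'
#' @param gene_ids Character vector of gene ids.
#' @param max_probes_per_gene Maximum probes per gene (>= 1).
#' @param good_sd,bad_sd Per-observation measurement noise of the designated
#'   best probe and of the remaining probes.
#' @param seed Integer seed (mandatory).
#' @return Tibble `(probe_id, gene_id, probe_sd, is_best)`.
#' @export
simulate_probe_map <- function(gene_ids, max_probes_per_gene = 3,
                               good_sd = 0.1, bad_sd = 0.6, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (max_probes_per_gene < 1) abort("max_probes_per_gene must be >= 1")
  withr::with_seed(seed, {
    n_probes <- sample.int(max_probes_per_gene, length(gene_ids), replace = TRUE)
    map <- tibble::tibble(
      gene_id = rep(gene_ids, n_probes),
      probe_index = unlist(lapply(n_probes, seq_len))
    ) |>
      dplyr::mutate(probe_id = sprintf("%s_p%d", .data$gene_id, .data$probe_index))
    best <- vapply(split(seq_len(nrow(map)), map$gene_id)[unique(map$gene_id)],
                   function(i) i[sample.int(length(i), 1)], integer(1))
    map$is_best <- seq_len(nrow(map)) %in% best
    map$probe_sd <- ifelse(map$is_best, good_sd, bad_sd)
    map[, base::c("probe_id", "gene_id", "probe_sd", "is_best")]
  })
}

#' @rdname simulate_probe_map
#' @param expr Gene-level expression tibble.
#' @param probe_map Output of [simulate_probe_map()].
#' @export
expand_probe_matrix <- function(expr, probe_map, seed) {
  if (missing(seed)) abort("seed is mandatory")
  m <- expr_matrix(expr)
  missing_genes <- setdiff(probe_map$gene_id, rownames(m))
  if (length(missing_genes)) abort(sprintf("gene '%s' absent from the matrix", missing_genes[1]))
  withr::with_seed(seed, {
    pm <- m[probe_map$gene_id, , drop = FALSE] +
      matrix(rnorm(nrow(probe_map) * ncol(m), 0, probe_map$probe_sd),
             nrow(probe_map), ncol(m))
    rownames(pm) <- probe_map$probe_id
    as_expression(pm)
  })
}
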