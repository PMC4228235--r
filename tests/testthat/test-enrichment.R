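test_that("supervised and unsupervised lists merge with provenance and intersection", {
  # the ten genes found by both approaches in the vitamin-D set assembly
  both <- c("CAMP", "CD274", "CYP19A1", "CYP24A1", "DHCR7",
            "LGMN", "MED13", "NFKBIA", "TNFSF4", "VDR")
  sup <- list(c(both[1:6], "SUP1", "SUP2"), c(both[7:10], "SUP3"))
  uns <- list(c(both, "UNS1", "UNS2"))
  merged <- assemble_union_set(sup, uns, name = "vitD")
  expect_s3_class(merged, "gene_set")
  expect_equal(merged$intersection, sort(both))
  expect_length(merged$intersection, 10L)
  expect_length(merged$genes, 15L)
  prov <- tidy(merged)
  expect_true(all(prov$supervised[prov$gene_id %in% c("SUP1", "SUP3")]))
  expect_false(any(prov$supervised[prov$gene_id %in% c("UNS1", "UNS2")]))

  disjoint <- assemble_union_set(list(c("a", "b")), list(c("c", "d", "e")))
  expect_length(disjoint$genes, 5L)
  expect_length(disjoint$intersection, 0L)
  expect_error(assemble_union_set(list(), list("x")), "required")
})

test_that("random unions equal brute-force set algebra", {
  withr::local_seed(61)
  pool <- sprintf("gene%03d", 1:200)
  for (i in 1:10) {
    sup <- lapply(1:2, function(j) sample(pool, sample(5:40, 1)))
    uns <- lapply(1:2, function(j) sample(pool, sample(5:40, 1)))
    merged <- assemble_union_set(sup, uns)
    expect_setequal(merged$genes, union(unlist(sup), unlist(uns)))
    expect_setequal(merged$intersection, intersect(unlist(sup), unlist(uns)))
  }
})

test_that("contingency construction matches direct membership counting", {
  t1 <- build_contingency("g1", "g1", c("g1", "g2"))
  expect_equal(unclass(t1)[c("a", "b", "c", "d")],
               list(a = 1L, b = 0L, c = 0L, d = 1L))

  # the sibling-pair analysis counts reconstructed from printed sizes
  u <- sprintf("u%05d", 1:20188)
  set_a <- u[1:38]
  set_b <- u[c(1:12, 39:(39 + 2684))]
  t2 <- build_contingency(set_a, set_b, u)
  expect_equal(unlist(unclass(t2)), c(a = 12L, b = 26L, c = 2685L, d = 17465L))

  withr::local_seed(62)
  for (i in 1:10) {
    universe <- sprintf("x%03d", 1:150)
    A <- sample(universe, 30); B <- sample(universe, 50)
    t <- build_contingency(A, B, universe)
    expect_equal(t$a, sum(A %in% B))
    expect_equal(t$b, sum(!A %in% B))
    expect_equal(t$c, sum(!B %in% A))
    expect_equal(t$a + t$b + t$c + t$d, 150L)
  }
  expect_message(build_contingency(c("x001", "alien"), "x002",
                                   sprintf("x%03d", 1:150)), "1 set-A")
  expect_error(build_contingency("a", "b", character(0)), "empty")
})

test_that("the two-sided Fisher p follows the point-probability rule", {
  expect_equal(fisher_exact_p(contingency_table(1, 1, 1, 1)), 1)
  withr::local_seed(63)
  for (i in 1:25) {
    t <- random_table()
    p <- fisher_exact_p(t)
    expect_equal(p, fisher_enum_p(t$a, t$b, t$c, t$d), tolerance = 1e-12)
    # transpose symmetry
    expect_equal(fisher_exact_p(contingency_table(t$a, t$c, t$b, t$d)), p,
                 tolerance = 1e-12)
    # independent reference implementation
    expect_equal(p, fisher.test(matrix(c(t$a, t$b, t$c, t$d), 2, 2,
                                       byrow = TRUE))$p.value, tolerance = 1e-9)
    expect_true(p > 0 && p <= 1)
    pd <- fisher_exact_p(t, method = "doubled")
    expect_true(pd > 0 && pd <= 1)
  }
})

test_that("sample odds ratios reproduce the printed study estimates", {
  expect_equal(round(odds_ratio_sample(contingency_table(12, 26, 2685, 17465)), 2), 3.00)
  expect_equal(round(odds_ratio_sample(contingency_table(11, 27, 3357, 21565)), 2), 2.62)
  # proportional table: independence
  expect_equal(odds_ratio_sample(contingency_table(10, 30, 20, 60)), 1)
  expect_identical(odds_ratio_sample(contingency_table(3, 0, 5, 7)), Inf)
  expect_identical(odds_ratio_sample(contingency_table(0, 4, 5, 7)), 0)
})

test_that("the conditional MLE matches the reference implementation", {
  withr::local_seed(64)
  for (i in 1:15) {
    t <- random_table()
    ft <- fisher.test(matrix(c(t$a, t$b, t$c, t$d), 2, 2, byrow = TRUE))
    # fisher.test itself solves the CMLE only to ~ 1e-4 relative precision
    expect_equal(odds_ratio_cmle(t), unname(ft$estimate), tolerance = 1e-3)
  }
  expect_identical(odds_ratio_cmle(contingency_table(0, 5, 3, 7)), 0)
  expect_identical(odds_ratio_cmle(contingency_table(4, 0, 3, 7)), Inf)
})

test_that("exact tail-inversion intervals match the reference and hit 0.025 tails", {
  withr::local_seed(65)
  for (i in 1:12) {
    t <- random_table()
    ci <- odds_ratio_ci(t, method = "exact")
    ft <- fisher.test(matrix(c(t$a, t$b, t$c, t$d), 2, 2, byrow = TRUE))
    expect_equal(unname(ci), ft$conf.int[1:2], tolerance = 1e-4)
  }
  # small-margin tables: direct tail summation at the bounds equals alpha/2
  for (cells in list(c(5, 3, 2, 9), c(8, 2, 4, 11), c(3, 7, 6, 4), c(12, 26, 40, 80))) {
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    ci <- odds_ratio_ci(t, method = "exact", tol = 1e-10)
    m <- t$a + t$b; n <- t$c + t$d; k <- t$a + t$c
    expect_equal(nchg_tail_direct(ci[["lower"]], t$a, m, n, k, upper = TRUE),
                 0.025, tolerance = 1e-6)
    expect_equal(nchg_tail_direct(ci[["upper"]], t$a, m, n, k, upper = FALSE),
                 0.025, tolerance = 1e-6)
  }
})

test_that("interval bounds bracket the CMLE and nest across confidence levels", {
  withr::local_seed(66)
  for (i in 1:8) {
    t <- random_table()
    est <- odds_ratio_cmle(t)
    for (method in c("exact", "cornfield")) {
      ci90 <- odds_ratio_ci(t, 0.90, method)
      ci95 <- odds_ratio_ci(t, 0.95, method)
      ci99 <- odds_ratio_ci(t, 0.99, method)
      expect_true(ci95[["lower"]] <= est && est <= ci95[["upper"]])
      expect_true(ci90[["lower"]] >= ci95[["lower"]] && ci95[["lower"]] >= ci99[["lower"]])
      expect_true(ci90[["upper"]] <= ci95[["upper"]] && ci95[["upper"]] <= ci99[["upper"]])
    }
  }
})

test_that("boundary cells push interval ends to 0 or infinity", {
  for (method in c("exact", "cornfield")) {
    lo0 <- odds_ratio_ci(contingency_table(0, 5, 3, 9), method = method)
    expect_identical(lo0[["lower"]], 0)
    expect_true(is.finite(lo0[["upper"]]))
    hiInf <- odds_ratio_ci(contingency_table(5, 0, 3, 9), method = method)
    expect_identical(hiInf[["upper"]], Inf)
    expect_true(hiInf[["lower"]] > 0)
  }
})

test_that("enrichment composes the pieces and is label-order invariant", {
  withr::local_seed(67)
  universe <- sprintf("g%03d", 1:300)
  A <- sample(universe, 40); B <- sample(universe, 60)
  r_ab <- enrich(A, B, universe)
  r_ba <- enrich(B, A, universe)
  expect_equal(r_ab$p, r_ba$p, tolerance = 1e-12)
  expect_equal(r_ab$or_sample, r_ba$or_sample, tolerance = 1e-12)
  expect_equal(r_ab$ci, r_ba$ci, tolerance = 1e-8)
  expect_equal(r_ab$table$a, sum(A %in% B))

  td <- tidy(r_ab)
  expect_equal(td$a + td$b + td$c + td$d, 300L)
  expect_equal(td$universe_size, 300L)

  # A = B: maximal association, p at the minimum of the support
  r_same <- enrich(A, A, universe)
  expect_identical(r_same$or_sample, Inf)
  m <- r_same$table$a + r_same$table$b
  k <- r_same$table$a + r_same$table$c
  expect_equal(r_same$p, dhyper(r_same$table$a, m, 300 - m, k), tolerance = 1e-12)
})

test_that("null overlaps keep the false-positive rate at or below nominal", {
  withr::local_seed(68)
  n_rep <- 400
  universe <- sprintf("g%03d", 1:200)
  pvals <- replicate(n_rep, {
    A <- sample(universe, 25); B <- sample(universe, 40)
    fisher_exact_p(build_contingency(A, B, universe))
  })
  rate <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(rate, 0.05 + 3 * se)
  expect_gt(median(pvals), 0.2)  # bulk of the null is unextreme
})

test_that("enrichment from printed counts validates its inputs", {
  expect_error(enrich_from_counts(40, 38, 2697, 20188), "overlap")
  expect_error(enrich_from_counts(0, 12000, 12000, 20188), "universe")
  r <- enrich_from_counts(12, 38, 2697, 20188)
  expect_equal(unlist(unclass(r$table)), c(a = 12L, b = 26L, c = 2685L, d = 17465L))
  js <- withr::local_tempfile(fileext = ".json")
  write_enrich_json(r, js)
  rec <- jsonlite::read_json(js)
  expect_equal(rec$cells$a, 12L)
  expect_equal(rec$ci$level, 0.95)
  expect_equal(rec$or_sample, r$or_sample, tolerance = 1e-12)
})
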