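# standardized matrix fixture with known structure: helper standardizes the
# random matrix so pca_loadings sees its expected input
std_expr <- function(m, ...) standardize_samples(make_expr(m, ...))

test_that("a single varying gene dominates the first component", {
  withr::local_seed(1)
  m <- matrix(rnorm(80, sd = 0.01), 10, 8)
  m[4, ] <- seq(-4, 4, length.out = 8)  # the only strong axis of variation
  pca <- pca_loadings(std_expr(m), n_components = 2)
  pc1 <- dplyr::filter(pca$loadings, pc == 1)
  expect_equal(pc1$gene_id[pc1$rank == 1], "g004")
})

test_that("loading ranks are sign-invariant and match a full sort oracle", {
  withr::local_seed(2)
  lt <- tidyr::expand_grid(pc = 1:3, gene_id = sprintf("g%03d", 1:40)) |>
    dplyr::mutate(loading = rnorm(120))
  ranked <- rank_loadings(lt)
  flipped <- rank_loadings(dplyr::mutate(lt, loading = -loading))
  expect_equal(
    dplyr::arrange(ranked, pc, gene_id)$rank,
    dplyr::arrange(flipped, pc, gene_id)$rank
  )
  for (k in 1:3) {
    sub <- dplyr::filter(ranked, pc == k)
    o <- order(-abs(sub$loading), sub$gene_id)
    expect_equal(sub$rank[o], 1:40)
    expect_setequal(sub$rank, 1:40)
  }
})

test_that("tied loading magnitudes rank in gene-id order", {
  lt <- tibble::tibble(gene_id = c("gB", "gA", "gC"), pc = 1,
                       loading = c(0.5, -0.5, 0.1))
  ranked <- rank_loadings(lt)
  expect_equal(ranked$gene_id[ranked$rank == 1], "gA")
  expect_equal(ranked$gene_id[ranked$rank == 2], "gB")
})

test_that("the decomposition matches an independent eigendecomposition and reconstructs", {
  withr::local_seed(3)
  m <- matrix(rnorm(1600), 200, 8)
  expr <- std_expr(m)
  x <- expr_to_matrix(expr)
  xc <- x - rowMeans(x)
  pca <- pca_loadings(expr, n_components = 7)

  # reconstruction from all components reproduces the centered matrix
  sv <- svd(xc)
  expect_equal(sv$u %*% diag(sv$d) %*% t(sv$v), xc, tolerance = 1e-8,
               ignore_attr = TRUE)

  # loadings match the eigenvectors of the gene-space covariance up to sign
  eig <- eigen(xc %*% t(xc), symmetric = TRUE)
  u <- matrix(pca$loadings$loading[order(pca$loadings$pc,
                                         match(pca$loadings$gene_id, rownames(x)))],
              nrow = 200)
  for (j in 1:7) {
    expect_equal(abs(sum(u[, j] * eig$vectors[, j])), 1, tolerance = 1e-8)
  }
  # explained-variance fractions agree with the eigenvalue spectrum
  expect_equal(pca$explained_variance$proportion,
               (eig$values / sum(pmax(eig$values, 0)))[1:7], tolerance = 1e-8)
})

test_that("per-PC loading vectors are orthonormal and fractions are sane", {
  withr::local_seed(4)
  pca <- pca_loadings(std_expr(matrix(rnorm(300), 50, 6)), n_components = 3)
  u <- matrix(pca$loadings$loading[order(pca$loadings$pc, pca$loadings$gene_id)],
              nrow = 50)
  g <- crossprod(u)
  expect_equal(diag(g), rep(1, 3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  ev <- pca$explained_variance$proportion
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(ev >= 0 & ev <= 1) && sum(ev) <= 1 + 1e-12)
})

test_that("results are invariant to sample order and component sign", {
  withr::local_seed(5)
  m <- matrix(rnorm(240), 40, 6)
  expr <- std_expr(m)
  pca <- pca_loadings(expr, n_components = 3)
  perm <- c(4, 1, 6, 2, 5, 3)
  pca_perm <- pca_loadings(expr[, c(1, perm + 1)], n_components = 3)
  expect_equal(
    characteristic_genes(pca, top_fraction = 0.2)$gene_ids,
    characteristic_genes(pca_perm, top_fraction = 0.2)$gene_ids
  )
  expect_equal(dplyr::arrange(pca$loadings, pc, gene_id)$rank,
               dplyr::arrange(pca_perm$loadings, pc, gene_id)$rank)
})

test_that("requesting more components than the rank fails", {
  withr::local_seed(6)
  expr <- std_expr(matrix(rnorm(50), 10, 5))
  expect_error(pca_loadings(expr, n_components = 5), "1\\.\\.4")
  rank1 <- make_expr(outer(rnorm(10), c(1, 2, 3, 4)))
  expect_error(pca_loadings(standardize_samples(rank1), n_components = 3), "rank")
})

test_that("characteristic set sizes follow the half-up top-fraction rule", {
  withr::local_seed(8)
  lt <- rank_loadings(
    tidyr::expand_grid(pc = 1:3, gene_id = sprintf("g%03d", 1:100)) |>
      dplyr::mutate(loading = rnorm(300))
  )
  cs <- characteristic_genes(lt, top_fraction = 0.05, pcs = 1)
  expect_length(cs$per_pc$PC1, 5L)
  expect_equal(cs$gene_ids, sort(cs$per_pc$PC1))
  # 100 * 0.015 = 1.5 rounds half-up to 2
  expect_length(characteristic_genes(lt, top_fraction = 0.015, pcs = 1)$per_pc$PC1, 2L)
})

test_that("identical per-PC rankings collapse to a union of the per-PC size", {
  one_pc <- tibble::tibble(gene_id = sprintf("g%02d", 1:50), pc = 1,
                           loading = seq(2, 0.1, length.out = 50))
  lt <- dplyr::bind_rows(one_pc, dplyr::mutate(one_pc, pc = 2),
                         dplyr::mutate(one_pc, pc = 3)) |> rank_loadings()
  cs <- characteristic_genes(lt, top_fraction = 0.1, pcs = 1:3)
  expect_length(cs$gene_ids, 5L)
  expect_equal(cs$per_pc$PC1, cs$per_pc$PC3)
})

test_that("growing top_fraction never removes a gene (monotonicity)", {
  withr::local_seed(9)
  lt <- rank_loadings(
    tidyr::expand_grid(pc = 1:3, gene_id = sprintf("g%03d", 1:80)) |>
      dplyr::mutate(loading = rnorm(240))
  )
  fracs <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  sets <- lapply(fracs, function(f) characteristic_genes(lt, f)$gene_ids)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
  expect_error(characteristic_genes(lt, top_fraction = 0), "top_fraction")
  expect_error(characteristic_genes(lt, top_fraction = 1), "top_fraction")
  expect_error(characteristic_genes(lt, pcs = 1:5), "component 4")
})

test_that("tidy and glance expose loadings and the variance spectrum", {
  withr::local_seed(10)
  pca <- pca_loadings(std_expr(matrix(rnorm(200), 40, 5)), n_components = 2)
  expect_named(tidy(pca), c("gene_id", "pc", "loading", "rank"))
  expect_named(glance(pca), c("pc", "variance", "proportion"))
  cs <- characteristic_genes(pca, top_fraction = 0.1, pcs = 1:2)
  td <- tidy(cs)
  expect_setequal(unique(td$gene_id), cs$gene_ids)
  expect_equal(glance(cs)$n_per_pc, 4L)
})
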