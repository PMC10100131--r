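test_that("prepare_xy square-roots, z-scores and rejects degenerate frequency", {
  expr <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  ramp <- seq_len(20)
  out <- prepare_xy(expr, ramp^2)
  expect_equal(out$y, as.numeric(scale(ramp)), tolerance = 1e-12)
  expect_equal(unname(colMeans(out$X)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(out$X, 2, sd)), rep(1, 6), tolerance = 1e-9)
  expect_error(prepare_xy(expr, rep(0.3, 20)), "constant")
  # regions with missing expression are dropped pairwise
  expr_na <- expr
  expr_na[3, 2] <- NA
  out2 <- prepare_xy(expr_na, ramp^2)
  expect_equal(nrow(out2$X), 19)
  expect_equal(out2$regions_kept, setdiff(1:20, 3))
})

test_that("single-response PLS is the normalized cross-covariance with exact algebra", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      R <- sample(15:40, 1)
      G <- sample(5:30, 1)
      X <- scale(matrix(rnorm(R * G), R, G))
      colnames(X) <- paste0("g", seq_len(G))
      y <- as.numeric(scale(rnorm(R)))
      pls <- pls_cross_covariance(X, y)
      cc <- as.numeric(crossprod(X, y)) / (R - 1)
      expect_equal(pls$singular_values[1], sqrt(sum(cc^2)),
                   tolerance = 1e-10)
      expect_equal(abs(as.numeric(pls$gene_loadings[, 1])),
                   abs(cc / sqrt(sum(cc^2))), tolerance = 1e-10)
    }
  })
})

test_that("PLS recovers a planted gene and vanishes on orthogonal responses", {
  withr::with_seed(32, {
    R <- 60
    y <- as.numeric(scale(rnorm(R)))
    noise <- matrix(rnorm(R * 9), R, 9)
    # make the noise genes exactly orthogonal to y
    noise <- noise - y %*% crossprod(y, noise) / sum(y^2)
    X <- scale(cbind(target = y + rnorm(R, sd = 0.05), noise))
    colnames(X) <- c("target", paste0("n", 1:9))
    pls <- pls_cross_covariance(X, y)
    expect_gt(abs(pls$gene_loadings["target", 1]), 0.9)
    expect_equal(pls$singular_values[1],
                 abs(sum(X[, "target"] * y)) / (R - 1), tolerance = 0.05)

    # y orthogonal to every column: all singular values ~ 0
    X0 <- scale(noise)
    colnames(X0) <- paste0("n", 1:9)
    pls0 <- pls_cross_covariance(X0, y)
    expect_lt(max(pls0$singular_values), 1e-10)
  })
  # multi-response: singular values match a dense SVD of the explicit matrix
  withr::with_seed(33, {
    R <- 30
    X <- scale(matrix(rnorm(R * 12), R, 12))
    colnames(X) <- paste0("g", 1:12)
    Y <- scale(matrix(rnorm(R * 3), R, 3))
    pls <- pls_cross_covariance(X, Y)
    Cexp <- matrix(0, 12, 3)
    for (i in 1:12) for (j in 1:3) Cexp[i, j] <- sum(X[, i] * Y[, j]) / (R - 1)
    expect_equal(pls$singular_values, svd(Cexp)$d, tolerance = 1e-10)
    expect_equal(sum(pls$singular_values^2), sum(Cexp^2), tolerance = 1e-9)
    expect_equal(sum(pls$covariance_explained), 1, tolerance = 1e-12)
  })
  expect_error(pls_cross_covariance(matrix(c(NA, rnorm(39)), 10), rnorm(10)),
               "non-finite")
})

test_that("surrogate maps preserve mean, variance and the variogram", {
  w <- shared_world()
  sp <- make_brain_space(c(16, 16, 16), voxel_size = c(3, 3, 3),
                         n_regions = 60, seed = 42)
  fld <- make_occurrence_field(sp, n_foci = 8, autocorr_length = 12, seed = 2)
  y <- sqrt(parcellate(fld$intensity, sp))
  cen <- sp$region_centroids
  nm <- spatial_null_maps(y, cen, n_null = 200, seed = 9)
  expect_equal(unname(colMeans(nm)), rep(mean(y), 200), tolerance = 1e-9)
  expect_equal(unname(apply(nm, 2, var)), rep(var(y), 200),
               tolerance = 1e-9)

  # binned variogram of surrogates tracks the original's (5 bins, 25%)
  D <- as.matrix(dist(cen))
  pr <- which(upper.tri(D))
  dv <- D[pr]
  ii <- row(D)[pr]
  jj <- col(D)[pr]
  use <- dv <= quantile(dv, 0.75)
  brk <- quantile(dv[use], seq(0, 1, length.out = 6))
  brk[1] <- -Inf
  bin <- cut(dv[use], brk, labels = FALSE)
  vg <- function(v) {
    as.numeric(rowsum(0.5 * (v[ii[use]] - v[jj[use]])^2, bin)) /
      tabulate(bin, 5)
  }
  v0 <- vg(y)
  relerr <- apply(abs(apply(nm, 2, vg) - v0) / v0, 1, median)
  expect_true(all(relerr < 0.25))

  # with block permutation the surrogates decorrelate from the original
  nm3 <- spatial_null_maps(y, cen, n_null = 200, seed = 9, block_size = 3)
  expect_lt(median(abs(apply(nm3, 2, cor, y = y, method = "spearman"))), 0.35)
  # pure sign flips stay on the map's orbit and resemble it more
  expect_lt(median(abs(apply(nm, 2, cor, y = y, method = "spearman"))), 0.8)
  expect_error(spatial_null_maps(rep(1, 60), cen, 100), "constant")
  # determinism
  expect_identical(nm, spatial_null_maps(y, cen, n_null = 200, seed = 9))
})

test_that("spin p-values follow the +1-corrected exceedance definition", {
  withr::with_seed(41, {
    R <- 30
    y <- as.numeric(scale(rnorm(R)))
    X <- scale(cbind(y + rnorm(R, sd = 0.01),
                     matrix(rnorm(R * 5), R, 5)))
    colnames(X) <- paste0("g", 1:6)
    pls <- pls_cross_covariance(X, y)
    # weak fabricated nulls: observed exceeds every one
    weak <- matrix(rnorm(R * 100, sd = 0.05), R, 100)
    got <- spin_pvalue(pls, X, weak)
    expect_equal(got$spin_p[1], 1 / 101)
    # y itself included as a null counts as >= (tie handling)
    with_self <- cbind(weak[, 1:99], y)
    got2 <- spin_pvalue(pls, X, with_self)
    expect_gt(got2$spin_p[1], 1 / 101)
    # definition check against the stored null singular values
    expect_equal(got2$spin_p[1],
                 (1 + sum(got2$null_singular_values[1, ] >=
                            pls$singular_values[1])) / 101)
  })
})

test_that("gene ranking is sign-antisymmetric and recovers planted genes", {
  sp <- make_brain_space(c(16, 16, 16), voxel_size = c(3, 3, 3),
                         n_regions = 60, seed = 42)
  fld <- make_occurrence_field(sp, n_foci = 8, autocorr_length = 12, seed = 3)
  freq <- parcellate(fld$intensity, sp)
  expr <- make_expression(sp, freq, n_genes = 400, n_assoc = 20,
                          effect = 0.9, seed = 4)
  pxy <- prepare_xy(expr, freq)
  pls <- pls_cross_covariance(pxy$X, pxy$y)
  rk <- rank_genes(pls)
  expect_equal(nrow(rk), 400)
  expect_true(all(diff(rk$loading) <= 0))

  pls_neg <- pls_cross_covariance(pxy$X, -pxy$y)
  rk_neg <- rank_genes(pls_neg)
  expect_equal(rk$gene, rev(rk_neg$gene))

  planted <- attr(expr, "planted_genes")
  ranks <- match(planted, rk$gene)
  extreme <- pmin(ranks, 400 + 1 - ranks)
  expect_lte(median(extreme), 20)  # top 5% of 400
  expect_error(rank_genes(pls, component = 5), "out of range")
})

test_that("set enrichment flags the planted set and skips degenerate sets", {
  sp <- make_brain_space(c(16, 16, 16), voxel_size = c(3, 3, 3),
                         n_regions = 60, seed = 42)
  fld <- make_occurrence_field(sp, n_foci = 8, autocorr_length = 12, seed = 3)
  freq <- parcellate(fld$intensity, sp)
  expr <- make_expression(sp, freq, n_genes = 400, n_assoc = 20,
                          effect = 0.9, seed = 4)
  pxy <- prepare_xy(expr, freq)
  pls <- pls_cross_covariance(pxy$X, pxy$y)
  loadings <- setNames(pls$gene_loadings[, 1],
                       rownames(pls$gene_loadings))
  planted <- attr(expr, "planted_genes")
  sets <- list(planted = planted,
               random1 = sample(names(loadings), 20),
               random2 = sample(names(loadings), 30))
  res <- gene_set_enrichment(loadings, sets, n_perm = 500, seed = 8)
  expect_lt(res$q[res$set == "planted"], 0.05)
  expect_true(all(res$q >= res$p))

  expect_warning(
    gene_set_enrichment(loadings, list(tiny = names(loadings)[1:3],
                                       ok = planted), n_perm = 100, seed = 1),
    "fewer than 5")
  expect_warning(
    gene_set_enrichment(loadings, list(all = names(loadings),
                                       ok = planted), n_perm = 100, seed = 1),
    "full background")
})

test_that("receptor correlation is a rank correlation with monotone invariance", {
  sp <- make_brain_space(c(16, 16, 16), voxel_size = c(3, 3, 3),
                         n_regions = 60, seed = 42)
  cen <- sp$region_centroids
  fld <- make_occurrence_field(sp, n_foci = 8, autocorr_length = 12, seed = 5)
  y <- parcellate(fld$intensity, sp)
  same <- receptor_correlation(y, y * 3 + 1, cen, n_null = 100, seed = 1)
  expect_equal(same$spearman_rho, 1)
  rev <- receptor_correlation(y, -y, cen, n_null = 100, seed = 1)
  expect_equal(rev$spearman_rho, -1)

  # definition oracle: rank-then-Pearson on random pairs
  withr::with_seed(51, {
    for (i in 1:100) {
      a <- rnorm(30)
      b <- rnorm(30)
      expect_equal(cor(a, b, method = "spearman"),
                   cor(rank(a), rank(b)), tolerance = 1e-12)
    }
  })
  # monotone transform invariance of the package's estimate
  rec <- make_receptor_map(y, 0.6, seed = 3)
  r1 <- receptor_correlation(y, rec, cen, n_null = 100, seed = 2)
  r2 <- receptor_correlation(y^3, exp(rec), cen, n_null = 100, seed = 2)
  expect_equal(r1$spearman_rho, r2$spearman_rho, tolerance = 1e-12)
  expect_error(receptor_correlation(rep(1, 60), rec, cen), "constant")

  scr <- receptor_screen(y, cbind(a = rec, b = -rec), cen, n_null = 100,
                         seed = 4)
  expect_equal(scr$rho[1], -scr$rho[2], tolerance = 1e-12)
  expect_true(all(scr$q >= scr$p - 1e-12))
})
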