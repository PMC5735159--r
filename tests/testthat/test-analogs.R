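test_that("an isolated sphere has the closed-form accessible area", {
  s <- shrake_rupley_sasa(rbind(c(0, 0, 0)), radii = 1.6,
                          probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(s$total, 4 * pi * 3.0^2, tolerance = 1e-12)
})

test_that("disjoint spheres are additive; buried duplicates are well defined", {
  two <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(10, 0, 0)), radii = 1.6)
  one <- shrake_rupley_sasa(rbind(c(0, 0, 0)), radii = 1.6)
  expect_equal(two$total, 2 * one$total, tolerance = 1e-12)
  dup <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(0, 0, 0)), radii = 1.6)
  expect_equal(dup$total, 0)
})

test_that("fused spheres match a Monte-Carlo surface oracle within 1%", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  mine <- shrake_rupley_sasa(coords, radii = 1.6, n_sphere_points = 960)$total
  oracle <- mc_sasa(coords, radii = 1.6, n_points = 2e5, seed = 13)
  expect_lt(abs(mine - oracle) / oracle, 0.01)
})

test_that("SASA converges in the number of sphere points", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0.5))
  a960 <- shrake_rupley_sasa(coords, radii = c(1.6, 1.5, 1.2),
                             n_sphere_points = 960)$total
  a4000 <- shrake_rupley_sasa(coords, radii = c(1.6, 1.5, 1.2),
                              n_sphere_points = 4000)$total
  expect_lt(abs(a4000 - a960) / a4000, 0.005)
})

test_that("identical points collapse to one cluster", {
  pts <- matrix(1, nrow = 6, ncol = 2)
  cl <- density_peak_cluster(pts, d_c = 0.5)
  expect_equal(length(unique(cl$labels)), 1L)
})

test_that("planted four-group analog tables are recovered with high ARI", {
  skip_if_not_installed("mclust")
  tab <- gen_analog_table(seed = 3)
  expect_equal(nrow(tab), 54L)
  feats <- scale(as.matrix(tab[, c("sasa", "dipole", "logp")]))
  cl <- density_peak_cluster(feats, n_centers = 4)
  ari <- mclust::adjustedRandIndex(cl$labels, tab$true_group)
  expect_gt(ari, 0.9)
})

test_that("density-peak labels equal the brute-force reference exactly", {
  for (seed in 1:3) {
    pts <- withr::with_seed(seed, {
      rbind(matrix(rnorm(60, 0), ncol = 2),
            matrix(rnorm(60, 5), ncol = 2),
            matrix(rnorm(40, c(10, -4)), ncol = 2))
    })
    d_c <- 1.2
    mine <- density_peak_cluster(pts, d_c = d_c, n_centers = 3)
    ref <- ref_density_peak(pts, d_c = d_c, n_centers = 3)
    expect_identical(mine$labels, ref)
  }
})

test_that("clustering is invariant under reordering and rigid motion", {
  tab <- gen_analog_table(seed = 5)
  feats <- scale(as.matrix(tab[, c("sasa", "dipole", "logp")]))
  cl <- density_peak_cluster(feats, d_c = 0.8, n_centers = 4)
  ## rotation about the first two axes preserves all distances
  th <- 0.7
  rot <- diag(3)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  cl_rot <- density_peak_cluster(feats %*% rot, d_c = 0.8, n_centers = 4)
  expect_identical(cl$labels, cl_rot$labels)
  ## reordering: the documented index tie-break means invariance holds as a
  ## partition whenever clusters are cleanly separated; use tight blobs well
  ## inside d_c so every in-cluster link beats every cross-cluster one
  pts <- withr::with_seed(8, rbind(
    matrix(rnorm(40, 0, 0.15), ncol = 2),
    matrix(rnorm(60, 6, 0.15), ncol = 2),
    matrix(rnorm(80, c(12, -6), 0.15), ncol = 2)))
  base <- density_peak_cluster(pts, d_c = 1, n_centers = 3)
  perm <- withr::with_seed(1, sample.int(nrow(pts)))
  cl_perm <- density_peak_cluster(pts[perm, ], d_c = 1, n_centers = 3)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(base$labels[perm], cl_perm$labels), 1)
})

test_that("degenerate clustering inputs are rejected", {
  expect_error(density_peak_cluster(matrix(1, 1, 2)), "at least 2")
  expect_error(density_peak_cluster(matrix(rnorm(20), 10, 2), d_c = -1),
               "positive")
})

test_that("collinear data put all variance on the first component", {
  t_vals <- seq(-2, 2, length.out = 30)
  rec <- data.frame(sasa = 100 + 10 * t_vals, dipole = 2 + t_vals,
                    logp = 1 + 0.5 * t_vals)
  pc <- pca_reduce(rec)
  expect_equal(pc$explained[1], 1.0, tolerance = 1e-9)
  ## loadings orthonormal
  expect_equal(crossprod(pc$loadings), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCA scores reconstruct the standardized data in the retained subspace", {
  tab <- gen_analog_table(seed = 7)
  pc <- pca_reduce(tab, k = 3)
  x <- scale(as.matrix(tab[, c("sasa", "dipole", "logp")]))
  expect_equal(unname(pc$scores %*% t(pc$loadings)), unname(x),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_all) <= 1e-12))
})

test_that("the size-dominated preset loads PC1 on SASA and PC2 on dipole", {
  tab <- gen_analog_table(seed = 2)
  pc <- pca_reduce(tab)
  expect_equal(rownames(pc$loadings)[which.max(abs(pc$loadings[, 1]))], "sasa")
  expect_equal(rownames(pc$loadings)[which.max(abs(pc$loadings[, 2]))],
               "dipole")
})

test_that("zero-variance features are rejected by name", {
  rec <- data.frame(sasa = rep(100, 10), dipole = rnorm(10), logp = rnorm(10))
  expect_error(pca_reduce(rec), "sasa")
})

test_that("size-logP correlation behaves across regimes", {
  rec <- data.frame(sasa = 1:20, logp = 2 * (1:20) + 3)
  expect_equal(volume_logp_correlation(rec)$r, 1, tolerance = 1e-12)
  ## independent features: |r| below the n=54 null 95% bound most of the time
  hits <- sapply(1:20, function(s) {
    d <- withr::with_seed(s, data.frame(sasa = rnorm(54, 300, 20),
                                        logp = rnorm(54, 2, 0.5)))
    abs(volume_logp_correlation(d)$r) < 0.27
  })
  expect_gte(mean(hits), 0.85)
  ## planted positive coupling in the default generator is detected
  tab <- gen_analog_table(seed = 4)
  ct <- volume_logp_correlation(tab)
  expect_gt(ct$r, 0.5)
  expect_lt(ct$p_value, 1e-6)
})

test_that("degenerate generator covariances behave per contract", {
  tab0 <- gen_analog_table(covariance = matrix(0, 3, 3), seed = 1)
  expect_equal(unique(tab0$sasa[tab0$true_group == 1]), 250)
  sing <- diag(c(1, 1, 0))
  expect_error(gen_analog_table(covariance = sing), "singular")
  one <- gen_analog_table(n_groups = 1L, sizes = 54L,
                          group_means = matrix(c(300, 3, 2), 1), seed = 1)
  expect_equal(nrow(one), 54L)
  expect_equal(length(unique(one$true_group)), 1L)
})
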