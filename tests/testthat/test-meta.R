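test_that("t to Hedges-g conversion matches hand-evaluated formulas", {
  e0 <- t_to_effect(0, 17, 23)
  expect_equal(e0$g, 0)
  expect_equal(e0$var_g, 40 / (17 * 23))

  e <- t_to_effect(2, 50, 50)
  expect_equal(e$g, (1 - 3 / 391) * 0.4, tolerance = 1e-9)
  expect_equal(e$g, 0.396931, tolerance = 1e-6)
  expect_equal(e$var_g, 0.040804, tolerance = 1e-5)

  en <- t_to_effect(-2, 50, 50)
  expect_equal(en$g, -e$g)
  expect_equal(en$var_g, e$var_g)

  expect_error(t_to_effect(NaN, 10, 10), "non-finite")
  expect_error(t_to_effect(1, 1, 10), ">= 2")
})

test_that("kernel map reconstruction matches the Gaussian weight formula", {
  grid <- small_grid(c(21, 21, 21))
  vox <- mask_coordinates(grid)
  n1 <- 50; n2 <- 50
  J <- 1 - 3 / (4 * 98 - 1)
  g2t <- function(g) g / (J * sqrt(1 / n1 + 1 / n2))

  # voxel exactly at a lone peak takes the peak's g
  s <- study_record("a", n1, n2,
                    peaks = data.frame(x = 0, y = 0, z = 0, t = g2t(0.8)))
  m <- reconstruct_study_map(s, grid, fwhm_mm = 20)
  at <- function(map, xyz) {
    i <- which(colSums(abs(t(vox) - xyz)) < 1e-9); map$g[i]
  }
  expect_equal(at(m, c(0, 0, 0)), 0.8, tolerance = 1e-9)

  # at one FWHM from a unit peak the kernel weight is ~0.0625
  s1 <- study_record("b", n1, n2,
                     peaks = data.frame(x = 0, y = 0, z = 0, t = g2t(1)))
  m1 <- reconstruct_study_map(s1, grid, fwhm_mm = 20)
  w <- exp(-400 / (2 * (20 / 2.3548)^2))
  expect_equal(at(m1, c(20, 0, 0)), w, tolerance = 1e-6)
  expect_equal(w, 0.0625, tolerance = 0.001)

  # coincident peaks average with total weight > 1
  s2 <- study_record("c", n1, n2,
                     peaks = data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0),
                                        t = g2t(c(1, 3))))
  m2 <- reconstruct_study_map(s2, grid, fwhm_mm = 20)
  expect_equal(at(m2, c(0, 0, 0)), 2, tolerance = 1e-9)

  # peakless study contributes zeros with a large default variance
  s3 <- study_record("d", n1, n2)
  m3 <- reconstruct_study_map(s3, grid)
  expect_true(all(m3$g == 0))
  expect_true(all(m3$var_g == 10 * (n1 + n2) / (n1 * n2)))

  s4 <- study_record("e", n1, n2,
                     peaks = data.frame(x = 500, y = 0, z = 0, t = 1))
  expect_error(reconstruct_study_map(s4, grid), "bounding box")
})

test_that("DerSimonian-Laird combination reproduces hand-worked values", {
  grid <- small_grid(c(6, 6, 6))

  r3 <- random_effects_combine(replicate(3, const_map(0.5, 0.04, grid),
                                         simplify = FALSE))
  expect_equal(r3$Q[1], 0, tolerance = 1e-12)
  expect_equal(r3$tau2[1], 0, tolerance = 1e-12)
  expect_equal(r3$g[1], 0.5, tolerance = 1e-12)
  expect_equal(r3$z[1], 0.5 / sqrt(0.04 / 3), tolerance = 1e-9)
  expect_equal(r3$I2[1], 0)

  maps <- list(const_map(0.2, 0.04, grid), const_map(0.6, 0.04, grid))
  r2 <- random_effects_combine(maps)
  expect_equal(r2$Q[1], 2, tolerance = 1e-9)
  expect_equal(r2$tau2[1], 0.04, tolerance = 1e-9)
  expect_equal(r2$g[1], 0.4, tolerance = 1e-9)
  expect_equal(r2$se[1], 0.2, tolerance = 1e-9)
  expect_equal(r2$z[1], 2, tolerance = 1e-9)
  expect_equal(r2$I2[1], 50, tolerance = 1e-9)

  # study order invariance
  r2r <- random_effects_combine(rev(maps))
  expect_equal(r2r$z, r2$z)
  expect_equal(r2r$tau2, r2$tau2)

  # fixed-effect limit: equal variances, heterogeneity absent
  mm <- list(const_map(0.3, 0.05, grid), const_map(0.3, 0.05, grid),
             const_map(0.3, 0.05, grid))
  rf <- random_effects_combine(mm)
  expect_equal(rf$g[1], 0.3, tolerance = 1e-12)
  expect_equal(rf$se[1], sqrt(0.05 / 3), tolerance = 1e-12)

  expect_error(random_effects_combine(maps[1]), "2 study maps")
})

test_that("DL combination agrees with metafor as an independent oracle", {
  skip_if_not_installed("metafor")
  grid <- small_grid(c(6, 6, 6))
  set.seed(21)
  g <- rnorm(6, 0.4, 0.2); v <- runif(6, 0.02, 0.08)
  maps <- lapply(seq_len(6), function(i) const_map(g[i], v[i], grid))
  ours <- random_effects_combine(maps)
  fit <- metafor::rma(yi = g, vi = v, method = "DL")
  expect_equal(ours$g[1], as.numeric(fit$beta), tolerance = 1e-9)
  expect_equal(ours$se[1], fit$se, tolerance = 1e-9)
  expect_equal(ours$tau2[1], fit$tau2, tolerance = 1e-9)
  expect_equal(ours$I2[1], fit$I2, tolerance = 1e-6)
})

test_that("one-sided tails match a quadrature oracle over z in [0, 6]", {
  zs <- seq(0, 6, by = 0.25)
  oracle <- vapply(zs, function(z)
    integrate(dnorm, z, Inf, rel.tol = 1e-12)$value, numeric(1))
  expect_equal(signif(z_to_p(zs), 3), signif(oracle, 3))
  expect_equal(z_to_p(0), 0.5)
  expect_true(all(diff(z_to_p(zs)) < 0))
  expect_error(z_to_p(Inf), "non-finite")
})

test_that("cluster thresholding separates signs and enforces extent", {
  grid <- small_grid(c(16, 16, 16))
  V <- sum(grid$mask)

  empty <- threshold_clusters(meta_from_z(rep(0, V), grid))
  expect_equal(nrow(empty), 0)

  # one 25-voxel block and one 10-voxel block, well separated
  z <- array(0, dim(grid$data))
  z[1:5, 1:5, 1] <- 3.5          # 25 voxels
  z[12:16, 12:14, 16] <- 3.5     # 15 voxels < extent 20? use 10: 5 x 2 x 1
  z[12:16, 12:14, 16] <- 0
  z[12:16, 12:13, 16] <- 3.5     # 10 voxels
  res <- meta_from_z(z[grid$mask], grid)
  cl <- threshold_clusters(res, p_voxel = 0.005, extent = 20)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 25)

  # adjacent opposite-sign blocks stay separate clusters
  z2 <- array(0, dim(grid$data))
  z2[1:5, 1:5, 1] <- 3.5
  z2[6:10, 1:5, 1] <- -3.5
  cl2 <- threshold_clusters(meta_from_z(z2[grid$mask], grid), extent = 20)
  expect_equal(nrow(cl2), 2)
  expect_setequal(cl2$sign, c(1, -1))

  # mirror property: negated map gives the same sizes with flipped signs
  set.seed(8)
  z3 <- array(rnorm(prod(dim(grid$data)), 0, 1.6), dim(grid$data))
  cl3 <- threshold_clusters(meta_from_z(z3[grid$mask], grid), extent = 3)
  cl3n <- threshold_clusters(meta_from_z(-z3[grid$mask], grid), extent = 3)
  expect_equal(sort(cl3$size[cl3$sign == 1]), sort(cl3n$size[cl3n$sign == -1]))
  expect_equal(sort(cl3$size[cl3$sign == -1]), sort(cl3n$size[cl3n$sign == 1]))
})

test_that("heterogeneity summary uses the 25/50/75 bands, boundary upward", {
  grid <- small_grid(c(8, 8, 8))
  maps <- list(const_map(0.2, 0.04, grid), const_map(0.6, 0.04, grid),
               const_map(0.4, 0.04, grid))
  res <- random_effects_combine(maps)
  # force one suprathreshold cluster over the constant map
  res$z <- rep(4, length(res$z)); res$p <- z_to_p(res$z)
  cl <- threshold_clusters(res, extent = 20)
  het <- heterogeneity_report(res, cl)
  expect_equal(nrow(het), 1)
  expect_true(all(res$I2 >= 0 & res$I2 <= 100))

  # identical studies: I2 = 0, negligible heterogeneity
  resid <- random_effects_combine(replicate(3, const_map(0.5, 0.04, grid),
                                            simplify = FALSE))
  resid$z <- rep(4, length(resid$z)); resid$p <- z_to_p(resid$z)
  hl <- heterogeneity_report(resid, threshold_clusters(resid, extent = 20))
  expect_equal(hl$I2_mean, 0)
  expect_equal(hl$label, "negligible")

  # the two-study worked example sits exactly at the 50 boundary -> medium
  res2 <- random_effects_combine(list(const_map(0.2, 0.04, grid),
                                      const_map(0.6, 0.04, grid)))
  res2$z <- rep(4, length(res2$z))
  h2 <- heterogeneity_report(res2, threshold_clusters(res2, extent = 20))
  expect_equal(h2$I2_mean, 50, tolerance = 1e-9)
  expect_equal(h2$label, "medium")
})

test_that("small-study diagnostics behave on constructed funnels", {
  grid <- small_grid(c(8, 8, 8))

  # identical SEs: Egger predictor degenerate, reported unavailable
  maps_eq <- lapply(c(0.5, 0.6, 0.7, 0.4), function(g) const_map(g, 0.04, grid))
  res_eq <- random_effects_combine(maps_eq)
  res_eq$z <- rep(4, length(res_eq$z))
  cl_eq <- threshold_clusters(res_eq, extent = 20)
  ss_eq <- small_study_tests(maps_eq, res_eq, cl_eq)
  expect_true(is.na(ss_eq$egger_intercept))
  expect_true(is.na(ss_eq$egger_p))

  # symmetric funnel: no small-study effect detected
  set.seed(13)
  se <- rep(seq(0.1, 0.3, length.out = 10), each = 2)
  eps <- rep(abs(rnorm(10)), each = 2) * c(1, -1)
  g <- 0.5 + se * eps
  maps_sym <- lapply(seq_along(g), function(i) const_map(g[i], se[i]^2, grid))
  res_sym <- random_effects_combine(maps_sym)
  res_sym$z <- rep(4, length(res_sym$z))
  cl_sym <- threshold_clusters(res_sym, extent = 20)
  ss <- small_study_tests(maps_sym, res_sym, cl_sym)
  expect_lt(abs(ss$egger_intercept), 0.5)
  expect_gt(ss$egger_p, 0.05)

  # all studies significant with power ~1: O = E = k, excess p = 1
  maps_big <- replicate(5, const_map(2, 0.01, grid), simplify = FALSE)
  res_big <- random_effects_combine(maps_big)
  res_big$z <- rep(6, length(res_big$z))
  ss_big <- small_study_tests(maps_big, res_big,
                              threshold_clusters(res_big, extent = 20))
  expect_equal(ss_big$o_significant, 5)
  expect_equal(ss_big$e_significant, 5, tolerance = 1e-6)
  expect_equal(ss_big$excess_sig_p, 1, tolerance = 1e-9)
})

test_that("jackknife consistency reflects how many studies drive a cluster", {
  grid <- small_grid(c(12, 12, 12))
  # K identical strong studies: every cluster survives all leave-one-outs
  maps <- replicate(5, const_map(1.2, 0.04, grid), simplify = FALSE)
  jk <- jackknife_consistency(maps, p_voxel = 0.005, extent = 20)
  expect_true(all(jk$consistency == 1))

  # a cluster driven by a single outlier study drops out without it
  maps_mix <- c(replicate(4, const_map(0, 0.04, grid), simplify = FALSE),
                list(const_map(3, 0.01, grid)))
  jk2 <- jackknife_consistency(maps_mix, p_voxel = 0.005, extent = 20)
  if (nrow(jk2)) expect_true(all(jk2$consistency <= 4 / 5))

  # order invariance
  jk3 <- jackknife_consistency(rev(maps), p_voxel = 0.005, extent = 20)
  expect_equal(jk3$consistency, jk$consistency)

  expect_error(jackknife_consistency(maps[1:2]), "3 studies")
})
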