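test_that("box smoothing preserves constants and spreads impulses", {
  v <- array(7, c(10, 10, 4))
  expect_equal(smooth_maps(v, c(4, 4, 1)), v)
  expect_equal(smooth_maps(v, c(1, 1, 1)), v)
  delta <- array(0, c(12, 12, 3)); delta[6, 6, 2] <- 1
  sm <- smooth_maps(delta, c(4, 4, 1))
  expect_equal(sum(sm > 0), 16)
  expect_equal(unique(sm[sm > 0]), 1 / 16)
  expect_equal(sum(sm), 1)
  # invalid voxels neither receive nor contribute
  valid <- array(TRUE, c(10, 10, 4)); valid[1, 1, 1] <- FALSE
  v2 <- v; v2[1, 1, 1] <- 1e6
  sm2 <- smooth_maps(v2, c(4, 4, 1), valid = valid)
  expect_true(is.na(sm2[1, 1, 1]))
  expect_equal(sm2[valid], v[valid])
  expect_error(smooth_maps(v, c(0, 4, 1)), "kernel")
})

test_that("map agreement statistics match their definitions", {
  x <- array(rep(c(1, 2, 3), 4), c(12, 1, 1))
  same <- compare_maps(x, x)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$lins_ccc, 1)
  # constant offset: perfect correlation, penalized concordance (CCC = 4/7)
  shifted <- compare_maps(x, x + 1)
  expect_equal(shifted$slope, 1)
  expect_equal(shifted$intercept, 1)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$lins_ccc, 4 / 7)
  # scale bias is penalized too
  doubled <- compare_maps(x, 2 * x)
  expect_equal(doubled$pearson_r, 1)
  expect_lt(doubled$lins_ccc, 1)
  expect_error(compare_maps(array(1:5, c(5, 1, 1)), array(1:5, c(5, 1, 1))),
               "insufficient overlap")
})

test_that("concordance is symmetric, bounded by |r|, and 1 iff identical", {
  set.seed(19)
  for (i in 1:100) {
    a <- rnorm(50, 1000, 200)
    b <- 0.5 * a + rnorm(50, 100, 150)
    A <- array(a, c(50, 1, 1)); B <- array(b, c(50, 1, 1))
    ab <- compare_maps(A, B); ba <- compare_maps(B, A)
    expect_equal(ab$lins_ccc, ba$lins_ccc, tolerance = 1e-12)
    expect_lte(abs(ab$lins_ccc), abs(ab$pearson_r) + 1e-12)
    expect_lt(ab$lins_ccc, 1)
  }
})

test_that("effective range matches closed-form and brute-force solutions", {
  er <- effective_range(1, 0)
  expect_equal(er$lower, 0)
  expect_equal(er$upper, 3000)
  er2 <- effective_range(0.8, 100)
  expect_equal(er2$lower, 1000 / 3, tolerance = 1e-9)
  expect_equal(er2$upper, 1000, tolerance = 1e-9)
  # brute-force scan of the band condition on a 1 ms grid
  set.seed(29)
  for (i in 1:100) {
    sl <- runif(1, 0.3, 1.7); ic <- runif(1, -200, 500)
    er <- effective_range(sl, ic)
    x <- seq(1, 3000, by = 1)
    inband <- sl * x + ic >= 0.9 * x & sl * x + ic <= 1.1 * x
    if (!any(inband)) {
      expect_true(er$empty)
    } else {
      expect_false(er$empty)
      expect_lt(abs(max(er$lower, 1) - min(x[inband])), 1 + 1e-9)
      expect_lt(abs(er$upper - max(x[inband])), 1 + 1e-9)
    }
  }
  expect_error(effective_range(2.5, 0), "slope")
})

test_that("CDF distances are 0 for identical and 1 for disjoint inputs", {
  a <- array(runif(200, 500, 1000), c(200, 1, 1))
  b <- array(runif(200, 2000, 3000), c(200, 1, 1))
  same <- cdf_curves(list(a, a))
  expect_equal(same$max_ks, 0)
  disjoint <- cdf_curves(list(a, b))
  expect_equal(disjoint$max_ks, 1)
  expect_equal(dim(disjoint$cdfs), c(512, 2))
  expect_true(all(diff(disjoint$cdfs[, 1]) >= 0))
})

test_that("T1 maps from two presets of one phantom nearly share a CDF", {
  # heterogeneous GM/WM so their T1 distribution is continuous; CSF is kept
  # at a fixed reference value by the generator, and a point mass makes the
  # Kolmogorov statistic jump for arbitrarily small shifts, so the CSF
  # component is checked by its location instead
  ph <- make_phantom(c(32, 32, 32), seed = 14, heterogeneity = 1)
  maps <- lapply(c("ingenia", "discovery1"), function(nm) {
    img <- simulate_mprage(ph, nm, M0 = 1000)
    t1_require(img, phantom_masks(ph), "mprage",
               params = scanner_presets(nm)$params)
  })
  cont <- ph$labels == 1L | ph$labels == 2L
  cc <- cdf_curves(lapply(maps, function(m) m$t1[cont & m$valid]))
  expect_lt(cc$max_ks, 0.02)
  csf_meds <- vapply(maps, function(m)
    median(m$t1[ph$labels == 3L & m$valid]), 0)
  expect_lt(abs(diff(csf_meds)) / 2500, 0.01)
})

test_that("error propagation reproduces the closed-form sensitivities", {
  p <- se_params_default
  expect_equal(t1_uncertainty_from_t2(1331, 110, 0, p), 0)
  # gray matter with 50% T2 uncertainty: ~5.6% T1 uncertainty
  expect_equal(t1_uncertainty_from_t2(1331, 110, 55, p), 0.0557,
               tolerance = 1e-2)
  # white matter analogue: ~8.8%
  expect_equal(t1_uncertainty_from_t2(832, 79.6, 39.8, p), 0.0876,
               tolerance = 1e-2)
  expect_error(t1_uncertainty_from_t2(-1, 110, 55, p), "positive")
})

test_that("closed-form T2 propagation agrees with a numeric perturbation", {
  p <- se_params_default
  for (cfg in list(c(1331, 110), c(832, 79.6))) {
    t1 <- cfg[1]; t2 <- cfg[2]
    dT2 <- 0.01 * t2
    # measured signal stays fixed; the assumed T2 in the correction changes
    s <- se_signal(t1, t2, 1, p, k = 1)
    s_t1_wrong <- s * exp(p$TE / (t2 + dT2))
    t1_wrong <- se_invert(s_t1_wrong, k = 1, TR = p$TR)
    numeric_rel <- abs(t1_wrong - t1) / t1
    closed <- t1_uncertainty_from_t2(t1, t2, dT2, p)
    expect_equal(numeric_rel, closed, tolerance = 0.01)
  }
})

test_that("signal sensitivity helpers implement their first-order forms", {
  p <- se_params_default
  expect_equal(se_sensitivity_t2(110, 8.7, p), 10 * 8.7 / 110^2)
  expect_equal(se_sensitivity_t1(1331, 57, p),
               525 * 57 / (1331^2 * (exp(525 / 1331) - 1)))
  # equating the two sensitivities reproduces the T2-to-T1 propagation
  dT1 <- se_sensitivity_t2(110, 55, p) / se_sensitivity_t1(1331, 1, p)
  expect_equal(dT1 / 1331, t1_uncertainty_from_t2(1331, 110, 55, p),
               tolerance = 1e-12)
})
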