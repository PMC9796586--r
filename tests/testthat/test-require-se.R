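make_sphere <- function(d = 21, r = 7) {
  ax <- seq_len(d) - (d + 1) / 2
  x <- array(ax, rep(d, 3))
  y <- aperm(x, c(2, 1, 3)); z <- aperm(x, c(3, 2, 1))
  x^2 + y^2 + z^2 <= r^2
}

test_that("brain mask closing is idempotent on solids and fills holes", {
  sph <- make_sphere()
  m <- tissue_masks(sph, array(FALSE, dim(sph)), array(FALSE, dim(sph)))
  expect_error(build_brain_mask(tissue_masks(array(FALSE, dim(sph)),
                                             array(FALSE, dim(sph)),
                                             array(FALSE, dim(sph)))),
               "empty")
  expect_identical(build_brain_mask(m), sph)
  holed <- sph; holed[11, 11, 11] <- FALSE
  m2 <- tissue_masks(holed, array(FALSE, dim(sph)), array(FALSE, dim(sph)))
  expect_identical(build_brain_mask(m2), sph)
})

test_that("brain mask covers every labeled phantom voxel", {
  ph <- phantom_hom32
  bm <- build_brain_mask(phantom_masks(ph))
  expect_true(all(bm[ph$labels > 0L]))
})

test_that("T2/rho correction is exact where it should be", {
  ph <- phantom_hom32
  masks <- phantom_masks(ph)
  # TE = 0 with unit proton density: correction is the identity
  refs1 <- reference_params(rho = c(1, 1, 1))
  p0 <- spin_echo_params(TR = 525, TE = 0)
  img <- simulate_spin_echo(ph, p0, k = 100)
  cor <- t2rho_correction(img, masks, refs1, p0, sigma = 3)
  brain <- ph$labels > 0L
  expect_equal(cor[brain], img[brain], tolerance = 1e-12)
  # noiseless phantom at sigma = 0: exact algebraic cancellation to S_T1
  p <- se_params_default
  img2 <- simulate_spin_echo(ph, p, k = 1000)
  cor2 <- t2rho_correction(img2, masks, ph$refs, p, sigma = 0)
  expect_lt(max(abs(cor2[brain] - se_t1_signal(ph$t1[brain], p, k = 1000)) /
                se_t1_signal(ph$t1[brain], p, k = 1000)), 1e-10)
})

test_that("smoothing a single-tissue correction field leaves it uniform", {
  d <- c(32, 32, 32)
  gm <- array(FALSE, d); gm[8:24, 8:24, 8:24] <- TRUE
  masks <- tissue_masks(gm, array(FALSE, d), array(FALSE, d))
  img <- array(0, d); img[gm] <- 50
  p <- se_params_default
  cor <- t2rho_correction(img, masks, reference_params(), p, sigma = 2,
                          brain_mask = gm)
  expect_equal(unique(round(cor[gm], 9)),
               round(50 * exp(p$TE / 110) / 0.807, 9))
})

test_that("gain fit k is exact, linear, and unbiased under noise", {
  t1_refs <- c(1331, 832, 2500)
  f <- 1 - exp(-525 / t1_refs)
  s <- 1000 * f
  fit <- fit_k(s, t1_refs, 525)
  expect_equal(fit$k, 1000, tolerance = 1e-9)
  expect_lt(fit$residual, 1e-18)
  expect_equal(fit_k(2 * s, t1_refs, 525)$k, 2000, tolerance = 1e-9)
  expect_false(fit_k(c(-1, 1, 1), t1_refs, 525)$valid)
  # Monte-Carlo: 1% iid noise on the tissue means, 1000 draws
  set.seed(11)
  ks <- replicate(1000, fit_k(s * (1 + rnorm(3, 0, 0.01)), t1_refs, 525)$k)
  expect_lt(abs(mean(ks) - 1000) / 1000, 0.002)
})

test_that("spin-echo pipeline recovers a noiseless homogeneous phantom", {
  ph <- phantom_hom32
  img <- simulate_spin_echo(ph, se_params_default, k = 1000)
  fit <- t1_require(img, phantom_masks(ph), "se", params = se_params_default,
                    sigma = 0)
  truth <- c(1331, 832, 2500)
  for (tis in 1:3) {
    sel <- ph$labels == tis & fit$valid
    expect_gt(sum(sel), 100)
    expect_lt(max(abs(fit$t1[sel] - truth[tis]) / truth[tis]), 1e-4)
  }
  # fitted gains equal the simulated gain on every calibrated slice
  expect_equal(unname(coef(fit)), rep(1000, sum(fit$fit$valid)),
               tolerance = 1e-9)
})

test_that("spin-echo calibration is invariant to a global intensity scale", {
  ph <- phantom_hom32
  img <- simulate_spin_echo(ph, se_params_default, k = 1000, noise_sd = 0.02,
                            seed = 2)
  base <- t1_require(img, phantom_masks(ph), "se", params = se_params_default)
  for (c0 in c(0.1, 1000)) {
    scaled <- t1_require(img * c0, phantom_masks(ph), "se",
                         params = se_params_default)
    expect_identical(scaled$valid, base$valid)
    expect_lt(max(abs(scaled$t1 - base$t1) / base$t1, na.rm = TRUE), 1e-10)
  }
})

test_that("only slices with all three reference tissues are calibrated", {
  ph <- phantom_hom32
  img <- simulate_spin_echo(ph, se_params_default, k = 1000)
  fit <- t1_require(img, phantom_masks(ph), "se", params = se_params_default,
                    sigma = 0, min_voxels = 50)
  expect_identical(fit$fit$valid, census_valid_slices(ph$labels, 50))
  # invalid slices contribute no valid voxels
  for (z in which(!fit$fit$valid))
    expect_false(any(fit$valid[, , z]))
})

test_that("voxels outside the model range are flagged, not clamped", {
  ph <- phantom_hom32
  img <- simulate_spin_echo(ph, se_params_default, k = 1000)
  # corrupt some voxels inside a calibrated slice beyond the model ceiling
  z <- 16
  gm_idx <- which(ph$labels[, , z] == 1L)[1:20]
  sl <- img[, , z]; sl[gm_idx] <- 1e7; img[, , z] <- sl
  fit <- t1_require(img, phantom_masks(ph), "se", params = se_params_default,
                    sigma = 0)
  vsl <- fit$valid[, , z]
  expect_true(all(!vsl[gm_idx]))
  expect_true(all(is.na(fit$t1[, , z][gm_idx])))
  expect_gt(fit$fit$n_invalid_voxels[z], 0)
  # all valid voxels lie in (0, clamp_max]
  expect_true(all(fit$t1[fit$valid] > 0 & fit$t1[fit$valid] <= 5000))
})

test_that("noisy heterogeneous phantom is recovered within 10% per tissue", {
  ph <- make_phantom(c(48, 48, 48), seed = 8, heterogeneity = 1)
  img <- simulate_spin_echo(ph, se_params_default, k = 800, noise_sd = 0.02,
                            seed = 8)
  # smoothing scale below the thinnest phantom structure (~3-voxel shells)
  fit <- t1_require(img, phantom_masks(ph), "se", params = se_params_default,
                    sigma = 1)
  truth <- c(1331, 832, 2500)
  for (tis in 1:3) {
    sel <- ph$labels == tis & fit$valid
    expect_lt(abs(median(fit$t1[sel]) - truth[tis]) / truth[tis], 0.10)
  }
})

test_that("no calibratable slice is an error", {
  ph <- phantom_hom32
  img <- simulate_spin_echo(ph, se_params_default, k = 1000)
  expect_error(t1_require(img, phantom_masks(ph), "se",
                          params = se_params_default, min_voxels = 1e6),
               "no axial slice")
})
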