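#' T2/proton-density correction of a T1-weighted spin-echo image
#'
#' Converts a measured spin-echo image `S` into the purely T1-weighted image
#' `S_T1 = S * exp(TE/T2_ref) / rho_ref` by assigning every brain voxel the
#' literature T2 and proton density of its tissue class.  The voxelwise
#' correction factor is smoothed with a two-dimensional Gaussian filter
#' applied in-plane (across the sagittal and coronal directions, i.e. within
#' each axial slice) so that the hard segmentation boundaries do not imprint
#' step artifacts; `sigma = 0` disables the smoothing.  Brain-mask voxels
#' without a tissue assignment inherit the factor of the nearest assigned
#' tissue by propagation.
#'
#' @param image 3D signal array.
#' @param masks a [tissue_masks()] object.
#' @param refs a [reference_params()] table.
#' @param params a [spin_echo_params()] object (supplies TE).
#' @param sigma in-plane Gaussian sd of the correction-field smoothing, in
#'   voxels.
#' @param brain_mask optional logical array; defaults to
#'   [build_brain_mask()] of `masks`.
#' @return The corrected `S_T1` array, zero outside the brain mask.
#' @export
t2rho_correction <- function(image, masks, refs = reference_params(),
                             params = spin_echo_params(), sigma = 2,
                             brain_mask = NULL) {
  stopifnot(inherits(masks, "tissue_masks"))
  check_same_grid(image, masks$gm, "image and masks")
  if (is.null(brain_mask)) brain_mask <- build_brain_mask(masks)
  hm <- hard_masks(masks)

  fac <- array(NA_real_, dim(image))
  for (tis in c("gm", "wm", "csf"))
    fac[hm[[tis]]] <- exp(params$TE / refs[tis, "t2"]) / refs[tis, "rho"]

  # in-mask voxels with no tissue assignment take the nearest assigned factor
  unassigned <- brain_mask & is.na(fac)
  if (any(unassigned)) {
    n_fill <- sum(unassigned)
    while (any(unassigned)) {
      have <- !is.na(fac)
      num <- den <- array(0, dim(fac))
      for (i in seq_len(nrow(.cross_offsets))) {
        s <- .cross_offsets[i, ]
        f <- fac; f[is.na(f)] <- 0
        num <- num + shift3(f, s)
        den <- den + shift3(have * 1, s)
      }
      new <- unassigned & den > 0
      if (!any(new)) break
      fac[new] <- num[new] / den[new]
      unassigned <- brain_mask & is.na(fac)
    }
    message(sprintf("t2rho_correction: %d in-mask voxels had no tissue %s",
                    n_fill, "assignment; nearest-tissue factor used"))
  }
  fac[is.na(fac)] <- 0

  if (sigma > 0) {
    w <- gauss_kernel_1d(sigma)
    fac <- smooth_weighted(fac, brain_mask, wx = w, wy = w, wz = 1)
  }
  out <- array(0, dim(image))
  out[brain_mask] <- image[brain_mask] * fac[brain_mask]
  attr(out, "voxel_size") <- attr(image, "voxel_size")
  out
}

#' Fit the scanner gain k from reference tissue means
#'
#' Least-squares fit of the one-parameter model `S_T1 = k * (1 - exp(-TR/T1))`
#' to the mean corrected signals of the reference tissues at their literature
#' T1 values.  Because the model is linear in `k`, the minimizer is the
#' closed-form weighted solution `k = sum(s_i f_i) / sum(f_i^2)` with
#' `f_i = 1 - exp(-TR/T1_i)`.
#'
#' @param s_means mean corrected signal per reference tissue (positive).
#' @param t1_refs literature T1 per tissue, ms.
#' @param TR repetition time, ms.
#' @return A list with `k` (fitted gain) and `residual` (sum of squared
#'   errors), or `k = NA` with `valid = FALSE` on degenerate input.
#' @export
fit_k <- function(s_means, t1_refs, TR) {
  if (length(s_means) != length(t1_refs) || length(s_means) < 1)
    stop("s_means and t1_refs must have equal, positive length")
  if (any(!is.finite(s_means)) || any(s_means <= 0) || any(t1_refs <= 0))
    return(list(k = NA_real_, residual = NA_real_, valid = FALSE))
  f <- 1 - exp(-TR / t1_refs)
  k <- sum(s_means * f) / sum(f^2)
  list(k = k, residual = sum((s_means - k * f)^2), valid = k > 0)
}

# slicewise spin-echo calibration engine; returns the pieces assembled into
# the fitted-map object by t1_require()
.require_se_engine <- function(image, masks, params, refs, sigma = 2,
                               min_voxels = 50, clamp_max = 5000) {
  stopifnot(inherits(params, "spin_echo_params"))
  brain <- build_brain_mask(masks)
  s_t1 <- t2rho_correction(image, masks, refs, params, sigma = sigma,
                           brain_mask = brain)
  hm <- hard_masks(masks)
  nz <- dim(image)[3]
  t1_refs <- refs[c("gm", "wm", "csf"), "t1"]

  t1 <- array(NA_real_, dim(image))
  valid <- array(FALSE, dim(image))
  fits <- data.frame(slice = seq_len(nz), k = NA_real_, residual = NA_real_,
                     n_gm = 0L, n_wm = 0L, n_csf = 0L,
                     n_invalid_voxels = 0L, valid = FALSE)
  for (z in seq_len(nz)) {
    sel <- lapply(hm, function(m) m[, , z])
    counts <- vapply(sel, sum, 0L)
    fits[z, c("n_gm", "n_wm", "n_csf")] <- as.list(as.integer(counts))
    if (any(counts < min_voxels)) next  # slice lacks a reference tissue
    sl <- s_t1[, , z]
    means <- vapply(sel, function(m) mean(sl[m]), 0)
    fit <- fit_k(means, t1_refs, params$TR)
    if (!isTRUE(fit$valid)) next
    fits$k[z] <- fit$k
    fits$residual[z] <- fit$residual
    fits$valid[z] <- TRUE
    bz <- brain[, , z]
    vox <- sl[bz]
    ok <- is.finite(vox) & vox > 0 & vox < fit$k
    t1z <- rep(NA_real_, length(vox))
    t1z[ok] <- -params$TR / log(1 - vox[ok] / fit$k)
    ok <- ok & is.finite(t1z) & t1z > 0 & t1z <= clamp_max
    t1z[!ok] <- NA_real_
    plane <- t1[, , z]; vplane <- valid[, , z]
    plane[bz] <- t1z; vplane[bz] <- ok
    t1[, , z] <- plane; valid[, , z] <- vplane
    fits$n_invalid_voxels[z] <- sum(!ok)
  }
  if (!any(fits$valid))
    stop("no axial slice contains all three reference tissues (>= ",
         min_voxels, " voxels each); cannot calibrate")
  list(t1 = t1, valid = valid, fits = fits, brain = brain, s_t1 = s_t1)
}
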