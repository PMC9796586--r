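#' Fit a quantitative T1 map from a T1-weighted image
#'
#' The main model-fitting entry point.  Calibrates the sequence signal
#' equation of a T1-weighted acquisition against the internal reference
#' tissues (GM, WM, CSF at their literature relaxation values) and inverts
#' every brain voxel to T1:
#'
#' * `sequence = "se"` (spin echo): the image is T2/proton-density corrected
#'   ([t2rho_correction()]), the scanner gain `k` is fitted per axial slice
#'   from the three reference-tissue means ([fit_k()]), and each slice is
#'   inverted analytically ([se_invert()]).  Only slices containing all three
#'   reference tissues (at least `min_voxels` voxels each) can be calibrated;
#'   other slices are left invalid.
#' * `sequence = "mprage"`: the equilibrium magnetization `M0` is fitted once
#'   from whole-volume tissue means ([fit_m0()]), a monotone signal lookup
#'   table is built ([build_lut()]) and inverted by piecewise-linear
#'   interpolation ([invert_via_lut()]).
#'
#' Both calibrations are invariant to any global rescaling of the input
#' image: the fitted gain absorbs the scale exactly.
#'
#' @param image 3D signal array (e.g. from [read_volume()] or a simulator).
#' @param masks a [tissue_masks()] object on the same grid.
#' @param sequence `"se"` or `"mprage"`.
#' @param params a [spin_echo_params()] or [mprage_params()] object matching
#'   `sequence`.
#' @param refs a [reference_params()] table of literature tissue values.
#' @param sigma in-plane Gaussian sd (voxels) for smoothing the T2/rho
#'   correction field (spin echo only); 0 disables.
#' @param min_voxels minimum voxel count per reference tissue for a slice to
#'   be calibrated (spin echo only).
#' @param clamp_max upper plausibility bound on T1, ms; voxels inverting
#'   beyond it are flagged invalid rather than silently clamped.
#' @param lut_range,lut_step lookup-table T1 range and step, ms
#'   (MPRAGE only).
#' @return An object of class `"t1require"` with components `t1` (3D array
#'   of T1 in ms, `NA` where invalid), `valid` (logical array), `method`,
#'   `fit` (per-slice gain table or the M0 fit and lookup table), and
#'   `config`.  Methods: `print`, `summary`, `coef`, `residuals`, `plot`.
#' @examples
#' ph <- make_phantom(c(32, 32, 32), seed = 7, heterogeneity = 0)
#' img <- simulate_spin_echo(ph, spin_echo_params(525, 10), k = 1000)
#' fit <- t1_require(img, phantom_masks(ph), "se",
#'                   params = spin_echo_params(525, 10), sigma = 0)
#' summary(fit)
#' @export
t1_require <- function(image, masks, sequence = c("se", "mprage"),
                       params = NULL, refs = reference_params(), sigma = 2,
                       min_voxels = 50, clamp_max = 5000,
                       lut_range = c(1, 5000), lut_step = 1) {
  sequence <- match.arg(sequence)
  stopifnot(inherits(masks, "tissue_masks"))
  if (length(dim(image)) != 3)
    stop("expected a 3D volume; got ", length(dim(image)), " dimensions")
  check_same_grid(image, masks$gm, "image and masks")
  if (is.null(params))
    params <- if (sequence == "se") spin_echo_params() else mprage_params()

  if (sequence == "se") {
    eng <- .require_se_engine(image, masks, params, refs, sigma = sigma,
                              min_voxels = min_voxels, clamp_max = clamp_max)
    obj <- new_t1require(eng$t1, eng$valid, method = "SE-REQUIRE",
                         fit = eng$fits,
                         config = list(params = unclass(params),
                                       sigma = sigma,
                                       min_voxels = min_voxels,
                                       clamp_max = clamp_max))
  } else {
    eng <- .require_mprage_engine(image, masks, params, refs,
                                  lut_range = lut_range, lut_step = lut_step)
    clamped <- eng$valid & eng$t1 > clamp_max
    eng$t1[clamped] <- NA_real_; eng$valid[clamped] <- FALSE
    obj <- new_t1require(eng$t1, eng$valid, method = "MPRAGE-REQUIRE",
                         fit = eng$fit, lut = eng$lut,
                         config = list(params = unclass(params),
                                       clamp_max = clamp_max,
                                       lut_range = lut_range,
                                       lut_step = lut_step))
  }
  obj$refs <- refs
  obj
}

# low-level constructor shared by the three mapping methods
new_t1require <- function(t1, valid, method, fit = NULL, lut = NULL,
                          residual_map = NULL, config = list()) {
  structure(list(t1 = t1, valid = valid, method = method, fit = fit,
                 lut = lut, residual_map = residual_map, config = config),
            class = "t1require")
}

#' @export
print.t1require <- function(x, ...) {
  d <- dim(x$t1)
  cat(sprintf("T1 map (%s), %dx%dx%d voxels\n", x$method, d[1], d[2], d[3]))
  nv <- sum(x$valid)
  cat(sprintf("  valid voxels: %d (%.1f%% of volume)\n",
              nv, 100 * nv / length(x$valid)))
  if (x$method == "SE-REQUIRE") {
    ks <- x$fit$k[x$fit$valid]
    cat(sprintf("  calibrated slices: %d of %d; k in [%.4g, %.4g]\n",
                sum(x$fit$valid), nrow(x$fit), min(ks), max(ks)))
  } else if (x$method == "MPRAGE-REQUIRE") {
    cat(sprintf("  fitted M0 = %.6g (residual %.3g)\n",
                x$fit$M0, x$fit$residual))
  }
  invisible(x)
}

#' @export
summary.t1require <- function(object, ...) {
  v <- object$t1[object$valid]
  out <- list(method = object$method,
              n_valid = length(v),
              quantiles = stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95)),
              mean = mean(v))
  class(out) <- "summary.t1require"
  out
}

#' @export
print.summary.t1require <- function(x, ...) {
  cat(sprintf("T1 map summary (%s): %d valid voxels\n", x$method, x$n_valid))
  cat(sprintf("  mean %.0f ms; quantiles (ms):\n", x$mean))
  print(round(x$quantiles))
  invisible(x)
}

#' Calibration coefficients of a fitted T1 map
#'
#' For a spin-echo fit, the per-slice scanner gains `k` (named by slice, only
#' calibrated slices); for an MPRAGE fit, the fitted equilibrium
#' magnetization `M0`; Look-Locker maps are fitted voxelwise and have no
#' global coefficient (an empty vector is returned).
#'
#' @param object a `"t1require"` object.
#' @param ... unused.
#' @export
coef.t1require <- function(object, ...) {
  if (object$method == "SE-REQUIRE") {
    f <- object$fit[object$fit$valid, ]
    stats::setNames(f$k, paste0("k.slice", f$slice))
  } else if (object$method == "MPRAGE-REQUIRE") {
    c(M0 = object$fit$M0)
  } else {
    numeric(0)
  }
}

#' Calibration residuals of a fitted T1 map
#'
#' Spin echo: per-slice sum of squared errors of the three-tissue gain fit.
#' MPRAGE: the squared-error residual of the M0 fit.  Look-Locker: the
#' voxelwise residual sum of squares of the recovery-curve fit.
#'
#' @param object a `"t1require"` object.
#' @param ... unused.
#' @export
residuals.t1require <- function(object, ...) {
  if (object$method == "SE-REQUIRE") {
    f <- object$fit[object$fit$valid, ]
    stats::setNames(f$residual, paste0("slice", f$slice))
  } else if (object$method == "MPRAGE-REQUIRE") {
    c(residual = object$fit$residual)
  } else {
    object$residual_map
  }
}

#' Display an axial slice of a fitted T1 map
#'
#' @param x a `"t1require"` object.
#' @param slice axial slice index; defaults to the middle slice.
#' @param zlim display range in ms.
#' @param ... passed to [graphics::image()].
#' @export
plot.t1require <- function(x, slice = NULL, zlim = c(0, 3500), ...) {
  d <- dim(x$t1)
  if (is.null(slice)) slice <- d[3] %/% 2
  sl <- x$t1[, , slice]
  sl[!x$valid[, , slice]] <- NA
  graphics::image(seq_len(d[1]), seq_len(d[2]), sl, zlim = zlim,
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "x", ylab = "y",
                  main = sprintf("%s T1 map, slice %d", x$method, slice), ...)
  invisible(x)
}
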