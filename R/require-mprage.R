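#' Fit the equilibrium magnetization M0 from reference tissue means
#'
#' Minimizes the squared error between the mean MPRAGE signals of the
#' reference tissues and the model signals at their literature T1 values.
#' The steady-state signal is proportional to `M0`, so the minimizer is the
#' closed-form `M0 = sum(s_t g_t) / sum(g_t^2)` with
#' `g_t = mprage_signal(T1_t, 1, params)`.
#'
#' @param s_means mean signal per reference tissue (positive).
#' @param t1_refs literature T1 per tissue, ms.
#' @param params an [mprage_params()] object.
#' @return A list with `M0`, `residual` and `valid`.
#' @export
fit_m0 <- function(s_means, t1_refs, params) {
  if (length(s_means) != length(t1_refs) || length(s_means) < 1)
    stop("s_means and t1_refs must have equal, positive length")
  if (any(!is.finite(s_means)) || any(s_means <= 0) || any(t1_refs <= 0))
    return(list(M0 = NA_real_, residual = NA_real_, valid = FALSE))
  g <- mprage_signal(t1_refs, 1, params)
  if (sum(g^2) < .Machine$double.eps)
    stop("degenerate model: reference signals vanish for these parameters")
  M0 <- sum(s_means * g) / sum(g^2)
  list(M0 = M0, residual = sum((s_means - M0 * g)^2), valid = M0 > 0)
}

#' Signal lookup table for MPRAGE inversion
#'
#' Tabulates the MPRAGE steady-state signal on a T1 grid for a fitted `M0`.
#' The table is only usable for inversion where the signal is strictly
#' monotone in T1; monotonicity is asserted at build time, and if it fails
#' over the requested range the table is restricted to the largest monotone
#' subrange -- which must still cover 400-4000 ms, the range the brain
#' tissues occupy -- with a message.
#'
#' @param M0 fitted equilibrium magnetization.
#' @param params an [mprage_params()] object.
#' @param t1_range T1 interval to tabulate, ms.
#' @param step grid step, ms.
#' @return An object of class `"signal_lut"`: list with `t1_grid`, `signals`,
#'   `M0`, `params`.
#' @export
build_lut <- function(M0, params, t1_range = c(1, 5000), step = 1) {
  stopifnot(inherits(params, "mprage_params"))
  if (M0 <= 0) stop("M0 must be positive")
  if (step <= 0) stop("step must be positive")
  grid <- seq(t1_range[1], t1_range[2], by = step)
  sig <- mprage_signal(grid, M0, params)
  d <- diff(sig)
  if (!(all(d > 0) || all(d < 0))) {
    # keep the longest strictly monotone run; it must cover 400-4000 ms
    runs <- rle(sign(d))
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    len <- runs$lengths
    best <- which.max(ifelse(runs$values == 0, 0, len))
    lo <- grid[starts[best]]; hi <- grid[ends[best] + 1]
    if (lo > 400 || hi < 4000)
      stop(sprintf(
        "MPRAGE signal is not monotone over [%g, %g] ms; largest monotone %s",
        t1_range[1], t1_range[2],
        sprintf("subrange [%g, %g] ms does not cover 400-4000 ms", lo, hi)))
    message(sprintf("build_lut: restricting to monotone subrange [%g, %g] ms",
                    lo, hi))
    keep <- grid >= lo & grid <= hi
    grid <- grid[keep]; sig <- sig[keep]
  }
  structure(list(t1_grid = grid, signals = sig, M0 = M0, params = params),
            class = "signal_lut")
}

#' @export
print.signal_lut <- function(x, ...) {
  cat(sprintf(
    "MPRAGE signal lookup table: T1 %g-%g ms (%d points), M0 = %.4g\n",
    min(x$t1_grid), max(x$t1_grid), length(x$t1_grid), x$M0))
  invisible(x)
}

#' Invert an MPRAGE image through a signal lookup table
#'
#' Maps every in-mask voxel signal to T1 by piecewise-linear interpolation of
#' the inverse table.  Signals outside the tabulated range are flagged
#' invalid (`NA`).  A single whole-volume calibration is used -- unlike the
#' slicewise spin-echo method, the MPRAGE inversion does not need all three
#' reference tissues in every slice.
#'
#' @param image 3D signal array.
#' @param lut a [build_lut()] table.
#' @param mask logical array of voxels to convert.
#' @return A list with `t1` (array, NA where invalid) and `valid`.
#' @export
invert_via_lut <- function(image, lut, mask) {
  stopifnot(inherits(lut, "signal_lut"))
  check_same_grid(image, mask, "image and mask")
  # approx() needs ascending x; the table is strictly monotone either way
  xs <- lut$signals; ys <- lut$t1_grid
  if (xs[1] > xs[length(xs)]) { xs <- rev(xs); ys <- rev(ys) }
  t1 <- array(NA_real_, dim(image))
  v <- image[mask]
  t1[mask] <- stats::approx(xs, ys, xout = v, rule = 1)$y
  valid <- !is.na(t1)
  valid[!mask] <- FALSE
  list(t1 = t1, valid = valid)
}

# whole-volume MPRAGE calibration engine
.require_mprage_engine <- function(image, masks, params, refs,
                                   lut_range = c(1, 5000), lut_step = 1) {
  stopifnot(inherits(params, "mprage_params"))
  brain <- build_brain_mask(masks)
  hm <- hard_masks(masks)
  means <- vapply(hm, function(m) mean(image[m]), 0)
  t1_refs <- refs[c("gm", "wm", "csf"), "t1"]
  fit <- fit_m0(means, t1_refs, params)
  if (!isTRUE(fit$valid)) stop("M0 fit failed on the reference tissue means")
  lut <- build_lut(fit$M0, params, t1_range = lut_range, step = lut_step)
  inv <- invert_via_lut(image, lut, brain)
  list(t1 = inv$t1, valid = inv$valid, brain = brain, lut = lut,
       fit = c(fit, list(tissue_means = means)))
}
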