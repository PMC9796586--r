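#' Box-kernel smoothing of a map restricted to valid voxels
#'
#' Convolves a volume with a normalized uniform (box) kernel, renormalizing
#' over the valid neighbors so edges and invalid voxels do not drag the
#' average toward zero.  The default 4 x 4 x 1 kernel is the in-plane
#' noise-reduction filter applied to T1 maps before agreement analysis.
#'
#' @param volume 3D array.
#' @param kernel integer triple of kernel dimensions (voxels).
#' @param valid optional logical array; only these voxels contribute and are
#'   returned (others are `NA`).
#' @return Smoothed array, `NA` outside `valid`.
#' @export
smooth_maps <- function(volume, kernel = c(4, 4, 1), valid = NULL) {
  if (length(kernel) != 3 || any(kernel < 1) || any(kernel != round(kernel)))
    stop("kernel must be a triple of positive integers")
  if (is.null(valid)) valid <- is.finite(volume)
  check_same_grid(volume, valid, "volume and validity mask")
  v <- volume; v[!valid] <- 0
  num <- v; den <- valid * 1
  for (ax in 1:3) {
    k <- kernel[ax]
    if (k == 1) next
    offs <- seq.int(-((k - 1) %/% 2), k %/% 2)  # k contiguous offsets
    n2 <- array(0, dim(v)); d2 <- array(0, dim(v))
    for (o in offs) {
      s <- c(0, 0, 0); s[ax] <- o
      n2 <- n2 + shift3(num, s)
      d2 <- d2 + shift3(den, s)
    }
    num <- n2; den <- d2
  }
  out <- array(NA_real_, dim(volume))
  ok <- valid & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

.map_values <- function(x) {
  # valid-voxel extraction for t1require objects, arrays, or plain vectors
  if (inherits(x, "t1require")) return(list(v = x$t1, ok = x$valid))
  if (is.null(dim(x))) return(list(v = x, ok = is.finite(x) & x != 0))
  list(v = x, ok = is.finite(x) & x != 0)
}

#' Voxelwise agreement between two T1 maps
#'
#' Over the jointly valid voxels, regresses map B on map A by ordinary least
#' squares and reports the regression slope and intercept, Pearson's
#' correlation coefficient, and Lin's concordance correlation coefficient
#' `CCC = 2 cov(A,B) / (var(A) + var(B) + (mean(A) - mean(B))^2)` with
#' population (1/n) moments, which penalizes both scatter and systematic
#' deviation from the line of unity.
#'
#' @param mapA,mapB `"t1require"` objects or arrays on the same grid.  By
#'   convention A is the reference method and B the map under evaluation
#'   (B is regressed on A).
#' @param sample_moments use 1/(n-1) moments in the CCC instead of Lin's
#'   population definition.
#' @return An object of class `"t1_compare"`: list with `slope`, `intercept`
#'   (ms), `pearson_r`, `lins_ccc`, `n`.
#' @export
compare_maps <- function(mapA, mapB, sample_moments = FALSE) {
  A <- .map_values(mapA); B <- .map_values(mapB)
  check_same_grid(A$v, B$v, "maps")
  ok <- A$ok & B$ok & is.finite(A$v) & is.finite(B$v)
  n <- sum(ok)
  if (n < 10)
    stop("insufficient overlap: only ", n, " jointly valid voxels")
  a <- as.numeric(A$v[ok]); b <- as.numeric(B$v[ok])
  ma <- mean(a); mb <- mean(b)
  denom <- if (sample_moments) n - 1 else n
  va <- sum((a - ma)^2) / denom
  vb <- sum((b - mb)^2) / denom
  cab <- sum((a - ma) * (b - mb)) / denom
  slope <- cab / va
  structure(list(slope = slope,
                 intercept = mb - slope * ma,
                 pearson_r = cab / sqrt(va * vb),
                 lins_ccc = 2 * cab / (va + vb + (ma - mb)^2),
                 n = n),
            class = "t1_compare")
}

#' @export
print.t1_compare <- function(x, ...) {
  cat(sprintf(
    "T1 map agreement (n = %d voxels)\n  slope %.3f, intercept %.1f ms\n",
    x$n, x$slope, x$intercept))
  cat(sprintf("  Pearson r %.3f, Lin's CCC %.3f\n", x$pearson_r, x$lins_ccc))
  er <- effective_range(x$slope, x$intercept)
  if (!er$empty)
    cat(sprintf("  effective range (+/-10%% band): %.0f-%.0f ms\n",
                er$lower, er$upper))
  invisible(x)
}

#' Effective T1 range of a regression line
#'
#' The maximal T1 interval on which the regression line
#' `y = slope * x + intercept` stays within the band
#' `[(1 - pct) x, (1 + pct) x]` around the line of unity, intersected with
#' `(0, upper_limit]`.  This is the range over which the method agrees with
#' the reference to within `pct` (10% by default).
#'
#' @param slope regression slope, in (0, 2).
#' @param intercept regression intercept, ms.
#' @param pct half-width of the relative agreement band (fraction).
#' @param upper_limit upper end of the analysed T1 range, ms.
#' @return A list with `lower`, `upper` (ms) and `empty`; when the line never
#'   enters the band the result is explicitly empty (`lower`/`upper` `NA`).
#' @examples
#' effective_range(0.939, 84.2)   # lower bound ~523 ms
#' @export
effective_range <- function(slope, intercept, pct = 0.10,
                            upper_limit = 3000) {
  if (slope <= 0 || slope >= 2) stop("slope must be in (0, 2)")
  if (pct <= 0 || pct >= 1) stop("pct must be in (0, 1)")
  # each band edge gives a half-line constraint a*x >= b on x > 0
  halfline <- function(a, b) {
    if (a > 0) c(max(0, b / a), Inf)
    else if (a < 0) c(0, b / a)   # may be degenerate if b/a <= 0
    else if (b <= 0) c(0, Inf) else c(NA, NA)
  }
  i1 <- halfline(slope - (1 - pct), -intercept)  # stay above (1-pct)x
  i2 <- halfline((1 + pct) - slope, intercept)   # stay below (1+pct)x
  lo <- max(i1[1], i2[1], 0)
  hi <- min(i1[2], i2[2], upper_limit)
  if (anyNA(c(lo, hi)) || hi <= lo || hi <= 0)
    return(list(lower = NA_real_, upper = NA_real_, empty = TRUE))
  list(lower = lo, upper = hi, empty = FALSE)
}

# exact two-sample Kolmogorov statistic (max vertical ECDF distance)
ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  max(abs(Fa - Fb))
}

#' Empirical CDFs of a set of maps and their pairwise distances
#'
#' Computes the empirical cumulative distribution of the valid voxel values
#' of each input on a common grid, together with the exact pairwise
#' Kolmogorov statistics (maximum vertical CDF distance).  Used to judge how
#' well maps from different scanners conform to a common distribution.
#'
#' @param maps list of `"t1require"` objects, arrays, or numeric vectors.
#'   For arrays/vectors, finite non-zero entries count as valid.
#' @param grid evaluation grid for the returned curves; defaults to 512
#'   points spanning all inputs.
#' @return An object of class `"cdf_set"`: list with `grid`, `cdfs` (matrix,
#'   one column per input), `ks` (pairwise distance matrix) and
#'   `max_ks`.
#' @export
cdf_curves <- function(maps, grid = NULL) {
  vals <- lapply(maps, function(m) {
    x <- .map_values(m)
    v <- as.numeric(x$v[x$ok])
    v <- v[is.finite(v)]
    if (length(v) == 0) stop("an input has no valid voxels")
    v
  })
  k <- length(vals)
  if (is.null(grid)) {
    rng <- range(unlist(lapply(vals, range)))
    grid <- seq(rng[1], rng[2], length.out = 512)
  }
  cdfs <- vapply(vals, function(v) stats::ecdf(v)(grid), numeric(length(grid)))
  ks <- matrix(0, k, k, dimnames = list(names(maps), names(maps)))
  if (k > 1)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      ks[i, j] <- ks[j, i] <- ks_stat(vals[[i]], vals[[j]])
  structure(list(grid = grid, cdfs = cdfs, ks = ks, max_ks = max(ks)),
            class = "cdf_set")
}

#' @export
print.cdf_set <- function(x, ...) {
  cat(sprintf("Empirical CDF set: %d distributions on a %d-point grid\n",
              ncol(x$cdfs), length(x$grid)))
  cat(sprintf("  maximum pairwise Kolmogorov distance: %.4f\n", x$max_ks))
  invisible(x)
}

#' Relative spin-echo signal change from a T1 perturbation
#'
#' First-order sensitivity of the purely T1-weighted spin-echo signal:
#' `dS/S = TR * dT1 / (T1^2 * (exp(TR/T1) - 1))`.
#'
#' @param T1 relaxation time, ms.
#' @param dT1 perturbation of T1, ms.
#' @param params a [spin_echo_params()] object.
#' @return Relative signal change (fraction).
#' @export
se_sensitivity_t1 <- function(T1, dT1, params) {
  stopifnot(inherits(params, "spin_echo_params"))
  if (any(T1 <= 0)) stop("T1 must be positive")
  params$TR * dT1 / (T1^2 * (exp(params$TR / T1) - 1))
}

#' Relative spin-echo signal change from a T2 perturbation
#'
#' First-order sensitivity of the spin-echo signal to the T2 used in the
#' echo-decay factor: `dS/S = TE * dT2 / T2^2`.
#'
#' @param T2 transverse relaxation time, ms.
#' @param dT2 perturbation of T2, ms.
#' @param params a [spin_echo_params()] object.
#' @return Relative signal change (fraction).
#' @export
se_sensitivity_t2 <- function(T2, dT2, params) {
  stopifnot(inherits(params, "spin_echo_params"))
  if (any(T2 <= 0)) stop("T2 must be positive")
  params$TE * dT2 / T2^2
}

#' T1 uncertainty induced by an uncertain reference T2
#'
#' Error propagation through the spin-echo calibration: equating the relative
#' signal perturbations from T1 and T2 gives the relative T1 uncertainty
#' caused by using a wrong reference T2,
#' `dT1/T1 = TE * dT2 * T1 * (exp(TR/T1) - 1) / (TR * T2^2)`.
#' For an average gray-matter voxel at the study's spin-echo settings a 50%
#' T2 error propagates to only a few percent in T1, which is why fixed
#' literature T2 values are tolerable in the calibration.
#'
#' @param T1 relaxation time of the tissue, ms.
#' @param T2 assumed transverse relaxation time, ms.
#' @param dT2 uncertainty in T2, ms.
#' @param params a [spin_echo_params()] object.
#' @return Relative T1 uncertainty (fraction).
#' @examples
#' t1_uncertainty_from_t2(1331, 110, 55, spin_echo_params(525, 10))
#' @export
t1_uncertainty_from_t2 <- function(T1, T2, dT2, params) {
  stopifnot(inherits(params, "spin_echo_params"))
  if (any(T1 <= 0) || any(T2 <= 0)) stop("T1 and T2 must be positive")
  if (any(dT2 < 0)) stop("dT2 must be non-negative")
  params$TE * dT2 * T1 * (exp(params$TR / T1) - 1) / (params$TR * T2^2)
}
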