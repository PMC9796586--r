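# Look-Locker multi-TI T1 mapping (reference standard).
#
# The three-parameter recovery model S(TI) = A - B exp(-TI/T1star) is fitted
# by nonlinear least squares using variable projection: for a fixed T1star
# the model is linear in (A, B) and solved in closed form, leaving a
# one-dimensional minimization over T1star (coarse geometric grid followed by
# golden-section refinement).  This separable formulation finds the same
# least-squares minimum as a full three-parameter optimizer but is robust,
# derivative-free, and vectorizes over all voxels of a volume at once.

# linear subproblem: given per-voxel T1star (vector nv) and signal matrix
# S (nTI x nv), return A, B and the residual sum of squares
.ll_linfit <- function(T1star, S, TIs) {
  n <- length(TIs)
  x <- exp(-outer(TIs, T1star, "/"))          # nTI x nv
  Sx <- colSums(x); Sxx <- colSums(x * x)
  Sy <- colSums(S); Syy <- colSums(S * S); Sxy <- colSums(x * S)
  den <- n * Sxx - Sx^2
  m <- (n * Sxy - Sx * Sy) / den              # slope on x; B = -m
  a <- (Sy - m * Sx) / n
  rss <- Syy + n * a^2 + m^2 * Sxx + 2 * (a * m * Sx - a * Sy - m * Sxy)
  list(A = a, B = -m, rss = pmax(rss, 0))
}

# vectorized separable fit over a signal matrix; returns per-voxel A, B,
# T1star, rss
.ll_fit_core <- function(S, TIs, t1s_range = c(30, 10000), n_grid = 64,
                         iter = 60) {
  nv <- ncol(S)
  grid <- exp(seq(log(t1s_range[1]), log(t1s_range[2]), length.out = n_grid))
  best_rss <- rep(Inf, nv); best_i <- rep(1L, nv)
  for (i in seq_along(grid)) {
    f <- .ll_linfit(rep(grid[i], nv), S, TIs)
    hit <- is.finite(f$rss) & f$rss < best_rss
    best_rss[hit] <- f$rss[hit]; best_i[hit] <- i
  }
  lo <- grid[pmax(best_i - 1L, 1L)]
  hi <- grid[pmin(best_i + 1L, n_grid)]
  # golden-section refinement of T1star within the per-voxel bracket
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- .ll_linfit(x1, S, TIs)$rss
  f2 <- .ll_linfit(x2, S, TIs)$rss
  for (it in seq_len(iter)) {
    take1 <- f1 <= f2 | !is.finite(f2)
    hi <- ifelse(take1, x2, hi)
    lo <- ifelse(take1, lo, x1)
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- .ll_linfit(x1, S, TIs)$rss
    f2 <- .ll_linfit(x2, S, TIs)$rss
  }
  t1s <- (lo + hi) / 2
  f <- .ll_linfit(t1s, S, TIs)
  list(A = f$A, B = f$B, T1star = t1s, rss = f$rss)
}

# polarity restoration for magnitude data: for each candidate flip index j
# (the first j signals in TI order negated) run the coarse fit and keep the
# sign pattern with the smallest residual, voxel by voxel
.ll_restore_polarity <- function(S, TIs) {
  ord <- order(TIs)
  nv <- ncol(S); nt <- length(TIs)
  best_rss <- rep(Inf, nv); best_j <- rep(0L, nv)
  for (j in 0:(nt - 1)) {
    Sj <- S
    if (j > 0) Sj[ord[seq_len(j)], ] <- -Sj[ord[seq_len(j)], ]
    f <- .ll_fit_core(Sj, TIs, iter = 12)
    hit <- is.finite(f$rss) & f$rss < best_rss  # ties keep the fewer flips
    best_rss[hit] <- f$rss[hit]; best_j[hit] <- j
  }
  for (j in unique(best_j)) {
    if (j == 0) next
    S[ord[seq_len(j)], best_j == j] <- -S[ord[seq_len(j)], best_j == j]
  }
  S
}

#' Fit the Look-Locker recovery model in one voxel
#'
#' Nonlinear least-squares fit of `S(TI) = A - B * exp(-TI/T1star)` to one
#' voxel's multi-TI signals.  For magnitude data the lost polarity is
#' restored by brute force: every candidate sign-flip index (the first `j`
#' signals in TI order negated) is tried and the pattern with the smallest
#' residual kept.
#'
#' @param signals numeric vector of signals, one per TI.
#' @param TIs inversion times in ms (>= 3).
#' @param magnitude set `TRUE` when `signals` are magnitude images.
#' @return A [looklocker_fit()] object with attributes `residual` (sum of
#'   squared errors) and `valid`.
#' @examples
#' tis <- c(150, 400, 750, 1500, 3500)
#' s <- 1000 - 2000 * exp(-tis / 900)
#' f <- fit_looklocker_voxel(s, tis)
#' looklocker_correct(f)
#' @export
fit_looklocker_voxel <- function(signals, TIs, magnitude = FALSE) {
  if (length(signals) != length(TIs)) stop("signals/TIs length mismatch")
  if (length(TIs) < 3) stop("need at least 3 TIs")
  if (any(!is.finite(signals))) stop("signals must be finite")
  S <- matrix(signals, ncol = 1)
  if (magnitude) S <- .ll_restore_polarity(S, TIs)
  f <- .ll_fit_core(S, TIs)
  valid <- is.finite(f$A) && is.finite(f$B) && is.finite(f$T1star) &&
    f$T1star > 0
  if (!valid)
    return(structure(list(A = NA_real_, B = NA_real_, T1star = NA_real_),
                     class = "looklocker_fit", residual = NA_real_,
                     valid = FALSE))
  out <- looklocker_fit(f$A, f$B, f$T1star)
  attr(out, "residual") <- f$rss
  attr(out, "valid") <- TRUE
  out
}

# voxelwise Look-Locker engine over a list of volumes
.lookl_engine <- function(images, TIs, mask = NULL, magnitude = FALSE,
                          clamp_max = 5000) {
  if (length(images) != length(TIs))
    stop("number of images (", length(images), ") does not match number of ",
         "TIs (", length(TIs), ")")
  if (length(TIs) < 3) stop("need at least 3 TIs")
  for (im in images) check_same_grid(images[[1]], im, "Look-Locker series")
  d <- dim(images[[1]])
  if (is.null(mask)) {
    mask <- Reduce(`|`, lapply(images, function(im) im != 0))
  }
  check_same_grid(images[[1]], mask, "images and mask")
  idx <- which(mask)
  S <- vapply(images, function(im) im[idx], numeric(length(idx)))
  S <- t(S)                                   # nTI x nvox
  if (magnitude) S <- .ll_restore_polarity(S, TIs)
  f <- .ll_fit_core(S, TIs)
  ratio <- f$B / f$A
  t1v <- f$T1star * (ratio - 1)
  ok <- is.finite(t1v) & is.finite(ratio) & ratio > 1 & t1v > 0 &
    t1v <= clamp_max
  t1v[!ok] <- NA_real_
  t1 <- array(NA_real_, d); valid <- array(FALSE, d)
  t1[idx] <- t1v; valid[idx] <- ok
  rss <- array(NA_real_, d); rss[idx] <- f$rss
  list(t1 = t1, valid = valid, rss = rss,
       fit = list(TIs = TIs, magnitude = magnitude))
}

#' Look-Locker T1 map from a multi-TI series
#'
#' Fits the apparent recovery curve voxelwise over a series of inversion-time
#' volumes and applies the Look-Locker correction
#' `T1 = T1star * (B/A - 1)`.  Voxels where the fit fails or where
#' `B/A <= 1` (no physical correction) are flagged invalid.
#'
#' @param images list of 3D arrays, one per inversion time.
#' @param TIs inversion times in ms, matching `images` in order and length.
#' @param mask optional logical array of voxels to fit; defaults to voxels
#'   that are non-zero in any volume of the series.
#' @param magnitude set `TRUE` for magnitude images (polarity restored by
#'   brute force).
#' @param clamp_max upper plausibility bound on T1, ms; larger fits are
#'   invalidated.
#' @return A fitted T1 map of class `"t1require"` (see [t1_require()]) with
#'   `method = "LOOK-LOCKER"`.
#' @export
lookl_map <- function(images, TIs, mask = NULL, magnitude = FALSE,
                      clamp_max = 5000) {
  eng <- .lookl_engine(images, TIs, mask, magnitude, clamp_max)
  new_t1require(t1 = eng$t1, valid = eng$valid, method = "LOOK-LOCKER",
                fit = eng$fit, residual_map = eng$rss,
                config = list(TIs = TIs, magnitude = magnitude,
                              clamp_max = clamp_max))
}
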