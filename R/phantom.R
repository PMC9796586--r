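#' Seeded digital brain phantom
#'
#' Builds a deterministic nested-ellipsoid brain phantom: an outer CSF shell,
#' a cortical gray-matter ribbon, a white-matter core, and two ventricle-like
#' CSF ellipsoids inside the white matter.  Per-voxel T1/T2/proton-density
#' values are drawn from truncated normal distributions with the literature
#' tissue means and `heterogeneity` times the literature standard deviations
#' (truncated at +/- 3 sd so relaxation times stay physical).
#'
#' The geometry is chosen so that the large majority of axial slices through
#' the head contain all three reference tissues, which is what the slicewise
#' spin-echo calibration requires.
#'
#' @param shape voxel dimensions, at least `c(32, 32, 32)`.
#' @param seed integer seed; the phantom is bit-reproducible given the seed.
#' @param refs a [reference_params()] table supplying tissue means and sds.
#' @param heterogeneity scale in `[0, 1]` applied to the literature sds;
#'   0 gives perfectly homogeneous tissue.
#' @param voxel_size voxel edge lengths in mm.
#' @return An object of class `"tissue_phantom"`: list with `labels`
#'   (0 = background, 1 = GM, 2 = WM, 3 = CSF), `t1`, `t2`, `rho` maps
#'   (zero outside the head), `voxel_size`, `seed`, `heterogeneity`, `refs`.
#' @examples
#' ph <- make_phantom(c(32, 32, 32), seed = 1, heterogeneity = 0)
#' table(ph$labels)
#' @export
make_phantom <- function(shape = c(64, 64, 64), seed = 1,
                         refs = reference_params(), heterogeneity = 1,
                         voxel_size = c(3, 3, 3)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 32))
    stop("shape must be a triple with every dimension >= 32")
  if (heterogeneity < 0 || heterogeneity > 1)
    stop("heterogeneity must be in [0, 1]")

  # normalized coordinates in [-1, 1] per axis
  ax <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  u <- array(ax[[1]], shape)
  v <- aperm(array(ax[[2]], shape[c(2, 1, 3)]), c(2, 1, 3))
  w <- aperm(array(ax[[3]], shape[c(3, 1, 2)]), c(2, 3, 1))

  inside <- function(cx, cy, cz, a, b, c)
    ((u - cx) / a)^2 + ((v - cy) / b)^2 + ((w - cz) / c)^2 <= 1

  outer_e <- inside(0, 0, 0, 0.90, 0.84, 0.94)
  gm_e    <- inside(0, 0, 0, 0.80, 0.72, 0.90)
  wm_e    <- inside(0, 0, 0, 0.64, 0.56, 0.84)
  vent    <- inside(0.20, 0.04, 0.10, 0.11, 0.22, 0.40) |
             inside(-0.20, 0.04, 0.10, 0.11, 0.22, 0.40)

  labels <- array(0L, shape)
  labels[outer_e] <- 3L                  # CSF shell
  labels[gm_e]    <- 1L                  # cortical ribbon
  labels[wm_e]    <- 2L                  # white-matter core
  labels[vent & wm_e] <- 3L              # ventricles

  set.seed(seed)
  draw <- function(n, mean, sd) {
    s <- heterogeneity * sd
    if (s == 0 || n == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, s)
    bad <- abs(x - mean) > 3 * s
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, s)
      bad <- abs(x - mean) > 3 * s
    }
    x
  }

  t1 <- t2 <- rho <- array(0, shape)
  for (i in seq_len(3)) {
    idx <- which(labels == c(1L, 2L, 3L)[i])
    tis <- c("gm", "wm", "csf")[i]
    t1[idx]  <- draw(length(idx), refs[tis, "t1"],  refs[tis, "t1_sd"])
    t2[idx]  <- draw(length(idx), refs[tis, "t2"],  refs[tis, "t2_sd"])
    rho[idx] <- draw(length(idx), refs[tis, "rho"], refs[tis, "rho_sd"])
  }

  structure(list(labels = labels, t1 = t1, t2 = t2, rho = rho,
                 voxel_size = voxel_size, seed = seed,
                 heterogeneity = heterogeneity, refs = refs),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Digital brain phantom %dx%dx%d (seed %d, heterogeneity %.2f)\n",
              d[1], d[2], d[3], x$seed, x$heterogeneity))
  n <- tabulate(x$labels + 1L, 4)
  cat(sprintf("  voxels: background %d, GM %d, WM %d, CSF %d\n",
              n[1], n[2], n[3], n[4]))
  invisible(x)
}

#' Tissue masks of a phantom
#'
#' @param ph a [make_phantom()] phantom.
#' @return A [tissue_masks()] object of logical arrays.
#' @export
phantom_masks <- function(ph) {
  stopifnot(inherits(ph, "tissue_phantom"))
  tissue_masks(ph$labels == 1L, ph$labels == 2L, ph$labels == 3L)
}

#' Built-in scanner presets for the multi-scanner MPRAGE experiment
#'
#' Six 3 T MPRAGE parameter sets spanning two vendors and a wide range of
#' inversion times (450 to 1010 ms), i.e. strongly differing T1 weighting.
#' TR, TE, TI and the number of phase-encoding steps follow the published
#' multi-scanner protocol table; the excitation flip angle (9 degrees) and
#' recovery period (400 ms), which that table does not list, are fixed at the
#' values of the single-site healthy-control protocol.
#'
#' @param name optional preset name; omit to get the named list of all six.
#' @return A list with elements `name` and `params` (an [mprage_params()]
#'   object), or the named list of all presets.
#' @examples
#' names(scanner_presets())
#' scanner_presets("ingenia")$params$TI
#' @export
scanner_presets <- function(name = NULL) {
  P <- list(
    discovery1 = mprage_params(TR = 8.5, TE = 3.2, alpha = 9, TI = 450,
                               Trec = 400, N = 182),
    discovery2 = mprage_params(TR = 8.6, TE = 3.2, alpha = 9, TI = 450,
                               Trec = 400, N = 174),
    architect  = mprage_params(TR = 7.9, TE = 3.1, alpha = 9, TI = 450,
                               Trec = 400, N = 174),
    achieva1   = mprage_params(TR = 7.9, TE = 3.5, alpha = 9, TI = 827.7,
                               Trec = 400, N = 160),
    achieva2   = mprage_params(TR = 6.9, TE = 3.5, alpha = 9, TI = 810,
                               Trec = 400, N = 180),
    ingenia    = mprage_params(TR = 8.1, TE = 3.7, alpha = 9, TI = 1010,
                               Trec = 400, N = 167))
  out <- lapply(names(P), function(nm) list(name = nm, params = P[[nm]]))
  names(out) <- names(P)
  if (is.null(name)) return(out)
  if (!name %in% names(out))
    stop("unknown scanner preset '", name, "'; available: ",
         paste(names(out), collapse = ", "))
  out[[name]]
}

.phantom_noise <- function(S, brain, noise_sd, seed, rician = FALSE) {
  if (noise_sd <= 0) return(S)
  set.seed(seed)
  sd_abs <- noise_sd * mean(abs(S[brain]))
  n <- sum(brain)
  if (rician) {
    S[brain] <- sqrt((S[brain] + stats::rnorm(n, 0, sd_abs))^2 +
                     stats::rnorm(n, 0, sd_abs)^2)
  } else {
    S[brain] <- S[brain] + stats::rnorm(n, 0, sd_abs)
  }
  S
}

#' Simulate a T1-weighted spin-echo acquisition of a phantom
#'
#' Evaluates the spin-echo signal equation voxelwise on the phantom's
#' parameter maps and adds seeded Gaussian noise (optionally Rician, i.e.
#' magnitude of a complex signal with Gaussian noise on both channels) inside
#' the head.  Background stays exactly zero.
#'
#' @param ph a [make_phantom()] phantom.
#' @param params a [spin_echo_params()] object.
#' @param k scanner gain.
#' @param noise_sd noise standard deviation as a fraction of the mean
#'   in-head signal.
#' @param seed integer seed for the noise draw.
#' @param rician if `TRUE`, magnitude (Rician) noise instead of additive
#'   Gaussian.
#' @return A 3D signal array with the phantom's `voxel_size` attribute.
#' @export
simulate_spin_echo <- function(ph, params = spin_echo_params(), k = 1000,
                               noise_sd = 0, seed = 1, rician = FALSE) {
  stopifnot(inherits(ph, "tissue_phantom"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  brain <- ph$labels > 0L
  S <- array(0, dim(ph$labels))
  S[brain] <- se_signal(ph$t1[brain], ph$t2[brain], ph$rho[brain], params, k)
  S <- .phantom_noise(S, brain, noise_sd, seed, rician)
  attr(S, "voxel_size") <- ph$voxel_size
  S
}

#' Simulate an MPRAGE acquisition of a phantom
#'
#' Voxelwise MPRAGE steady-state signal at the center of k-space, plus seeded
#' noise.  The equilibrium magnetization `M0` is treated as a global scanner
#' scale (proton-density differences between tissues are not modelled for
#' this sequence, matching the signal model used by the calibration).
#'
#' @param ph a [make_phantom()] phantom.
#' @param preset an [mprage_params()] object, a preset name, or an element of
#'   [scanner_presets()].
#' @param M0 equilibrium magnetization (global scale).
#' @inheritParams simulate_spin_echo
#' @return A 3D signal array.
#' @export
simulate_mprage <- function(ph, preset = "ingenia", M0 = 1000,
                            noise_sd = 0, seed = 1, rician = FALSE) {
  stopifnot(inherits(ph, "tissue_phantom"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  params <- if (inherits(preset, "mprage_params")) preset
            else if (is.character(preset)) scanner_presets(preset)$params
            else preset$params
  brain <- ph$labels > 0L
  S <- array(0, dim(ph$labels))
  S[brain] <- mprage_signal(ph$t1[brain], M0, params)
  S <- .phantom_noise(S, brain, noise_sd, seed, rician)
  attr(S, "voxel_size") <- ph$voxel_size
  S
}

#' Simulate a multi-TI Look-Locker series of a phantom
#'
#' For every voxel the apparent relaxation time is
#' `T1star = T1 / (BoverA - 1)` (the inverse of the Look-Locker correction),
#' the offset amplitude is `A = A_scale * rho`, and the recovery amplitude is
#' `B = BoverA * A`; each inversion time yields one volume of
#' `A - B * exp(-TI/T1star)` plus seeded noise.
#'
#' @param ph a [make_phantom()] phantom.
#' @param TIs inversion times in ms (at least 3 distinct); the default is the
#'   five-point protocol 150, 400, 750, 1500, 3500 ms.
#' @param A_scale amplitude scale.
#' @param BoverA ratio of recovery to offset amplitude, > 1; 2 corresponds to
#'   an ideal inversion with fully recovered magnetization.
#' @param magnitude if `TRUE`, return magnitude images (polarity lost).
#' @inheritParams simulate_spin_echo
#' @return A list of 3D signal arrays, one per TI, with the TIs as names.
#' @export
simulate_look_locker <- function(ph, TIs = c(150, 400, 750, 1500, 3500),
                                 A_scale = 1000, BoverA = 2, noise_sd = 0,
                                 seed = 1, magnitude = FALSE) {
  stopifnot(inherits(ph, "tissue_phantom"))
  if (length(unique(TIs)) < 3) stop("need at least 3 distinct TIs")
  if (BoverA <= 1) stop("BoverA must exceed 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  brain <- ph$labels > 0L
  A <- A_scale * ph$rho[brain]
  T1star <- ph$t1[brain] / (BoverA - 1)
  mean_abs <- mean(abs(A))    # noise scale shared across the series
  set.seed(seed)
  out <- lapply(TIs, function(ti) {
    S <- array(0, dim(ph$labels))
    S[brain] <- A - (BoverA * A) * exp(-ti / T1star)
    if (noise_sd > 0)
      S[brain] <- S[brain] + stats::rnorm(sum(brain), 0, noise_sd * mean_abs)
    if (magnitude) S <- abs(S)
    attr(S, "voxel_size") <- ph$voxel_size
    S
  })
  names(out) <- as.character(TIs)
  out
}
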