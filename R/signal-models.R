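#' Spin-echo sequence parameters
#'
#' Container for the two timing parameters of a T1-weighted spin-echo
#' acquisition.  All times are in milliseconds.
#'
#' @param TR repetition time, ms (> 0).
#' @param TE echo time, ms (>= 0 and < TR).
#' @return An object of class `"spin_echo_params"`.
#' @examples
#' spin_echo_params(TR = 525, TE = 10)
#' @export
spin_echo_params <- function(TR = 525, TE = 10) {
  stopifnot(is.numeric(TR), is.numeric(TE), length(TR) == 1, length(TE) == 1)
  if (TR <= 0) stop("TR must be positive")
  if (TE < 0) stop("TE must be non-negative")
  if (TE >= TR) stop("TE must be smaller than TR")
  structure(list(TR = TR, TE = TE), class = "spin_echo_params")
}

#' MPRAGE sequence parameters
#'
#' Timing and excitation parameters for a magnetization-prepared rapid
#' gradient-echo (MPRAGE) acquisition: an adiabatic inversion pulse, a wait of
#' `TI` ms, then a train of `N` spoiled gradient-echo readouts with flip angle
#' `alpha` spaced `TR` ms apart, and finally a recovery period `Trec` before
#' the next inversion.  `TE` is carried for provenance but does not enter the
#' longitudinal signal model (transverse decay at these short echo times is
#' neglected).
#'
#' @param TR inter-echo repetition time within the readout train, ms.
#' @param TE echo time, ms (carried but unused by the signal model).
#' @param alpha excitation flip angle of the readout train, degrees,
#'   in (0, 90).
#' @param TI inversion time: delay between the inversion pulse and the first
#'   readout, ms.
#' @param Trec recovery period after the readout train, ms (>= 0).
#' @param N number of phase-encoding steps (readouts per inversion), >= 4.
#' @return An object of class `"mprage_params"`.
#' @examples
#' mprage_params(TR = 8, TE = 2.89, alpha = 9, TI = 358, Trec = 400, N = 176)
#' @export
mprage_params <- function(TR = 8, TE = 2.89, alpha = 9, TI = 358,
                          Trec = 400, N = 176) {
  stopifnot(length(TR) == 1, length(alpha) == 1, length(TI) == 1,
            length(Trec) == 1, length(N) == 1)
  if (TR <= 0) stop("TR must be positive")
  if (alpha <= 0 || alpha >= 90) stop("alpha must be in (0, 90) degrees")
  if (TI <= 0) stop("TI must be positive")
  if (Trec < 0) stop("Trec must be non-negative")
  if (N < 4 || N != round(N)) stop("N must be an integer >= 4")
  structure(list(TR = TR, TE = TE, alpha = alpha, TI = TI,
                 Trec = Trec, N = as.integer(N)),
            class = "mprage_params")
}

#' Look-Locker three-parameter fit
#'
#' Parameters of the apparent inversion-recovery curve
#' `S(TI) = A - B * exp(-TI / T1star)` sampled by a Look-Locker readout.
#' The apparent time constant `T1star` underestimates the true T1 because
#' the repeated low-flip-angle readouts drive recovery; the correction
#' `T1 = T1star * (B/A - 1)` restores it (see [looklocker_correct()]).
#'
#' @param A offset amplitude (signal as TI tends to infinity), arbitrary units.
#' @param B recovery amplitude, arbitrary units.
#' @param T1star apparent relaxation time, ms (> 0).
#' @return An object of class `"looklocker_fit"`.
#' @export
looklocker_fit <- function(A, B, T1star) {
  stopifnot(length(A) == 1, length(B) == 1, length(T1star) == 1)
  if (T1star <= 0) stop("T1star must be positive")
  structure(list(A = A, B = B, T1star = T1star), class = "looklocker_fit")
}

#' Literature reference relaxation parameters for healthy brain tissue
#'
#' Per-tissue means and standard deviations of T1, T2 (ms) and relative proton
#' density at 3 T for the three internal reference tissues.  Defaults are the
#' values used throughout the package: GM T1 = 1331 +/- 57 ms,
#' T2 = 110 +/- 8.7 ms, rho = 0.807 +/- 0.016; WM T1 = 832 +/- 44 ms,
#' T2 = 79.6 +/- 2.6 ms, rho = 0.679 +/- 0.0168; CSF T1 = 2500 ms (fixed; the
#' working value chosen to keep GM/CSF contrast, literature values spread from
#' 2000 to beyond 4000 ms), T2 = 1447 +/- 52 ms, rho = 1 (water).
#'
#' @param tissue,t1,t1_sd,t2,t2_sd,rho,rho_sd vectors of equal length giving,
#'   per tissue, the reference means and standard deviations.
#' @return A data frame of class `"reference_params"` with one row per tissue.
#' @examples
#' reference_params()
#' @export
reference_params <- function(tissue = c("gm", "wm", "csf"),
                             t1     = c(1331, 832, 2500),
                             t1_sd  = c(57, 44, 0),
                             t2     = c(110, 79.6, 1447),
                             t2_sd  = c(8.7, 2.6, 52),
                             rho    = c(0.807, 0.679, 1),
                             rho_sd = c(0.016, 0.0168, 0)) {
  n <- length(tissue)
  stopifnot(length(t1) == n, length(t2) == n, length(rho) == n,
            length(t1_sd) == n, length(t2_sd) == n, length(rho_sd) == n)
  if (any(t1 <= 0) || any(t2 <= 0) || any(rho <= 0))
    stop("reference means must be positive")
  out <- data.frame(tissue = tolower(tissue), t1 = t1, t1_sd = t1_sd,
                    t2 = t2, t2_sd = t2_sd, rho = rho, rho_sd = rho_sd,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$tissue
  class(out) <- c("reference_params", "data.frame")
  out
}

#' Spin-echo signal equation
#'
#' Theoretical T1-weighted spin-echo signal
#' `S = k * rho * (1 - exp(-TR/T1)) * exp(-TE/T2)`, where `k` collects all
#' T1-independent scanner gains.  Vectorized over `T1`, `T2` and `rho`.
#'
#' @param T1 longitudinal relaxation time(s), ms (> 0).
#' @param T2 transverse relaxation time(s), ms (> 0).
#' @param rho relative proton density (>= 0).
#' @param params a [spin_echo_params()] object.
#' @param k scanner gain (> 0).
#' @return Signal in arbitrary units, same shape as the inputs.
#' @examples
#' se_signal(1331, 110, 0.807, spin_echo_params(525, 10), k = 1)
#' @export
se_signal <- function(T1, T2, rho, params, k = 1) {
  stopifnot(inherits(params, "spin_echo_params"))
  if (any(T1 <= 0, na.rm = TRUE)) stop("T1 must be positive")
  if (any(T2 <= 0, na.rm = TRUE)) stop("T2 must be positive")
  if (any(rho < 0, na.rm = TRUE)) stop("rho must be non-negative")
  if (k <= 0) stop("k must be positive")
  k * rho * (1 - exp(-params$TR / T1)) * exp(-params$TE / T2)
}

#' Purely T1-weighted spin-echo signal
#'
#' The spin-echo signal with the T2 and proton-density factors divided out:
#' `S_T1 = k * (1 - exp(-TR/T1))`.  This is the quantity the T2/rho correction
#' produces from a measured image and the model the per-slice gain `k` is
#' fitted to.
#'
#' @inheritParams se_signal
#' @return Corrected signal `S_T1`, arbitrary units.
#' @export
se_t1_signal <- function(T1, params, k = 1) {
  stopifnot(inherits(params, "spin_echo_params"))
  if (any(T1 <= 0, na.rm = TRUE)) stop("T1 must be positive")
  if (k <= 0) stop("k must be positive")
  k * (1 - exp(-params$TR / T1))
}

#' Analytic inversion of the purely T1-weighted spin-echo signal
#'
#' Inverts `S_T1 = k * (1 - exp(-TR/T1))` to
#' `T1 = -TR / log(1 - S_T1/k)`.  The model only covers `0 < S_T1 < k`;
#' values outside that range have no finite positive T1.  For a scalar input
#' an out-of-range value is a domain error; for a vector or volume it is
#' flagged invalid (`NA`), which is how the slicewise pipeline treats noisy
#' voxels.
#'
#' @param S_T1 corrected signal(s), arbitrary units.
#' @param k fitted scanner gain (> 0).
#' @param TR repetition time, ms.
#' @return T1 in ms; `NA` where the signal is outside `(0, k)`.
#' @export
se_invert <- function(S_T1, k, TR) {
  if (k <= 0) stop("k must be positive")
  if (TR <= 0) stop("TR must be positive")
  bad <- !is.finite(S_T1) | S_T1 <= 0 | S_T1 >= k
  if (length(S_T1) == 1 && bad)
    stop("S_T1 outside the model range (0, k)")
  out <- S_T1
  out[bad] <- NA_real_
  out[!bad] <- -TR / log(1 - S_T1[!bad] / k)
  out
}

#' MPRAGE steady-state signal
#'
#' Longitudinal magnetization available at the `n`-th readout of the MPRAGE
#' train, in the periodic steady state of the cycle
#' inversion -> TI wait -> N spoiled readouts (flip `alpha`, spacing `TR`) ->
#' Trec recovery.  Perfect inversion and ideal spoiling are assumed, and
#' transverse (T2*) decay at the echo time is neglected, so the image signal
#' is proportional to this magnetization; the `sin(alpha)` receive factor is a
#' T1-independent scale absorbed into `M0`.
#'
#' The steady state is obtained in closed form: with
#' `E1 = exp(-TR/T1)`, `q = cos(alpha) * E1`, the readout train maps the
#' magnetization affinely and the fixed point of the full cycle is solved
#' exactly (geometric sums rather than an iterated recursion).
#'
#' @param T1 longitudinal relaxation time(s), ms; vectorized.
#' @param M0 equilibrium magnetization (scale), > 0.
#' @param params an [mprage_params()] object.
#' @param n 0-based readout index at which the signal is taken; default is the
#'   center of k-space, `floor(N/2) - 1`, which sets the image contrast.
#' @return Magnetization (= signal in arbitrary units), same shape as `T1`.
#'   Linear in `M0`.
#' @examples
#' p <- mprage_params(TR = 8, alpha = 9, TI = 358, Trec = 400, N = 176)
#' mprage_signal(c(832, 1331, 2500), M0 = 1000, p)
#' @export
mprage_signal <- function(T1, M0, params, n = NULL) {
  stopifnot(inherits(params, "mprage_params"))
  if (any(T1 <= 0, na.rm = TRUE)) stop("T1 must be positive")
  if (any(M0 <= 0)) stop("M0 must be positive")
  N <- params$N
  if (is.null(n)) n <- N %/% 2 - 1
  if (n < 0 || n >= N) stop("readout index n must be in [0, N)")

  ca <- cos(params$alpha * pi / 180)
  E1 <- exp(-params$TR / T1)
  EI <- exp(-params$TI / T1)
  Er <- exp(-params$Trec / T1)
  q  <- ca * E1

  geom <- function(m) (1 - q^m) / (1 - q)  # sum_{i=0}^{m-1} q^i, q < 1

  # magnetization after the full readout train, as an affine map of the
  # magnetization at the first flip: M_end = (1-E1)*G_N + q^N * M_first
  # (units of M0); the cycle fixed point gives the pre-inversion steady state.
  qN  <- q^N
  GN  <- geom(N)
  a   <- (1 - Er) + Er * ((1 - E1) * GN + qN * (1 - EI))
  b   <- -Er * qN * EI
  Mss <- a / (1 - b)                       # pre-inversion Mz / M0

  Mfirst <- (1 - EI) - Mss * EI            # after inversion + TI recovery
  Mn <- (1 - E1) * geom(n) + q^n * Mfirst
  M0 * Mn
}

#' Look-Locker apparent recovery curve
#'
#' Signal of the three-parameter apparent inversion-recovery model,
#' `S(TI) = A - B * exp(-TI / T1star)` (decaying-exponential convention).
#'
#' @param TI inversion time(s), ms (>= 0); vectorized.
#' @param fit a [looklocker_fit()] object.
#' @return Signal in arbitrary units.
#' @export
looklocker_signal <- function(TI, fit) {
  stopifnot(inherits(fit, "looklocker_fit"))
  if (any(TI < 0)) stop("TI must be non-negative")
  fit$A - fit$B * exp(-TI / fit$T1star)
}

#' Look-Locker correction from apparent to true T1
#'
#' Converts the apparent relaxation time of the Look-Locker readout to the
#' true T1 via `T1 = T1star * (B/A - 1)`.  A fit with `B/A <= 1` has no
#' physically meaningful correction (it would imply non-positive T1) and is
#' flagged invalid.
#'
#' @param fit a [looklocker_fit()] object with `A != 0`.
#' @return True T1 in ms, or `NA` if `B/A <= 1`.
#' @export
looklocker_correct <- function(fit) {
  stopifnot(inherits(fit, "looklocker_fit"))
  if (fit$A == 0) stop("A must be non-zero")
  r <- fit$B / fit$A
  if (!is.finite(r) || r <= 1) return(NA_real_)
  fit$T1star * (r - 1)
}

#' Effective T1 of a two-species voxel
#'
#' Longitudinal relaxation time of a voxel containing two water pools with
#' relaxation times `T1a` and `T1b` at volume fractions `alpha_frac` and
#' `beta_frac` (fast-exchange limit):
#' `T1 = T1a * T1b / (beta_frac * T1a + alpha_frac * T1b)`, a
#' fraction-weighted harmonic combination of the two rates.
#'
#' @param T1a,T1b relaxation times of the two species, ms (> 0).
#' @param alpha_frac,beta_frac volume fractions (>= 0, summing to 1).
#' @return Voxel T1 in ms.
#' @examples
#' mix_t1(832, 1331, 0.5, 0.5)
#' @export
mix_t1 <- function(T1a, T1b, alpha_frac, beta_frac) {
  if (any(T1a <= 0) || any(T1b <= 0)) stop("T1 values must be positive")
  if (any(alpha_frac < 0) || any(beta_frac < 0))
    stop("volume fractions must be non-negative")
  if (any(abs(alpha_frac + beta_frac - 1) > 1e-8))
    stop("volume fractions must sum to 1")
  den <- beta_frac * T1a + alpha_frac * T1b
  if (any(den == 0)) stop("degenerate mixture: zero denominator")
  T1a * T1b / den
}
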