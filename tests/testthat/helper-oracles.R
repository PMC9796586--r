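# Independent oracles and shared fixtures for the test suite.

# Step-by-step Bloch recursion for the MPRAGE steady state: simulates the
# cycle inversion -> TI -> N spoiled readouts -> Trec by explicit looping
# until the probed magnetization converges.  Shares no code with the closed
# form in mprage_signal() (no geometric sums, no fixed-point solve).
bloch_mprage_ss <- function(T1, M0, params, n = params$N %/% 2 - 1) {
  ca <- cos(params$alpha * pi / 180)
  relax <- function(M, t) M0 + (M - M0) * exp(-t / T1)
  M <- M0
  probe_prev <- Inf
  for (cyc in 1:5000) {
    M <- relax(-M, params$TI)
    probe <- NA_real_
    for (i in 0:(params$N - 1)) {
      if (i == n) probe <- M
      M <- relax(ca * M, params$TR)
    }
    M <- relax(M, params$Trec)
    if (abs(probe - probe_prev) < 1e-12 * M0) return(probe)
    probe_prev <- probe
  }
  probe
}

# brute-force census of slices that carry all three reference tissues
census_valid_slices <- function(labels, min_voxels = 50) {
  vapply(seq_len(dim(labels)[3]), function(z) {
    sl <- labels[, , z]
    all(vapply(1:3, function(t) sum(sl == t), 0L) >= min_voxels)
  }, logical(1))
}

# small shared fixtures (built once per test run)
phantom_hom32 <- make_phantom(c(32, 32, 32), seed = 42, heterogeneity = 0)
se_params_default <- spin_echo_params(TR = 525, TE = 10)
hc_mprage <- mprage_params(TR = 8, TE = 2.89, alpha = 9, TI = 358,
                           Trec = 400, N = 176)
ll_tis <- c(150, 400, 750, 1500, 3500)
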