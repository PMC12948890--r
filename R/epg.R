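# Extended phase graph (EPG) forward model of the MESE echo train.
#
# Configuration states are tracked as three complex matrices Fp, Fm, Z with
# one row per dephasing order k = 0..K and one column per T2 value, so a
# whole dictionary column (all T2 at one B1) is simulated in a single pass.
# Ideal crusher gradients are assumed: one unit of gradient dephasing per
# half echo-spacing. CPMG phase convention: excitation about x, refocusing
# about y. K = n_echoes + 1 orders are allocated, enough that no populated
# state is ever shifted out of the state space.

# 3x3 mixing matrix of an RF pulse with flip `alpha` and phase `phi` (rad),
# acting on (Fp_k, Fm_k, Z_k) for every order k.
epg_rotation_matrix <- function(alpha, phi) {
  ca2 <- cos(alpha / 2)^2
  sa2 <- sin(alpha / 2)^2
  sa <- sin(alpha)
  matrix(c(
    ca2,                        exp(2i * phi) * sa2,       -1i * exp(1i * phi) * sa,
    exp(-2i * phi) * sa2,       ca2,                        1i * exp(-1i * phi) * sa,
    -0.5i * exp(-1i * phi) * sa, 0.5i * exp(1i * phi) * sa, cos(alpha) + 0i
  ), nrow = 3, byrow = TRUE)
}

# Complex F0 amplitude at each echo for a vector of T2 values (one flip-angle
# scale). Returns a length(t2) x n_echoes complex matrix.
epg_mese_core <- function(t2, t1, exc_rad, refoc_rad, esp, n_echoes) {
  nt <- length(t2)
  K <- n_echoes + 1L                      # orders 0..K
  nr <- K + 1L
  Fp <- matrix(0 + 0i, nr, nt)
  Fm <- matrix(0 + 0i, nr, nt)
  Z <- matrix(0 + 0i, nr, nt)
  Z[1L, ] <- 1 + 0i

  E2 <- matrix(rep(exp(-(esp / 2) / t2), each = nr), nr, nt)
  e1 <- exp(-(esp / 2) / t1)

  Rx <- epg_rotation_matrix(exc_rad, 0)       # excitation about x
  Ry <- epg_rotation_matrix(refoc_rad, pi / 2) # refocusing about y

  apply_pulse <- function(R) {
    Fp2 <- R[1, 1] * Fp + R[1, 2] * Fm + R[1, 3] * Z
    Fm2 <- R[2, 1] * Fp + R[2, 2] * Fm + R[2, 3] * Z
    Z2 <- R[3, 1] * Fp + R[3, 2] * Fm + R[3, 3] * Z
    Fp <<- Fp2; Fm <<- Fm2; Z <<- Z2
    invisible(NULL)
  }
  # T2/T1 relaxation over ESP/2 followed by one unit of crusher dephasing.
  relax_shift <- function() {
    Fp <<- Fp * E2
    Fm <<- Fm * E2
    Z <<- Z * e1
    Z[1L, ] <<- Z[1L, ] + (1 - e1)
    Fp <<- rbind(Conj(Fm[2L, , drop = FALSE]), Fp[seq_len(nr - 1L), , drop = FALSE])
    Fm <<- rbind(Fm[2:nr, , drop = FALSE], matrix(0 + 0i, 1L, nt))
    invisible(NULL)
  }

  out <- matrix(0 + 0i, nt, n_echoes)
  apply_pulse(Rx)
  for (n in seq_len(n_echoes)) {
    relax_shift()
    apply_pulse(Ry)
    relax_shift()
    out[, n] <- Fp[1L, ]
  }
  out
}

#' Simulate the echo-modulation curve (EMC) of a MESE acquisition
#'
#' Forward-simulates the per-echo signal magnitude of a CPMG multi-echo
#' spin-echo train with an extended phase graph recursion, including the
#' stimulated-echo pathways created by non-180 degree refocusing. The
#' transmit field scale `b1` multiplies both nominal flip angles. For a
#' shaped refocusing pulse the slice is split into sub-slices whose flip
#' angles follow the tabulated profile; their complex signals are summed
#' before taking magnitudes.
#'
#' Absolute signal scale is arbitrary (equilibrium magnetization 1); the
#' dictionary matching step is scale-invariant. T1 relaxation acts on
#' longitudinal states within the train; no inter-TR steady state is
#' modelled (TR is much longer than the train).
#'
#' @param t2 Transverse relaxation time in ms (> 0). May be a vector, in
#'   which case a matrix with one row per T2 is returned by
#'   [simulate_emc_multi()]; `simulate_emc()` expects a scalar.
#' @param t1 Longitudinal relaxation time in ms (> 0), default 1000.
#' @param b1 Transmit field scale, 1.0 = nominal flip angles.
#' @param seq A [mese_sequence()].
#' @return A list of class `echo_curve` with `echo_times` (ms) and
#'   `amplitudes` (non-negative magnitudes, length `n_echoes`).
#' @examples
#' seq <- mese_sequence()
#' emc <- simulate_emc(t2 = 40, b1 = 1, seq = seq)
#' plot(emc$echo_times, emc$amplitudes, type = "b")
#' @export
simulate_emc <- function(t2, t1 = 1000, b1 = 1, seq = mese_sequence()) {
  stopifnot(length(t2) == 1L)
  amp <- simulate_emc_multi(t2, t1 = t1, b1 = b1, seq = seq)
  structure(list(echo_times = echo_train(seq), amplitudes = as.vector(amp)),
            class = "echo_curve")
}

#' @rdname simulate_emc
#' @return `simulate_emc_multi()` returns a `length(t2) x n_echoes` matrix
#'   of magnitudes.
#' @export
simulate_emc_multi <- function(t2, t1 = 1000, b1 = 1, seq = mese_sequence()) {
  stopifnot(inherits(seq, "mese_sequence"))
  if (any(!is.finite(t2)) || any(t2 <= 0))
    stop("`t2` must be strictly positive", call. = FALSE)
  if (!is.finite(t1) || t1 <= 0)
    stop("`t1` must be strictly positive", call. = FALSE)
  if (!is.finite(b1) || b1 <= 0)
    stop("`b1` must be strictly positive", call. = FALSE)
  deg2rad <- pi / 180
  acc <- matrix(0 + 0i, length(t2), seq$n_echoes)
  for (w in seq$pulse_profile) {
    acc <- acc + epg_mese_core(
      t2, t1,
      exc_rad = b1 * w * seq$exc_deg * deg2rad,
      refoc_rad = b1 * w * seq$refoc_deg * deg2rad,
      esp = seq$esp_ms, n_echoes = seq$n_echoes)
  }
  Mod(acc) / seq$slice_subdivisions
}

#' @export
print.echo_curve <- function(x, ...) {
  cat(sprintf("Echo-modulation curve, %d echoes (TE %g-%g ms)\n",
              length(x$amplitudes), min(x$echo_times), max(x$echo_times)))
  print(data.frame(echo_time_ms = x$echo_times, amplitude = x$amplitudes),
        row.names = FALSE)
  invisible(x)
}

#' Write an echo curve as CSV
#'
#' @param curve An `echo_curve` from [simulate_emc()].
#' @param path Output CSV path; columns `echo_time_ms`, `amplitude`.
#' @export
write_echo_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(echo_time_ms = curve$echo_times, amplitude = curve$amplitudes),
    path, row.names = FALSE)
  invisible(path)
}
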