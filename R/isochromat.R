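#' Brute-force isochromat Bloch simulation of a MESE train
#'
#' Independent time-domain oracle for [simulate_emc()]: an ensemble of
#' isochromats is propagated through the CPMG train with explicit 3x3
#' rotation/relaxation operations. Each half echo-spacing every isochromat
#' accrues a crusher-gradient phase; the ensemble spans 2*pi of dephasing
#' per half-period on an offset uniform grid, so unrefocused coherences
#' average to zero exactly (ideal crushing) and the echo amplitudes
#' converge to the extended-phase-graph result as the ensemble grows.
#'
#' This function shares no code with the EPG recursion and is kept in the
#' test suite as a verification oracle.
#'
#' @inheritParams simulate_emc
#' @param n_isochromats Ensemble size (>= 1000).
#' @return An `echo_curve` (see [simulate_emc()]).
#' @export
isochromat_mese <- function(t2, t1 = 1000, b1 = 1, seq = mese_sequence(),
                            n_isochromats = 10000L) {
  stopifnot(inherits(seq, "mese_sequence"))
  if (n_isochromats < 1000)
    stop("`n_isochromats` must be >= 1000", call. = FALSE)
  if (!is.finite(t2) || t2 <= 0 || !is.finite(t1) || t1 <= 0)
    stop("relaxation times must be strictly positive", call. = FALSE)
  n <- as.integer(n_isochromats)
  theta <- 2 * pi * (seq_len(n) - 0.5) / n   # dephasing per half-period
  ct <- cos(theta); st <- sin(theta)
  esp <- seq$esp_ms
  e2 <- exp(-(esp / 2) / t2)
  e1 <- exp(-(esp / 2) / t1)
  deg2rad <- pi / 180

  acc_x <- numeric(seq$n_echoes)
  acc_y <- numeric(seq$n_echoes)
  for (w in seq$pulse_profile) {
    a_exc <- b1 * w * seq$exc_deg * deg2rad
    a_ref <- b1 * w * seq$refoc_deg * deg2rad
    mx <- numeric(n); my <- numeric(n); mz <- rep(1, n)
    # excitation about x
    my2 <- cos(a_exc) * my + sin(a_exc) * mz
    mz <- -sin(a_exc) * my + cos(a_exc) * mz
    my <- my2
    half_period <- function() {
      mx <<- mx * e2; my <<- my * e2
      mz <<- 1 + (mz - 1) * e1
      mx2 <- ct * mx - st * my
      my <<- st * mx + ct * my
      mx <<- mx2
      invisible(NULL)
    }
    cr <- cos(a_ref); sr <- sin(a_ref)
    for (k in seq_len(seq$n_echoes)) {
      half_period()
      # refocusing about y
      mx2 <- cr * mx - sr * mz
      mz <- sr * mx + cr * mz
      mx <- mx2
      half_period()
      acc_x[k] <- acc_x[k] + mean(mx)
      acc_y[k] <- acc_y[k] + mean(my)
    }
  }
  s <- seq$slice_subdivisions
  structure(list(echo_times = echo_train(seq),
                 amplitudes = sqrt((acc_x / s)^2 + (acc_y / s)^2)),
            class = "echo_curve")
}
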