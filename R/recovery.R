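# Timepoint deltas and the Proportional Recovery Index (PRI) across the
# rest -> post-run (21k) -> one-week control design.

#' Proportional Recovery Index
#'
#' `PRI = (t2_control - t2_21k) / (t2_rest - t2_21k)`: the ratio between the
#' T2 recovery from post-run to control and the run-induced T2 reduction
#' from rest to post-run. PRI = 1 means complete recovery to baseline,
#' PRI < 1 incomplete recovery, PRI > 1 overcompensation; negative values
#' mean the change continued in the run direction. Undefined (NA, with a
#' warning) when rest and post-run values coincide.
#'
#' @param t2_rest,t2_21k,t2_control T2 values in ms (vectorized).
#' @return Dimensionless PRI (full precision; reports round to one decimal).
#' @examples
#' compute_pri(43.1, 42.2, 43.1)  # 1: complete recovery
#' compute_pri(40.9, 39.3, 43.4)  # 2.5625: overcompensation
#' @export
compute_pri <- function(t2_rest, t2_21k, t2_control) {
  den <- t2_rest - t2_21k
  out <- ifelse(den == 0, NA_real_, (t2_control - t2_21k) / den)
  if (any(den == 0, na.rm = TRUE))
    warning("PRI undefined where rest and 21k T2 coincide", call. = FALSE)
  out
}

#' Timepoint differences in ms and percent
#'
#' Signed deltas (negative = T2 loss): `delta_run = t2_21k - t2_rest`,
#' `delta_ctrl = t2_control - t2_rest`; percent deltas are relative to the
#' rest value times 100 (NA when rest is zero).
#'
#' @inheritParams compute_pri
#' @return data.frame with `delta_run_ms`, `delta_run_pct`, `delta_ctrl_ms`,
#'   `delta_ctrl_pct`.
#' @export
compute_deltas <- function(t2_rest, t2_21k, t2_control) {
  pct <- function(d) ifelse(t2_rest == 0, NA_real_, 100 * d / t2_rest)
  run <- t2_21k - t2_rest
  ctrl <- t2_control - t2_rest
  data.frame(delta_run_ms = run, delta_run_pct = pct(run),
             delta_ctrl_ms = ctrl, delta_ctrl_pct = pct(ctrl))
}

#' Summarize recovery over a group of samples
#'
#' Mirrors the study's mixed reporting convention: the ms/percent delta
#' columns are mean +- SD of the per-sample deltas, while the group PRI is
#' computed from the group-mean T2 triplet (this is the convention that
#' reproduces the published tables; both levels are returned).
#'
#' @param t2_rest,t2_21k,t2_control Per-sample T2 values (equal length >= 1).
#' @return One-row data.frame: `n`, per-timepoint mean/sd, delta summaries,
#'   `pri` (group-mean level) and `pri_sample_mean` (mean of per-sample PRIs
#'   over samples where the per-sample PRI is defined).
#' @export
summarize_group <- function(t2_rest, t2_21k, t2_control) {
  n <- length(t2_rest)
  if (n < 1L || length(t2_21k) != n || length(t2_control) != n)
    stop("need >= 1 complete sample triplet", call. = FALSE)
  d <- compute_deltas(t2_rest, t2_21k, t2_control)
  pri_s <- suppressWarnings(compute_pri(t2_rest, t2_21k, t2_control))
  msd <- function(x) c(mean(x), if (n > 1L) stats::sd(x) else NA_real_)
  data.frame(
    n = n,
    t2_rest_mean = mean(t2_rest), t2_rest_sd = msd(t2_rest)[2],
    t2_21k_mean = mean(t2_21k), t2_21k_sd = msd(t2_21k)[2],
    t2_control_mean = mean(t2_control), t2_control_sd = msd(t2_control)[2],
    delta_run_ms_mean = mean(d$delta_run_ms), delta_run_ms_sd = msd(d$delta_run_ms)[2],
    delta_run_pct_mean = mean(d$delta_run_pct), delta_run_pct_sd = msd(d$delta_run_pct)[2],
    delta_ctrl_ms_mean = mean(d$delta_ctrl_ms), delta_ctrl_ms_sd = msd(d$delta_ctrl_ms)[2],
    delta_ctrl_pct_mean = mean(d$delta_ctrl_pct), delta_ctrl_pct_sd = msd(d$delta_ctrl_pct)[2],
    pri = suppressWarnings(compute_pri(mean(t2_rest), mean(t2_21k), mean(t2_control))),
    pri_sample_mean = if (all(is.na(pri_s))) NA_real_ else mean(pri_s, na.rm = TRUE))
}

# Round half away from zero to `digits` decimals (report convention; R's
# round() would round half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reference group-mean T2 table
#'
#' Published group-mean cartilage T2 values (ms) at the rest, post-run (21k)
#' and one-week control timepoints for the global/laterality/sex groups,
#' anatomic compartments, compartment sections and compartment-by-subgroup
#' strata of an 11-runner half-marathon recovery study, together with the
#' printed delta columns and PRI. Used as regression input for the recovery
#' arithmetic (the imaging data themselves are not public).
#'
#' @return data.frame with columns `table`, `group`, `subgroup`, `n`,
#'   `t2_rest`, `t2_21k`, `t2_control`, `delta_run_ms`, `delta_run_pct`,
#'   `delta_ctrl_ms`, `delta_ctrl_pct`, `pri_printed`.
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "reference_group_means.csv",
                      package = "emcT2", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
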