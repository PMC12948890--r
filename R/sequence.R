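#' Describe a multi-echo spin-echo (MESE) acquisition
#'
#' Bundles the acquisition parameters needed to forward-simulate the
#' echo-modulation curve of a CPMG-style MESE sequence: repetition time,
#' echo spacing, number of echoes, nominal excitation/refocusing flip angles,
#' and the refocusing pulse model (ideal "hard" pulse, or a "shaped" pulse
#' described by a tabulated flip-angle profile across the slice).
#'
#' Defaults reproduce a 3 T knee protocol: TR 2057 ms, 10 evenly spaced
#' echoes 5.9 ms apart (TE 5.9--59 ms), 90/125 degree nominal flip angles.
#'
#' @param tr_ms Repetition time in milliseconds.
#' @param esp_ms Echo spacing in milliseconds (> 0).
#' @param n_echoes Number of echoes (>= 2).
#' @param exc_deg Nominal excitation flip angle in degrees.
#' @param refoc_deg Nominal refocusing flip angle in degrees, in (0, 180].
#' @param pulse_shape `"hard"` (single effective flip angle) or `"shaped"`
#'   (slice subdivided; each sub-slice sees `pulse_profile * flip`).
#' @param slice_subdivisions Number of sub-slices for the shaped model.
#' @param pulse_profile Relative flip-angle weights per sub-slice in (0, 1];
#'   default is a half-sine profile of length `slice_subdivisions`.
#' @return An object of class `mese_sequence`.
#' @examples
#' seq <- mese_sequence()
#' echo_train(seq)
#' @export
mese_sequence <- function(tr_ms = 2057, esp_ms = 5.9, n_echoes = 10L,
                          exc_deg = 90, refoc_deg = 125,
                          pulse_shape = c("hard", "shaped"),
                          slice_subdivisions = 15L,
                          pulse_profile = NULL) {
  pulse_shape <- match.arg(pulse_shape)
  if (!is.numeric(esp_ms) || length(esp_ms) != 1L || !is.finite(esp_ms) || esp_ms <= 0)
    stop("`esp_ms` must be a single positive number", call. = FALSE)
  if (!is.numeric(n_echoes) || length(n_echoes) != 1L || n_echoes < 2 ||
      n_echoes != round(n_echoes))
    stop("`n_echoes` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(tr_ms) || tr_ms <= 0)
    stop("`tr_ms` must be positive", call. = FALSE)
  if (!is.finite(refoc_deg) || refoc_deg <= 0 || refoc_deg > 180)
    stop("`refoc_deg` must lie in (0, 180]", call. = FALSE)
  if (!is.finite(exc_deg))
    stop("`exc_deg` must be finite", call. = FALSE)
  if (slice_subdivisions < 1 || slice_subdivisions != round(slice_subdivisions))
    stop("`slice_subdivisions` must be a positive integer", call. = FALSE)
  if (pulse_shape == "shaped") {
    if (is.null(pulse_profile)) {
      s <- as.integer(slice_subdivisions)
      pulse_profile <- sin(pi * (seq_len(s) - 0.5) / s)
    }
    if (any(!is.finite(pulse_profile)) || any(pulse_profile <= 0) ||
        any(pulse_profile > 1))
      stop("`pulse_profile` weights must lie in (0, 1]", call. = FALSE)
    slice_subdivisions <- length(pulse_profile)
  } else {
    pulse_profile <- 1
    slice_subdivisions <- 1L
  }
  structure(
    list(tr_ms = tr_ms, esp_ms = esp_ms, n_echoes = as.integer(n_echoes),
         exc_deg = exc_deg, refoc_deg = refoc_deg, pulse_shape = pulse_shape,
         slice_subdivisions = as.integer(slice_subdivisions),
         pulse_profile = pulse_profile),
    class = "mese_sequence")
}

#' @export
print.mese_sequence <- function(x, ...) {
  cat(sprintf("MESE sequence: TR %g ms, %d echoes, ESP %g ms (TE %g-%g ms)\n",
              x$tr_ms, x$n_echoes, x$esp_ms, x$esp_ms, x$esp_ms * x$n_echoes))
  cat(sprintf("  flip angles %g/%g deg, %s pulse%s\n", x$exc_deg, x$refoc_deg,
              x$pulse_shape,
              if (x$pulse_shape == "shaped")
                sprintf(" (%d sub-slices)", x$slice_subdivisions) else ""))
  invisible(x)
}

#' Echo times of a MESE acquisition
#'
#' @param seq A [mese_sequence()].
#' @return Numeric vector `c(ESP, 2 ESP, ..., n ESP)` in milliseconds.
#' @examples
#' echo_train(mese_sequence(esp_ms = 5.9, n_echoes = 10))  # ends at 59 ms
#' @export
echo_train <- function(seq) {
  stopifnot(inherits(seq, "mese_sequence"))
  seq$esp_ms * seq_len(seq$n_echoes)
}

#' Read a sequence description from a YAML/JSON config block
#'
#' Accepts the keys `tr_ms`, `esp_ms`, `n_echoes`, `exc_deg`, `refoc_deg`,
#' `pulse_shape`, `slice_subdivisions`, `pulse_profile` (missing keys fall
#' back to the package defaults).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return A [mese_sequence()].
#' @export
read_sequence_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  keys <- c("tr_ms", "esp_ms", "n_echoes", "exc_deg", "refoc_deg",
            "pulse_shape", "slice_subdivisions", "pulse_profile")
  do.call(mese_sequence, cfg[intersect(names(cfg), keys)])
}
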