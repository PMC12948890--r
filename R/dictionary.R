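#' Build a (T2, B1+) dictionary grid
#'
#' Inclusive arithmetic grids over T2 and transmit-field scale. Defaults:
#' T2 from 1 to 300 ms in 1 ms steps (300 values), B1+ from 0.60 to 1.40 in
#' 0.01 steps (81 values), T1 fixed at 1000 ms. Ranges must be exact
#' multiples of the step; no silent truncation.
#'
#' @param t2_min,t2_max,t2_step T2 range and step in ms.
#' @param b1_min,b1_max,b1_step B1+ scale range and step (fractions).
#' @param t1 Fixed T1 in ms used for every atom.
#' @return Object of class `emc_grid` with `t2_values`, `b1_values`, `t1`.
#' @examples
#' g <- build_grid()
#' length(g$t2_values)  # 300
#' length(g$b1_values)  # 81
#' @export
build_grid <- function(t2_min = 1, t2_max = 300, t2_step = 1,
                       b1_min = 0.60, b1_max = 1.40, b1_step = 0.01,
                       t1 = 1000) {
  grid_axis <- function(min, max, step, what) {
    if (!(min < max) && !(min == max)) # allow degenerate single-value axis
      stop(sprintf("%s: min must be <= max", what), call. = FALSE)
    if (step <= 0) stop(sprintf("%s: step must be > 0", what), call. = FALSE)
    k <- (max - min) / step
    if (abs(k - round(k)) > 1e-9)
      stop(sprintf("%s range (%g..%g) is not divisible by step %g",
                   what, min, max, step), call. = FALSE)
    min + step * (0:round(k))
  }
  t2v <- grid_axis(t2_min, t2_max, t2_step, "t2")
  b1v <- grid_axis(b1_min, b1_max, b1_step, "b1")
  if (any(t2v <= 0)) stop("t2 grid must be strictly positive", call. = FALSE)
  if (!is.finite(t1) || t1 <= 0) stop("`t1` must be positive", call. = FALSE)
  structure(list(t2_values = t2v, b1_values = b1v, t1 = t1),
            class = "emc_grid")
}

dictionary_hash <- function(grid, seq, skip_first_echo) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(unclass(grid), unclass(seq), skip_first_echo), tmp,
          compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Build an EMC dictionary of normalized theoretical decay curves
#'
#' Simulates one echo-modulation curve per (T2, B1+) grid pair with the EPG
#' forward model and stores them as rows of a flat atom matrix, each scaled
#' to unit Euclidean norm so that the maximum dot product with a normalized
#' pixel series equals maximum cosine similarity. The build is deterministic;
#' an optional on-disk cache (RDS payload plus JSON metadata sidecar keyed by
#' a content hash of grid and sequence) avoids recomputation.
#'
#' @param grid An `emc_grid` from [build_grid()].
#' @param seq A [mese_sequence()].
#' @param skip_first_echo Drop echo 1 from matching (a common MESE practice);
#'   default `FALSE`, all echoes are used.
#' @param cache_dir Directory for the dictionary cache, or `NULL` (no cache).
#' @return Object of class `emc_dictionary`: `atoms` (n_atoms x n_used_echoes,
#'   unit-norm rows), `t2`/`b1` (per-row grid coordinates), `echo_idx`
#'   (echo indices used), plus `grid`, `seq`, `norm_kind`, `hash`.
#' @examples
#' g <- build_grid(40, 50, 5, 1, 1, 0.01)
#' d <- build_dictionary(g, mese_sequence())
#' dim(d$atoms)
#' @export
build_dictionary <- function(grid, seq = mese_sequence(),
                             skip_first_echo = FALSE, cache_dir = NULL) {
  stopifnot(inherits(grid, "emc_grid"), inherits(seq, "mese_sequence"))
  hash <- dictionary_hash(grid, seq, skip_first_echo)
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir, paste0("emc_dict_", hash, ".rds"))
    if (file.exists(cache_file)) {
      dict <- readRDS(cache_file)
      if (identical(dict$hash, hash)) return(dict)
    }
  }
  echo_idx <- if (skip_first_echo) 2:seq$n_echoes else seq_len(seq$n_echoes)
  nt <- length(grid$t2_values)
  nb <- length(grid$b1_values)
  atoms <- matrix(NA_real_, nt * nb, length(echo_idx))
  # row order: b1 outer, t2 inner -> row index (j-1)*nt + i
  for (j in seq_len(nb)) {
    amp <- simulate_emc_multi(grid$t2_values, t1 = grid$t1,
                              b1 = grid$b1_values[j], seq = seq)
    atoms[(j - 1L) * nt + seq_len(nt), ] <- amp[, echo_idx, drop = FALSE]
  }
  nrm <- sqrt(rowSums(atoms^2))
  atoms <- atoms / nrm
  dict <- structure(
    list(atoms = atoms,
         t2 = rep(grid$t2_values, times = nb),
         b1 = rep(grid$b1_values, each = nt),
         echo_idx = echo_idx, grid = grid, seq = seq,
         norm_kind = "l2", hash = hash),
    class = "emc_dictionary")
  if (!is.null(cache_dir)) {
    ok <- tryCatch({
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(dict, cache_file)
      jsonlite::write_json(
        list(hash = hash, n_atoms = nrow(atoms),
             t2_range_ms = range(grid$t2_values),
             b1_range = range(grid$b1_values), t1_ms = grid$t1,
             echo_idx = echo_idx,
             seq = unclass(seq)[c("tr_ms", "esp_ms", "n_echoes", "exc_deg",
                                  "refoc_deg", "pulse_shape")]),
        sub("\\.rds$", ".json", cache_file), auto_unbox = TRUE)
      TRUE
    }, error = function(e) {
      warning("dictionary cache write failed: ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
  }
  dict
}

#' @export
print.emc_dictionary <- function(x, ...) {
  cat(sprintf(
    "EMC dictionary: %d atoms (%d T2 x %d B1+), %d echoes, T1 = %g ms\n",
    nrow(x$atoms), length(x$grid$t2_values), length(x$grid$b1_values),
    ncol(x$atoms), x$grid$t1))
  cat(sprintf("  T2 %g-%g ms, B1+ %g-%g, hash %s\n",
              min(x$grid$t2_values), max(x$grid$t2_values),
              min(x$grid$b1_values), max(x$grid$b1_values), x$hash))
  invisible(x)
}

# Row index of the atom for (t2, b1); used by tests and readers.
dict_atom_index <- function(dict, t2, b1) {
  i <- match(TRUE, abs(dict$grid$t2_values - t2) < 1e-9)
  j <- match(TRUE, abs(dict$grid$b1_values - b1) < 1e-9)
  if (is.na(i) || is.na(j)) stop("(t2, b1) not on the dictionary grid")
  (j - 1L) * length(dict$grid$t2_values) + i
}
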