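# Pixel-wise T2/B1+ estimation by exhaustive dictionary matching, plus a
# log-linear mono-exponential baseline fit for bias comparison.

# Permutation putting atoms in tie-break priority order: smallest T2 first,
# then B1+ closest to nominal. With rows in this order the first occurrence
# of the maximal score is the wanted match.
match_priority_order <- function(dict) {
  order(dict$t2, abs(dict$b1 - 1), dict$b1)
}

#' Match one pixel echo series against an EMC dictionary
#'
#' The series is L2-normalized and the atom with the maximum dot product
#' (equivalently maximum cosine similarity, since atoms are unit norm) is
#' selected by exhaustive search over the whole grid. Exact score ties are
#' broken towards the smallest T2, then the B1+ closest to 1.00.
#'
#' @param values Numeric vector of echo magnitudes (full train; if the
#'   dictionary was built with `skip_first_echo`, the matching echoes are
#'   selected automatically).
#' @param dict An `emc_dictionary`.
#' @return List with `t2` (ms), `b1`, `score` in `[-1, 1]`, and `valid`
#'   (`FALSE`, with `NA` estimates, for a zero-norm or non-finite series).
#' @examples
#' d <- build_dictionary(build_grid(30, 60, 1, 1, 1, 0.01))
#' p <- simulate_emc(43, 1000, 1, d$seq)$amplitudes
#' match_pixel(p, d)
#' @export
match_pixel <- function(values, dict) {
  stopifnot(inherits(dict, "emc_dictionary"))
  if (length(values) == dict$seq$n_echoes)
    values <- values[dict$echo_idx]
  else if (length(values) != ncol(dict$atoms))
    stop("echo count mismatch between pixel series and dictionary",
         call. = FALSE)
  nrm <- sqrt(sum(values^2))
  if (!all(is.finite(values)) || nrm == 0)
    return(list(t2 = NA_real_, b1 = NA_real_, score = NA_real_, valid = FALSE))
  s <- as.vector(dict$atoms %*% (values / nrm))
  best <- which(s == max(s))
  if (length(best) > 1L) {
    best <- best[order(dict$t2[best], abs(dict$b1[best] - 1))][1L]
  }
  list(t2 = dict$t2[best], b1 = dict$b1[best], score = s[best], valid = TRUE)
}

#' Fit T2/B1+ maps over a masked image series
#'
#' Applies [match_pixel()] to every voxel inside `mask`, in chunks so the
#' score matrix (`pixels x atoms`) stays small. Deterministic; emits one
#' progress message per slice when `verbose = TRUE`.
#'
#' @param series 4-D array `X x Y x Z x n_echoes` of magnitudes.
#' @param mask Logical 3-D array matching the spatial dimensions.
#' @param dict An `emc_dictionary`.
#' @param chunk_size Number of voxels matched per matrix product.
#' @param verbose Log per-slice progress via [message()].
#' @return A `quant_maps` list: `t2_map`, `b1_map`, `score_map` (3-D arrays,
#'   `NA` outside the mask and for invalid pixels) and `validity_mask`.
#' @export
fit_map <- function(series, mask, dict, chunk_size = 500L, verbose = FALSE) {
  stopifnot(inherits(dict, "emc_dictionary"))
  dm <- dim(series)
  if (length(dm) != 4L)
    stop("`series` must be a 4-D array (X x Y x Z x echoes)", call. = FALSE)
  if (dm[4L] != dict$seq$n_echoes)
    stop("echo count mismatch between series and dictionary", call. = FALSE)
  sp <- dm[1:3]
  if (!identical(dim(mask), as.integer(sp)) && !identical(dim(mask), sp))
    stop("mask shape must match the spatial shape of `series`", call. = FALSE)

  t2_map <- array(NA_real_, sp)
  b1_map <- array(NA_real_, sp)
  score_map <- array(NA_real_, sp)
  validity <- array(FALSE, sp)

  ord <- match_priority_order(dict)
  atoms_t <- t(dict$atoms[ord, , drop = FALSE])  # echoes x atoms
  t2_ord <- dict$t2[ord]
  b1_ord <- dict$b1[ord]

  vox <- matrix(series, prod(sp), dm[4L])[, dict$echo_idx, drop = FALSE]
  idx_all <- which(mask)
  if (length(idx_all)) {
    slice_of <- ((idx_all - 1L) %/% (sp[1L] * sp[2L])) + 1L
    for (z in sort(unique(slice_of))) {
      idx <- idx_all[slice_of == z]
      P <- vox[idx, , drop = FALSE]
      nrm <- sqrt(rowSums(P^2))
      ok <- is.finite(nrm) & nrm > 0 & apply(is.finite(P), 1L, all)
      if (any(ok)) {
        Pn <- P[ok, , drop = FALSE] / nrm[ok]
        iok <- idx[ok]
        for (start in seq(1L, nrow(Pn), by = chunk_size)) {
          rows <- start:min(start + chunk_size - 1L, nrow(Pn))
          S <- Pn[rows, , drop = FALSE] %*% atoms_t
          best <- max.col(S, ties.method = "first")
          ii <- iok[rows]
          t2_map[ii] <- t2_ord[best]
          b1_map[ii] <- b1_ord[best]
          score_map[ii] <- S[cbind(seq_along(rows), best)]
          validity[ii] <- TRUE
        }
      }
      if (verbose)
        message(sprintf("fit_map: slice %d, %d voxels matched", z, sum(ok)))
    }
  }
  structure(list(t2_map = t2_map, b1_map = b1_map, score_map = score_map,
                 validity_mask = validity),
            class = "quant_maps")
}

#' Mono-exponential T2 fit (log-linear least squares)
#'
#' Baseline estimator: ordinary least squares of `log(signal)` against echo
#' time over the strictly positive samples; `t2 = -1/slope`. Biased for
#' non-180 degree refocusing because stimulated echoes make the decay
#' non-mono-exponential; kept for comparison with dictionary matching.
#'
#' @param values Echo magnitudes.
#' @param echo_times Echo times in ms, same length.
#' @return Estimated T2 in ms, or `NA` when fewer than 2 positive samples
#'   remain or the fitted slope is non-negative.
#' @export
fit_monoexponential <- function(values, echo_times) {
  stopifnot(length(values) == length(echo_times))
  keep <- is.finite(values) & values > 0
  if (sum(keep) < 2L) return(NA_real_)
  x <- echo_times[keep]
  y <- log(values[keep])
  slope <- stats::cov(x, y) / stats::var(x)
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  -1 / slope
}
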