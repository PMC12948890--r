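# WORMS-derived cartilage region scheme: 16 base labels (12 condyle
# sections, 4 patellofemoral plates) and pixel-pooling aggregates, giving
# the 25 reported regions.

.base_labels <- c(
  LF_a = 1L, LF_c = 2L, LF_p = 3L,
  LT_a = 4L, LT_c = 5L, LT_p = 6L,
  MF_a = 7L, MF_c = 8L, MF_p = 9L,
  MT_a = 10L, MT_c = 11L, MT_p = 12L,
  LPpf = 13L, LFpf = 14L, Pt = 15L, Ft = 16L)

#' Cartilage region scheme (WORMS-derived)
#'
#' Base labels are the 12 condyle plate sections (`{LF, LT, MF, MT} x
#' {anterior (a), central (c), posterior (p)}`) plus the four patellofemoral
#' plates (`LPpf`, `LFpf`, `Pt`, `Ft`), each an integer code in a label map.
#' Aggregates are pixel unions: the four condyle plates `LF`, `LT`, `MF`,
#' `MT`; lateral/medial condyles `LatC = LF + LT`, `MedC = MF + MT`;
#' `LPF = LPpf + LFpf`; `TrPF = Pt + Ft`; and `T2Tot` pooling every base
#' label once. The full reported set has 25 regions; the condyle-only
#' variant (no patellofemoral labels, no total) has 18.
#'
#' @param include_patellofemoral Include the patellofemoral labels and their
#'   aggregates (and `T2Tot`); `FALSE` gives the 18-region condyle subset.
#' @return Object of class `region_scheme` with `base` (named codes),
#'   `aggregates` (named lists of base-label names) and `regions` (canonical
#'   reporting order).
#' @examples
#' length(enumerate_regions(region_scheme()))         # 25
#' length(enumerate_regions(region_scheme(FALSE)))    # 18
#' @export
region_scheme <- function(include_patellofemoral = TRUE) {
  base <- .base_labels
  if (!include_patellofemoral)
    base <- base[!names(base) %in% c("LPpf", "LFpf", "Pt", "Ft")]
  sect <- function(p) paste0(p, c("_a", "_c", "_p"))
  agg <- list(
    LF = sect("LF"), LT = sect("LT"), MF = sect("MF"), MT = sect("MT"),
    LatC = c(sect("LF"), sect("LT")),
    MedC = c(sect("MF"), sect("MT")))
  regions <- c(sect("LF"), sect("LT"), sect("MF"), sect("MT"),
               "LF", "LT", "MF", "MT", "LatC", "MedC")
  if (include_patellofemoral) {
    agg$LPF <- c("LPpf", "LFpf")
    agg$TrPF <- c("Pt", "Ft")
    agg$T2Tot <- names(base)
    regions <- c(regions, "LPpf", "LFpf", "LPF", "Pt", "Ft", "TrPF", "T2Tot")
  }
  structure(list(base = base, aggregates = agg, regions = regions),
            class = "region_scheme")
}

#' Canonical ordered list of reported regions
#'
#' Order: condyle sections, plate aggregates, condyle aggregates,
#' patellofemoral, total.
#'
#' @param scheme A [region_scheme()].
#' @return Character vector of region names (25 for the default scheme).
#' @export
enumerate_regions <- function(scheme = region_scheme()) {
  stopifnot(inherits(scheme, "region_scheme"))
  scheme$regions
}

# Base-label integer codes belonging to a reported region.
region_codes <- function(scheme, region) {
  if (region %in% names(scheme$base)) return(unname(scheme$base[region]))
  if (region %in% names(scheme$aggregates))
    return(unname(scheme$base[scheme$aggregates[[region]]]))
  stop(sprintf("unknown region '%s'", region), call. = FALSE)
}

#' Synovial fluid exclusion filter
#'
#' Retains, within an ROI, exactly the voxels with a valid dictionary match
#' and fitted T2 less than or equal to the threshold; voxels with T2
#' strictly greater than the cutoff are treated as synovial fluid and
#' removed. Idempotent.
#'
#' @param maps A `quant_maps` object from [fit_map()].
#' @param roi_mask Logical array selecting the ROI.
#' @param threshold_ms Fluid cutoff in ms (default 100).
#' @return Logical array: filtered ROI mask.
#' @export
fluid_filter <- function(maps, roi_mask, threshold_ms = 100) {
  stopifnot(inherits(maps, "quant_maps"), threshold_ms > 0)
  keep <- roi_mask & maps$validity_mask &
    !is.na(maps$t2_map) & maps$t2_map <= threshold_ms
  keep[is.na(keep)] <- FALSE
  if (any(roi_mask, na.rm = TRUE) && !any(keep))
    warning("fluid filter removed every voxel in the ROI", call. = FALSE)
  keep
}

#' Per-region T2 statistics for one cartilage sample
#'
#' Computes, for every reported region of the scheme, the mean and sample
#' standard deviation (n - 1 denominator) of fluid-filtered T2 over the
#' voxels carrying that region's base labels. Aggregates pool pixels, not
#' section means. Regions emptied by the filter (or absent from the label
#' map) are dropped with a warning naming them.
#'
#' @param maps A `quant_maps` object from [fit_map()].
#' @param labels Integer array of base-label codes (0 = background), same
#'   spatial shape as the maps.
#' @param scheme A [region_scheme()].
#' @param key Named list or one-row data.frame of sample bookkeeping copied
#'   onto every output row (e.g. participant, knee, dominance, slice,
#'   timepoint, sex).
#' @param fluid_threshold_ms Synovial fluid cutoff passed to [fluid_filter()].
#' @return data.frame with the key columns plus `region`, `mean_t2_ms`,
#'   `sd_t2_ms`, `n_pixels`.
#' @export
region_stats <- function(maps, labels, scheme = region_scheme(),
                         key = list(), fluid_threshold_ms = 100) {
  stopifnot(inherits(maps, "quant_maps"), inherits(scheme, "region_scheme"))
  if (!identical(dim(labels), dim(maps$t2_map)))
    stop("label map shape must match the maps", call. = FALSE)
  codes_seen <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(codes_seen, unname(scheme$base))
  if (length(unknown))
    stop("unknown label code(s) in label map: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  keep <- suppressWarnings(
    fluid_filter(maps, labels > 0, threshold_ms = fluid_threshold_ms))
  key <- as.data.frame(key, stringsAsFactors = FALSE)
  rows <- lapply(scheme$regions, function(rg) {
    sel <- keep & array(labels %in% region_codes(scheme, rg), dim(labels))
    n <- sum(sel)
    if (n == 0L) {
      warning(sprintf("region '%s' is empty after filtering; row dropped", rg),
              call. = FALSE)
      return(NULL)
    }
    vals <- maps$t2_map[sel]
    stats_df <- data.frame(region = rg, mean_t2_ms = mean(vals),
                           sd_t2_ms = if (n > 1L) stats::sd(vals) else NA_real_,
                           n_pixels = n, stringsAsFactors = FALSE)
    if (ncol(key)) cbind(key[1L, , drop = FALSE], stats_df, row.names = NULL)
    else stats_df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write or read a region scheme as JSON
#'
#' @param scheme A [region_scheme()].
#' @param path JSON file path.
#' @return `read_region_scheme()` returns a `region_scheme`.
#' @export
write_region_scheme <- function(scheme, path) {
  jsonlite::write_json(
    list(base = as.list(scheme$base), aggregates = scheme$aggregates,
         regions = scheme$regions),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_scheme
#' @export
read_region_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(base = unlist(x$base),
                 aggregates = lapply(x$aggregates, as.character),
                 regions = as.character(x$regions)),
            class = "region_scheme")
}
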