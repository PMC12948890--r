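# Orchestration: dictionary -> per-pixel fit -> ROI statistics -> recovery
# and longitudinal tests, shaped like the study's report tables.

# Per-sample complete-case triplet matrix for one region (optionally
# filtered to a subgroup), columns rest / 21k / control.
region_triplets <- function(roi, region, filter = NULL) {
  d <- roi[roi$region == region, , drop = FALSE]
  if (!is.null(filter)) d <- d[filter(d), , drop = FALSE]
  if (!nrow(d)) return(NULL)
  d$sample <- paste(d$participant, d$knee, d$slice, sep = "_")
  w <- stats::reshape(d[, c("sample", "timepoint", "mean_t2_ms")],
                      idvar = "sample", timevar = "timepoint",
                      direction = "wide")
  names(w) <- sub("^mean_t2_ms\\.", "", names(w))
  need <- c("rest", "21k", "control")
  if (!all(need %in% names(w))) return(NULL)
  w <- w[stats::complete.cases(w[, need]), , drop = FALSE]
  if (!nrow(w)) return(NULL)
  m <- as.matrix(w[, need])
  rownames(m) <- w$sample
  m
}

# One report row: group summary + test battery p-values.
recovery_row <- function(trip, group_label, subgroup_label = "") {
  s <- summarize_group(trip[, "rest"], trip[, "21k"], trip[, "control"])
  if (nrow(trip) >= 3L) {
    tt <- timepoint_test(trip)
    p_run <- tt$pairwise$p_bonferroni[1]
    p_ctrl <- tt$pairwise$p_bonferroni[2]
    p_omni <- tt$p_omnibus
    method <- tt$method
  } else {
    p_run <- p_ctrl <- p_omni <- NA_real_
    method <- "none"
  }
  cbind(data.frame(group = group_label, subgroup = subgroup_label,
                   stringsAsFactors = FALSE),
        s,
        data.frame(p_omnibus = p_omni, p_run = p_run, p_ctrl = p_ctrl,
                   method = method, stringsAsFactors = FALSE))
}

#' Recovery/statistics report over a ROI table
#'
#' Builds one row per (region, subgroup) with the group T2 summary, delta
#' columns, PRI from the group-mean triplet, and the longitudinal test
#' battery (planned rest-vs-21k and rest-vs-control Bonferroni p-values;
#' omnibus RM-ANOVA or Friedman depending on the normality screen).
#' Samples with incomplete timepoint triplets are excluded.
#'
#' @param roi ROI table as produced by [region_stats()] rows bound together,
#'   with columns `participant`, `knee`, `dominance`, `sex`, `slice`,
#'   `timepoint`, `region`, `mean_t2_ms`.
#' @param regions Regions to report (default: every region present).
#' @param by `"none"` for pooled rows, or `"laterality"` / `"sex"` /
#'   `"both"` to stratify each region.
#' @return data.frame, one row per region x subgroup.
#' @export
recovery_report <- function(roi, regions = unique(roi$region),
                            by = c("none", "laterality", "sex", "both")) {
  by <- match.arg(by)
  subs <- switch(by,
    none = list(list(label = "", filter = NULL)),
    laterality = list(
      list(label = "Left", filter = function(d) d$knee == "left"),
      list(label = "Right", filter = function(d) d$knee == "right")),
    sex = list(
      list(label = "Male", filter = function(d) d$sex == "male"),
      list(label = "Female", filter = function(d) d$sex == "female")),
    both = list(
      list(label = "Left", filter = function(d) d$knee == "left"),
      list(label = "Right", filter = function(d) d$knee == "right"),
      list(label = "Male", filter = function(d) d$sex == "male"),
      list(label = "Female", filter = function(d) d$sex == "female")))
  rows <- list()
  for (rg in regions) {
    for (sb in subs) {
      trip <- region_triplets(roi, rg, sb$filter)
      if (is.null(trip)) next
      rows[[length(rows) + 1L]] <- recovery_row(trip, rg, sb$label)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Report rounding convention: T2/deltas/percent/PRI to one decimal
# (half away from zero), p-values to three decimals.
round_report <- function(report) {
  one <- grep("^(t2_|delta_|pri)", names(report), value = TRUE)
  for (cl in one) report[[cl]] <- round_half_up(report[[cl]], 1)
  for (cl in grep("^p_", names(report), value = TRUE))
    report[[cl]] <- round_half_up(report[[cl]], 3)
  report
}

#' Run the full synthetic-study pipeline
#'
#' Dictionary build, per-pixel dictionary matching of every image series,
#' fluid-filtered per-region statistics per sample and timepoint, and the
#' four report tables (global/laterality/sex on total cartilage T2; by
#' compartment; by section; compartment by laterality/sex). Incomplete
#' timepoint triplets are excluded, mirroring motion-artefact dropout.
#'
#' @param study A `synthetic_study` from [make_study()].
#' @param grid Dictionary grid (default [build_grid()]).
#' @param dict Optional prebuilt `emc_dictionary` (overrides `grid`).
#' @param scheme A [region_scheme()].
#' @param out_dir If non-NULL, write `rois.csv`, the four report CSVs and a
#'   `provenance.json` sidecar there.
#' @param verbose Log progress.
#' @return List of class `study_report`: `roi` (per-sample region table),
#'   `reports` (named list of rounded report data.frames), `reports_raw`
#'   (unrounded), `dictionary_hash`.
#' @export
run_study <- function(study, grid = build_grid(), dict = NULL,
                      scheme = region_scheme(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(dict)) dict <- build_dictionary(grid, study$seq)
  roi <- list()
  for (nm in names(study$images)) {
    img <- study$images[[nm]]
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    participant <- parts[1]; knee <- parts[2]; tp <- parts[3]
    mrow <- study$manifest[study$manifest$participant == participant &
                             study$manifest$knee == knee, ][1, ]
    maps <- fit_map(img$series, img$labels > 0, dict)
    for (z in seq_len(dim(img$series)[3])) {
      slice_maps <- structure(list(
        t2_map = img$labels[, , z, drop = FALSE] * NA_real_,
        b1_map = NULL, score_map = NULL, validity_mask = NULL),
        class = "quant_maps")
      slice_maps$t2_map <- maps$t2_map[, , z, drop = FALSE]
      slice_maps$b1_map <- maps$b1_map[, , z, drop = FALSE]
      slice_maps$score_map <- maps$score_map[, , z, drop = FALSE]
      slice_maps$validity_mask <- maps$validity_mask[, , z, drop = FALSE]
      key <- list(participant = participant, knee = knee,
                  dominance = mrow$dominance, sex = mrow$sex,
                  slice = z, timepoint = tp)
      rs <- withCallingHandlers(
        region_stats(slice_maps, img$labels[, , z, drop = FALSE],
                     scheme = scheme, key = key),
        warning = function(w) {
          if (verbose) message(nm, ": ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      roi[[length(roi) + 1L]] <- rs
    }
    if (verbose) message("fitted ", nm)
  }
  roi <- do.call(rbind, roi)

  comp <- c("LF", "LT", "MF", "MT", "LatC", "MedC", "LPF", "TrPF")
  sect <- c("LF_a", "LF_c", "LF_p", "LT_a", "LT_c", "LT_p",
            "MF_a", "MF_c", "MF_p", "MT_a", "MT_c", "MT_p",
            "LPpf", "LFpf", "Pt", "Ft")
  reports_raw <- list(
    global = rbind(
      {
        r <- recovery_report(roi, "T2Tot", by = "none")
        if (!is.null(r)) { r$group <- "Total"; r }
      },
      recovery_report(roi, "T2Tot", by = "both")),
    compartment = recovery_report(roi, intersect(comp, roi$region), by = "none"),
    section = recovery_report(roi, intersect(sect, roi$region), by = "none"),
    subgroup = recovery_report(roi, intersect(comp, roi$region), by = "both"))
  reports <- lapply(reports_raw, round_report)

  out <- structure(list(roi = roi, reports = reports,
                        reports_raw = reports_raw,
                        dictionary_hash = dict$hash),
                   class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(roi, file.path(out_dir, "rois.csv"), row.names = FALSE)
    for (nm in names(reports))
      utils::write.csv(reports[[nm]],
                       file.path(out_dir, paste0("report_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(dictionary_hash = dict$hash,
           package_version = as.character(utils::packageVersion("emcT2")),
           seed = study$spec$seed, n_samples = nrow(study$manifest),
           noise = study$spec$noise, snr = study$spec$snr),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
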