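# Synthetic three-timepoint MESE knee phantom: schematic cartilage plates
# (curved femoral bands, flat tibial/patellofemoral bands) labeled with the
# WORMS-derived base scheme, fluid pixels above the cutoff, smooth or
# constant B1+ fields, and Rician/Gaussian noise. The geometry is schematic
# on purpose: the pipeline is geometry-agnostic, and the generator's job is
# to provide known ground truth for every downstream stage.

# Per-section baseline T2 (ms): published rest-column compartment values.
.default_baseline_t2 <- c(
  LF_a = 45.8, LF_c = 42.7, LF_p = 46.3,
  LT_a = 35.4, LT_c = 31.0, LT_p = 42.7,
  MF_a = 47.0, MF_c = 40.7, MF_p = 49.9,
  MT_a = 44.0, MT_c = 37.5, MT_p = 41.0,
  LPpf = 41.4, LFpf = 47.0, Pt = 43.4, Ft = 44.6)

#' Specify a synthetic knee phantom
#'
#' Defaults emulate the study conditions: per-section baseline T2 from the
#' published rest-column values (~31-50 ms), synovial fluid well above the
#' 100 ms exclusion cutoff, a global -2 percent post-run T2 change with full
#' recovery at control, first-echo SNR 50 and Rician noise.
#'
#' @param nx,ny In-plane matrix size.
#' @param n_slices Number of slices (the study design uses 3).
#' @param baseline_t2 Named vector of per-base-label baseline T2 (ms); names
#'   must match the base labels of [region_scheme()]. A single unnamed value
#'   is applied to every label.
#' @param fluid_t2 T2 assigned to synovial fluid pixels (ms; > 100).
#' @param effect_21k,effect_control Percent T2 change at the post-run and
#'   control timepoints relative to rest; scalar (global) or named per-label
#'   vector. Defaults: -2 percent at 21k, 0 (full recovery) at control.
#' @param b1_model `"constant"` or `"smooth"` (a smooth second-order
#'   polynomial field clipped to [0.60, 1.40] and quantized to the 0.01
#'   dictionary step so on-grid closed loops stay exact).
#' @param b1_value B1+ scale for the constant model / center of the smooth one.
#' @param noise `"none"`, `"gaussian"` or `"rician"`.
#' @param snr First-echo signal-to-noise ratio defining the channel sigma.
#' @param seed Integer seed for all phantom randomness.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 96, ny = 96, n_slices = 3,
                         baseline_t2 = .default_baseline_t2,
                         fluid_t2 = 150,
                         effect_21k = -2.0, effect_control = 0.0,
                         b1_model = c("constant", "smooth"), b1_value = 1.0,
                         noise = c("rician", "gaussian", "none"), snr = 50,
                         seed = 1L) {
  b1_model <- match.arg(b1_model)
  noise <- match.arg(noise)
  labs <- names(.default_baseline_t2)
  if (length(baseline_t2) == 1L && is.null(names(baseline_t2)))
    baseline_t2 <- stats::setNames(rep(baseline_t2, length(labs)), labs)
  if (!all(labs %in% names(baseline_t2)))
    stop("`baseline_t2` must name every base label", call. = FALSE)
  baseline_t2 <- baseline_t2[labs]
  if (any(baseline_t2 <= 0) || any(baseline_t2 > 300))
    stop("baseline T2 must lie inside the dictionary range", call. = FALSE)
  if (fluid_t2 <= 100 || fluid_t2 > 300)
    stop("`fluid_t2` must exceed the 100 ms fluid cutoff and stay in-grid",
         call. = FALSE)
  expand_effect <- function(e) {
    if (length(e) == 1L && is.null(names(e)))
      e <- stats::setNames(rep(e, length(labs)), labs)
    if (!all(labs %in% names(e)))
      stop("per-label effects must name every base label", call. = FALSE)
    e[labs]
  }
  effect_21k <- expand_effect(effect_21k)
  effect_control <- expand_effect(effect_control)
  if (any(baseline_t2 * (1 + effect_21k / 100) <= 0) ||
      any(baseline_t2 * (1 + effect_control / 100) <= 0))
    stop("effects must leave T2 positive at all timepoints", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 n_slices = as.integer(n_slices),
                 baseline_t2 = baseline_t2, fluid_t2 = fluid_t2,
                 effect_21k = effect_21k, effect_control = effect_control,
                 b1_model = b1_model, b1_value = b1_value,
                 noise = noise, snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Paint a set of pixel indices with a label, refusing overlaps.
paint <- function(lab_img, idx, code) {
  if (any(lab_img[idx] != 0L))
    stop("phantom construction error: labels would overlap", call. = FALSE)
  lab_img[idx] <- code
  lab_img
}

# One slice of base labels + fluid mask. Femoral plates are annular arcs,
# tibial plateaus flat bands split into thirds, patellofemoral plates small
# bands; fluid lines one superficial margin of each condyle structure.
phantom_slice_labels <- function(nx, ny, slice = 1L) {
  codes <- .base_labels
  lab <- matrix(0L, nx, ny)
  fluid <- matrix(FALSE, nx, ny)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  dr <- (slice - 1L) * 0.5  # slight per-slice radial offset

  arc <- function(cx, cy, r0, r1, a0, a1) {
    r <- sqrt((xs - cx)^2 + (ys - cy)^2)
    ang <- (atan2(ys - cy, xs - cx) * 180 / pi) %% 360
    which(r >= r0 & r < r1 & ang >= a0 & ang < a1)
  }
  band <- function(x0, x1, y0, y1)
    which(xs >= x0 & xs < x1 & ys >= y0 & ys < y1)

  sx <- nx / 96; sy <- ny / 96  # geometry scales with matrix size
  # lateral structures on the left half, medial on the right (schematic)
  for (side in c("L", "M")) {
    cx <- (if (side == "L") 26 else 70) * sx
    cy <- 40 * sy
    r0 <- 16 * min(sx, sy) + dr; r1 <- r0 + 4 * min(sx, sy)
    pre <- paste0(side, "F_")
    # arc opens towards the tibial plateau (angles 20-160 deg)
    segs <- list(c(20, 200 / 3), c(200 / 3, 340 / 3), c(340 / 3, 160))
    nmseg <- c("a", "c", "p")
    for (i in 1:3)
      lab <- paint(lab, arc(cx, cy, r0, r1, segs[[i]][1], segs[[i]][2]),
                   codes[paste0(pre, nmseg[i])])
    # fluid rim just superficial to the femoral cartilage
    fl <- arc(cx, cy, r1, r1 + 1.5 * min(sx, sy), 60, 120)
    fl <- fl[lab[fl] == 0L]
    fluid[fl] <- TRUE
    # tibial plateau band under the condyle, thirds a/c/p
    x0 <- cx - 18 * sx; w <- 12 * sx
    y0 <- 70 * sy; y1 <- y0 + 4 * sy
    pret <- paste0(side, "T_")
    for (i in 1:3)
      lab <- paint(lab, band(x0 + (i - 1) * w, x0 + i * w, y0, y1),
                   codes[paste0(pret, nmseg[i])])
  }
  # patellofemoral plates: two pairs of thin bands at the top
  lab <- paint(lab, band(10 * sx, 30 * sx, 8 * sy, 12 * sy), codes["LPpf"])
  lab <- paint(lab, band(10 * sx, 30 * sx, 15 * sy, 19 * sy), codes["LFpf"])
  lab <- paint(lab, band(60 * sx, 80 * sx, 8 * sy, 12 * sy), codes["Pt"])
  lab <- paint(lab, band(60 * sx, 80 * sx, 15 * sy, 19 * sy), codes["Ft"])
  list(labels = lab, fluid = fluid)
}

# Smooth quadratic B1+ field clipped to the dictionary range and quantized
# to its 0.01 step.
phantom_b1_field <- function(nx, ny, center = 1.0) {
  u <- (seq_len(nx) - (nx + 1) / 2) / nx
  v <- (seq_len(ny) - (ny + 1) / 2) / ny
  f <- center + 0.10 * outer(u, rep(1, ny)) - 0.06 * outer(rep(1, nx), v) -
    0.15 * (outer(u^2, rep(1, ny)) + outer(rep(1, nx), v^2))
  f <- pmin(1.40, pmax(0.60, f))
  round(f * 100) / 100
}

#' Generate a single-knee, single-timepoint phantom
#'
#' Builds the label volume, a fluid mask (fluid pixels are *included* in the
#' cartilage ROI labels of their neighbouring plate so the downstream fluid
#' filter has something to remove), and ground-truth T2/B1+ volumes.
#'
#' @param spec A [phantom_spec()].
#' @param timepoint One of `"rest"`, `"21k"`, `"control"`; selects the
#'   per-label effect applied to baseline T2.
#' @return List with `labels`, `fluid_mask`, `truth_t2`, `truth_b1`
#'   (arrays `nx x ny x n_slices`) and the `spec`.
#' @export
make_phantom <- function(spec, timepoint = c("rest", "21k", "control")) {
  stopifnot(inherits(spec, "phantom_spec"))
  timepoint <- match.arg(timepoint)
  eff <- switch(timepoint, rest = 0 * spec$effect_21k,
                `21k` = spec$effect_21k, control = spec$effect_control)
  t2_by_label <- spec$baseline_t2 * (1 + eff / 100)
  dims <- c(spec$nx, spec$ny, spec$n_slices)
  labels <- array(0L, dims)
  fluid <- array(FALSE, dims)
  truth_t2 <- array(NA_real_, dims)
  b1_img <- if (spec$b1_model == "smooth")
    phantom_b1_field(spec$nx, spec$ny, spec$b1_value)
  else matrix(spec$b1_value, spec$nx, spec$ny)
  truth_b1 <- array(NA_real_, dims)
  for (z in seq_len(spec$n_slices)) {
    sl <- phantom_slice_labels(spec$nx, spec$ny, z)
    lab <- sl$labels
    # fluid pixels adopt the overlying femoral central-section label (the
    # ROI as drawn includes them); their truth T2 is the fluid value, so the
    # downstream fluid filter is what removes them
    fl <- sl$fluid
    lab[fl] <- ifelse(matrix(seq_len(spec$nx), spec$nx, spec$ny)[fl] <= spec$nx / 2,
                      .base_labels[["LF_c"]], .base_labels[["MF_c"]])
    labels[, , z] <- lab
    fluid[, , z] <- fl
    t2 <- array(NA_real_, dim(lab))
    for (nm in names(t2_by_label))
      t2[lab == .base_labels[[nm]] & !fl] <- t2_by_label[[nm]]
    t2[fl] <- spec$fluid_t2
    truth_t2[, , z] <- t2
    truth_b1[, , z] <- ifelse(lab > 0, b1_img, NA_real_)
  }
  list(labels = labels, fluid_mask = fluid, truth_t2 = truth_t2,
       truth_b1 = truth_b1, spec = spec, timepoint = timepoint)
}

#' Render a MESE image series from ground-truth maps
#'
#' Per-pixel EPG forward simulation (grouped by unique (T2, B1+) pairs),
#' scaled by a constant proton-density factor, with optional Gaussian or
#' Rician noise. The channel sigma is `ref / snr` where `ref` is the median
#' first-echo amplitude over labeled pixels. Rician noise adds two
#' independent Gaussian channels to the complex signal before taking the
#' magnitude; Gaussian noise perturbs the magnitude directly (folded at 0).
#'
#' @param truth_t2,truth_b1 Arrays of ground-truth values (`NA` = background).
#' @param seq A [mese_sequence()].
#' @param noise `"none"`, `"gaussian"` or `"rician"`.
#' @param snr First-echo SNR defining sigma.
#' @param seed Integer seed (used only when noise is added).
#' @param proton_density Global signal scale.
#' @return 4-D array `nx x ny x n_slices x n_echoes`.
#' @export
render_mese <- function(truth_t2, truth_b1, seq = mese_sequence(),
                        noise = c("none", "gaussian", "rician"), snr = 50,
                        seed = 1L, proton_density = 1) {
  noise <- match.arg(noise)
  dims <- dim(truth_t2)
  stopifnot(length(dims) == 3L, identical(dim(truth_b1), dims))
  ne <- seq$n_echoes
  series <- array(0, c(dims, ne))
  sel <- which(!is.na(truth_t2))
  if (length(sel)) {
    key <- paste(truth_t2[sel], truth_b1[sel])
    uk <- unique(key)
    curves <- matrix(NA_real_, length(uk), ne)
    for (i in seq_along(uk)) {
      parts <- strsplit(uk[i], " ", fixed = TRUE)[[1]]
      curves[i, ] <- simulate_emc_multi(as.numeric(parts[1]), t1 = 1000,
                                        b1 = as.numeric(parts[2]), seq = seq)
    }
    sig <- proton_density * curves[match(key, uk), , drop = FALSE]
    flat <- matrix(series, prod(dims), ne)
    flat[sel, ] <- sig
    if (noise != "none") {
      sigma <- stats::median(sig[, 1]) / snr
      set.seed(seed)
      if (noise == "gaussian") {
        flat <- abs(flat + matrix(stats::rnorm(length(flat), 0, sigma),
                                  nrow(flat), ne))
      } else {
        n1 <- matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat), ne)
        n2 <- matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat), ne)
        flat <- sqrt((flat + n1)^2 + n2^2)
      }
    }
    series <- array(flat, c(dims, ne))
  }
  series
}

# Deterministic per-knee sub-seed (kept below 2^31) so that dropping one
# knee never shifts another knee's noise stream.
knee_seed <- function(seed, participant, knee_idx, timepoint_idx) {
  (as.numeric(seed) * 7919 + participant * 104729 + knee_idx * 1299709 +
     timepoint_idx * 15485863) %% 2147483629
}

#' Generate a full synthetic three-timepoint study
#'
#' Emulates the study design: `n_participants` bilateral knees, 3 slices per
#' knee treated as independent cartilage samples, 3 timepoints, with an
#' optional number of knees excluded (mimicking motion-artefact dropout).
#' 11 participants with 3 dropped knees yield 57 manifest samples.
#'
#' @param spec A [phantom_spec()].
#' @param seq A [mese_sequence()].
#' @param n_participants Number of participants (default 11).
#' @param n_female Number of female participants (default 4; the rest male).
#' @param dropout_knees Number of knees to exclude entirely (default 0).
#' @return List of class `synthetic_study`: `manifest` (one row per retained
#'   participant/knee/slice with dominance and sex), `images` (named list
#'   per participant/knee/timepoint with `series`, `labels`, `fluid_mask`,
#'   `truth_t2`, `truth_b1`), `spec`, `seq`.
#' @export
make_study <- function(spec = phantom_spec(), seq = mese_sequence(),
                       n_participants = 11, n_female = 4,
                       dropout_knees = 0) {
  stopifnot(n_participants >= 1, n_female <= n_participants)
  participants <- sprintf("P%02d", seq_len(n_participants))
  sex <- rep(c("female", "male"),
             c(n_female, n_participants - n_female))[seq_len(n_participants)]
  knees <- expand.grid(participant = participants, knee = c("left", "right"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  knees$sex <- sex[match(knees$participant, participants)]
  knees$dominance <- ifelse(knees$knee == "right", "dom", "ndom")  # all right-dominant
  if (dropout_knees > 0) {
    set.seed(spec$seed)
    drop_idx <- sample(nrow(knees), dropout_knees)
    knees <- knees[-drop_idx, , drop = FALSE]
  }
  timepoints <- c("rest", "21k", "control")
  images <- list()
  for (i in seq_len(nrow(knees))) {
    for (tp_i in seq_along(timepoints)) {
      tp <- timepoints[tp_i]
      ph <- make_phantom(spec, timepoint = tp)
      sd_i <- knee_seed(spec$seed, match(knees$participant[i], participants),
                        match(knees$knee[i], c("left", "right")), tp_i)
      series <- render_mese(ph$truth_t2, ph$truth_b1, seq = seq,
                            noise = spec$noise, snr = spec$snr, seed = sd_i)
      images[[paste(knees$participant[i], knees$knee[i], tp, sep = "_")]] <-
        list(series = series, labels = ph$labels, fluid_mask = ph$fluid_mask,
             truth_t2 = ph$truth_t2, truth_b1 = ph$truth_b1)
    }
  }
  manifest <- do.call(rbind, lapply(seq_len(nrow(knees)), function(i) {
    data.frame(participant = knees$participant[i], knee = knees$knee[i],
               dominance = knees$dominance[i], sex = knees$sex[i],
               slice = seq_len(spec$n_slices), stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, images = images, spec = spec, seq = seq),
            class = "synthetic_study")
}
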