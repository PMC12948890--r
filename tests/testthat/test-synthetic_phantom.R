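# Synthetic knee phantom generator: geometry, rendering, study design.

test_that("phantom construction is deterministic with disjoint labels", {
  sp <- phantom_spec(seed = 5)
  p1 <- make_phantom(sp, "rest")
  p2 <- make_phantom(sp, "rest")
  expect_identical(p1, p2)
  # all 16 base labels present in every slice
  for (z in 1:3)
    expect_setequal(setdiff(unique(as.vector(p1$labels[, , z])), 0L), 1:16)
  # truth maps defined exactly on labeled voxels
  expect_identical(!is.na(p1$truth_t2), p1$labels > 0)
})

test_that("timepoint effects scale the per-label truth values", {
  sp <- phantom_spec(effect_21k = -2.0, effect_control = 0.0)
  rest <- make_phantom(sp, "rest")
  run <- make_phantom(sp, "21k")
  ctrl <- make_phantom(sp, "control")
  cart <- rest$labels > 0 & !rest$fluid_mask
  expect_equal(run$truth_t2[cart], rest$truth_t2[cart] * 0.98)
  expect_equal(ctrl$truth_t2[cart], rest$truth_t2[cart])
  # fluid T2 is unaffected and above the exclusion cutoff
  expect_true(all(run$truth_t2[run$fluid_mask] > 100))
})

test_that("fluid pixels carry cartilage labels and are removed by the filter", {
  d <- default_dictionary()
  sp <- phantom_spec(baseline_t2 = 40, noise = "none", b1_model = "constant")
  ph <- make_phantom(sp, "rest")
  expect_gt(sum(ph$fluid_mask), 0)
  expect_true(all(ph$labels[ph$fluid_mask] > 0))
  ser <- render_mese(ph$truth_t2, ph$truth_b1, paper_sequence(), noise = "none")
  maps <- fit_map(ser, ph$labels > 0, d)
  keep <- fluid_filter(maps, ph$labels > 0)
  expect_identical(keep, ph$labels > 0 & !ph$fluid_mask)
})

test_that("zero-noise on-grid closed loop is exact through the ROI stage", {
  d <- default_dictionary()
  sp <- phantom_spec(baseline_t2 = 40, noise = "none", b1_model = "constant")
  ph <- make_phantom(sp, "rest")
  ser <- render_mese(ph$truth_t2, ph$truth_b1, paper_sequence(), noise = "none")
  maps <- fit_map(ser, ph$labels > 0, d)
  rs <- region_stats(slice_maps(maps, 1), ph$labels[, , 1, drop = FALSE])
  expect_equal(nrow(rs), 25)
  expect_true(all(rs$mean_t2_ms == 40))
  expect_true(all(rs$sd_t2_ms == 0))
})

test_that("noise-free rendering reproduces dictionary atoms (score 1)", {
  d <- default_dictionary()
  sp <- phantom_spec(baseline_t2 = 45, noise = "none", b1_model = "constant",
                     b1_value = 1.1)
  ph <- make_phantom(sp, "rest")
  ser <- render_mese(ph$truth_t2, ph$truth_b1, paper_sequence(), noise = "none")
  maps <- fit_map(ser, ph$labels > 0 & !ph$fluid_mask, d)
  sel <- ph$labels > 0 & !ph$fluid_mask
  expect_true(all(maps$score_map[sel] > 1 - 1e-12))
  expect_true(all(maps$b1_map[sel] == 1.1))
})

test_that("rendering with a fixed seed is reproducible; sigma tracks SNR", {
  sp <- phantom_spec(baseline_t2 = 40)
  ph <- make_phantom(sp, "rest")
  s1 <- render_mese(ph$truth_t2, ph$truth_b1, paper_sequence(),
                    noise = "rician", snr = 50, seed = 77)
  s2 <- render_mese(ph$truth_t2, ph$truth_b1, paper_sequence(),
                    noise = "rician", snr = 50, seed = 77)
  expect_identical(s1, s2)
  s3 <- render_mese(ph$truth_t2, ph$truth_b1, paper_sequence(),
                    noise = "rician", snr = 50, seed = 78)
  expect_false(identical(s1, s3))
})

test_that("doubling the noise raises the T2 map RMSE", {
  d <- default_dictionary()
  sp <- phantom_spec(baseline_t2 = 40, b1_model = "constant")
  ph <- make_phantom(sp, "rest")
  sel <- ph$labels > 0 & !ph$fluid_mask
  rmse_at <- function(snr, seeds) {
    vapply(seeds, function(s) {
      ser <- render_mese(ph$truth_t2, ph$truth_b1, paper_sequence(),
                         noise = "rician", snr = snr, seed = s)
      maps <- fit_map(ser, sel, d)
      sqrt(mean((maps$t2_map[sel] - 40)^2))
    }, numeric(1))
  }
  seeds <- 1:10
  expect_gt(mean(rmse_at(25, seeds)), mean(rmse_at(50, seeds)))
  expect_gt(mean(rmse_at(12.5, seeds)), mean(rmse_at(25, seeds)))
})

test_that("study manifests reproduce the bilateral three-slice design", {
  sp <- phantom_spec(nx = 32, ny = 32, noise = "none")
  st <- make_study(sp, paper_sequence(), n_participants = 11, n_female = 4,
                   dropout_knees = 0)
  expect_equal(nrow(st$manifest), 66)   # 11 x 2 knees x 3 slices
  st2 <- make_study(sp, paper_sequence(), n_participants = 11, n_female = 4,
                    dropout_knees = 3)
  expect_equal(nrow(st2$manifest), 57)  # 19 knees x 3 slices
  expect_equal(length(unique(paste(st2$manifest$participant,
                                   st2$manifest$knee))), 19)
  expect_setequal(unique(st2$manifest$sex), c("male", "female"))
  expect_true(all(st2$manifest$dominance[st2$manifest$knee == "right"] == "dom"))
})

test_that("per-knee noise substreams are unaffected by dropout elsewhere", {
  sp <- phantom_spec(nx = 32, ny = 32, seed = 9)
  st_full <- make_study(sp, paper_sequence(), n_participants = 3,
                        n_female = 1, dropout_knees = 0)
  st_drop <- make_study(sp, paper_sequence(), n_participants = 3,
                        n_female = 1, dropout_knees = 1)
  shared <- intersect(names(st_full$images), names(st_drop$images))
  expect_gt(length(shared), 0)
  for (nm in shared)
    expect_identical(st_full$images[[nm]]$series, st_drop$images[[nm]]$series)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(fluid_t2 = 90), "cutoff")
  expect_error(phantom_spec(baseline_t2 = c(LF_a = 45)), "base label")
  expect_error(phantom_spec(effect_21k = -150), "positive")
})
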