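# Region scheme, synovial fluid filter and per-region statistics.

test_that("the default scheme enumerates the 25 reported regions", {
  regions <- enumerate_regions(region_scheme())
  expect_length(regions, 25)
  expect_length(unique(regions), 25)
  expect_true(all(c("LF_a", "MT_p", "LF", "MT", "LatC", "MedC",
                    "LPpf", "LFpf", "LPF", "Pt", "Ft", "TrPF", "T2Tot")
                  %in% regions))
  # stable ordering across calls
  expect_identical(regions, enumerate_regions(region_scheme()))
})

test_that("the condyle-only scheme has 18 regions", {
  regions <- enumerate_regions(region_scheme(include_patellofemoral = FALSE))
  expect_length(regions, 18)
  expect_false(any(c("LPpf", "LFpf", "LPF", "Pt", "Ft", "TrPF", "T2Tot")
                   %in% regions))
})

test_that("base labels are disjoint and aggregates are unions of them", {
  sc <- region_scheme()
  expect_length(unique(sc$base), 16)
  for (ag in names(sc$aggregates))
    expect_true(all(sc$aggregates[[ag]] %in% names(sc$base)))
  expect_setequal(sc$aggregates$T2Tot, names(sc$base))
  expect_setequal(sc$aggregates$LatC,
                  c(sc$aggregates$LF, sc$aggregates$LT))
})

test_that("fluid filter keeps T2 <= 100 and removes strictly greater", {
  fx <- strip_maps(c(50, 99, 100, 101, 150))
  keep <- fluid_filter(fx$maps, fx$labels > 0)
  expect_equal(which(keep), 1:3)

  # no-op when everything is below the cutoff; idempotent
  fx2 <- strip_maps(c(30, 60, 100))
  k2 <- fluid_filter(fx2$maps, fx2$labels > 0)
  expect_true(all(k2))
  expect_identical(fluid_filter(fx2$maps, k2), k2)

  # everything above the cutoff: empty result with a warning
  fx3 <- strip_maps(c(120, 180))
  expect_warning(k3 <- fluid_filter(fx3$maps, fx3$labels > 0), "removed every")
  expect_false(any(k3))
})

test_that("region statistics use pixel-pooled means and sample SD", {
  fx <- strip_maps(c(40, 42, 44, 46), labels = rep(1L, 4))  # LF_a
  # fixture populates a single label; absent-region warnings are expected
  rs <- suppressWarnings(region_stats(fx$maps, fx$labels, key = list(slice = 1)))
  row <- rs[rs$region == "LF_a", ]
  expect_equal(row$mean_t2_ms, 43)
  expect_equal(row$sd_t2_ms, sd(c(40, 42, 44, 46)))  # n-1 form, 2.582
  expect_equal(row$sd_t2_ms, 2.581989, tolerance = 1e-6)
  expect_equal(row$n_pixels, 4)
})

test_that("aggregates pool pixels, not section means", {
  # LF pixels at 45, LT pixels at 36, equal counts -> LatC mean 40.5
  fx <- strip_maps(c(rep(45, 6), rep(36, 6)),
                   labels = c(rep(1L, 6), rep(4L, 6)))  # LF_a, LT_a
  rs <- suppressWarnings(region_stats(fx$maps, fx$labels))
  expect_equal(rs$mean_t2_ms[rs$region == "LF"], 45)
  expect_equal(rs$mean_t2_ms[rs$region == "LT"], 36)
  expect_equal(rs$mean_t2_ms[rs$region == "LatC"], 40.5)
  expect_equal(rs$n_pixels[rs$region == "LatC"], 12)
})

test_that("a complete fixture yields 25 rows with consistent bookkeeping", {
  sc <- region_scheme()
  fx <- strip_maps(20 + seq_len(32), labels = rep(unname(sc$base), each = 2))
  rs <- region_stats(fx$maps, fx$labels, key = list(participant = "P01"))
  expect_equal(nrow(rs), 25)
  # aggregate counts equal the sum of their base-label counts
  for (ag in c("LF", "LatC", "LPF", "TrPF", "T2Tot")) {
    members <- sc$aggregates[[ag]]
    expect_equal(rs$n_pixels[rs$region == ag],
                 sum(rs$n_pixels[rs$region %in% members]))
  }
  # total mean lies within the range of base-section means
  base_means <- rs$mean_t2_ms[rs$region %in% names(sc$base)]
  tot <- rs$mean_t2_ms[rs$region == "T2Tot"]
  expect_gte(tot, min(base_means))
  expect_lte(tot, max(base_means))
})

test_that("fluid-emptied regions are dropped with a warning naming them", {
  fx <- strip_maps(c(150, 160, 40, 41), labels = c(1L, 1L, 2L, 2L))
  w <- capture_warnings({rs <- region_stats(fx$maps, fx$labels)})
  expect_true(any(grepl("'LF_a'", w)))
  expect_false("LF_a" %in% rs$region)
  expect_true("LF_c" %in% rs$region)
})

test_that("unknown label codes are reported as errors", {
  fx <- strip_maps(c(40, 41), labels = c(1L, 77L))
  expect_error(region_stats(fx$maps, fx$labels), "77")
})

test_that("region schemes round-trip through JSON", {
  sc <- region_scheme()
  path <- withr::local_tempfile(fileext = ".json")
  write_region_scheme(sc, path)
  sc2 <- read_region_scheme(path)
  expect_equal(enumerate_regions(sc2), enumerate_regions(sc))
  expect_equal(unname(sc2$base[names(sc$base)]), unname(sc$base))
})
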