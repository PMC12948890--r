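# Shared fixtures. The full default dictionary (24,300 atoms) is built once
# per test session and memoized; everything else is constructed per test.

.fixture_env <- new.env(parent = emptyenv())

paper_sequence <- function() {
  mese_sequence(tr_ms = 2057, esp_ms = 5.9, n_echoes = 10,
                exc_deg = 90, refoc_deg = 125)
}

default_dictionary <- function() {
  if (is.null(.fixture_env$dict))
    .fixture_env$dict <- build_dictionary(build_grid(), paper_sequence())
  .fixture_env$dict
}

# Small single-B1 dictionary for cheap matching tests.
small_dictionary <- function() {
  if (is.null(.fixture_env$small_dict))
    .fixture_env$small_dict <- build_dictionary(
      build_grid(20, 80, 1, 1, 1, 0.01), paper_sequence())
  .fixture_env$small_dict
}

# Independent naive matcher: double loop over atoms, no shared code with
# match_pixel beyond the dictionary object.
naive_match <- function(values, dict) {
  v <- values[dict$echo_idx] / sqrt(sum(values[dict$echo_idx]^2))
  best_i <- 0L; best_s <- -Inf
  for (i in seq_len(nrow(dict$atoms))) {
    s <- sum(dict$atoms[i, ] * v)
    if (s > best_s + 1e-15 ||
        (abs(s - best_s) <= 1e-15 &&
         (dict$t2[i] < dict$t2[best_i] ||
          (dict$t2[i] == dict$t2[best_i] &&
           abs(dict$b1[i] - 1) < abs(dict$b1[best_i] - 1))))) {
      best_s <- s; best_i <- i
    }
  }
  list(t2 = dict$t2[best_i], b1 = dict$b1[best_i], score = best_s)
}

# quant_maps restricted to one slice (keeps region_stats fixtures small)
slice_maps <- function(maps, z) {
  structure(list(t2_map = maps$t2_map[, , z, drop = FALSE],
                 b1_map = maps$b1_map[, , z, drop = FALSE],
                 score_map = maps$score_map[, , z, drop = FALSE],
                 validity_mask = maps$validity_mask[, , z, drop = FALSE]),
            class = "quant_maps")
}

# Hand-built quant_maps from a vector of T2 values laid out on a 1-D strip.
strip_maps <- function(t2_values, labels = rep(1L, length(t2_values))) {
  n <- length(t2_values)
  t2 <- array(t2_values, c(n, 1, 1))
  list(maps = structure(list(t2_map = t2,
                             b1_map = array(1, c(n, 1, 1)),
                             score_map = array(1, c(n, 1, 1)),
                             validity_mask = array(TRUE, c(n, 1, 1))),
                        class = "quant_maps"),
       labels = array(as.integer(labels), c(n, 1, 1)))
}
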