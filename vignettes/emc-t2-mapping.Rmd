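---
title: "Dictionary-matching T2 mapping of knee cartilage and recovery analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-matching T2 mapping of knee cartilage and recovery analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emcT2)
```

## The signal model

A multi-echo spin-echo (MESE) acquisition excites the magnetization once and
refocuses it `n` times, reading one echo per refocusing period at
`TE_k = k * ESP`. If every refocusing pulse were exactly 180°, the echo
amplitudes would decay as `exp(-TE/T2)`. In practice refocusing angles are
deliberately lower (here nominally 125°) and further scaled by the spatial
transmit-field inhomogeneity B1+, so part of the magnetization is stored
longitudinally for one or more periods and returns as stimulated echoes.
The resulting echo-modulation curve (EMC) is not mono-exponential — its
first echoes are visibly non-monotonic — and a log-linear fit overestimates
T2 by several milliseconds.

`simulate_emc()` computes the EMC with an extended phase graph (EPG)
recursion: configuration states `(F+_k, F-_k, Z_k)` over dephasing orders
`k = 0..n+1` are relaxed (T2 on transverse, T1 on longitudinal states, with
regrowth into `Z_0`), shifted by one order per half echo-spacing (ideal
crusher gradients), and mixed by each RF pulse's rotation matrix. The CPMG
convention is used (excitation about x, refocusing about y); angles are
degrees at the interface and radians internally. Allocating `n + 1` orders
is sufficient because no populated state can reach a higher order within
`n` periods, so the recursion is exact, not truncated.

Two deliberate simplifications, both harmless for matching:

- **No inter-TR steady state.** TR (2057 ms) is ~35× the train length
  (59 ms); residual saturation only rescales the curve, and matching is
  scale-invariant by construction.
- **Hard pulses by default.** The vendor's pulse shapes are not public. A
  `shaped` option subdivides the slice (default 15 sub-slices) with flip
  angles weighted by a tabulated profile and sums the complex sub-slice
  signals; the ±40 % B1+ search range then absorbs residual profile error.
  The default half-sine profile is a configurable approximation, not a
  reproduction of any vendor pulse.

### The isochromat oracle

`isochromat_mese()` is an independent time-domain check: thousands of
isochromats propagated with explicit 3×3 rotations, each accruing crusher
phase per half-period on an offset uniform grid spanning 2π. One EPG
gradient shift per half-period corresponds to 2π of ensemble dephasing per
*half*-period; with that identification the discrete ensemble sums of all
unrefocused coherence orders vanish exactly, and the two simulators agree
to machine precision (~1e-15, far inside the 1e-6 bound the tests assert).
The oracle shares no code with the EPG path and stays in the test suite.

## Dictionary and matching

`build_grid()` reproduces the published search space: T2 = 1…300 ms step
1 ms (300 values), B1+ = 0.60…1.40 step 0.01 (81 values), T1 fixed at
1000 ms — 24,300 atoms of 10 echoes. Atoms are stored L2-normalized so the
"maximum dot product" criterion equals maximum cosine similarity and is
independent of per-pixel signal scale; unnormalized dot products would be
meaningless across pixels. Matching (`match_pixel()`, `fit_map()`) is
exhaustive — one matrix product per pixel chunk; at this dictionary size
approximate search structures buy nothing. Exact score ties break towards
the smaller T2, then the B1+ closer to 1.00. A `skip_first_echo` switch
exists because discarding echo 1 is common MESE practice; the default uses
all 10 echoes. Zero-norm pixels are marked invalid rather than raising.

The T2–B1+ manifold is locally degenerate: at first-echo SNR 50 a single
pixel's T2 lands within ±3 ms of truth in ≥95 % of draws under the joint
search (±2 ms when B1+ is known). Region means average this out — a
200-pixel region recovers its mean T2 to ~0.1 ms at the same SNR.

## Regions, fluid exclusion, recovery

The WORMS-derived scheme has 16 base labels (4 condyle plates × 3 sections,
plus LPpf, LFpf, Pt, Ft) and pixel-pooling aggregates, 25 reported regions
in total. Two conventions matter and are stated explicitly:

- **Aggregates pool pixels**, they do not average section means; the two
  differ whenever sections differ in size. `T2Tot` pools each base label
  once (pooling the 25 reported regions would double-count pixels).
- **Sample SD** (n−1 denominator), the default of the statistics packages
  such studies use.

Synovial fluid is removed by the `T2 > 100 ms` rule *before* any mean; the
boundary value 100 ms is retained (strict inequality removes). Slices are
independent samples (one knee contributes three), and maps and labels must
share a voxel grid — no resampling is performed.

`compute_pri()` implements
`PRI = (T2_control − T2_21k) / (T2_rest − T2_21k)`, undefined when rest and
post-run coincide. Group summaries use a mixed convention chosen because it
is the only one that reproduces the published tables: delta columns are
mean ± SD of per-sample deltas (the printed columns carry SDs, so they must
be per-sample summaries), while the group PRI is computed from the
group-mean triplet — recomputing the printed group-mean PRIs this way
reproduces every compartment/section/subgroup row to one decimal. Both
levels are exposed (`pri`, `pri_sample_mean`). Reports round T2, percent
and PRI to one decimal, half away from zero.

## Longitudinal inference

`rm_anova()` is the classical one-way within-subject decomposition with
Mauchly's W on the orthonormal-contrast covariance and Greenhouse–Geisser /
Huynh–Feldt epsilons (HF clipped at 1). The correction is applied when
Mauchly's p < 0.05, choosing GG below the conventional ε = 0.75 and HF
above. Planned comparisons are exactly the two the study design names —
rest vs 21k and rest vs control — Bonferroni factor 2 (a switch enables all
three pairs, factor 3). The implementation is hand-written because its
result object needs the full field set (W, both epsilons, correction used);
it is verified against `car::Anova()` and `stats::mauchly.test()` to 1e-8
in the tests.

`friedman_rm()` adds the tie correction missing from the classical
statistic (midranks in the denominator term); it reduces exactly to
`stats::friedman.test()` on tie-free data. `normality_screen()` uses the
Lilliefors KS test (`nortest::lillie.test`) — naive KS with estimated
parameters is anti-conservative — plus SPSS-style (type 2) skewness and
excess kurtosis with the conventional screening bounds 2 and 7.
`timepoint_test()` wires the three together: RM-ANOVA when every timepoint
passes the screen, Friedman otherwise. Simulated at n = 19 null blocks the
combined procedure rejects at ≤ 0.07 for nominal 0.05 (measured ≈ 0.045).

## The synthetic phantom

`make_phantom()` draws schematic plates: annular femoral arcs split into
anterior/central/posterior sectors, flat tibial bands in thirds, and four
patellofemoral bands; fluid pixels line the superficial femoral margin and
*carry cartilage labels* with fluid T2 (default 150 ms), so the fluid
filter has real work to do. Geometry is deliberately schematic — the
pipeline never looks at shape, only at labels, and anatomical realism would
add nothing testable. Default per-section baseline T2 values are the
published rest-column values (~31–50 ms); the default timepoint effect is
a global −2 % at 21k with full recovery at control, matching the study's
headline global effect. B1+ fields are constant or smooth quadratic,
clipped to [0.60, 1.40] and quantized to the dictionary's 0.01 step so that
zero-noise closed loops are exact rather than limited by grid rounding.
Rician noise is generated physically (two Gaussian channels on the complex
signal before magnitude); sigma is set from the configured first-echo SNR.
Per-knee noise streams are derived deterministically from the study seed,
so excluding a knee never changes another knee's data.

What the phantom does *not* emulate — and what passing tests therefore do
not show about in-vivo data: anatomical geometry and partial-volume mixing
at cartilage boundaries, the magic-angle orientation dependence of
cartilage T2, multi-component relaxation, diffusion sensitization, motion,
and inter-scan repositioning error.

## Problem sizes and numerical choices

The test suite and acceptance script run the full 24,300-atom dictionary
but scale simulation sizes to what the checks need: 75-point parameter
grids for the EPG/Bloch agreement, 100–200 noise seeds for Monte-Carlo
recovery, one full 11-participant study (57 samples) for the end-to-end
PRI, and 1000 null blocks for the type-I calibration. Grid divisibility is
checked to 1e-9 (no silent truncation); atom norms to 1e-12; affine/grid
agreement between maps and labels is required exactly (no resampling).
Degenerate inputs have defined behaviour: empty masks produce all-missing
maps, constant blocks give F = 0 with p = 1, zero-variance columns fail the
normality screen with a named reason, and regions emptied by the fluid
filter are dropped with a warning naming them.

## Known limitations

- The dictionary is single-compartment, single-T1; multi-T1 dictionaries
  and SVD compression are out of scope.
- No spatial regularization: matching is pixel-wise, as in the study
  design being replicated.
- The statistical design treats knees and slices as independent samples.
  This replicates the published analysis; a mixed-effects model of
  knee-within-participant correlation would be the methodological upgrade,
  and is intentionally not offered here.
- No minimum match-score threshold is applied to accepted pixels; the
  score map is returned so users can impose one.
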