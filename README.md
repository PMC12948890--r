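# emcT2

Dictionary-matching T2 relaxometry of knee articular cartilage (KAC) from
multi-echo spin-echo (MESE) MRI, with a three-timepoint recovery analysis
for exercise studies (rest → post-run → one-week control).

## The problem

Cartilage T2 reflects water content and collagen organization, and transient
T2 drops after long-distance running are a candidate biomarker for cartilage
loading and recovery. Quantifying T2 from a MESE train by fitting a
mono-exponential `S(TE) = S0 exp(-TE/T2)` is biased whenever refocusing
pulses deviate from 180°: imperfect refocusing generates stimulated-echo
pathways that make the decay non-mono-exponential. The echo-modulation-curve
(EMC) approach fixes this by *simulating* the sequence: an extended phase
graph (EPG) model produces the theoretical echo amplitudes for every
`(T2, B1+)` pair on a grid (T2 = 1…300 ms in 1 ms steps, B1+ = 60…140 % in
1 % steps, T1 fixed at 1000 ms), and each pixel's echo series is assigned
the grid pair whose normalized curve has the maximum dot product with it.

On top of the maps, the package implements the longitudinal analysis used
in cartilage recovery studies:

- WORMS-derived region scheme: 12 condyle plate sections, 4 patellofemoral
  plates, and pixel-pooled aggregates (LF/LT/MF/MT, LatC, MedC, LPF, TrPF,
  T2Tot) — 25 reported regions; synovial fluid excluded by the
  T2 > 100 ms rule before any region mean.
- Proportional Recovery Index,
  `PRI = (T2_control − T2_21k) / (T2_rest − T2_21k)`
  (1 = complete recovery, < 1 incomplete, > 1 overcompensation, < 0
  continued worsening).
- Repeated-measures ANOVA with Mauchly's sphericity test and
  Greenhouse–Geisser / Huynh–Feldt correction, Bonferroni planned
  comparisons (rest vs 21k, rest vs control), a tie-corrected Friedman
  fallback, and Lilliefors-style normality screening.

A synthetic knee phantom generator (schematic cartilage plates with known
per-section T2, smooth B1+ fields, Rician noise, bilateral three-slice
three-timepoint study design) makes the whole pipeline testable end to end
without scanner data.

## Worked example

```r
library(emcT2)

sq <- mese_sequence()               # TR 2057 ms, 10 echoes, ESP 5.9 ms, 90/125 deg
emc <- simulate_emc(t2 = 43, t1 = 1000, b1 = 1.0, seq = sq)
print(emc)
#> Echo-modulation curve, 10 echoes (TE 5.9-59 ms)
#>  echo_time_ms amplitude
#>           5.9 0.6859123
#>          11.8 0.7612443
#>          17.7 0.5794897
#>          ...
#>          59.0 0.2686266
```

Note the non-monotonic start (echo 2 exceeds echo 1): that is the
stimulated-echo contribution of the 125° refocusing train, which a
mono-exponential fit cannot represent. Matching a noisy copy of this curve
against the full dictionary recovers the truth; the mono-exponential fit
does not:

```r
dict <- build_dictionary(build_grid(), sq)   # 24,300 atoms x 10 echoes
set.seed(1)
noisy <- emc$amplitudes + rnorm(10, 0, emc$amplitudes[1] / 50)  # SNR 50
str(match_pixel(noisy, dict))
#> $ t2   : num 44      <- 1 ms off at SNR 50
#> $ b1   : num 1
#> $ score: num 1
fit_monoexponential(emc$amplitudes, echo_train(sq))
#> [1] 50.37927            <- ~7 ms bias on the *noise-free* train
```

Recovery metrics work on T2 triplets (values in ms):

```r
compute_pri(40.9, 39.3, 43.4)   # 2.5625 -> prints as 2.6: overcompensation
compute_pri(43.1, 42.2, 43.1)   # 1: complete recovery
```

A full synthetic study — 11 bilateral participants, 3 slices per knee,
3 knees excluded (57 samples), −2 % global post-run effect, full recovery
at control, Rician noise at first-echo SNR 50 — runs end to end in about
two minutes:

```r
sp <- phantom_spec(noise = "rician", snr = 50, b1_model = "smooth",
                   effect_21k = -2, effect_control = 0, seed = 1)
st <- make_study(sp, sq, n_participants = 11, n_female = 4, dropout_knees = 3)
rep <- run_study(st, dict = dict)
rep$reports$global[1, c("group", "n", "t2_rest_mean", "delta_run_pct_mean",
                        "delta_ctrl_ms_mean", "pri", "p_run", "p_ctrl")]
#>   group  n t2_rest_mean delta_run_pct_mean delta_ctrl_ms_mean pri p_run p_ctrl
#> 1 Total 57           43                 -2                  0   1     0      1
```

The configured effect (−2 %), its disappearance at control (0 ms) and the
full-recovery PRI of 1 are all recovered from the rendered images, and the
planned comparisons flag the run effect (p_run ≈ 0) but not the recovered
control timepoint (p_ctrl ≈ 1).

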