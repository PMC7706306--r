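# wiltflow

Quantifies short-term **leaf wilting** of greenhouse plants from
minute-cadence RGB time-lapse images and relates it to short-term
**stem-diameter variation**, estimating the lag between the two stress
responses — a proxy for the stem-to-leaf water-transport time. The package
is aimed at plant-phenotyping researchers who have (or want to simulate)
co-registered camera, dendrometer and environment streams under cyclic
irrigation.

## What it computes

**Wilt score.** For frames at `t − w` and `t` (default `w = 5` min), dense
optical flow is estimated (pluggable backend; a deterministic
block-matching estimator is built in), masked to vegetation by the
excess-green index `ExG = 2g − r − b > 0`, and reduced to a two-bin
histogram of oriented optical flow: each masked vector adds its magnitude
to a downward (`v > 0`) or upward (`v < 0`) bin. The wilt scalar is

    Δwilt_t = (up_t − down_t) / masked pixels      [px per masked pixel]

negative = net downward leaf motion (wilting).

**Stem score.** `Δstem_t = stem_t − stem_{t−w}` (mm), which removes
diurnal trends. Irrigation is driven by the relative stem diameter since
the last irrigation, `rsr_t = stem_t / max(stem_{t−n}, …, stem_t)`: when
`rsr < T_rsr` (default 0.9975) between sunrise (PPFD ≥ 14.8 µmol s⁻¹ m⁻²)
and 19:00, the controller irrigates and resets (`rsr = 1.0000`).

**Lag analysis.** Per plant-day (09:00–17:00 grid), the lagged
cross-correlation

    C(l) = [ ⟨Δstem_{t−l} Δwilt_t⟩ − μ_s μ_w ] / (σ_s σ_w),
    ⟨·⟩ = lagged product sum / (n − |l|)

is scanned over `l ∈ [−60, 60]` min; the peak `(R_max, l_max)` is reported
(positive `l_max` = stem precedes wilting), with 99% bounds
`z_{0.995}/√(n−|l|)`. Per-day peaks are then regressed on daily mean PPFD
and VPD with five candidate families (linear, quadratic, segmented linear,
log, exponential), selected by R².

**Synthetic greenhouse.** A tested generator produces environment traces,
a closed-loop stem simulation (soil→stem→leaf reservoir chain with a
configurable transport delay `D` and RSR-controlled irrigation), rendered
144×144 image sequences with exact ExG ground truth, and a flow-field fast
path — so the whole pipeline can be validated against a known injected
delay.

## Worked example

```r
library(wiltflow)
cfg <- scenario_config(seed = 7, weather = "sunny", transport_delay_D = 2)
bundle <- run_pipeline(run_config(scenario = cfg, flow = "synthetic",
                                  out_dir = "run_out"))
bundle$summary
#>   plant_id       date  r_max l_max r_max_nonneg l_max_nonneg   n mean_ppfd mean_vpd
#> 1   plant1 2024-04-01 0.9282     2       0.9282            2 476     189.1    1.626
```

The injected 2-minute water-transport delay is recovered as `l_max = 2`
with a peak correlation of 0.93 over the 476 paired minutes of the day;
`run_out/` receives `wilt.csv`, `delta_stem.csv`, `correlograms.csv`,
`summary.csv`, `regression.csv` and a `manifest.json` that reproduces the
run bit-identically. Swapping `flow = "synthetic"` for `"block_match"`
renders the day's 481 frames and runs the real image pipeline (≈1 min of
compute); the lag survives the integer-quantizing matcher (`l_max` within
a minute of the truth, `R_max ≈ 0.55–0.6`).

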