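---
title: "Leaf wilting, stem diameter and the water-transport lag: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf wilting, stem diameter and the water-transport lag: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wiltflow)
```

## The scientific question

When a plant transpires faster than its roots can resupply water, the water
potential of its tissues falls in a characteristic order: the stem dehydrates
first (measurable as a shrinking stem diameter), and the leaves follow
(visible as wilting) once the potential drop propagates through the petioles.
`wiltflow` implements a pipeline that measures both responses at 1-minute
cadence — wilting from time-lapse RGB images, stem status from a dendrometer
trace — and estimates the *lag* between them by per-day cross-correlation.
On real greenhouse data this lag is a proxy for the stem-to-leaf
water-transport time (on the order of two minutes for tomato); here every
stage can additionally be exercised on synthetic data in which the transport
delay is injected and therefore known exactly.

## Wilt quantification

Leaf motion between the frames at `t - w` and `t` is summarized in four
steps:

1. **Dense optical flow.** A pluggable estimator returns per-pixel
   displacements `(u, v)`; row indices grow downward, so `v > 0` is downward
   motion. The production-grade estimator for real imagery (DeepFlow-class
   dense flow) is consumed as an external backend and intentionally not
   re-implemented; the built-in backends are `block_match`, an exhaustive
   integer-shift SSD matcher, and `dense_reference`, the same matcher with
   parabolic sub-pixel refinement. The matcher aggregates squared grayscale
   differences over a 17x17 window (`patch = 8`) and searches +/- 4 px;
   these defaults sit at the fidelity plateau observed when the estimated
   wilt signal is compared against the renderer's ground-truth leaf motion.
2. **Vegetation masking.** The excess-green index on chromatic coordinates,
   `ExG = 2g - r - b`, with the strict threshold `ExG > 0`, isolates plant
   pixels; this removes moving non-plant structure (clouds) from the flow.
   The mask of the *later* frame of each pair is used — one deterministic
   choice among equally defensible ones (union and intersection behave
   nearly identically on our fixtures).
3. **Two-bin HOOF.** Each masked vector contributes its Euclidean magnitude
   to a downward bin (`v > 0`) or an upward bin (`v < 0`); purely horizontal
   vectors (`v = 0`) are uninformative for wilting and contribute to
   neither.
4. **Reduction.** `delta_wilt = (up - down) / masked_pixel_count`, in pixels
   per masked pixel: negative values mean net downward leaf motion
   (wilting), positive values recovery.

The window is `w = 5` min by default — half the shortest irrigation interval
the controller produces, so a single window never straddles two irrigation
events — evaluated at 1-min stride.

## Stem processing and the RSR controller

Short-term stem variation is the plain difference
`delta_stem(t) = stem(t) - stem(t - w)`; differencing removes the diurnal
trend that would otherwise dominate any correlation. Gaps are never
interpolated.

Irrigation is controlled by the *relative stem diameter since the last
irrigation*: `rsr_t = stem_t / max(stem_{t-n}, ..., stem_t)`, which is 1 at
and immediately after each irrigation and falls below 1 under water stress.
When `rsr < t_rsr` (default 0.9975) within the active window — from sunrise,
defined as PPFD reaching 14.8 umol s-1 m-2, until 19:00 (half-open: events
at 19:00 itself are not issued) — the controller irrigates and resets the
window, so the very next RSR value is 1.0000. The controller applies the
threshold rule only; the ~10-min minimum interval between events is an
emergent property of the plant dynamics, not an imposed guard. Strict `<`
at the threshold and the half-open active window are fixed conventions;
the boundary behaviour of the original rule is not documented anywhere we
could rely on, so one convention is chosen and stated. After a gap in the
stem trace the RSR window restarts (conservative: a gap hides a possible
irrigation).

## Per-day lagged cross-correlation

For each plant-day, `delta_wilt` and `delta_stem` are aligned on the common
minute grid inside 09:00-17:00 (the camera operating window; a full day
yields n = 476 paired minutes, because the first `w` minutes of the window
have no difference value). Days with any interior gap are excluded rather
than bridged — the estimator has no principled treatment of missing minutes.

The estimator is

C(l) = [ (1/(n-|l|)) * sum_t dstem(t-l) * dwilt(t) - mu_s * mu_w ]
       / (sigma_s * sigma_w)

with *day-level* means and population SDs and the raw lagged product sum
divided by the per-lag overlap `n - |l|`. Positive `l` pairs wilting with
earlier stem values, so a peak at `l > 0` means stem variation precedes
wilting. This estimator is not the per-overlap Pearson coefficient: at large
`|l|` it can exceed 1 slightly because the global moments no longer match
the overlap. A per-overlap Pearson variant is available
(`method = "pearson"`) for sensitivity analysis; at small lags the two agree
to within 0.02 on white noise. The default lag range is +/- 60 min —
generous relative to the few-minute lags of interest, and narrow enough
(|l| << n) that the estimator stays well behaved.

Peaks are reported both unrestricted and restricted to `l >= 0` (both
conventions are defensible for "maximum at a lag of 0 or more"; the summary
carries both). Ties break toward the smallest `|l|`, then the positive lag.
Per-lag 99% bounds use the large-sample null
`z_{0.995} / sqrt(n - |l|)`; this is the independent-white-noise null, and
`w`-minute differencing induces a known negative autocorrelation at lag `w`
in both series, so the bounds are approximate — the null-scenario test
checks empirically that the realized false-positive rate stays below the
nominal 5%.

## Environmental regression

Daily environment means (arithmetic, over the half-open window
09:00-19:00) summarize each day's evaporative demand. Five response
families relate the per-day peak correlation (or its lag) to mean PPFD or
VPD: linear, quadratic, continuous two-segment (piecewise) linear with the
breakpoint fitted by profiling over interior quantiles plus local
refinement, logarithmic, and exponential `a*exp(b*x) + c` initialized from
a log-linearization with the offset pinned just below the response minimum
(initialization, not the optimizer, is the usual failure mode of this
family). Selection maximizes raw R-squared, with exact ties (within 1e-9)
broken toward fewer parameters so that nested families cannot win on
rounding noise; the adjusted value is reported alongside for transparency.
The piecewise fit is constrained continuous at the breakpoint — the
standard segmented-regression convention, and the only identifiable variant
at n ~ 18 days. Overall significance uses the F statistic
`(R2/k) / ((1-R2)/(n-k-1))` with `k` the predictor-side parameter count
(3 for piecewise, counting the breakpoint); this is a defined, calibrated
choice (null p-values are verified approximately uniform in the tests), not
a claim about how any particular published analysis computed its p-values.

Under range-scaled noise the exponential amplitude and rate trade off
almost freely (the low-`x` points that pin the amplitude carry noise
comparable to their signal), so parameter-recovery checks judge that family
on its rate parameter.

## The synthetic greenhouse

Because no public dataset pairs minute-cadence plant images with dendrometer
and environment traces, the generator is a first-class, tested module. It
emulates:

- **Environment.** Clear-sky PPFD as a half-sine over the 06:00-18:30
  photoperiod (peak 300 umol s-1 m-2 of scattered light, a bright day
  *inside* a greenhouse), attenuated by a clipped AR(1) cloud process;
  temperature a diurnal sinusoid peaking mid-afternoon, relative humidity in
  anti-phase, VPD from the Tetens saturation curve.
- **Plant.** A discrete-time soil -> stem -> leaf reservoir chain.
  Transpiration demand is proportional to normalized light times
  `min(VPD, 4 kPa)` — the plateau represents stomatal closure under high
  evaporative demand. Root uptake restores the stem water pool at a rate
  limited by soil availability, so the stem dries between irrigations and
  recovers after each dose; stem diameter is baseline + slow growth +
  `shrink_gain` times the water pool + sensor noise. The leaf water status
  is a first-order low-pass (time constant `tau`, default 1 min) of the stem
  pool delayed by `D` minutes — `D` is the ground-truth transport delay the
  pipeline must recover. Leaf droop is `-coupling_gamma * leaf_water`
  pixels, a monotone function of leaf water; an independent "sway" channel
  (SD 0.2 px) adds wind/camera micro-motion, which doubles as the
  independent leaf signal in zero-coupling null scenarios.
- **Controller in the loop.** The same RSR rule drives irrigation during
  simulation, closing the feedback loop; replaying the rule offline on the
  simulated stem trace reproduces the simulator's events exactly, which the
  tests assert.
- **Imagery.** 144x144 frames (the working resolution of the wilt stage)
  for the 09:00-17:00 camera window: a grey-blue sky band with drifting
  achromatic cloud ellipses, a soil band, and a plant whose four leaf
  ellipses rotate about their stem attachment points so the tip sits exactly
  `droop` pixels below rest. The palette is constructed so that plant pixels
  have ExG > 0 and everything else (including every convex blend of
  non-plant colors, since `2G - R - B` is linear in raw channels) has
  ExG <= 0 — the ExG mask therefore has exact ground truth on noise-free
  frames. Ellipses are rasterized with anti-aliased coverage so sub-pixel
  droop is expressible. A "fast path" emits the flow fields directly on a
  small raster (masked pixels carry the exact droop difference), bypassing
  flow estimation for tests that target the downstream statistics.

Calibration was chosen for realism of the *dynamics*, not of appearance:
~0.7 mm diurnal shrinkage on a 10-mm stem, a ~11-min median irrigation
interval on sunny days (the threshold rule then reproduces the observed
~10-min minimum interval), dendrometer noise of 2 um, and leaf droop of
order 10-20 px with short-term swings of ~1 px per irrigation cycle.

What the generator does **not** emulate: leaf rolling or 3-D leaf geometry,
photorealistic texture and lighting, occlusion by neighbouring plants,
camera exposure changes, correlated sensor drift, and multi-plant valve
scheduling. Passing tests therefore demonstrate that the *algorithms*
recover known structure under controlled conditions — not that any specific
greenhouse deployment will achieve the same accuracy.

## Problem sizes and numerical choices

The test-suite and acceptance experiments run single simulated days (1440
minutes; 476 analyzable pairs per day), 20 seeds per condition for
lag-recovery and coupling sweeps, 100 seeds for the null and
regression-selection studies, and one full rendered day (481 frames) for the
image path — sizes at which every statistic of interest is stable while the
whole suite stays fast on one core. Other numerical choices worth stating:
SSD ties in the block matcher resolve to the smaller displacement via an
epsilon (1e-3 in squared-intensity units) that absorbs integral-image
rounding; all-zero pixels have ExG 0 by convention; correlation is declared
undefined (an error, not NA) when either series has zero variance; lags with
fewer than 10 overlapping points are NA; timestamps are timezone-naive local
clock times stored as UTC.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_config(seed = 7, weather = "sunny", transport_delay_D = 2)
bundle <- run_pipeline(run_config(scenario = cfg, flow = "synthetic",
                                  out_dir = "run_out"))
bundle$summary[, c("date", "r_max", "l_max", "n", "mean_ppfd", "mean_vpd")]
```

On the flow fast path this recovers `l_max = 2` (the injected delay) with
`r_max` around 0.9; the rendered-image path with the block-matching backend
recovers the same lag within a minute with `r_max` around 0.55-0.6 — the
integer quantization of the matcher costs correlation but not the lag.

## Known limitations

- The day-level cross-correlation estimator inherits the usual caveats of
  raw cross-correlation between autocorrelated series; no pre-whitening is
  applied (deliberately out of scope), so the confidence bounds are
  approximate.
- The block-matching backend quantizes sub-pixel motion; on real imagery a
  dense sub-pixel estimator (the `deepflow` slot) should be used.
- Regression families are fitted per predictor; PPFD and VPD are strongly
  collinear on real days, and no joint model is attempted.
- The generator's parameters are plausible for greenhouse tomato but not
  fitted to any dataset; growth rate and noise magnitudes in particular are
  order-of-magnitude choices.
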