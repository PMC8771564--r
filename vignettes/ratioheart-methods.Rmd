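---
title: "Methods: ratiometric calcium and contraction analysis in the beating heart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric calcium and contraction analysis in the beating heart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioheart)
```

## The measurement problem

Intensiometric calcium indicators (GCaMP-type) are nearly useless on an
uninterrupted beating heart: every contraction moves tissue through the
imaging plane and modulates fluorescence far more than calcium does, so
hearts are usually arrested pharmacologically or genetically before
imaging — destroying the very physiology of interest. A FRET-based
ratiometric sensor solves this because heart motion is *common-mode*: it
multiplies the donor and acceptor emission channels by the same factor, so
the pixel-wise emission ratio

$$R = \frac{F_{\mathrm{FRET}}}{F_{\mathrm{donor}}}$$

is invariant to it, while calcium binding moves donor and FRET intensities
in opposite directions and shifts $R$. The same image frames record the
ventricular wall position, so calcium and contraction can be measured
simultaneously and correlated beat by beat.

`ratioheart` implements this analysis end to end: split-view channel
separation and registration, clipped pixel-wise ratioing,
intensity-weighted ROI traces, automatic transient detection with
per-cycle kinetics, kymogram outer-wall tracking with fractional
shortening (FS), the calcium-peak-to-maximal-shortening delay, Lissajous
phase loops with atrioventricular (AV) rhythm classification, a dF/F0
path for intensiometric data, and a fully ground-truthed synthetic video
generator used to validate everything without real data.

## Ratiometry

**Clipping.** Ratios of near-background pixels diverge, so pixel values
are clamped into $[r_{\min}/4,\; 4\,r_{\max}]$ where $(r_{\min}, r_{\max})$
is the display range; a zero-donor pixel clips to the upper bound. The
display range is user-set or defaults to the 1st–99th percentile of the
intensity-weighted pixel ratios of the first frame. Clipped pixels are
clamped rather than discarded so every frame keeps the same pixel count;
intensity weighting already suppresses them.

**ROI traces.** The per-frame ROI ratio is
$R_{\mathrm{ROI}} = \sum_i w_i R_i / \sum_i w_i$ with
$w_i = (D_i + F_i)/2$. Because bright myocardium dominates the weights, a
*static* ROI drawn generously around a chamber yields a clean trace even
though the wall moves inside it. Under a pure common-mode per-frame factor
$m(t)$ both $w_i$ and the clipped $R_i$ are unchanged or rescale
compatibly, so the trace is exactly invariant — the package asserts this
to floating-point tolerance. Background autofluorescence is *not*
subtracted.

## Transient detection and kinetics

Detection uses a mid-level rising-edge criterion: the threshold is the
rolling baseline plus `prominence_fraction` (default 0.5) of the rolling
amplitude, computed over a centered window (default 1 s, i.e. about four
beats); crossings closer than the refractory period `min_interval_s`
(default 0.1 s, half the shortest plausible larval beat) are merged. Each
cycle takes the intensity maximum between consecutive rising edges as its
systolic peak and the adjacent diastolic minima as bounds; cycles
truncated by the recording edges are excluded from all summaries.

Per cycle the package reports diastolic and systolic ratio, amplitude
$\Delta R$, 10–90 % rise and 90–10 % decay times with crossing times
located by linear interpolation between bracketing samples, and the
corresponding slopes. Two numerical choices matter:

* **Sub-sample behavior.** Peak position is the raw argmax (no parabolic
  fit) for determinism; only the 10/90 % crossings are interpolated.
* **Fused beats.** At 4–4.6 Hz the ratio does not always return to the
  same diastolic level before the next beat. The 10/90 % levels are
  therefore referenced to each limb's own diastolic end (the trace value
  at the cycle onset for the rising limb, at the cycle end for the falling
  limb). For well-separated beats this is identical to referencing the
  cycle minimum; for fused beats it keeps the decay time defined, and the
  cycle is flagged `fused`.

Heart rate is 60 divided by the *median* peak-to-peak interval — robust to
a single missed beat (the mean is available behind a flag).
Savitzky–Golay smoothing of traces is available but **off by default**;
when enabled it uses window 7, order 3, and reproduces any polynomial up
to the filter order exactly.

## Contraction

A kymogram samples the FRET-channel frames by bilinear interpolation at
unit-pixel steps along a fixed measurement line through the ventricle,
averaged over an odd `band_width` of perpendicular offsets. Per time row,
the wall threshold is `background + 0.5 * (row max − background)` with the
background taken as the row's 5th percentile (the line should extend past
the heart); the diameter is the distance between the outermost upward and
downward threshold crossings, sub-pixel interpolated. The *outer* wall is
used because the inner wall lacks contrast. Rows without two crossings are
flagged untracked and filled by interpolation; more than 20 % untracked
rows aborts with a suggestion to move the line.

The tracked diameter is used raw by default. A Savitzky–Golay option
(window 5, order 2) exists but is off: crossing interpolation plus band
averaging already keeps tracking noise well below a pixel, while at 50 Hz
a 5-sample quadratic spans half the systolic dip and measurably biases the
per-cycle extrema that FS is built from.

Contraction events are detected on the inverted diameter trace with the
same detector as the calcium transients; per cycle
$FS = (EDD - ESD)/EDD$. FS is dimensionless and independent of the pixel
size. The calcium-to-contraction delay is, per cycle, the time of minimal
diameter minus the time of the systolic ratio peak, both frame-quantized,
paired by nearest match within half a period. Fractional area change
(FAC), a secondary measure, thresholds a bounding box with Otsu's method
on the time-averaged frame and counts pixels.

## Phase loops and rhythm

Lissajous diagrams pair two synchronized traces (ventricular vs atrial
ratio, or shortening vs ratio) with time markers every `marker_stride_s`
(20 ms marks every frame at 50 Hz, every second frame at 100 Hz). Loop
hysteresis is quantified as the shoelace signed area of the closed loop;
orientation is reported as the principal-axis angle, with no threshold
attached. Chamber activation order uses the 10 %-rise times as onsets:
per beat $\Delta = t_{\mathrm{ventricle}} - t_{\mathrm{atrium}}$, labeled
`normal` ($\Delta > w$), `simultaneous` ($|\Delta| \le w$) or
`ventricle_first` ($\Delta < -w$) with $w$ one frame by default —
simultaneous or reversed activation is the signature of sinoatrial failure
with an escape rhythm.

## Intensiometric path

For single-channel data the package provides exponentially weighted
moving-average smoothing with factor 0.7 — interpreted as the weight on
the previous smoothed value, $s_t = 0.7\,s_{t-1} + 0.3\,x_t$, the heavier
of the two conventions in circulation; the opposite one is selectable —
followed by $\Delta F/F_0 = (F_t - F_0)/F_0$ with $F_0$ the global trace
minimum (the minimum diastolic fluorescence). Kinetics then reuse the
ratiometric machinery on the $\Delta F/F_0$ scale.

## The synthetic heart

The generator exists so that every stage above can be tested against
known truth. It emulates, in order:

1. **Calcium trains.** Per chamber, exponential rise
   ($\tau_{\mathrm{rise}}$ = 20 ms, duration $3\tau$) to systolic free
   calcium and exponential return ($\tau_{\mathrm{decay}}$ = 80 ms) to
   diastolic; defaults 0.15/1.5 µM span the working range of a low-affinity
   cardiac sensor. Ventricular onsets lag atrial onsets by the AV delay
   (60 ms). Beat periods carry seeded Gaussian jitter (SD 5 ms) emulating
   physiological heart-rate variability; this also decorrelates beat phase
   from the frame grid, so frame-quantized event-time estimates average to
   the truth instead of locking to one rounding.
2. **Biosensor kinetics.** The bound fraction obeys
   $\dot b = k_{\mathrm{on}}\,\mathrm{Ca}\,(1-b) - k_{\mathrm{off}}\,b$
   with $K_d$ = 2.8 µM, $k_{\mathrm{off}}$ = 2 s⁻¹ and
   $k_{\mathrm{on}} = k_{\mathrm{off}}/K_d$ ≈ 7×10⁵ M⁻¹s⁻¹, integrated by
   the per-step exact exponential update (unconditionally stable; matches
   the analytic step response to 10⁻⁶). The ratio is
   $R = R_{\mathrm{apo}} + b\,(R_{\mathrm{sat}} - R_{\mathrm{apo}})$ with
   endpoints (1.0, 3.0) — no in vivo cardiomyocyte values are published
   for this construct, so the endpoints are exposed in the preset.
3. **Geometry and motion.** Chambers are elliptical wall annuli; the
   ventricular outer diameter along the measurement axis oscillates
   between EDD and ESD with a smoothstep contraction (0.24 T), a short
   hold at end-systole (0.16 T) carrying a 2 % parabolic dip — so the
   minimum is identifiable at frame resolution while the sampled ESD stays
   within 1 % of truth — and a slower smoothstep relaxation (0.40 T). The
   dip center lags the fine-grid ventricular *ratio* peak (the quantity
   the analysis tracks) by the preset lag. Myocardial fluorophore is
   conserved: the wall thickens as it shortens such that the annulus area,
   hence total wall fluorescence, is constant
   ($w(a) = a - \sqrt{a^2 - C}$ with $C$ set by the diastolic geometry).
   Without this, total wall intensity oscillates with contraction and the
   wall-versus-background weight mixture measurably tilts the flat sensor
   peak.
4. **Channels and artifacts.** Total wall fluorescence splits as
   $D = S/(1+R)$ and $F = S\,R/(1+R)$ — FRET redistributes photons, so the
   donor dims while the FRET channel brightens with calcium and the pixel
   ratio equals the ground-truth $R$ exactly. A global per-frame factor
   (amplitude 5 % of the contraction drive) applies common-mode
   motion/defocus to everything; a static Gaussian autofluorescence patch
   (ratio ≈ 1) sits near the atrium; a camera offset of 10 counts,
   Poisson shot noise and Gaussian read noise (SD 2) complete the camera
   model at a mid-wall budget of 1500 counts (donor + FRET summed).
5. **Presets.** `3dpf`: 4.0 Hz, EDD 95 µm, FS 25.9 %, lag 17 ms. `5dpf`:
   4.6 Hz (reported only as "faster"; 4.6 chosen once), EDD 110 µm, FS
   25.3 %, lag 44 ms. `motion_only`: the 3 dpf heart with a
   calcium-insensitive construct — constant $b$, full motion. For this
   preset autofluorescence and offset are zero so the noiseless ROI ratio
   is *exactly* constant; with any ratio-1 background the wall/background
   mixture varies as the wall moves and exact constancy is unattainable
   even for a perfect construct.

**What the generator does not emulate:** optical point-spread, z-motion
and out-of-plane loss, photobleaching, blood-cell shadows, wall
trabeculation, or spatial calcium gradients within a chamber. Passing the
recovery tests therefore demonstrates that the *analysis* is correct and
unbiased under realistic photon statistics and motion, not that every
property of real recordings is covered.

## Problem sizes, tolerances and reproducibility

Validation recordings are 10 s at 50 Hz (FS, heart rate) or 100 Hz
(delay) on 128×128 px frames at 1.45 µm/px — about 40 beats, the same
order as a real 5–10 s acquisition; unit tests use compact 64×64
geometries and 1–5 s durations. Expected recovery under default noise:
heart rate exact to the frame quantization of the median interval, FS
within 1 percentage point, AV delay and calcium-to-contraction lag within
half a frame of the mean. For delay estimation the analysis enables
ratio-trace Savitzky–Golay smoothing: near the peak of a
kinetics-limited sensor the trace is flat to within the shot-noise floor
over ±10 ms, so the frame-quantized argmax needs noise reduction before
it is meaningful — the standard treatment for noisy raw ratio traces.

All randomness (beat jitter, shot and read noise) flows from a single
seed; the same seed reproduces bit-identical videos and results, and the
analysis itself is deterministic.

## Known limitations

* Registration is a single global integer-pixel shift estimated from
  time-averaged images; sub-pixel or per-frame registration is out of
  scope.
* Diameter is measured along a fixed line; if the wall tilts strongly
  relative to the line the convention measures the chord, not the
  anatomical minor axis.
* The simultaneity window, prominence fraction, refractory period and
  rolling window are heuristics exposed in the configuration; the rhythm
  classification is only as fine as one frame.
* FAC by box-restricted Otsu is a convenience, not a segmentation method;
  it assumes a filled, roughly convex bright chamber.
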