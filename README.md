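# ratioheart

Ratiometric calcium imaging and contraction analysis for beating
(zebrafish larval) hearts.

## The problem

Measuring myocardial Ca²⁺ in a heart that is allowed to keep beating is
hard: contraction moves tissue through the imaging plane and modulates
single-channel fluorescence far more than Ca²⁺ does, which is why
GCaMP-style recordings are usually made in pharmacologically or
genetically arrested hearts. A FRET-based ratiometric sensor avoids the
arrest entirely. Motion is *common-mode* — it multiplies donor and
acceptor emission by the same factor — so the pixel-wise emission ratio

    R = F_FRET / F_donor

cancels it, while Ca²⁺ binding moves the two channels in opposite
directions and shifts R. The same frames also record the ventricular wall,
so Ca²⁺ and contraction can be measured simultaneously and correlated
beat by beat.

`ratioheart` is for experimentalists analyzing dual-emission (split-view
W-View-style or pre-split) fluorescence videos of beating hearts. It
provides:

* **imagestack IO** — 16-bit multi-page TIFF in/out with JSON metadata
  sidecars, dual-view splitting, integer-pixel channel registration by
  cross-correlation of time-averaged images;
* **ratiometry** — pixel-wise ratio stacks with near-background clipping
  into `[r_min/4, 4*r_max]`, intensity-weighted ROI traces
  `R = Σ wᵢRᵢ / Σ wᵢ` with `wᵢ = (Dᵢ+Fᵢ)/2`, a motion-artifact variance
  index, and intensity-modulated pseudo-color rendering;
* **transient kinetics** — automatic detection of Ca²⁺ transients
  (mid-level rising-edge criterion with refractory period) and per-cycle
  diastolic/systolic ratio, amplitude ΔR, 10–90 % rise and 90–10 % decay
  times and slopes, heart rate (median beat interval), R/R_Diast
  normalization, recording summaries;
* **contraction** — kymograms along a measurement line, outer-wall
  diameter tracking with sub-pixel threshold crossings, per-cycle
  end-diastolic/end-systolic diameter and fractional shortening
  `FS = (EDD − ESD)/EDD`, fractional area change, and the per-beat delay
  between the systolic Ca²⁺ peak and maximal shortening;
* **phase loops** — Lissajous diagrams with 20-ms arrowhead markers,
  shoelace loop area (hysteresis), and atrioventricular rhythm
  classification (`normal` / `simultaneous` / `ventricle_first`, the
  latter two indicating an escape rhythm);
* **intensiometric path** — EWMA smoothing (factor 0.7) and
  ΔF/F₀ = (F_t − F₀)/F₀ analysis for GCaMP-style single-channel traces;
* **synthetic heart** — a fully ground-truthed two-chamber video
  generator with biosensor binding kinetics (K_d = 2.8 µM,
  k_off = 2 s⁻¹, k_on = k_off/K_d ≈ 7×10⁵ M⁻¹s⁻¹), beating geometry,
  common-mode motion, autofluorescence and camera noise, used to validate
  the whole pipeline against known truth.

## Worked example

Generate a 10 s, 50 Hz recording of a 3 days-post-fertilization heart
preset (heart rate 4 Hz, EDD 95 µm, FS 25.9 %, Ca²⁺-to-contraction lag
17 ms) and run the full analysis:

```r
library(ratioheart)

vid   <- renderHeartVideo("3dpf", durationS = 10, frameRateHz = 50, seed = 0)
truth <- vid$truth

res <- analyzeHeartVideo(
  vid$donor, vid$fret,
  rois = list(ventricle = truth$roiVentricle, atrium = truth$roiAtrium),
  line = truth$line)

s <- res$summaries$ventricle
cat(sprintf("ventricle: %d cycles, HR %.0f bpm\n", s$n_cycles, s$heart_rate_bpm))
cat(sprintf("diastolic ratio %.3f, systolic %.3f, dR %.3f\n",
            s$mean_diastolic_ratio, s$mean_systolic_ratio, s$mean_amplitude))
cat(sprintf("rise %.0f ms, decay %.0f ms\n",
            1000 * s$mean_rise_time_s, 1000 * s$mean_decay_time_s))
cat(sprintf("FS %.1f%% over %d cycles (truth %.1f%%)\n",
            100 * res$fs$mean, res$fs$n, 100 * truth$trueFS))
cat(sprintf("Ca-peak to max-FS delay %.0f +- %.0f ms (truth %.0f ms)\n",
            1000 * res$delay$mean_s, 1000 * res$delay$sd_s,
            1000 * truth$caToFsLagS))
cat(sprintf("AV rhythm: %s (mean AV onset delay %.0f ms)\n",
            res$rhythm$label, 1000 * mean(res$rhythm$perBeat$delta_s)))
cat(sprintf("ventricle-vs-atrium loop area %.4f\n", res$loopArea))
```

Output:

```
ventricle: 34 cycles, HR 250 bpm
diastolic ratio 1.377, systolic 1.426, dR 0.049
rise 80 ms, decay 100 ms
FS 26.0% over 37 cycles (truth 25.9%)
Ca-peak to max-FS delay 16 +- 15 ms (truth 17 ms)
AV rhythm: normal (mean AV onset delay 59 ms)
ventricle-vs-atrium loop area -0.0528
```

Reading the numbers: the detector found 34 complete ventricular Ca²⁺
cycles; the heart rate is the 4 Hz preset quantized to the 20 ms frame
grid (median interval 0.24 s → 250 bpm). The diastolic ratio sits well
above the sensor's apo value because at 4 Hz the transients fuse — Ca²⁺
(and the slow sensor) never fully relax between beats, as expected for a
kinetics-limited sensor at this rate. Kymogram wall tracking recovers the
preset's fractional shortening within 0.1 percentage points, the
Ca²⁺-peak-to-maximal-shortening delay within a frame, and the
atrioventricular onset delay (60 ms in the generator) within 1 ms. The
negative loop area reflects the ventricle-leads-atrium orientation of the
pooled Lissajous trajectory.

File-based workflows use `runPipeline()` with a YAML config (see
`?runPipeline` and `?validateConfig`), which writes trace/cycle CSVs, a
kymogram TIFF, a summary JSON and a log; a thin command-line wrapper with
`analyze` and `synth` subcommands is installed at
`inst/scripts/ratioheart-cli.R`.

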