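---
title: "Methods: pillar tracking and contractility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pillar tracking and contractility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Engineered cardiac microbundles — 3-D microtissues of hiPSC-derived
cardiomyocytes grown between two flexible elastomeric pillars — report their
contractile function through the deflection of those pillars. Each pillar is
a cantilever that behaves, at the small deflections involved, as a linear
spring: a twitch that deflects a pillar cap by $\delta$ micrometres exerts a
force

$$F = k\,\delta,$$

where $k$ is the pillar bending stiffness in µN/µm. When $k$ has not been
measured experimentally it is derived from beam theory for a cantilever of
length $L$ loaded at height $a$:

$$k = \frac{6EI}{a^2(3L - a)}, \qquad
I_\text{rect} = \frac{w t^3}{12}, \qquad
I_\text{circ} = \frac{\pi D^4}{64},$$

with $E$ the elastic modulus of the pillar material and $I$ the second
moment of area of its cross-section. At $a = L$ the expression reduces to
the textbook end-loaded cantilever stiffness $3EI/L^3$, which the test suite
checks to machine precision.

**Deflection convention.** `pillartrack` computes the deflection of *each
pillar from its own rest position* and reports per-pillar forces plus their
mean. It never uses the change of the inter-pillar distance as "the"
deflection: that convention double-counts the motion and reports forces and
stresses twice as high. This is the single most important interoperability
choice in the package and it is fixed, not configurable.

Tissue stress divides the mean force by the tissue cross-sectional area,
`width × depth`, where the width is measured automatically on the first
fully relaxed frame and the depth is user-supplied (from 3-D imaging).

## Pipeline

1. **Segmentation** (`segment_pillars_threshold`). The first frame is
   thresholded with a *local Otsu* scheme: Otsu thresholds are computed on
   overlapping windows centred on a coarse grid (window radius defaults to
   1/8 of the smaller image dimension) and bilinearly interpolated to the
   pixel grid. Each local threshold is floored at the frame's global Otsu
   threshold; without that floor, windows lying entirely in flat background
   would split sensor noise into spurious foreground. The binary image is
   hole-filled, components below 50 px or touching the border are dropped,
   and the leftmost and rightmost surviving components become the left and
   right pillar masks (both supported platform designs have the pillars
   flanking the tissue laterally). Two fallbacks make the chain robust:
   if only one merged blob survives (pillars fused with the tissue band), a
   second Otsu threshold computed on the foreground intensities separates
   the high-contrast caps; and both contrast polarities (pillars brighter /
   darker than background) are tried. When no valid pair is found a
   `pt_segmentation_failure` is raised and the user can supply externally
   generated binary masks (`load_external_mask`).

2. **Feature detection** (`detect_features`, `auto_tune_params`).
   Fiducial markers are Shi–Tomasi "good features to track": local maxima
   of the smaller eigenvalue of the 5×5-block structure tensor, restricted
   to the pillar mask, thresholded at `quality × max(response)` and
   non-maximum-suppressed at 5 px. The response is computed on a 3×3
   smoothed copy of the frame so i.i.d. sensor noise, which carries no
   trackable structure, cannot masquerade as corners. Auto-tuning is a
   deterministic, monotone fallback: starting from quality 0.1, the level
   is halved (floor $10^{-4}$) until at least 10 corners are found; fewer
   than 3 corners at the floor is a `pt_tracking_failure`.

3. **Tracking** (`track_markers`, compiled in `src/tracking.cpp`).
   Iterative pyramidal Lucas–Kanade sparse optical flow (3 levels, 15 px
   window, 30 iterations, 0.01 px convergence) with two accuracy-oriented
   choices. First, the iteration uses *symmetric* window gradients (the
   average of the reference and target gradients), which suppresses the
   sub-pixel interpolation bias of the classic one-sided scheme. Second,
   tracking is *reference-anchored*: every frame is matched against the
   first-frame template, warm-started from the previous frame's
   displacement. The warm start keeps per-step increments far below the
   window size, while anchoring makes frame-to-frame error accumulation
   structurally impossible — in development, sequential tracking showed a
   systematic noise-induced creep of weak-texture markers toward
   high-gradient regions (≈0.9 px/beat at 4% noise on heavily eroded
   masks), which anchoring eliminates. Markers whose window leaves the
   image or whose normal equations degenerate are flagged invalid and
   dropped from all means, never interpolated; losing more than half of
   them aborts with `pt_tracking_failure`.

4. **Beat analysis** (`find_valleys`, `adjust_start`, `detect_drift`,
   `split_beats`, `detect_irregular_beats`). Beat timing is detected on the
   signed inter-pillar convergence (`dcol_left − dcol_right`) rather than
   on the mean absolute displacement: the convergence cancels common-mode
   drift exactly and is sign-unambiguous about which frames are relaxed
   even when the movie starts mid-beat (the absolute trace of a symmetric
   twitch measured from a contracted first frame is indistinguishable from
   a valid twitch train). The trace is smoothed by a moving average of
   width period/10 — the period taken from the periodogram peak of the
   *first-differenced* trace, so baseline drift cannot dominate — twitch
   peaks above 30% of the dynamic range are located (low enough that a
   depressed irregular beat is still segmented and can be flagged), and one
   valley is placed at the earliest minimum of each inter-peak interval.
   Candidate valleys whose trace value stays far above the relaxed baseline
   (a partial beat clipped by the movie edge) are discarded. At least 2
   complete beats are required for any analysis; if the movie does not open
   at a valley it is truncated to the first valley, markers are re-detected
   there, and the movie is tracked a second time. Drift is flagged when any
   valley offset of the mean absolute displacement exceeds 0.5 px
   (strictly); the optional per-beat split — available from 3 complete
   beats — re-bases each beat's displacements on the marker positions at
   that beat's own starting valley, which removes accumulated baseline
   offsets. Beats whose period or amplitude deviates more than 25% from the
   across-beat median are flagged irregular with a warning; no further
   action is taken.

5. **Mechanics and temporal metrics** (`force_trace`, `stress_trace`,
   `temporal_metrics`). Forces follow $F = k\delta$ pointwise on the
   deflection in µm. Per beat, the package reports amplitude, peak force,
   period, beating rate, contraction velocity (maximum positive
   central-difference derivative before the peak), relaxation velocity
   (maximum negative derivative magnitude after it), and the full
   durations at 50% (FWHM) and 80% (FW80M) of the peak, computed from
   linearly interpolated threshold crossings so they do not quantize to the
   frame rate. "FW80M" is interpreted as the full width at 80% of maximum,
   which is necessarily no larger than the FWHM for a unimodal beat.

## The synthetic movie generator

`render_movie` is first-class, tested code, not a fixture: it produces the
ground truth against which the whole pipeline is validated. It emulates the
features of brightfield two-pillar recordings that matter to tracking:

* two textured pillar caps (rectangular for "type1" strain-gauge devices,
  circular for "type2" fiber-matrix cantilevers) rendered as static
  speckle templates (uniform noise, lightly smoothed so Shi–Tomasi corners
  exist) on a darker uniform background, stored as 16-bit gray levels;
* a low-contrast tissue band joining the caps, whose texture stretches
  linearly between the two cap centres;
* rigid, mirror-signed horizontal cap translation following a raised-cosine
  twitch waveform (rising over `contraction_frac` of the period, relaxing
  over `relaxation_frac`, exactly zero in between), rendered by bilinear
  resampling of the templates so integer-pixel shifts reproduce rolled
  copies exactly and the ground truth is exact at any sub-pixel phase;
* optional common-mode baseline drift (px/frame), per-beat amplitude and
  period multipliers for irregular beats, a start-phase offset, and i.i.d.
  Gaussian sensor noise.

Default conditions: 160×256 px frames, 30-frame beat period at 30 fps
(1 Hz pacing), 95 frames (3 complete beats), 4 px peak deflection, noise
1–5% of the gray range in the validation set. These mirror the acquisition
regime of standard strain-gauge devices (30 fps, pacing at 1 Hz); the peak
amplitudes span 2–6 px because sub-pixel motions below ≈1 px are outside
the validated accuracy envelope of sparse optical flow.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: out-of-plane motion and defocus, illumination flicker
and shading, deforming (non-rigid) pillar texture, camera shot noise
statistics, and debris. The validation bounds reproduced here (tracking
error and mask-perturbation sensitivity both below 10%) therefore
demonstrate the correctness of the algorithmic chain under controlled
conditions, not the field performance on any particular microscope.

## Numerical and design choices

* Coordinates are 1-based `(row, col)` from the top-left corner, R's native
  convention; every scientific output is a displacement (a difference), so
  the base does not affect results.
* The waveform's sampled peak is rescaled to the requested amplitude, so
  `max(make_waveform(...)) == peak_amplitude_px` holds exactly for any
  pulse shape and period.
* Valley ties (flat diastolic intervals) break toward the earliest frame.
* Beat intervals are half-open `[start_valley, end_valley)`; the number of
  complete beats is the number of valleys minus one and is invariant to a
  trailing partial beat.
* The drift tolerance (0.5 px) sits below typical whole-mask tracking noise
  but above rounding effects; the irregular-beat tolerance (25% of median)
  is exposed in the configuration. Neither is stated by the measurement
  model itself — both are package choices.
* Degenerate inputs fail loudly with typed conditions
  (`pt_segmentation_failure`, `pt_tracking_failure`,
  `pt_insufficient_beats`) so batch runs can report per-movie failures
  without aborting.

## Problem sizes

The bundled validation uses five movies of 95 frames at 160×256 px
(deflections 2–6 px, noise 1–5%), tracked with the reference mask and with
four 5×5-kernel erode/dilate perturbations each. These sizes make the
whole acceptance computation reproducible on a laptop CPU in well under
two minutes while keeping every displacement regime of interest (sub-pixel
per frame, multi-pixel per beat) represented.

## Known limitations

* Beats smaller than ≈30% of the dominant amplitude are merged into their
  neighbouring beat rather than flagged.
* The tissue-width measurement assumes a roughly horizontal tissue band
  between the pillars; strongly tilted tissues need a manually supplied
  width.
* Only TIFF input is supported, and only the threshold-based segmentation
  path is implemented; learned segmentation models are out of scope.
* The per-pillar deflection convention is intentionally not configurable.
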