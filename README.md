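# pillartrack

Automated tracking and contractility analysis of two-pillar cardiac
microbundle movies.

Engineered cardiac microtissues ("microbundles") of hiPSC-derived
cardiomyocytes are grown between two flexible elastomeric pillars. Each
pillar is a cantilever that acts as a linear spring, so the tissue's twitch
force can be read out non-invasively from brightfield time-lapse movies:

> F = k·δ,  with k = 6EI / (a²(3L − a)) when not measured directly,
> I = wt³/12 (rectangular cross-section) or πD⁴/64 (circular),

where δ is the deflection of a pillar cap from its rest position, E the
elastic modulus, L the cantilever length, a the loading height, and I the
second moment of area. Stress divides the force by the tissue
cross-section (width × depth). **Deflection is measured per pillar from its
own rest position and averaged over the two pillars — never as the change
of the inter-pillar distance, which would report forces twice as high.**

The package is aimed at labs doing microbundle contractility assays who
want a fully automated, parameter-free pipeline: given a movie, a frame
rate, a length scale, a pillar stiffness (or geometry) and a tissue depth,
it produces displacement, force and stress traces plus per-beat metrics
(amplitude, peak force, period, beating rate, contraction/relaxation
velocities, FWHM, FW80M), in single or batch mode.

## What it does

1. Segments the two pillar regions on the first frame by local Otsu
   thresholding (externally generated binary masks are accepted when
   automatic segmentation fails).
2. Detects Shi–Tomasi corner markers inside each mask (parameters
   auto-tuned) and tracks them with a sub-pixel pyramidal Lucas–Kanade
   sparse optical flow tracker (Rcpp).
3. Finds the valley (fully relaxed) frames, re-bases the movie to start at
   a valley (re-tracking if needed), detects baseline drift, optionally
   splits the movie into beats with per-beat baselines (≥ 3 beats), and
   flags irregular beats. Movies with fewer than 2 complete beats are
   rejected.
4. Converts deflections to twitch forces and tissue stresses via the
   cantilever model and writes traces (`.txt`), plots (`.png`), masks,
   raw marker positions, warnings and machine-readable flags.

A synthetic two-pillar movie generator with exactly known ground-truth
motion (`synthetic_movie_spec()` / `render_movie()`) backs the entire test
suite, so every stage is validated end-to-end without any data download.

## Worked example

```r
library(pillartrack)

# a synthetic recording: 3 beats at 1 Hz (30 fps), 4 px peak deflection
mv  <- render_movie(synthetic_movie_spec(peak_amplitude_px = 4,
                                         noise_sigma = 0.02))
cfg <- run_config("type1", fps = 30, length_scale = 4,   # um/px
                  stiffness = 2.677,                     # uN/um
                  tissue_depth = 350)                    # um
res <- run_single(mv$stack, cfg, output_dir = "results_demo")
res
#> <contractility_result>
#>   beats: 3 complete | rate: 1.000 Hz | drift: FALSE | split: FALSE
#>   mean peak force: 41.963 uN | mean amplitude: 15.675 um | mean FWHM: 0.497 s
#>   tissue width: 164.0 um
```

Reading the numbers: the 4 px twitch at 4 µm/px is recovered as a
15.68 µm mean peak deflection (within 2% of the 16 µm ground truth), the
peak force is k·δ = 2.677 × 15.675 ≈ 41.96 µN, the beating rate matches
the 30-frame period at 30 fps (1 Hz), and the FWHM of a raised-cosine
twitch spanning a 1 s beat is 0.5 s.

The same pipeline runs from the shell:

```sh
inst/scripts/pillartrack synth --out demo --amplitude 4 --seed 5
inst/scripts/pillartrack run --movie demo/frames --config config.yaml --out results
inst/scripts/pillartrack batch --root movies/ --config config.yaml --out results
inst/scripts/pillartrack mask-check --movie demo/frames
```

## Documentation

The methods vignette (`vignettes/pillartrack-methods.Rmd`) documents the
model, the algorithmic choices (local Otsu cleanup chain, symmetric-gradient
reference-anchored Lucas–Kanade, drift-robust valley detection), the
synthetic generator's scope, and known limitations.
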