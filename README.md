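# holopollen

Computational reconstruction and evaluation statistics for lens-less
digital in-line holographic microscopy (DIHM) of pollen slides.

A lens-less DIHM places a microscope slide a few millimetres above a bare
image sensor and illuminates it with a quasi-plane laser wave (here:
658 nm over a 3840 x 2160, 2.0 µm-pitch, 12-bit sensor). The recorded
in-line hologram is the interference of the unscattered reference wave
with the light scattered by the grains. A single numerical
backpropagation to the object plane recovers a focused image, but one
contaminated by the defocused "twin" image; iterative phase retrieval
suppresses the twin and yields a brightfield-like amplitude image that a
trained observer can classify by eye. This package is for optics and
image-analysis researchers who want that pipeline — and the statistics
used to compare human classification across imaging modalities — as
tested, scriptable R functions.

## What it implements

**Wave optics.** Angular spectrum propagation with the exact kernel
`exp(i 2π d sqrt(1/λ² − fx² − fy²))` on the propagating band and hard
zero on the evanescent band; background-fill padding; signed distances
with `+i` forward convention (`make_transfer_function()`, `propagate()`,
`backpropagate()`).

**Reconstruction.** Background normalisation, the initial field
`Ũ = sqrt(H)`, single backpropagation, and the Gerchberg–Saxton loop
(default 200 iterations) alternating between planes with two constraints:
at the object, amplitudes above 1 are clipped to `1 + 0i` (a passive
object; phase reset only at clipped pixels); at the sensor, the amplitude
is replaced by the measured `sqrt(H)` while the retrieved phase is kept
(`gs_reconstruct()`). Automated refocus-distance selection scans a
single backpropagation with a Tamura-of-gradient sharpness score
(`autofocus()`), and `twin_suppression_ratio()` quantifies the background
cleanup.

**Synthetic data.** Stylised phantoms of six allergenic pollen taxa
(timothy grass, common ragweed, silver birch, common alder, olive tree,
hazel), forward-simulated holograms with shot/read noise and 12-bit
quantisation, and simulated two-evaluator reading studies drawn from
per-modality confusion structures (`render_phantom()`,
`simulate_hologram()`, `generate_study_records()`).

**Evaluation statistics.** Accuracy (percent, half-up to one decimal),
pooled-by-counts accuracy, confusion matrices, per-class
`F1 = 2TP/(2TP+FP+FN)`, and Cohen's `κ = (p_o − p_e)/(1 − p_e)` for
inter-observer and inter-modality agreement (`summarize_study()`).

## Worked example

Simulate a noiseless hologram of two grains, reconstruct it both ways,
and compare:

```r
library(holopollen)

geom  <- field_geometry(192, 192)            # 2 µm pitch, 658 nm defaults
scene <- render_phantom(geom, 2, seed = 3)
holo  <- normalize_hologram(simulate_hologram(scene, 2546, noise_model(0)))

bp <- single_backpropagation(holo, 2546)
gs <- gs_reconstruct(holo, 2546, gs_config(n_iterations = 200))

truth <- Mod(scene$transmission$values)
sqrt(mean((bp$amplitude - truth)^2))   # 0.0238  twin-image-contaminated
sqrt(mean((gs$amplitude - truth)^2))   # 0.0053  after phase retrieval
twin_suppression_ratio(bp, gs, scene$truth_mask)   # 31.3x cleaner background

autofocus(holo, 2300, 2800, 10)$best_h  # 2580: the apparent focal plane
```

The iterative result is ~4x closer to the true transmission amplitude and
its background ringing is ~31x weaker — the twin image is suppressed.
The autofocus lands 34 µm beyond the simulated distance: a phase-shifting
grain acts as a weak lens, so the sharpest-amplitude plane sits slightly
beyond the geometric object plane (see the vignette).

Reading-study statistics from the deterministic benchmark record set:

```r
summarize_study(pollen_study_records())
#>                 metric modality evaluator  value
#>               accuracy     DIHM   expert1  97.9
#>               accuracy     DIHM   expert2  93.8
#>        pooled_accuracy     DIHM       all  95.8
#>               accuracy  optical   expert1  95.8
#>               accuracy  optical   expert2  97.9
#>        pooled_accuracy  optical       all  96.9
#>    kappa_interobserver     DIHM      pair  0.950
#>    ...
per_class_f1(build_confusion(pollen_study_records()))
#>  timothy_grass common_ragweed   silver_birch   common_alder
#>          1.000          1.000          0.889          0.938
#>     olive_tree          hazel
#>          0.984          0.970
```

A thin command-line front end (`inst/exec/holopollen`) exposes the same
pipeline as `simulate`, `reconstruct`, `focus` and `stats` subcommands
driven by a YAML configuration.

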