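---
title: "Lens-less holographic reconstruction of pollen slides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lens-less holographic reconstruction of pollen slides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holopollen)
```

## The imaging model

A lens-less digital in-line holographic microscope (DIHM) places a
transparent slide a few millimetres above a bare sensor and illuminates it
with a quasi-plane wave from a laser diode. The sensor records the
interference of the unscattered reference wave with the light scattered by
the specimen — the in-line hologram $H(x, y)$. `holopollen` works in the
geometry of a 3840 x 2160 monochrome sensor with 2.0 µm pixels under
658 nm illumination, with an object-to-sensor distance $h$ around 2.5 mm;
all of these are parameters of `field_geometry()` and the run
configuration, not hard-coded constants.

Propagation between the object and sensor planes uses the angular spectrum
method: the field is decomposed into plane waves by a discrete Fourier
transform, each component at spatial frequency $(f_x, f_y)$ (cycles/µm) is
multiplied by

$$H_d(f_x, f_y) = \exp\!\left( i\, 2\pi d \sqrt{1/\lambda^2 - f_x^2 -
f_y^2} \right),$$

and the field is recomposed. We use the exact square-root kernel rather
than the paraxial (Fresnel) quadratic approximation because at $h \approx
2.5$ mm over a 7.7 mm sensor the marginal ray angles are not deeply
paraxial. Frequencies beyond $1/\lambda$ are evanescent; their kernel
value is set to exactly zero, which prevents exponential blow-up under
backpropagation. At the native 2.0 µm pitch the discrete frequency grid
never reaches the evanescent band, so this guard only matters for
finer-sampled simulations. Forward propagation (object to sensor,
positive $d$) carries the $+i$ exponent; `transfer(-d)` is the complex
conjugate of `transfer(d)`.

Before each transform the field is embedded in a grid enlarged twofold per
axis (`pad_factor = 2`), with the border filled with the mean of the
field's outer 8-pixel frame. A normalised hologram has unit background,
so zero-padding would carve a spurious dark aperture into the field and
diffract energy from its edge; mean-filling does not. The result is
cropped back after the transform.

## Reconstruction

A raw hologram is first normalised to its background
(`normalize_hologram()`). The default estimator is the frame mean —
appropriate because grains are sparse on the slide — with a border-mean
and a pixelwise reference-frame option for crowded fields or structured
illumination. The initial sensor-plane wavefield is
$\tilde U = \sqrt{H}$ with zero phase.

A **single backpropagation** transports $\tilde U$ to the object plane in
one step. The focused ("real") image appears superimposed with the
defocused conjugate ("twin") image, visible as concentric rings around
every grain.

The **iterative reconstruction** (`gs_reconstruct()`) is a
Gerchberg–Saxton loop with a physical constraint in each plane:

1. backpropagate the sensor field by $h$;
2. object constraint: a passive slide cannot amplify light, so at pixels
   where the amplitude exceeds 1 the value is replaced by $1 + 0i$ — the
   amplitude is clipped and the phase at those (and only those) pixels is
   reset to zero;
3. propagate forward by $h$;
4. sensor constraint: the amplitude is replaced by the measured
   $\sqrt{H}$ while the retrieved phase is kept.

The loop runs for a fixed 200 iterations by default — enough for
convergence on pollen holograms — with no tolerance-based early exit. A
final backpropagation plus object constraint yields the transmission
amplitude $\tilde T$ (a brightfield-like image) and phase
$\tilde\varphi$; taking the output *after* the constraint guarantees
$\tilde T \le 1$. With `record_misfit = TRUE` the RMS sensor-plane
amplitude residual is logged each iteration, immediately before step 4;
it is a diagnostic only, never a stopping rule.

Two conventions are worth stating explicitly because they are invisible
in the formulas. Retrieved phases are referenced to the illuminating
plane wave: the global carrier phase $e^{\pm 2\pi i h/\lambda}$
accumulated by propagation is divided out inside the reconstruction, so a
clear background sits at amplitude 1 and phase 0 and the zero-phase reset
in step 2 is meaningful. And pixels that arrive at the sensor constraint
with exactly zero amplitude have no defined phase; they adopt phase 0, a
deterministic convention.

With zero iterations `gs_reconstruct()` reduces exactly to a clipped
single backpropagation, which the test suite checks bit-for-bit.

## Refocus-distance selection

Reconstruction quality depends sharply on $h$. The package automates the
visual procedure of scanning a single backpropagation through candidate
distances and choosing the sharpest: `sharpness_score()` is the Tamura
coefficient of the gradient magnitude, $\sqrt{\sigma(g)/\mu(g)}$ with
$g = |\nabla \tilde T|$ by central differences — a well-established focus
metric for holography. `autofocus()` scans a grid (default 2300–2800 µm
in 10 µm steps), breaks ties toward the smaller distance, and can polish
the coarse optimum with a golden-section pass within one grid step. A
constant image scores 0 by convention.

A property of this procedure that users should understand: **for
phase-shifting objects the sharpest-amplitude plane is not the geometric
object plane.** A pollen grain's dome-shaped optical thickness acts as a
weak lens, and we measure that it displaces the best-focus plane of the
backpropagated amplitude by roughly 20–55 µm beyond the geometric
distance for phantoms with a 1 rad peak phase shift. This is not a
defect of the metric: an independent oracle — the distance minimising the
truth-RMSE of the backpropagated amplitude — lands on the same displaced
plane, while phase-free control scenes are recovered to within one grid
step. Any sharpness-based selection, including visual inspection,
returns this apparent focal plane; the spread is of the same order as the
±54 µm slide-to-slide variability reported for manually focused pollen
holograms. On a minority of scenes the metric can also lock onto a
secondary maximum created by overlapping twin-image fringes, so a bounded
scan range remains important.

## The synthetic-data generator

No pollen hologram dataset is bundled, so the package ships a generator
that emulates the study conditions end to end.

**Phantoms.** `render_phantom()` places non-overlapping grains at random
positions and orientations and rasterises a complex transmission
function. Silhouettes are stylised versions of the morphology evaluators
actually use: timothy grass as a smooth oval, common ragweed as a round
grain with short radial spikes, hazel as a rounded triangle, silver birch
as a triangular shape with per-grain variability (the source of its
confusability), common alder as a rounded pentagon, and olive as a bean
outline with a darker central furrow. Absorption and phase follow the
chord thickness of a dome — peaking at the centre, zero at the rim —
with species defaults of 0.25–0.30 minimum transmission and 1.0–1.2 rad
peak phase. Grain diameters (20–40 µm, species-specific means) are
literature-typical pollen scales; the study itself prints no sizes, so
these are package defaults, exposed in `pollen_species()`. Every scene
satisfies $\max|T| \le 1$, the assumption behind the object constraint.

**Holograms.** `simulate_hologram()` propagates the transmission forward
by $h$, records $|U|^2$, and applies a sensor model: Poisson shot noise
at `photons_at_unit_intensity` expected photons for the unit background
(default 5000, a mid-exposure setting), Gaussian read noise (default 3
counts), and 12-bit quantisation with the digital gain set so that unit
intensity sits at a quarter of full scale — constructive interference up
to four times the background never saturates. Setting the photon budget
to 0 selects exact, noiseless simulation (still quantised), which the
closed-loop tests use.

What the generator does *not* emulate: real grain texture (exine
ornamentation beyond spikes), wrapped multi-radian phases of thick grains
in index-mismatched media, plant debris, illumination non-uniformity and
speckle, and slide-to-slide density variation. Passing closed-loop tests
therefore demonstrate the correctness and stability of the reconstruction
machinery under the stated optical model, not classification performance
on real slides.

**Reading studies.** `generate_study_records()` draws two-evaluator,
two-modality classification records from per-modality 6 x 6 confusion
matrices, with image identities shared between evaluators and modalities
so that both inter-observer and inter-modality agreement are computable
on matched content. The default confusion structure concentrates errors
among silver birch, common alder and hazel. `pollen_study_records()` is
the deterministic record set whose counts reproduce the benchmark
study's accuracies and per-class F1 exactly; evaluator psychology beyond
a confusion matrix is out of scope.

## Evaluation statistics

Accuracies are percentages rounded half-up to one decimal, the convention
of the benchmark tables (45/48 prints as 93.8). Pooled accuracies are
computed from summed counts, never by averaging rounded percentages —
47/48 and 45/48 pool to 92/96 = 95.8, whereas the rounded per-set values
average to 95.85. Per-class F1 is $2\,TP/(2\,TP + FP + FN)$ from the
pooled confusion matrix, three decimals, with an empty class defined as 0
and flagged. Cohen's $\kappa = (p_o - p_e)/(1 - p_e)$ uses the raters'
marginal label frequencies for $p_e$; the implementation is validated
against an exhaustive from-definition oracle over all 4096 binary
label-pair vectors of length six. Inter-modality agreement pairs each
evaluator's holographic labels with their own optical labels on the same
image content.

The headline agreement values of the benchmark study cannot be recomputed
from its printed tables — the paired label vectors are never published —
so the package validates the $\kappa$ implementation by oracle and
reports the values computed from its own deterministic record set.

## Problem sizes and numerical choices

The test suite and the acceptance script run the multi-seed closed-loop
properties on 192 x 192 px scenes with two grains each (20 seeds, 200 GS
iterations, twofold padding) and exercise the full 3840 x 2160 sensor
format through a short iterative run; the full-frame, 200-iteration
reconstruction is supported unchanged and scales linearly in iterations
and in FFT cost. Other defaults: clip level 1.0, autofocus scan
2300–2800 µm in 10 µm steps, golden-section refinement off, frame-mean
background normalisation. Ties in the focus scan resolve to the smaller
distance; degenerate inputs (all-zero frames, empty backgrounds, empty
record sets) raise errors rather than returning silent defaults.

## Known limitations

* Quasi-plane-wave illumination only: no point-source magnification or
  partial-coherence modelling.
* Single-plane reconstruction: no multi-focus stacks or volumetric
  refocusing.
* The phase output is carried through but not further analysed; only the
  amplitude feeds the evaluation workflow.
* Sharpness-based autofocus returns the apparent focal plane, which for
  strongly phase-shifting specimens can sit tens of micrometres from the
  geometric object plane (see above).
* Stylised phantoms: conclusions about human classification of real
  pollen require real slides.
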