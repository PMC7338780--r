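---
title: "Counting stained pollen: the pollenQuant pipeline and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting stained pollen: the pollenQuant pipeline and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenQuant)
```

## The measurement problem

Under a modified Alexander stain, viable pollen grains stain dark blue and
dead grains light blue on a pale background. A human scorer tallies both
classes under the microscope; `pollenQuant` automates the tally from an RGB
micrograph. The central observation is spectral: *both* stain classes are
dark in the red channel, while only the dark-blue (viable) class is dark in
the green channel. Counting dark particles per channel therefore gives the
total pollen number $N$ (red) and the viable number $V$ (green), and percent
viability is

$$\mathrm{PV} = 100 \cdot V / N.$$

PV is reported as `NA` when $N = 0$ — "no pollen seen" must stay
distinguishable from "0% viable" in downstream aggregation — and values
above 100 (the green count overshooting the red count, a documented failure
mode of miscalibrated filters or poor stain contrast) are returned as-is
with a flag, never silently clamped.

## The pipeline, stage by stage

`processImage()` composes, in order:

1. *(optional)* **Contrast enhancement** (`enhanceContrast`): per-channel
   linear stretch saturating a chosen percentage of pixels, half per tail.
   Off by default: it is a rescue step for weakly stained slides, and
   overuse makes lightly stained grains register in the green channel,
   inflating the viable count.
2. **Background subtraction** (`subtractBackground`): per channel, the
   illumination field is the grayscale morphological closing with a disc of
   radius 50 px — the surface a rolling ball of that radius traces over the
   dark grains. The estimate is subtracted and the channel's median
   background level re-added, so an already-flat image passes through nearly
   unchanged while gradients are levelled. The radius must exceed the grain
   radius (grains of 100–900 px² have radii ~6–17 px) or grains leak into
   the background estimate; 50 px leaves a generous margin and is
   configurable.
3. **Channel split** (`splitChannels`).
4. **Binarization** (`binarize`): a global histogram threshold; foreground
   is *strictly below* it (stained grains are dark in their diagnostic
   channel). The default method is IsoData iterative intermeans
   ($t \leftarrow (\mu_{\le t} + \mu_{> t})/2$ iterated from the global mean
   to a fixed point); Otsu is selectable by name. Because any histogram
   split always isolates *some* darkest mode — sensor noise on a blank
   channel, or the faint light-blue mode on a channel with no viable
   grains — the split is accepted only when the background mean exceeds the
   foreground mean by at least `minContrast` (default 50 of 255 levels).
   Stain classes are distinguished by strong contrast (dark-blue grains sit
   ~165–175 levels below background in their diagnostic channels, the
   light-blue green-channel offset is only ~35), so 50 separates the two
   regimes with wide margins; set `minContrast = 0` to recover the raw
   threshold behaviour.
5. **Refinement** (`refineMask`): dilate ×$k$, fill holes, erode ×$k$ with a
   3×3 square element ($k$ = 1 by default) — closes stain-centre holes and
   ragged edges while approximately preserving outlines of convex objects.
6. **Watershed separation** (`watershedSplit`): the Euclidean distance
   transform of the foreground, segmented by the watershed transform with
   seeds at distance-map local maxima. Seed policy is fixed for
   determinism: maxima detected in a 5×5 neighbourhood (minimum peak
   separation ~5 px) with plateau maxima differing by less than 1 distance
   unit merged — elongated single grains have flat ridges and must not be
   oversplit, while touching convex grains have distinct peaks and must be.
7. **Measurement and filtering** (`measureParticles`, `filterParticles`):
   per labelled object, exact pixel-count area, contour perimeter, the
   circularity $C = \min(1,\, 4\pi A / P^2)$, centroid in 0-based
   (row, col), and a border-touching flag; then the scenario's inclusive
   size and circularity windows are applied.

## Numerical choices worth knowing about

**Perimeter estimator.** Circularity thresholds are only meaningful with a
fixed perimeter definition. The package traces each object's outer contour
by Moore-neighbour tracing (Jacob's stopping criterion) and sums chain-code
step weights **0.948 per straight and 1.340 per diagonal step** — the
bias-corrected (Vossepoel–Smeulders) weights. The naive 1/√2 weighting
overestimates contour length by ~5% averaged over orientations, which drags
rasterized discs down to $C \approx 0.9$ and would make the 0.4/0.5/0.6
window bounds mean something different from their continuous-geometry
reading; with the corrected weights, discs of radius ≥ 8 measure
$C \approx 1$. Single-pixel objects get the crack perimeter 4.

**Circularity clipping.** Discrete perimeters of small objects can push
$4\pi A/P^2$ above 1; clipping to 1 keeps the windows' upper bound of 1
attainable.

**Inclusive windows.** All filter bounds are closed intervals, matching how
ranges such as 100–900 px² and 0.4–1 are conventionally printed: a particle
of area exactly 100 at circularity exactly 0.4 survives the S1 filter.

**Connectivity and borders.** Foreground objects are 8-connected (the
watershed transform joins diagonal neighbours; a 4-connectivity mode
additionally splits labels into 4-components). Border-touching particles
are *counted* by default: excluding them silently biases counts downward on
dense images; `excludeEdges = TRUE` is available since both conventions are
in use among particle-analysis tools.

**Selection tie-breaks.** `selectBestScenario()` maximizes the count
correlation, breaking ties by the viability correlation and then by
scenario name. The count correlation leads because every reported quantity,
PV included, derives from the two counts; the name tie-break makes the
selection deterministic when several windows contain every measured
particle and are therefore empirically indistinguishable.

**Over-100% PV.** Images with automatic PV > 100 are retained in the
viability correlation by default (`includeOver100 = FALSE` excludes them):
they are informative evidence of a miscalibrated scenario, and dropping
them would flatter exactly the parameterizations being screened out.

## The synthetic scene generator

`generateScene()` renders what the pipeline exploits, with exact per-grain
ground truth:

* **Colour model** (RGB, ± per-grain jitter of SD 4): background
  (235, 225, 230); viable grains (70, 50, 120) — dark in red *and* green;
  non-viable grains (140, 190, 220) — dark in red only. The non-viable red
  level sits at 140 so that the IsoData fixed point, which approaches
  $(\bar\mu_\text{grain} + 235)/2 \approx 153$ in high-viability scenes,
  keeps better than 3σ of margin to the non-viable mode in every class mix.
* **Geometry**: ellipses with areas uniform on `grainAreaRange` (default
  150–850 px²) and eccentricity ≤ 0.6, keeping grain circularity well
  inside every catalog window; orientation uniform.
* **Spatial layout**: non-clustered objects keep ≥ 6 px of background
  between boundaries (one dilate/erode cycle cannot merge them);
  a `clusterFraction` of grains (default 15%) is placed in touching chains
  of 2–3 with centre separation 1.25–1.7 × mean effective radius. A packing
  guard rejects scenes above 30% grain cover. Debris distractors that do
  not fit in a crowded scene are dropped; requested *grain* counts are
  always honoured or the scene errors.
* **Distractors**: small dark specks (~10–32 px², below every size window)
  and large dark blobs (≥ 1000 px², above every window; capped to stay
  placeable in small scenes).
* **Noise and illumination**: i.i.d. Gaussian sensor noise (SD 3 levels by
  default) and an optional ±15-level linear illumination ramp.
* **Determinism**: one seed drives a private RNG stream with a fixed draw
  order (classes, geometry, cluster assignment, placement, colours, noise),
  so scenes are bit-reproducible and the caller's RNG state is untouched.

`generateBenchmark()` assembles an optimization set in the style of a real
validation campaign: 31 images by default, true totals spanning 20–120,
true viabilities 10–95%, grain areas drawn with probability 0.1 from
[100, 200) px² and otherwise from [200, 900] px², every other image carrying
the illumination ramp, and the ground-truth table emitted in the
manual-count CSV format. The small-area admixture and the upper size tail
are what make the sweep discriminating: windows starting at 200 px²
(S2/S4/S6) lose a *varying* fraction of grains per image, and S0's 800 px²
ceiling clips the upper tail, degrading their count correlations relative
to S1.

What the generator does **not** emulate: optical point-spread and chromatic
aberration, partially stained or germinating grains, out-of-focus planes,
and debris with stain-like colour *inside* the size windows. Passing the
synthetic validation therefore demonstrates the correctness of the
processing chain and the discriminating power of the scenario sweep under
the stain-contrast model — not robustness to every real-world imaging
defect; for a new crop or camera, the intended workflow remains a small
manual-count calibration via `evaluateScenarios()`.

## Validation problem sizes

The shipped test-and-validation suite works at these scales, chosen to make
the geometry non-trivial while each property is re-checked from scratch at
every run: exact count recovery on 100 seeded 512×384 scenes of 10–28
well-separated grains each (expected exact on ≥ 95%); watershed separation
on 100 seeded 2- and 3-grain clusters of radius 10–16 px with centre
separation 1.25–1.8 × mean radius and per-cluster radius spread of ±8%
(grains of one species are near-uniform in size); the full scenario sweep on
the 31-image default benchmark at 1024×768; and exhaustive or randomized
oracles for the PV formula, the filter windows, and the correlation
statistic.

## Known limitations

* The counts-by-colour principle breaks when stain contrast is poor; the
  contrast-enhancement rescue exists but trades total-count accuracy
  against viable-count inflation, in line with staining practice guides.
* Heavily over-clustered samples undercount even with watershed splitting —
  slide preparation (thorough vortexing) matters more than any parameter.
* Areas are reported in raw pixel²; no physical calibration (µm²) is
  attempted, so filter windows are only transferable between images of the
  same optical configuration.
* Germination scoring (tube growth) is out of scope: the pipeline measures
  stain uptake, not germinability.
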