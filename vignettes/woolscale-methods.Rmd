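---
title: "Scale morphometry and dye kinetics: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale morphometry and dye kinetics: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woolscale)
```

## The problem

The cuticle of a wool fibre is tiled with overlapping keratinised cells
("scales"). The visible scale edges are the openings of intercellular gaps,
which are the main route by which water, dyes and other small molecules
enter the otherwise hydrophobic, crosslinked fibre surface. Two summary
statistics of a 2-D micrograph quantify this "effective diffusion pathway":

* **Total scale perimeter per 100 µm** — the summed length of all visible
  scale-boundary traces inside a 100 µm axial window of a single straight
  fibre, in µm.
* **Scale perimeter index (SPI)** — that perimeter divided by the fibre
  diameter; dimensionless, and empirically decreasing with diameter.

Fibre diameter also predicts the qualitative arrangement of the scales:
fine fibres (< 25 µm) carry transverse ring-like *coronal* boundaries,
medium fibres (25–50 µm) diagonal-banded *coronal-reticulate* networks, and
coarse fibres (> 50 µm) irregular random *reticulate* tiles.

On the kinetics side, early dye uptake by a cylinder of radius $r$ obeys

$$\frac{M_t}{M_e} = 4\sqrt{\frac{D\,t}{\pi r^2}},$$

so the **apparent diffusion coefficient** $D$ follows from the slope $k$ of
relative uptake against $\sqrt{t}$: $D = k^2 \pi r^2 / 16$. Uptake itself is
the bath mass balance $M_t = (C_0 - C_e)\,V/W$, with residual concentration
$C_e$ read off a Beer–Lambert calibration at the dye's absorbance maximum.

The morphology–kinetics bridge is a through-origin quadratic
$y = a x + b x^2$ linking perimeter per 100 µm ($y$) to diameter ($x$),
with reference coefficients $(a, b) = (14.41, -0.04)$, plus breed-level
straight-line relations between $D$ and each morphology summary.

## Pipeline and assumptions

`measure_fibre()` chains three stages:

1. **`detect_fibre()`** — Otsu threshold, largest connected component,
   principal axis through the component's pixel centroids, and the diameter
   as the mean of 50 chords perpendicular to the axis (the 50-reading
   protocol; CV% across chords is reported). Assumes one straight fibre
   band spanning the frame. If the first Otsu split lands between the
   fibre surface and its bright boundary curves (which happens when the
   band fills most of the frame), the split is retried on the lower grey
   levels; the candidate with the more solid component wins.
2. **`segment_scale_edges()`** — scale boundaries render as bright ridge
   lines; a light 3×3 binomial smooth, hysteresis thresholds at 25% / 50%
   of the ridge contrast above the in-mask median, Zhang–Suen thinning, and
   pruning of spurs shorter than 3 px. Two repairs matter in practice:
   thinning retracts the ends of thick lines by 1–2 px, which would
   disconnect scale regions at the fibre margin, so the edge support is
   extended 2 px beyond the mask before thinning and cropped after; and
   Zhang–Suen leaves redundant "staircase corner" pixels whose adjacent
   pairs read as spurious chain-code triangles (up to +60% length on
   diagonal bands), so a sequential simple-point cleanup removes every
   pixel whose neighbours stay mutually 8-connected without it.
3. **`measure_windows()`** — 100 µm windows tile the axis from its first
   station; an incomplete trailing window is dropped. Perimeter is the
   chain code of skeleton edges (1 per orthogonal step, $\sqrt2$ per
   diagonal step, each adjacent pair once) assigned to windows by edge
   midpoint. Scale regions are 4-connected components of mask minus
   skeleton; a region wholly inside a window counts 1, a region cut by a
   window line or the axial frame ends counts 0.5 (the "partially visible"
   rule made operational).

A single boundary trace is measured once, as its centre-line skeleton; the
two margins of an intercellular gap are not counted separately.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_um` | 100 | axial window length (µm); the reference protocol value |
| `n_chords` | 50 | chords averaged for the diameter |
| `high`, `low` | 0.5, 0.25 | hysteresis thresholds, fraction of ridge contrast |
| `min_region_px` | 4 | regions smaller than this are segmentation debris |
| `cutoff` | 0.5 | early-phase $M_t/M_e$ limit for the Hill fit |

The Hill fit is forced through the origin because the model has zero uptake
at $t = 0$; the source protocol does not state intercept handling, so this
is the package's choice. Equilibrium uptake $M_e$ defaults to the mean of
the last two points at $t \ge 180$ min (flagged `"no plateau"` if the
series is still rising); a user-supplied $M_e$ overrides. Times are
converted minutes → seconds before $\sqrt t$; $D$ is carried in cm² s⁻¹ and
displayed ×10⁻⁸ to 3 decimals with the standard error across replicates.

### R² conventions

The through-origin quadratic has no unique $R^2$. The headline value is the
*centered* convention $1 - SS_{res}/\sum(y-\bar y)^2$, comparable to the
reference fit's 0.94; the uncentered variant is computed and carried
alongside (`r_squared_uncentered`) since the source does not say which it
used. The restricted Hill fit reports the centered $R^2$ of the
through-origin line on the points actually used.

### SPI bands and boundary conventions

Fine 19–29 µm → SPI 14–20; medium 30–65 µm → SPI 11–15; coarse > 65 µm →
SPI 6–11. The stated bands leave (29, 30) µm open; this implementation
closes the gap at 30 (fine is [19, 30)) so the bands tile the axis.
Diameters below 19 µm return `"unclassified"` rather than extrapolating.
Pattern thresholds assign both 25 and 50 µm to coronal-reticulate (the
stated "25–50 µm" read as a closed interval). Note the source narrative is
internally inconsistent about the medium SPI band (one statement gives
11–15, another calls a value of "15 to 20" medium); the strict 11–15 band
is used and `spi_band_check(36, 15.1)` therefore reports `in_range =
FALSE`. Similarly, the reference quadratic at $x = 36$ gives 466.9 µm while
the source quotes its own prediction as 482 µm (consistent with an
unrounded diameter near 37.3 µm); `validate_new_breed()` reports the
residual against the model as fitted and does not guess which diameter was
used.

## The synthetic world

Because no micrographs or bath records are published, the generators *are*
the test bed, with exact analytic ground truth.

**Images** (`generate_fibre_image()`): one straight horizontal band (grey
128) on background 30 with boundaries at 255 before noise — levels chosen
for a robust thresholding margin. Boundary geometry is built as polylines
in physical µm first; ground truth records their exact per-window lengths
and the 0.5-granularity cell counts before rasterisation. Patterns:

* *coronal* — transverse circular arcs at spacing 100/`scales_per_100um`
  µm, bulging by `arc_sagitta_frac` (default 0.15) of the diameter; 0
  gives straight chords whose per-window length equals the diameter
  exactly.
* *coronal_reticulate* — parallel bands at 35° from transverse.
* *reticulate* — a nearest-seed (Voronoi, via `deldir`) tessellation of a
  seeded point process. Seeds sit on a jittered grid at mean density
  matching `scales_per_100um` rather than a uniform Poisson draw, so that
  cell walls stay resolvable at raster scale while remaining "irregular in
  size and shape, randomly distributed".

Defaults: fibres are 300 µm long (three full windows); pixel pitch resolves
the band to ≥ 25 px across and never exceeds 1 µm/px; boundary lines are
2 px wide; grey noise is Gaussian with sd 8 (on the 0–255 scale) — the
source reports only duplicate runs, no noise law, so these are one-time
realism choices, not calibrated values. What the generator does **not**
emulate: SEM charging and depth-of-field artefacts, crimped or tapering
fibres, medullated kemp fibres, scale-height relief. A green recovery test
therefore establishes correctness of the measurement chain on clean
geometry, not robustness to every SEM pathology.

**Kinetics** (`generate_uptake_series()`): either the early-time Hill form
(clipped at saturation) or the exact Fickian cylinder series
$M_t/M_e = 1 - \sum_n (4/\beta_n^2)\exp(-D\beta_n^2 t/r^2)$ over roots
$\beta_n$ of $J_0$, truncated below $10^{-10}$ per term; for dimensionless
time $T = Dt/r^2 < 0.01$ the short-time expansion
$(4/\sqrt\pi)\sqrt T - T - T^{3/2}/(3\sqrt\pi)$ is used instead (the two
agree to ~$10^{-6}$ at the joint). Default sampling follows the 5–240 min
bath schedule at 5 min steps; recovery studies use denser early grids
because at the studied $D$ and radii the early phase is over within the
first few scheduled minutes.

**Tables** (`generate_measurement_table()`): diameters uniform over a
range, perimeter from the quadratic plus Gaussian noise clipped at 0,
counts as perimeter over a typical 50 µm single-scale boundary length
(breed-average perimeter over breed-average count spans 47–52 µm), rounded
to 0.5.

All generators draw through an isolated RNG stream seeded from their spec;
repeat calls are bit-identical and the caller's RNG state is untouched.

## Numerical behaviour worth knowing

* **Chain-code bias.** The 1/√2 chain code overestimates straight lines at
  intermediate orientations by up to 8%; thinning-end losses partly
  compensate. Measured on noise-free synthetics (20 fibres, 20–80 µm):
  median |relative error| ≈ 3–4%, maximum ≈ 6%, diameters within 0.5 px.
  `skeleton_length(..., method = "corrected")` offers Kulpa's weights for
  isotropic curves but is not the pipeline default, because it would break
  the exact chord-length identity on axis-aligned boundaries.
* **Early-phase estimator bias.** Fitting the *exact* cylinder solution
  with the through-origin √t line underestimates $D$: ratios ≈ 0.97 at
  cutoff 0.1, 0.90 at 0.3, 0.84 at 0.5 (monotone in the cutoff — the
  formal version of "the apparent coefficient is only constant in the
  initial phase"). With data generated by the Hill model itself the fit is
  exact to machine precision at any cutoff below saturation. A 5% accuracy
  target on cylinder data therefore requires a cutoff ≤ ~0.15; at the
  conventional cutoff 0.3 the error is ~10% and the corresponding
  acceptance check is knowingly red.
* **Window counts at frame ends.** Cells cut by the axial frame count 0.5,
  so short fibres (few windows) deflate the mean count by up to ~0.5;
  longer fibres dilute the artefact.
* **Degenerate inputs.** Negative fitted slopes return $D = 0$ with a
  flag; all-zero uptake gives $D = 0$; fewer than 3 early-phase points,
  axes shorter than one window, and missing physical scale metadata are
  hard errors rather than guesses.

## Worked example

```{r example}
g <- generate_fibre_image(image_spec(36, pattern = "coronal_reticulate",
                                     scales_per_100um = 8, seed = 4))
m <- measure_fibre(g$image)
m

compute_spi(542, 36)          # the held-out validation fibre
classify_pattern(c(22, 36, 72))

model <- correlation_model(14.41, -0.04)
validate_new_breed(36, 542, model, observed_pattern = "coronal_reticulate",
                   id = "validation fibre")
```

## Known limitations

Single straight fibre per frame; no 3-D surface reconstruction or
scale-height estimation; no concentration-dependent or surface-barrier
(non-Fickian) diffusion models; breed-level linear relations are fitted on
as few as three points and are descriptive, not mechanistic.
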