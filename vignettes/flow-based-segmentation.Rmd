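---
title: "Motion-based label-free cell segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based label-free cell segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowseg)
```

## The model

Every live-cell movie, whatever the optics, is dynamic: cell boundaries
advance and retract, and the interior intensity flickers with
intracellular activity even when the cell as a whole does not translate.
The background — the dish, the substrate, even etched topographical
structures — is static. `flowseg` turns this single shared property into
a segmentation rule: estimate the apparent motion of every pixel between
consecutive frames and call a pixel "cell" when its motion magnitude
exceeds a threshold Th.

The motion field comes from the brightness-constancy assumption
$I(x, y, t) \approx I(x+u,\, y+v,\, t+\Delta t)$, whose linearisation is
the optical flow constraint $u I_x + v I_y + I_t = 0$. One equation per
pixel cannot determine two unknowns, so a spatial model is needed. The
Farnebäck estimator used here models each local neighbourhood as a
quadratic polynomial
$f(\mathbf{x}) = \mathbf{x}^\top A \mathbf{x} + \mathbf{b}^\top\mathbf{x} + c$,
fitted at every pixel by weighted least squares over a square window with
a Gaussian applicability that weights the fit towards the window centre.
If the second frame is the first translated by $\mathbf{d}$, the
polynomial coefficients satisfy
$A\,\mathbf{d} = -\tfrac12(\mathbf{b}_2 - \mathbf{b}_1)$.
Solving this pointwise is fragile, so the 2×2 normal equations are
averaged over a larger window before solving, and the estimate is refined
iteratively: the current displacement warps the sampling of the second
frame's coefficients, and the solve then only has to account for the
residual. A coarse-to-fine resolution pyramid (2×2 pixel averaging per
level) supplies priors for displacements larger than any single window
could capture.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `th` | — (user) | px/frame | flow magnitude above which a pixel is cell; the one primary knob |
| `disk_radius` | 1 | px | disk structuring element for morphological closing |
| `min_size` | 1000 | px | minimum connected-component area kept |
| `pyramid_levels` | 3 | — | resolution levels; coarsest must stay ≥ 8×8 |
| `pyramid_scale` | 0.5 (fixed) | — | 2×2 pixel averaging between levels |
| `expansion_window` | 5 | px | neighbourhood of the quadratic fit |
| `expansion_sigma` | 1.1 | px | Gaussian applicability sd of that fit |
| `averaging_window` | 15 | px | box window averaging the displacement normal equations |
| `iterations_per_level` | 3 | — | fixed-point refinements per level |

The flow defaults mirror the values commonly used by the mainstream
implementations of this estimator; all are exposed under the `flow:` key
of the YAML configuration. Th is deliberately left without a default:
its useful value depends on how fast the imaged cells move and fluctuate,
and scanning it is the intended tuning workflow (too high undersegments,
too low picks up sensor noise). Intensities are always normalized to
[0, 1] first (`normalize_frame()`), so a given Th means the same thing
for 8-, 12- and 16-bit acquisitions.

Units: flow (and hence Th) is reported in pixels/frame at native
resolution. Frame interval is carried as metadata only.

## Numerical choices

* **Warp-consistent compensation.** With nearest-pixel warping, the
  fixed-point update must add $A\,\mathrm{round}(\tilde{\mathbf d})$ —
  the displacement actually applied when sampling the second frame's
  coefficients (after rounding *and* border clamping) — rather than
  $A\tilde{\mathbf d}$ with the fractional prior. Using the fractional
  prior biases the fixed point low by up to ~35 % for small shifts;
  with the consistent term, integer translations are recovered to
  machine-level median error and 0.5 px bandlimited shifts to ~0.02 px.
* **Pyramid smoothing boundary.** The Gaussian pre-smooth (sd 1) before
  each decimation uses a mirrored (symmetric) image border: with a
  symmetric kernel this conserves the image sum exactly, so for
  even-sized images every pyramid level preserves its parent's mean
  intensity to floating-point precision. All other correlations
  (expansion moments, normal-equation averaging) use edge replication,
  so the flow is defined at every pixel with no undefined margin.
* **Degenerate systems.** Where the averaged 2×2 system has determinant
  below 1e−12 (constant regions carry no motion information) the solver
  keeps the prior displacement instead of amplifying noise.
* **Threshold and size-filter boundaries.** The mask rule is strictly
  `magnitude > th` (a pixel exactly at Th is background), and components
  exactly at `min_size` survive the filter.
* **Morphology on the set definition.** Closing pads the canvas by the
  disk radius before dilating, so dilation may extend past the image and
  the closing is genuinely extensive (output ⊇ input) at borders; the
  radius-r element is the discrete Euclidean disk
  $\{(dr,dc): dr^2+dc^2 \le r^2\}$. Note the radius-1 disk is a
  4-neighbour cross: it bridges 1-pixel gaps between bars but not
  between two isolated pixels (erosion removes the lone bridge again) —
  verified exhaustively against a brute-force implementation on all
  65 536 4×4 masks.
* **Connectivity.** Foreground components are 8-connected, the
  hole-filling background flood is 4-connected — the standard dual
  pairing that avoids topological paradoxes. Labels are assigned
  1..N in raster-scan order of each region's first pixel, so region IDs
  are reproducible.
* **Mask/frame assignment.** The pair (t, t+1) produces the mask for
  frame t, matching the flow's "push" reading (pixels of frame t are
  pushed onto frame t+1); the final frame has no mask.
* **Object matching.** The evaluation matches predicted to true regions
  greedily in descending IoU, one-to-one, counting a pair as TP at
  IoU ≥ 0.5 (exposed as a parameter). F-score is micro-averaged (counts
  summed over images, then scored once) and Jaccard is pooled globally;
  both conventions are robust to images containing few cells. Empty-vs-
  empty comparisons score 1 by convention.

## The synthetic scene generator

The generator exists so the entire pipeline can be exercised with exact
ground truth and no external imagery. It emulates the features that
matter to a motion-based segmenter:

* **Deformable cells**: star-convex boundaries
  $r(\theta, t) = R\,(1 + a \sum_{m=2}^{4} c_m \cos(m\theta + \phi_m + \omega t))$
  with seeded random mode weights and phases advancing at the wobble
  rate — the simplest shape family that produces boundary flow without
  rigid-body assumptions.
* **Interior activity**: the cell is filled with a smoothed noise
  texture that translates with the cell; two quadrature noise fields
  mixed with a phase advancing at `texture_flicker_rate` make the
  texture fluctuate in place, so a cell with zero velocity still
  produces interior flow — the phenomenon that makes stationary cells
  segmentable in real imagery.
* **Static backgrounds**: flat, or high-contrast square-wave stripes
  (period/contrast configurable) emulating etched contact-guidance
  grooves whose intensities overlap the cell's. Both carry a weak static
  spatial texture (default contrast 0.04, correlation length 4 px)
  under the per-frame Gaussian sensor noise. The static texture is not
  cosmetic: real detector images always contain static structure
  (substrate, illumination), and dense flow anchors the background to
  zero displacement through it. A hypothetical background that is pure
  i.i.d. noise frame to frame has no stable displacement at all — the
  estimator would match noise to noise and report arbitrary motion — so
  such a scene tests nothing a real microscope produces.
* **Sensor noise** is added after normalization, so preset thresholds
  are directly comparable across scenes.

What it does **not** emulate: modality-specific optics (phase halos, DIC
shear, IRM fringes), photobleaching, cell division, or cells in contact.
Passing the synthetic suite therefore demonstrates the motion logic,
morphology chain and metrics are correct — not that any particular
modality's artefacts are handled.

The four frozen presets (`preset_scenes()`) fix seeds, geometry and a
recorded `calibrated_th` found once by a development grid search
(maximizing pooled Jaccard subject to perfect detection) and then frozen:
`single_migrating` (Th 1.1), `multi_morphology` (0.7), `grooves` (0.9),
`stationary_active` (1.1). Preset cells are 60–100 px in radius on
320–384 px canvases — the scale of adherent cells in 40× fields — and the
test suite evaluates flow accuracy on 128 px texture fixtures; these sizes
keep the whole suite comfortably fast on one CPU.

## Known limitations

* **Flow support halo.** Averaging the normal equations over a window
  half-width of ~7 px (default 15) extends flow support ~6–7 px beyond
  a moving object's true boundary, because inside the window the cell's
  strong gradients dominate the weakly textured background. The
  achievable Jaccard is therefore bounded near $(r/(r+7))^2$ for a cell
  of radius r: ≈ 0.6 at r = 20 but ≈ 0.87 at r = 100. Small objects are
  detected reliably but their pixel-accurate outline is intrinsically
  blurred by this scale; shrinking `averaging_window` trades this halo
  against noise robustness.
* **Stage drift and focus changes** translate the whole field and
  produce flow everywhere; the method assumes a stable setup, and
  registration should happen upstream.
* **Long frame intervals** violate the small-displacement and
  brightness-constancy assumptions; the pyramid extends the usable range
  but not indefinitely.
* **Touching cells** merge into one region: the pipeline performs no
  declumping, and a segmented object may be a multicellular aggregate.
* **The last frame** of a sequence has no mask of its own, since masks
  attach to the earlier frame of each pair.
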