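# flowseg

Label-free segmentation of living cells from time-lapse microscopy, using
the one property every live-cell movie shares regardless of optical
modality: **cells move, backgrounds don't**. Between consecutive frames a
cell's boundary advances and retracts and its interior flickers with
intracellular activity, while the substrate — even a high-contrast,
structured one — stays put. `flowseg` estimates dense optical flow between
each frame pair and classifies pixels by the magnitude of their motion,
so no fluorescent label, no intensity model and no training data are
needed. It is aimed at cell-biology labs doing migration, adhesion or
morphology analysis on phase-contrast, DIC, transmitted-light, IRM or
fluorescence time-lapse imagery.

## Method

**Dense optical flow (Farnebäck).** Under brightness constancy,
`I(x, y, t) ≈ I(x + u, y + v, t + Δt)`; linearising gives the optical flow
constraint `u Iₓ + v I_y + I_t = 0`. The Farnebäck estimator solves for a
dense displacement field `(u, v)` by approximating every local
neighbourhood with a quadratic polynomial `f(x) = xᵀA x + bᵀx + c`
(weighted least squares over a 5×5 window with a Gaussian applicability,
sd 1.1) and relating the polynomials of the two frames: for a local
displacement `d`, `A d = −½(b₂ − b₁)`. The per-pixel 2×2 normal equations
are averaged over a 15-pixel window and solved everywhere, iterating three
times per level with warped re-sampling of the second frame's
coefficients. A resolution pyramid (2×2 pixel averaging per level, three
levels by default) lets coarse levels capture large displacements and
hand them down as priors, so motions well beyond the window size are
recovered. All of this is implemented from scratch in vectorised R.

**Segmentation.** The flow magnitude `√(u² + v²)` (pixels/frame, on
[0,1]-normalized intensities) is thresholded at **Th** — the method's one
primary parameter: pixels above Th are cell, the rest background. The
binary mask is then closed with a disk structuring element (default
radius 1), background holes not connected to the image border are filled,
and connected components smaller than the size filter (default 1000 px)
are discarded as debris. The result is a labeled mask with per-region
area, perimeter, centroid and bounding box.

**Evaluation.** Against ground-truth masks the package reports the
object-level detection F-score `F₁ = TP / (TP + ½(FN + FP))` (greedy
one-to-one IoU ≥ 0.5 matching) and the pixel-level Jaccard index
`J(T, S) = |T ∩ S| / |T ∪ S|`, pooled across images.

**Synthetic scenes.** Because the method is defined by motion, it can be
tested end-to-end on simulated imagery: star-convex cells with
Fourier-mode boundary wobble and advected, flickering interior texture
move over static backgrounds (flat or high-contrast groove stripes) under
per-frame sensor noise, with exact ground-truth masks. Four seeded presets
cover migration, multiple morphologies, the structured-background
robustness case and a stationary-but-active cell.

## Worked example

```r
library(flowseg)

sc    <- preset_scenes()$single_migrating   # one migrating cell, frozen seed
scene <- render_scene(sc)
scene$sequence
#> <image_sequence> 6 frames of 320 x 320, interval 1 s

masks <- segment_sequence(scene$sequence, flow_params(),
                          seg_params(th = sc$calibrated_th))
masks[[1]]
#> <labeled_mask> 320 x 320, 1 region(s), t = 0
#> # A tibble: 1 × 10
#>   frame label area_px perimeter_px centroid_row centroid_col ...
#> 1     0     1   35951          714         160.         148.

res <- evaluate_dataset(masks, scene$truth[1:5])
res
#> <eval_result> 5 image(s): TP 5, FP 0, FN 0 | F1 1.000, Jaccard 0.855 (IoU match >= 0.50)
glance(res)   # one-row tibble; tidy(res) gives per-image rows
```

The six-frame scene yields five frame-pair masks. Every pair detects
exactly the one true cell (F₁ = 1, no false or missed detections) and the
pooled pixel overlap with the exact simulated ground truth is
Jaccard ≈ 0.86. `autoplot(masks[[1]])`, `autoplot(farneback_flow(...))`
and `plot_segmentation(frame, mask)` draw the results; `regions(masks)`
pools the per-region tibbles for downstream migration/morphology work.

## Command line

```sh
inst/scripts/flowseg synth --preset grooves --outdir scene/
inst/scripts/flowseg run   --input scene/sequence.tif --outdir out/ --th 0.9
inst/scripts/flowseg eval  --pred out/ --truth scene/ --iou 0.5
```

Beyond input/output paths, `run` needs at most `--th`; the smoothing disk
(1 px) and size filter (1000 px) defaults rarely need changing.

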