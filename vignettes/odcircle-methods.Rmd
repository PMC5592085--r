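---
title: "Circular optic disc segmentation by maximal ring contrast: models, parameters and design notes"
author: "odcircle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular optic disc segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The optic disc (OD) is the bright, roughly circular region of a retinal
fundus photograph where the optic nerve and the major blood vessels
enter the retina. Locating its center and delineating its boundary are
prerequisites for glaucoma screening (cup-to-disc analysis), for using
the disc as a spatial landmark, and for vessel tracking. The two
anatomical priors the method exploits are (1) the disc is bright
relative to its surround, and (2) the vessel tree converges on it.

`odcircle` implements a two-stage pipeline:

1. **Localization.** The image is resized so the retina (field of view,
   FOV) diameter equals 540 px, making every filter size below
   resolution independent. Vessels are enhanced by a white top-hat
   (radius-8 disc) of the complemented green channel, `V_E`. Two maps
   are derived from `V_E`: a *vessel density* map (difference of an
   80x40 and an 80x120 box mean, clipped at zero, max-normalized) and a
   *vessel convergence* map (Canny edges, straight-line Hough transform,
   +1 at every pairwise line intersection, circular mean of radius 40,
   max-normalized). Thresholding both at 0.3 and taking the pixelwise
   AND yields a constraint mask. The disc detector is the difference
   between a radius-40 circular mean and an 80x160 box mean of the
   intensity image `I = R + G + B`, after vessel pixels (top 1.5% of
   `V_E`) are raised to `max(I)` so that vessels crossing the disc do
   not punch dark holes in it. The located center is the detector
   argmax inside the constraint mask.
2. **Segmentation.** The intensity image is cropped to a square window
   around the located center. For a radius grid of 25-45% of the window
   side (step 1%), the *ring contrast* `CM(r)` is the mean intensity of
   the inner ring (r - t, r] minus that of the outer ring [r, r + t),
   with thickness t = 4% of the side. The rigid model takes the
   grid argmax; the flexible model runs the scan separately in the four
   half-planes (up/down/left/right of the window center), then reports
   the circle with radius `mean(r_u, r_d, r_l, r_r)` and center shifted
   by `((r_d - r_u)/2, (r_r - r_l)/2)`.

Evaluation uses the normalized center error `D*` (center error divided
by the radius of the area-equivalent circle of the truth mask), the
center-inside-mask success criterion, Jaccard and Dice overlap, and the
symmetric mean average boundary distance (MAD).

## Parameters

All lengths are in pixels of the 540-px-retina frame; all are fields of
`od_config()`.

| parameter | default | role |
|---|---|---|
| `retina_diameter` | 540 | normalization target; fixes all other scales |
| `tophat_radius` | 8 | structuring element; vessels are thinner than this |
| `density_kernel_narrow` / `wide` | 80x40 / 80x120 | the vertical vessel band through the disc is flanked *horizontally* by low density, so the kernels differ in width, not height |
| `density_threshold`, `convergence_threshold` | 0.3 | binarization of the max-normalized maps |
| `convergence_avg_radius` | 40 | smoothing of the sparse intersection counts |
| `hough_top_k` | 30 | at most 435 line pairs; bounded cost |
| `vessel_percentile` | 98.5 | fraction of `V_E` treated as certain vessel |
| `detector_circle_radius`, `detector_rect` | 40, 80x160 | disc-sized blob vs horizontally flanking background |
| `crop_side` | 172 | segmentation window (derivation below) |
| `radius_grid` | 25-45% step 1% | scan grid, relative to the window |
| `ring_thickness` | 4% | ring thickness, relative to the window |

Choices the method leaves open, fixed here once:

* **Canny thresholds** — hysteresis at the 70th/90th percentiles of the
  gradient magnitude inside the FOV; percentile form keeps the detector
  resolution- and exposure-robust.
* **Hough peaks** — up to 30 peaks, non-maximum suppression of ±5 px
  and ±5° in the accumulator, and a vote floor at 0.3 of the strongest
  peak. The floor is the lowest that suppresses the aliasing side
  lobes a single rasterized line leaves in neighbouring angle bins
  (measured at up to 0.24 of the main peak); without it a lone vessel
  edge can fabricate intersections. Near-parallel pairs (< 3°) are
  skipped when accumulating intersections: their intersection point is
  numerically unstable.
* **Window side 172.** The scan grid spans [0.25, 0.45] x side. Discs
  in these images have radii of roughly 43-65 px, and the localization
  stage can hand the window a center displaced by up to (r - 40) px
  (see *Limitations*), so the grid's upper end should reach
  2r - 40 ≈ 90 px while its lower end must still reach the smallest
  disc. The lower bound binds: side = 43 / 0.25 = 172, giving a grid
  of 43-77 px. The window runs in the normalized frame and the fitted
  circle is mapped back by 1/scale.
* **FOV detection** — binarize the channel sum at 10% of its maximum,
  keep the largest 4-connected component, fill holes; retina diameter =
  the larger bounding-box side (robust to frames that crop the FOV top
  and bottom).

## Numerical conventions

* Rasters are (row, col), 1-based, as native R matrices; the CLI emits
  0-based coordinates.
* Box/circular means use symmetric-reflect padding (folding as often as
  needed), computed exactly via summed-area tables — no FFT round-off,
  no rim artifacts. Even-sized kernels place `k %/% 2` taps before the
  center.
* Grayscale morphology uses clipped-neighbourhood min/max (the kernel
  intersected with the image domain); EBImage supplies the operation,
  with an affine rescale around it because EBImage clamps gray values
  to [0,1].
* Bicubic resampling is the Keys cubic-convolution kernel (a = -0.5)
  with pixel-center alignment, written here because no installed
  package provides a bicubic image resize.
* Map normalizations guard 0/0 → 0; thresholding is strict (`>`);
  argmax ties break to the smallest row, then column; radius-scan ties
  break to the smallest radius.
* If the vessel constraint mask is empty inside the FOV, localization
  falls back to the unconstrained argmax and flags the result
  (`constrained = FALSE`): a center must always be produced for the
  segmentation stage.
* The flexible model's center shift uses *half* the sector radius
  differences. The printed form of this update in the source method
  doubles the window-center coordinate, which is dimensionally
  inconsistent; the half-difference is exact when the two opposing
  sector radii sit at the axis edge distances ρ ± d. We verified on
  ideal offset discs that this happens once the offset exceeds the
  ring thickness (the contrast optimum pins to the edge-distance
  extreme), while smaller offsets are smoothed toward (2/π)d by the
  semicircle average, and that the plausible alternative (the full
  difference) measures strictly worse on both window-recovery and
  end-to-end batteries.

## The synthetic generator

`synth_fundus()` renders: a dark surround; a reddish FOV disc with a
multiplicative linear illumination ramp in a random direction (±10%);
a bright disc with a sigmoid rim (scale 3 px) at RGB means
(235, 200, 130) over background (170, 80, 50) — sum-intensity contrast
≈ 250 of 765; quadratic-Bezier vessels from within 0.2 disc radii of
the disc center out to the FOV rim, darkened 55% in green and 27.5% in
red/blue, width 4 px; optional exudate blobs (kept ≥ 2 disc radii away
by default, or adjacent under the stress preset); additive Gaussian
noise, clipped to 0-255. The ground truth is the exact rasterized disc
before noise. `synth_battery()` draws disc centers in the nasal half
of the FOV, radii uniform in 8-12% of the FOV diameter, 6-12 vessels
and noise sd 4-8, deterministically from a master seed (R's
Mersenne-Twister, fixed across platforms; a test pins an image
checksum).

What the generator does *not* emulate: peripapillary atrophy,
haemorrhages, camera color profiles, vessel calibre variation and
central reflexes, and texture of the nerve fibre layer. Passing tests
on the battery therefore demonstrate the pipeline's mechanics —
correct filters, masks, argmaxes, scan geometry, metrics — under the
stated appearance model, not clinical-grade performance on real
photographs.

## Test problem sizes

The suite exercises: oracle equivalence of every numeric primitive on
20 random rasters up to 64x64 against brute-force implementations;
metric identities on 100 random mask pairs; ring-scan recovery on 50
ideal noisy windows; one 50-image end-to-end battery (shared by the
localization and segmentation checks); a 4 x 20-image noise ladder
(sd 0, 5, 10, 20); and 10 shifted images for translation equivariance.

## Known limitations

* **Detector plateau bias.** For discs larger than the radius-40
  detector kernel, the circular mean is flat within (r - 40) of the
  center while the rectangular mean still peaks there, so the detector
  maximum sits on a ring about (r - 40) px from the true center — the
  localization error grows linearly with disc size beyond 40 px
  (measured correlation 0.99 on the battery). For typical discs near
  the kernel size the bias vanishes.
* **Sector direction confounding.** For a disc displaced obliquely from
  the window center, *both* half-plane radius differences respond to
  the displacement magnitude rather than its components (the offset
  direction pins each sector's contrast optimum near an edge-distance
  extreme), so the flexible model's recovered center carries errors up
  to ~0.6 of the displacement for diagonal displacements. Axis-aligned
  displacements — the common case downstream of the plateau bias,
  which is vertical — are recovered well.
* **Noise robustness, not noise monotonicity.** Ring contrasts average
  thousands of pixels, so overlap scores are essentially flat across
  sensor noise sd 0-20; residual variation tracks the Hough line
  multiplicity, which *increases* with noise (fragmented accumulator
  hierarchy), slightly tightening the convergence constraint. Overlap
  does not necessarily degrade monotonically until noise reaches the
  ring-contrast scale.
* A single circle cannot follow an elliptical or notched disc rim; the
  cup boundary of glaucomatous discs with a high cup-to-disc ratio may
  offer stronger ring contrast than the rim itself. No cup
  segmentation is attempted.

## Reading the outputs

```{r}
library(odcircle)
s <- synth_fundus(synth_spec(seed = 1))
fit <- od_fit(s$rgb, truth = s$truth)
print(fit)       # fitted circle, scale, constraint flag, metrics
summary(fit)     # + sector radii and detector value
coef(fit)        # center_row, center_col, radius (original frame)
mask <- predict(fit)              # logical disc mask
plot(fit, s$rgb)                  # overlay
```
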