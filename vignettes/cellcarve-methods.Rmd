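---
title: "Nucleus-preserving resizing of blood-smear images: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleus-preserving resizing of blood-smear images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcarve)
```

## The problem

Differential counting of white blood cells (WBCs) is done on stained
peripheral-blood smears, nominally digitized at 800 x 600. The
diagnostically relevant content — the size and shape of the WBC nuclei —
occupies a small part of the frame; the rest is red-cell clutter and pale
plasma. Shrinking these images saves storage and downstream analysis time,
but uniform scaling shrinks the nuclei with everything else, and plain
content-aware resizing (seam carving over a gradient-magnitude energy) has
no notion of which content matters: in smear images the gradient energy of
a nucleus is not much higher than that of the ubiquitous red-cell edges, so
under a strong size reduction the carver eventually cuts through nuclei.

`cellcarve` resizes a smear while leaving every detected nucleus
geometrically untouched. It does so by replacing the carving energy with a
*Saliency Strength Map* (SSM) built in three stages:

1. **Saliency map** `C_m`: a visual-attention map fusing color,
   orientation and saturation center-surround features,
   `C_m = w1*C + w2*S + w3*O` with default weights 0.6 / 0.2 / 0.2
   (color dominates because stained nuclei are chiefly a chromatic
   phenomenon).
2. **Elliptical attention windows** (EAWs): nucleus candidates extracted
   from `C_m` by Otsu thresholding, hole-filling, small-region removal,
   X-Y-projection windows and ellipse fitting; each window gets a
   Euclidean distance-transform strength ramp `EAW_S` peaking at its
   center.
3. **Fusion**: `SSM = g(0.5 * (C_m + EAW_S))`, `g` a small Gaussian,
   min-max normalized to 0..255.

Seam carving then removes minimum-cost *forward-energy* seams: the cost of
removing pixel `(i,j)` prices the new adjacencies the removal creates,

```
cU = |E(i,j+1) - E(i,j-1)|
cL = cU + |E(i-1,j) - E(i,j-1)|
cR = cU + |E(i-1,j) - E(i,j+1)|
M(i,j) = P(i,j) + min(M(i-1,j-1)+cL, M(i-1,j)+cU, M(i-1,j+1)+cR)
```

with `P` the L1 gradient magnitude of the energy raster. Because `EAW_S`
gives every nucleus a tall plateau with a sloped ramp, both `P` and the
step costs are large anywhere inside or across a nucleus, and seams flow
around them. The target size is derived from the EAWs themselves
(`auto_target_size`): the union span of their bounding boxes plus a margin,
so a nucleus-free corridor always remains and the reduction is as strong as
the content allows.

Quality is scored with PSNR and the *Ratio of Distortion*
`ROD = |M \ (M ∩ S)| / |M|`, the fraction of original nucleus pixels
absent from the resized image.

## Tunable parameters

| parameter | default | unit | why this value |
|---|---|---|---|
| filter scales | 11, 13 | px (at 800x600) | center-surround window sizes; scale linearly with image size, rounded to odd |
| weights | 0.6/0.2/0.2 | — | color/orientation/saturation fusion weights |
| wavelet | haar | — | one-level decomposition for orientation features; simplest separable choice |
| closing radius | 5 | px (at 800x600) | disc for hole filling; fills holes up to 10 px wide |
| min region | 0.03 | fraction | components below 3% of image pixels are noise |
| SSM sigma | 2 | px (at 800x600) | suppresses pixel-scale noise without moving peaks |
| auto margin | 10 | px | background kept on each side of the EAW union |

All pixel-sized defaults are stated at the 800 x 600 reference size and
scale linearly with the input dimensions; a 400 x 300 image uses half-size
windows.

Two points where the design was genuinely open, and what this package
does:

* **Center-surround operator.** Response is
  `|value(p) - mean of the s x s window excluding p|` with reflect
  padding. This is the simplest operator consistent with a
  "center-minus-surround" contrast, it is exactly zero on constant
  channels, and the box mean makes it O(1) per pixel via summed-area
  tables.
* **Hole filling.** Implemented as morphological *closing* with a disc:
  of the standard openings/closings only closing fills interior holes,
  which is the stage's stated purpose. The disc is exact (Euclidean
  distance-transform thresholding), not an octagonal approximation.
* **Saturation.** HSI saturation `S = 1 - 3 min(R,G,B)/(R+G+B)` with
  `S = 0` on black pixels.
* **Fusion normalization.** Each feature map is min-max normalized to
  [0,1] before weighting — the three maps have incommensurate dynamic
  ranges (Lab units, wavelet coefficients, saturation fractions). A
  degenerate (constant) map normalizes to zero with a warning. `C_m` is
  rescaled to 0..255 before averaging with `EAW_S` so the two operands
  of the SSM are commensurate.
* **Auto target policy.** Whether the target should be the union span of
  the EAW boxes or the sum of their extents is ambiguous when windows are
  far apart; both are implemented (`auto_policy`), union span + margin is
  the default because it never demands removing a seam *between* two
  nuclei beyond what the corridor allows.
* **Seam order.** Vertical and horizontal removals strictly alternate
  while both dimensions still need shrinking; the order is a convention,
  not derived from the method.

## Numerical conventions

* Ties in the DP argmin and in the last-row argmin go to the smallest
  column index; Otsu ties go to the lowest threshold. This makes every
  stage bit-reproducible.
* Border policy for the seam costs: a difference whose neighbor index
  leaves the raster contributes 0; out-of-grid DP predecessors cost
  `+Inf`. Gradients use central differences in the interior, one-sided at
  borders.
* The energy raster has the seam entries removed at each iteration
  (the cost matrix is rebuilt every seam); full recomputation of the SSM
  from the carved image is available via `recompute_every` but is off by
  default — the carved SSM is a faithful energy because carving never
  touches the windows it protects.
* Seam bookkeeping: two integer rasters carry every surviving pixel's
  original coordinates. ROD's set comparison between images of different
  sizes is therefore exact; no registration heuristic is involved. The
  per-nucleus PSNR compares, inside the bounding box of each original
  mask, the surviving original pixels with their resized values — with
  plain shift-removal these are bit-identical, so PSNR is reported as
  `Inf` and any finite value indicates resampling or blending upstream.

## The synthetic world

The smear images this package is tested against are synthetic, because the
kind of clinical images the method targets are not freely distributable.
`generate_smear()` renders, deterministically per seed:

* a pale field (RGB 245, 240, 235);
* dense red-cell clutter: 150 discs of radius 26-36 px with pale centers
  around RGB (230, 170, 170) — smears are densely tiled with red cells,
  and this density is what makes the gradient-energy baseline fail
  honestly (a seam cannot cross the field without paying for many cell
  edges);
* 2-4 purple elliptical nuclei (semi-axes 75-95 px, ellipticity 0.85-1,
  base RGB (120, 60, 150)), pairwise separated and away from borders,
  every one covering at least 3% of the image;
* chromatin texture inside each nucleus: dense, fine heterochromatin
  clumps (radius 4-9 px, darker and strongly saturated) plus faint
  granularity at the camera-noise level, and 0-2 pale vacuoles;
* additive Gaussian noise (sigma 2) over everything.

The texture is not cosmetic: center-surround features respond to contrast
*within* the filter window, so a large perfectly uniform disc is salient
only at its rim. Real nuclei are salient throughout because chromatin is
textured at exactly the scale these windows see; the clump size was chosen
so the synthetic interiors have that property too. The grain is kept at
the noise level so that the nucleus interior stays cheap for the
*gradient* baseline — the two energies must disagree for the comparison to
mean anything, and they disagree in real smears.

What the generator does **not** emulate: nucleus lobulation (bands,
segmented neutrophils), cytoplasm and its boundary, staining gradients
across the slide, overlap between red cells and nuclei, focus blur. A
green test on this world therefore establishes that the pipeline's
geometry and bookkeeping behave as specified and that the SSM/gradient
contrast has the documented sign — not that detection performance on
clinical material matches any published figure.

## Known limitations

* Only the Haar wavelet is built in; the configuration field exists so
  another separable wavelet could be added without interface changes.
* Axis-aligned ellipses: a strongly lobulated nucleus yields one window
  covering its bounding box, which is conservative (protects too much,
  never too little).
* Image I/O is PNM (always) and PNG (when the `png` package is
  installed); TIFF/BMP readers are not available offline.
* Seam insertion (enlargement) is out of scope; requesting a target
  larger than the source is an error.
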