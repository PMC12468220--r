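---
title: "Adaptive enhancement and multi-Otsu thresholding for cervical nucleus segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive enhancement and multi-Otsu thresholding for cervical nucleus segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoseg)
```

## The problem

In a Papanicolaou-stained cervical smear the diagnostically relevant region
is the cell nucleus: hematoxylin renders it the darkest structure in the
field, inside lighter cytoplasm, on a bright background. Automated screening
needs a pixel-level nucleus mask, and classical difficulties are low
contrast, uneven illumination, stain variability and touching cells.
`nucleoseg` implements a fully unsupervised pipeline for this task — no
training data, a handful of interpretable parameters — together with the
five classical local-thresholding binarizers it is meant to be compared
against, pixel-level evaluation machinery, and a synthetic scene generator
so the whole comparison experiment runs reproducibly without any external
image collection.

## The pipeline

Each RGB image goes through five stages:

1. **HSV decomposition.** The value channel `V = max(R, G, B)` carries the
   brightness structure; hue and saturation are held fixed so enhancement
   never shifts the stain colour. The inverse transform uses the chroma
   decomposition (`C = V*S`, `X = C(1 - |(H/60 mod 2) - 1|)`, `m = V - C`,
   six 60-degree hue sectors); the forward hue formula is the standard
   hexcone expression, which is the unique inverse of that sector table.
   Everything stays in floating point on [0,1]; the only quantization to
   8 bits happens when a file is written (round half to even) or when the
   256-bin histogram is built (`floor(255 v + 0.5)`, a fixed tie direction
   so histograms are bit-reproducible).

2. **Bilateral filtering of V.** Weights are the product of an unnormalized
   spatial Gaussian (`spatial_sigma`, pixels; default 3) and an unnormalized
   range Gaussian (`range_sigma`, intensity on [0,1]; default 0.1) over a
   square window of radius `window_radius` (default 6, i.e. at least
   `2*spatial_sigma` so the spatial kernel is not truncated early). Borders
   are mirror-reflected; zero padding would darken the rim and bias the
   mean-intensity measurement below. The defaults are ordinary choices for
   8-bit micrographs and are all exposed in the configuration.

3. **Adaptive gamma correction.** The mean of the *filtered* V channel picks
   the exponent: `gamma = 1 + (0.5 - mean)` when the mean exceeds 0.5 and
   `gamma = 1/(2*mean)` otherwise, applied as the power law `V^gamma`. Both
   formulas give exactly 1 at a mean of 0.5, so the rule is continuous. The
   reciprocal branch diverges as the mean approaches zero, so gamma is
   clamped at `gamma.max` (default 5) with a warning — an all-black input
   then degrades gracefully instead of overflowing.

   One genuine ambiguity deserves a note. On [0,1] the power law with
   `gamma > 1` *darkens* and with `gamma < 1` *brightens*; the branch
   assignment above therefore brightens bright images further and darkens
   dark ones, which increases the separation between nuclei and background
   (the useful effect for thresholding) but is the opposite of what a
   brightness-normalizing reading would do. Because the two readings cannot
   be reconciled, the package implements the formulas as given under
   `gamma.convention = "equations"` (the default) and offers `"prose"`,
   which swaps the branch assignment; both are continuous at 0.5 and both
   push the exponent to the same side of 1, differing only in magnitude.
   The choice is logged per image.

4. **Three-class multi-Otsu thresholding.** The enhanced image is converted
   to grayscale (BT.601 luminance 0.299/0.587/0.114, configurable) and its
   256-bin histogram `p(i)` computed. For a threshold pair `(t1, t2)` the
   classes `[0, t1]`, `[t1+1, t2]`, `[t2+1, 255]` have probabilities
   `w_k` and means `mu_k`, and the between-class variance is
   `sigma_B^2 = sum_k w_k (mu_k - mu_T)^2` over the three classes (empty
   classes contribute zero). The search maximizes `sigma_B^2` over all
   32,385 admissible pairs using cumulative zeroth/first moments in one
   vectorized sweep; the test suite proves it identical to exhaustive
   enumeration, with ties broken toward the lexicographically smallest
   pair so the optimum is deterministic. Class 1 — the darkest class — is
   extracted as the nucleus mask (a `class_index` override exists for
   non-cytology material). Three classes, not two, because the scene
   genuinely has three intensity populations; a histogram with fewer than
   three occupied levels is rejected with advice rather than silently
   degenerating.

5. **Conditional morphological refinement.** The raw mask is repaired only
   where a measurable defect is found, in this order: (i) if any
   4-connected component is smaller than `a_min` pixels, morphological
   opening (disk of radius `open_radius`, default 2) removes speckle;
   (ii) if any interior hole of at least `hole_area` pixels (default 10)
   exists, all holes are filled by border flood fill; (iii) if the boundary
   jaggedness exceeds its threshold, closing (disk radius `close_radius`,
   default 3) smooths the outline, optionally followed by Canny/Sobel
   edge refinement confined to a 2-px band around the boundary (off by
   default); (iv) components below `a_min` are always removed at the end.
   `a_min` is expressed as a fraction of the image area
   (`a_min_fraction`, default 0.001) so the same configuration works across
   crop sizes. Every branch decision is logged per image.

   Two conventions here are deliberate. The structuring "disk" of radius r
   is the exact Euclidean set `{(dr, dc) : dr^2 + dc^2 <= r^2}` (radius 1 is
   the 4-neighbor cross); erosion treats the outside of the image as
   foreground and dilation as background, which preserves the
   anti-extensive/extensive algebra of opening and closing on a finite
   grid. Hole filling uses 4-connected background to mirror the
   4-connected foreground convention — this deviates from the common 8/4
   duality, so diagonally-pinched cavities count as holes; an 8-connected
   option is exposed.

   Jaggedness needed a concrete definition (the criterion "irregular
   boundaries" is qualitative). The package uses the area-weighted mean,
   over components, of the traced boundary length (Moore contour through
   pixel centers, diagonal steps counting sqrt(2)) divided by the perimeter
   of the convex hull of that contour. The hull is the shortest enclosing
   curve, so the ratio is at least 1, dimensionless and rotation-invariant;
   digitized ellipses score about 1.03-1.08, so the default trigger of 1.15
   leaves smooth nuclei untouched while branched or ragged masks exceed it
   comfortably. A naive edge-count perimeter was rejected: it overestimates
   a digital disk's boundary by roughly 4/pi and would fire the closing
   branch on perfectly smooth shapes.

## The baselines

Bradley, Feng, Niblack, Nick and Sauvola all threshold each pixel against a
statistic of its `(2r+1)^2` window (default radius 15, cropped at borders),
computed in O(1) per pixel from integral images of `I` and `I^2` on the
0-255 scale where the published constants live: Bradley
`T = m(1 - k/100)` with `k = 12`; Niblack `T = m + k s` with `k = -0.2`
(its canonical value, not stated in the comparison source); Nick
`T = m + k sqrt((sum I^2 - m^2)/N)` with `k = -0.13`; Sauvola
`T = m(1 - k(1 - s/R))` with `k = 0.1`, `R = 128`. Feng's formula needs two
windows: the primary supplies `m`, `s` and the local minimum `M`, a
secondary window of twice the radius supplies the standard-deviation range
`Rs`, and `T = (1 - a1) m + a2 (s/Rs)(m - M) + a3 M` with
`a2 = k1 (s/Rs)^g`, `a3 = k2 (s/Rs)^g`; the coefficients
(`a1 = 0.12, g = 2, k1 = 0.25, k2 = 0.04`) follow the method's original
description and are documented as such. Masks follow the dark-object
convention (`I < T` is foreground) so they compare directly with nucleus
masks; an `invert` flag covers the opposite use. In the comparison harness
the baselines binarize the *raw* grayscale — they are standalone methods,
and handing them the proposed enhancement would blur the comparison.

## Evaluation

Pixel-level precision, recall (sensitivity), F1 and accuracy from the
confusion counts, with fixed flagged conventions for degenerate cases
(an empty prediction has precision 1 — it makes no false claims — and an
empty prediction against an empty truth scores recall and F1 as 1); the
flags column marks such rows so batch tables stay NaN-free without hiding
anything. PSNR is `10 log10(1/MSE)` on the normalized scale and is reported
between the original and enhanced grayscales. Method comparison uses the
classical paired t-test on per-image metric values (two-sided, `n-1`
degrees of freedom, significance reported at 0.05); zero-variance
difference vectors are flagged rather than producing NaN. Aggregation uses
the sample (n-1) standard deviation.

## What the synthetic generator does and does not emulate

`generate_scene()` renders dark elliptical nuclei (value 0.15 +/- 0.05)
inside cytoplasm ellipses (0.55 +/- 0.05) on a bright background (0.85),
colourized through a purple-magenta stain hue (300 degrees) in HSV — the
three-plateau intensity structure that three-class thresholding assumes,
with nucleus < cytoplasm < background enforced as an invariant. Overlap is
controlled by rejection sampling on center distances; degradations are
applied in a fixed order (left-to-right linear illumination ramp, Gaussian
blur, additive Gaussian noise, then clamping to [0,1] to mimic 8-bit
sensor saturation). The ground-truth mask is the exact ellipse union
*before* degradation. Identical spec and seed reproduce a scene bitwise,
and the fixture-suite manifest stores every parameter so each file can be
regenerated from its row.

What it does not emulate: chromatin texture, debris and leukocytes,
out-of-focus regions, stain colour mixing, and the irregular (non-ellipse)
nucleus contours of dysplastic cells. Passing the end-to-end tests
therefore shows that the pipeline recovers nuclei under controlled
contrast, overlap, illumination and noise; it does not certify performance
on clinical material, where the published evaluation on curated Herlev
images is the relevant evidence and is out of scope here because that
dataset is external.

## Problem sizes and numerical choices

The test suite exercises the oracle comparisons at the sizes where naive
reference implementations are exact and fast: 32x32 images for the
bilateral filter (against a quadruple-loop evaluation, 1e-9) and the five
binarizers (bitwise mask equality against sliding-window loops), 200
random histograms for the threshold search (exact equality against
exhaustive enumeration), 64x64 masks for component labeling (against a
flood-fill oracle), and 128x128 three-nucleus scenes for the end-to-end
property (F1 at least 0.90 on the easy grid corner across 10 seeds). The
acceptance script runs the full comparison experiment on ten 128x128
scenes spanning the difficulty grid. These sizes were chosen so every
check runs from first principles in seconds; nothing in the pipeline is
size-dependent beyond memory.

Ties and degeneracies are all pinned: threshold ties break
lexicographically; achromatic pixels take hue 0; saturation is 0 where
V = 0; histogram quantization rounds half up; file quantization rounds
half to even; empty masks propagate with warnings rather than errors
where a valid empty result exists (post-processing), and with errors where
the quantity is undefined (jaggedness).

## Known limitations

- No splitting of touching nuclei (no watershed/concavity analysis): a
  fused clump segments as one component, matching the method being
  implemented.
- Class 1 extraction assumes the darkest population is nuclear; heavy
  debris or pen marks would be claimed as nuclei.
- The Feng coefficients are not calibrated for cytology; the method is
  included as a comparison point, faithfully parameterized from its
  original description.
- 8-bit input only; 16-bit or floating-point TIFFs are out of scope, as is
  ICC colour management.
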