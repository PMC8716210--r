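---
title: "Segmenting macular holes in OCT B-scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting macular holes in OCT B-scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhseg)
```

## The problem

A full-thickness macular hole is a defect of the neurosensory retina at the
fovea. On an OCT B-scan it appears as a hypo-reflective (dark) gap
interrupting the bright retinal band, at or near the foveal depression —
the natural thinning of the retina at the scan center. `mhseg` detects and
delineates that gap in a single grayscale B-scan by combining two classical
cues: **multilevel gray-level thresholding**, which partitions the scan into
reflectivity classes, and **derivative (Sobel) edge detection**, which
locates the sharp transitions bounding the hole. Neither cue alone is
reliable on speckled scans; the package uses the threshold classes to
propose candidate regions and the edge field to vet and score them.

The working representation is a `GrayImage`: intensities in $[0,1]$, row 1
at the top of the scan (vitreous side), all indices 1-based and ranges
inclusive. Scans of any size are accepted and standardized to
$224 \times 224$ before processing.

## Pipeline

1. **Standardize** — bilinear resize to the working geometry, then global
   min–max normalization to span $[0,1]$. No illumination-field correction
   is attempted: OCT exports are treated as linear, and a low-order field
   fit would risk flattening the very contrast (band vs. vitreous) the
   method relies on.
2. **Denoise** — a local-statistics adaptive (Lee/Wiener-type) filter:
   $$\hat I = m + \frac{\max(0,\, v - v_n)}{v}\,(I - m),$$
   with $m,v$ the mean and variance in a $5\times 5$ window (replicate
   padding) and $v_n$ the noise variance. Where the window is flat
   ($v \le v_n$) the output is the local mean; with $v_n = 0$ the filter is
   the identity, so the stage is monotone and conservative. $v_n$ defaults
   to an estimate from the image itself: the mean variance of the
   lowest-variance decile of $16\times16$ tiles, which in a B-scan is
   dominated by vitreous background. The estimate is deliberately
   conservative; speckle in the bright band is stronger than in the
   background (it is multiplicative), so the filter under- rather than
   over-smooths tissue. An optional log-domain mode
   (`logDomain = TRUE`) applies the same filter to $\log(I + \epsilon)$ for
   closer multiplicative fidelity; the additive default keeps the stage
   monotone in intensity.
3. **Edges** — the $3\times3$ Sobel pair applied by correlation under
   replicate padding (zero padding would manufacture strong edges along
   the image border wherever the band touches it). Magnitude
   $\sqrt{L_x^2+L_y^2}$ and direction $\mathrm{atan2}(L_y, L_x)$ are
   retained; the binary edge map marks pixels above a fraction (default
   0.2) of the maximum magnitude. No hysteresis or non-maximum
   suppression: edges here are evidence, not curves to be linked.
4. **Thresholds** — a 256-bin histogram is cut into $k+1$ classes. The
   default criterion is multilevel Otsu (between-class variance), searched
   *exhaustively* over all increasing cut tuples for $k \le 3$ with
   lexicographically-smallest tie-breaking, so results are deterministic
   and verifiable against brute force; $k > 3$ is not supported. The
   classical valley rule (smoothed histogram, minimum between the two
   highest-prominence peaks) is available as `method = "valley"`; it is
   brittle on speckled histograms, so the pipeline falls back to Otsu when
   fewer modes than needed survive smoothing. Default $k = 3$: four
   classes are the minimum that separate vitreous/hole, the dimmer
   nuclear layers, brighter outer retina, and the hyper-reflective RPE
   band.
5. **Band and fovea** — per column, the retinal band spans the first to
   last non-background label. Both traces are median filtered (7 columns)
   along the *observed* columns, then gaps are bridged by linear
   interpolation. The ordering matters: a full-thickness hole blanks its
   columns entirely, and blur erodes the columns flanking the gap, so
   filtering the observed trace first removes those corrupted anchors
   before interpolation crosses the gap. The fovea is the argmin of the
   smoothed band thickness restricted to the central half of the width
   (fovea-centered acquisition is assumed); a thickness minimum outside
   the central half is flagged in the provenance rather than followed.
6. **Hole extraction** — candidate pixels are darkest-class pixels
   strictly inside the band; 8-connected components (4-connectivity
   splits speckle-pitted regions) are filtered by area
   ($\ge$ `minArea` = 25 px at $224\times224$, about the smallest
   clinically plausible hole after resizing) and by edge support (at
   least 10% of boundary pixels within 2 px of the edge map). Survivors
   are scored
   $$\text{score} = \text{area} \times \text{edgeSupport} \times
     e^{-|c - c_{\text{fovea}}| / (W/8)},$$
   a soft foveal prior rather than a hard crop — an eccentric but
   otherwise convincing component can still win. Ties break toward larger
   area, then leftmost centroid. The winner is refined by morphological
   closing, hole-filling and opening with a $3\times3$ box (a box rather
   than a cross: cross-opening clips rectangle corners, and the
   refinement must leave solid convex masks untouched), then clipped back
   to the band interior.

Every stage is deterministic, so identical input and configuration give
bit-identical masks and reports.

## The erf edge model

For sub-pixel localization along a 1-D profile the package fits the
blurred-step model
$$f(x) = \frac{I_r - I_\ell}{2}\,
  \mathrm{erf}\!\left(\frac{x - x_0}{\sigma\sqrt2}\right) +
  \frac{I_r + I_\ell}{2},$$
the profile of an ideal step blurred by a Gaussian PSF of scale $\sigma$.
Fitting is bounded Levenberg–Marquardt (`minpack.lm`), initialized with
quartile means for the asymptotes, the maximum finite difference for
$x_0$, and $\sigma = 1$, with $\sigma \in [0.3, n/2]$. The edge *outset*
and *end* are reported at $x_0 \mp 2\sigma$, bracketing about 95% of the
intensity transition; this interval is a package convention for
summarizing edge extent, exposed via `edgeBounds()`.

```{r erf}
truth <- EdgeProfileModel(iLeft = 0.2, iRight = 0.8, sigma = 2, center = 10)
fit <- fitEdgeProfile(edgeProfileValue(truth, 1:32))
fit
```

## The phantom generator

Real B-scans with expert hole delineations are not distributable with the
package, so every stage is exercised on synthetic phantoms whose ground
truth is known by construction. `PhantomSpec` defaults describe the study
conditions used throughout the test suite: $224\times224$ px, retinal band
in rows 60–150 with four sublayers (reflectivities 0.55, 0.40, 0.65, 0.85
— bright inner surface, dimmer nuclear layers, bright outer retina and
RPE), a Gaussian foveal pit 25 px deep with $\sigma = 30$ px at the center
column, an optional full-thickness 30-column hole, optional vessel
shadows (columnwise attenuation), multiplicative gamma speckle with 8
looks (mean 1, variance $1/\text{looks}$ — the fully-developed-speckle
model), and a 1 px Gaussian detector blur. Speckle precedes blur, as the
detector PSF acts on the speckled signal. The truth mask is the
*pre-noise* hole region, so evaluation measures recovery of the latent
object, not of a noisy appearance.

```{r phantom}
ph <- generatePhantom(PhantomSpec(seed = 7))
seg <- segmentHole(ph$image)
seg
evaluateMasks(holeMask(seg), ph$truth)[, c("accuracy", "sensitivity", "jaccard", "dsc")]
```

What the phantom does **not** model: physically realistic OCT forward
physics (coherent PSF, depth-dependent attenuation, roll-off), curved or
tilted retinas, cysts, epiretinal membranes, lamellar holes, and operculum
remnants. Passing the phantom suite therefore demonstrates that the
algorithm recovers a latent hole under speckle, shadows and blur in an
idealized flat-band geometry — not clinical performance. Pixel-wise
accuracy on clinical data additionally depends on how ground truth is
drawn, which the package cannot settle; its reports label accuracy as
pixel-wise explicitly.

## Evaluation metrics

With pixel-wise counts TP/FP/FN/TN: accuracy $(TP+TN)/N$, sensitivity
$TP/(TP+FN)$, Jaccard $TP/(TP+FP+FN)$, Dice $2TP/(2TP+FP+FN)$, related by
$\mathrm{DSC} = 2J/(1+J)$. Sensitivity of a truth-empty image is reported
as missing, never 0, and excluded from means — averaging zeros over
no-hole images would silently punish correct rejections. Jaccard and Dice
are likewise missing when both masks are empty.

Hole shape features are the clinical size descriptors: area, base width
(maximum per-row extent), minimum diameter (minimum per-row extent over
interior rows), height, aspect, circularity and centroid. The perimeter
underlying circularity is the Freeman chain-code length of the outer
contour (diagonal steps weighted $\sqrt2$) plus a half-pixel-offset
correction of $\pi$, floored at 4: raw boundary-pixel counts
systematically bias circularity (a radius-15 disk scores 0.66 with 8-way
counts and 1.26 with 4-way counts, versus 0.91 for the chain code), and
circularity should sit near 1 for round holes. It remains advisory — it
is never used as a filter.

Feature selection is unsupervised (the method has no labels to select
against): zero-variance features are dropped, the rest are ranked by the
variance of their min–max-scaled values — a scale-free spread measure;
z-scoring would make every variance 1 — and greedily accepted unless
correlated above 0.95 with an already-kept feature.

## Numerical choices and degenerate inputs

* Tie-breaking is lexicographic/leftmost everywhere (thresholds, valley
  minima, candidate selection, fovea ties toward the center then left).
* Otsu thresholds are bin-edge values, so applying them to quantized data
  is exact; valley thresholds are bin centers, since the valley rule names
  a bin.
* Constant images: standardize to all-zeros; zero noise variance; no
  edges; degenerate-histogram errors from Otsu rather than arbitrary cuts.
* Errors are typed conditions (`mhseg_validation_error`, `mhseg_no_retina`,
  `mhseg_insufficient_modes`, ...) so callers can fall back selectively;
  the pipeline itself only catches the valley-mode fallback.
* A scan is declared hole-free (all-zero mask), not an error, when no
  candidate survives the filters; the CLI turns this into exit code 3
  only under `--require-hole`.

## Problem sizes in the test suite

The suite verifies the Sobel field against a nested-loop correlation
oracle on 16×16 images, multilevel Otsu against exhaustive enumeration on
64-bin histograms for $k \in \{1,2,3\}$, and the end-to-end pipeline on 30
hole phantoms plus 30 hole-free phantoms at default conditions, with a
noise-robustness sweep over speckle looks $\{1, 4, 16\}$ (20 seeds each).
These sizes make the oracles exact and the phantom statistics stable while
keeping a full run in tens of seconds.

## Known limitations

* Single 2-D B-scans only; no volumetric context, no DICOM/vendor formats.
* The fovea search assumes fovea-centered acquisition; far-eccentric
  pathology is flagged, not followed.
* The candidate score is a heuristic fusion; its decay constant ($W/8$)
  and the filter defaults are exposed in the configuration and should be
  treated as tunable on real data.
* No lesion taxonomy: cysts or sub-retinal fluid pockets inside the band
  that pass the filters would be segmented as the hole.
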