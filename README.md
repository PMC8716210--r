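# mhseg — macular hole segmentation in retinal OCT B-scans

`mhseg` detects and delineates full-thickness macular holes in single
optical coherence tomography (OCT) B-scans. A macular hole is a defect of
the neurosensory retina at the fovea; on OCT it appears as a
hypo-reflective gap interrupting the bright retinal band at the foveal
depression. The package is aimed at image-analysis researchers and
ophthalmic imaging groups who need a transparent, fully deterministic,
classical (non-learned) baseline with per-stage access to intermediate
results.

## Method

The segmentation fuses two classical cues:

* **Multilevel thresholding.** A 256-bin histogram of the denoised scan is
  cut into k+1 reflectivity classes. The default criterion is multilevel
  Otsu — the cut tuple (t₁ < … < t_k) maximizing the between-class
  variance Σ w_c (μ_c − μ)², found by exhaustive search for k ≤ 3 with
  deterministic tie-breaking. The classical histogram-valley rule
  (minimum between the two highest-prominence peaks of the smoothed
  histogram) is available as an alternative, with automatic fallback to
  Otsu.
* **Derivative edge detection.** The 3×3 Sobel pair gives L_x, L_y, the
  gradient magnitude ∇L = √(L_x² + L_y²) and direction θ = atan2(L_y, L_x).
  For sub-pixel edge localization on 1-D profiles the package fits the
  blurred-step model f(x) = (I_r − I_ℓ)/2 · erf((x − x₀)/(σ√2)) +
  (I_r + I_ℓ)/2, reporting the edge outset/end at x₀ ∓ 2σ.

Around these sit a local-statistics adaptive (Lee/Wiener-type) speckle
filter, retinal-band and foveal-pit localization, extraction of
darkest-class components inside the band scored by area, edge support and
foveal proximity, morphological refinement, clinical shape features
(area, base width, minimum diameter, height, circularity), and pixel-wise
evaluation metrics (accuracy, sensitivity, Jaccard, Dice). A synthetic
fovea-centered phantom generator (layered band, Gaussian foveal pit,
optional full-thickness hole, vessel shadows, multiplicative gamma
speckle, detector blur) provides ground truth for the whole test suite.
The methods vignette (`vignettes/macular-hole-segmentation.Rmd`) documents
every model, default and design decision.

## Worked example

```r
library(mhseg)

ph  <- generatePhantom(PhantomSpec(seed = 7))   # 224x224 scan + truth mask
seg <- segmentHole(ph$image)
seg
#> HoleSegmentation: fovea column 112, 1 candidate(s), hole area 1945 px

computeHoleFeatures(holeMask(seg))[, c("area", "baseWidth", "minDiameter",
                                       "height", "circularity")]
#>   area baseWidth minDiameter height circularity
#> 1 1945        30          28     67    0.646383

round(evaluateMasks(holeMask(seg), ph$truth)[,
      c("accuracy", "sensitivity", "jaccard", "dsc")], 4)
#>   accuracy sensitivity jaccard    dsc
#> 1   0.9974      0.9512  0.9354 0.9666
```

The phantom carries a 30-column full-thickness hole at the fovea
(column 112). The pipeline finds one candidate there; its base width (30)
matches the generative hole width, the minimum mid-hole diameter is 28,
and the recovered mask overlaps the latent truth with Dice 0.967.
The low circularity (0.65) reflects the tall, flat-sided shape of a
full-thickness hole — it is advisory, never a filter.

## Command line

A thin CLI over the same functions lives at `inst/scripts/mhseg.R`
(installed under `system.file("scripts", "mhseg.R", package = "mhseg")`):

```sh
Rscript mhseg.R segment  --input scan.png --output-mask hole.png --report prov.json
Rscript mhseg.R evaluate --pred hole.png --truth truth.png --json metrics.json
Rscript mhseg.R simulate --n 20 --seed 1 --out-dir phantoms/
Rscript mhseg.R pipeline --config run.yaml
```

Exit codes: 0 success, 2 validation error, 3 no hole detected (with
`--require-hole`). YAML configs mirror the flags; explicit flags win.

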