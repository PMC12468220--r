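# nucleoseg

Unsupervised segmentation of cell nuclei in stained cervical cytology
(Pap smear) images, where hematoxylin-stained nuclei are the darkest
structures inside lighter cytoplasm on a bright background. The package is
aimed at people building or benchmarking classical (non-deep-learning)
screening pipelines: it implements the full adaptive enhancement +
multi-Otsu pipeline, the five local-thresholding baselines it is commonly
compared against, pixel-level evaluation with paired t-tests, and a
seed-controlled synthetic scene generator so every experiment here runs
without downloading any dataset.

## The method

For an RGB image with channels in [0, 1]:

1. **HSV enhancement.** Convert to HSV (V = max(R, G, B)); smooth V with an
   edge-preserving bilateral filter,

   I'(x, y) = (1/W) Σ_{(i,j) ∈ S} I(i, j) · G_s(‖(i,j) − (x,y)‖) · G_r(I(i,j) − I(x,y)),

   then apply adaptive gamma correction V ← V^γ with the exponent chosen
   from the mean μ of the filtered channel:

   γ = 1 + (0.5 − μ)  if μ > 0.5,    γ = 1 / (2μ)  otherwise,

   (both give γ = 1 at μ = 0.5), and convert back to RGB with the original
   hue and saturation.

2. **Three-class multi-Otsu.** On the 256-bin grayscale histogram p(i),
   find the threshold pair (t₁, t₂) maximizing the between-class variance

   σ_B² = Σ_{k=1..3} ω_k (μ_k − μ_T)²

   over the classes [0, t₁], [t₁+1, t₂], [t₂+1, 255], by exhaustive search
   with cumulative moments (verified identical to brute-force enumeration).
   Class 1 — the darkest — is the nucleus mask.

3. **Adaptive morphological refinement.** Connected-component screening
   (4-connectivity), then conditionally: opening (speckle present), hole
   filling (large interior holes present), closing (jagged boundaries),
   optional Canny/Sobel edge refinement, and always a final area filter
   A_k ≥ A_min.

Baselines: Bradley (T = m(1 − k/100)), Niblack (T = m + ks), Nick,
Sauvola (T = m(1 − k(1 − s/R))) and Feng, all on a shared integral-image
sliding-window engine. Evaluation: precision, recall/sensitivity, F1,
accuracy, PSNR, and paired t-tests across trials.

See `vignettes/nucleus-segmentation.Rmd` for the full account of the model,
parameter defaults and design choices.

## Worked example

```r
library(nucleoseg)

# a synthetic Pap-smear-like scene with ground truth
sc  <- generate_scene(scene_spec(n_nuclei = 3, noise_sigma = 0.02,
                                 gradient = 0.1, blur_sigma = 0.8, seed = 42))
seg <- segment_image(sc$image)
seg$log[c("mean_intensity", "gamma", "t1", "t2")]
#> mean V 0.749  gamma 0.751  thresholds (87, 177)

m <- seg_metrics(confusion(seg$mask, sc$mask))
#> precision 1.0000  recall 1.0000  F1 1.0000  accuracy 1.0000
```

The filtered value channel averaged 0.749, so the bright-image branch chose
γ = 1 + (0.5 − 0.749) = 0.751; the histogram split at levels 87 and 177
(nucleus / cytoplasm / background), and the refined mask matched the
generated truth on every pixel of this easy scene.

Comparing methods on six scenes:

```r
scenes <- lapply(1:6, function(s)
  generate_scene(scene_spec(seed = s, noise_sigma = 0.02, blur_sigma = 0.8)))
cmp <- run_comparison(lapply(scenes, `[[`, "image"),
                      lapply(scenes, `[[`, "mask"))
cmp$table[, 1:5]
#>     method precision f_measure sensitivity accuracy
#> 1  bradley     0.357     0.523       1.000    0.893
#> 2     feng     0.256     0.407       1.000    0.830
#> 3  niblack     0.171     0.291       1.000    0.716
#> 4     nick     0.389     0.557       1.000    0.906
#> 5  sauvola     0.295     0.453       1.000    0.859
#> 6 proposed     1.000     1.000       0.999    1.000
```

The window-statistics baselines find every nucleus (sensitivity 1.0) but
also claim most of the cytoplasm, collapsing their precision; the proposed
pipeline separates the three intensity populations first and keeps only the
darkest class. `cmp$t_tests` holds the paired t-test summaries against
Sauvola and Bradley.

## Command line

A thin CLI over the same functions lives at `inst/cli/nucleoseg`:

```sh
Rscript inst/cli/nucleoseg synth    --out fixtures --n 8 --seed 42
Rscript inst/cli/nucleoseg segment  fixtures/image_001.png --out masks
Rscript inst/cli/nucleoseg baseline fixtures/image_001.png out.png --method sauvola
Rscript inst/cli/nucleoseg compare  --images imgs --truths truths --out table.csv
Rscript inst/cli/nucleoseg evaluate --pred masks --truth truths --out report.csv
```

Exit codes: 0 success, 1 usage error, 2 partial batch failure.

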