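# pnseg — pentagonal-neutrosophic segmentation of dermoscopic skin lesions

`pnseg` is an R package for classical (non-deep-learning) computer-aided
analysis of dermoscopic skin-lesion images. It restores an acquired image
— edge-preserving adaptive denoising, removal of digital artifacts (hair
strands, ruler tick marks, dark circular frames) with inpainting, and
contrast-limited histogram equalization — and then segments the lesion in
two phases:

1. **Weighted global threshold.** The three channels are unified by the
   per-pixel geometric mean, and the threshold
   γ = (I_min·w₁ + I_max·w₂)/(w₁ + w₂), with w₁ = 0.4 and w₂ = 0.6, splits
   the (darker) lesion from the skin. A 3×3 sliding minimum, a 7×7 sliding
   maximum, and a largest-component filter clean the rough mask.
2. **Pentagonal-neutrosophic refinement.** Pixels in a band around the
   phase-1 boundary are genuinely ambiguous. Their darkness is normalized
   over the band and each is kept or discarded against the threshold

   ϑ = (1/15)(m₁+m₂+m₃+m₄+m₅)(2 + π − σ − μ),

   where (m₁…m₅) is a pentagonal neutrosophic quintuple on the normalized
   intensity axis (by default the 10/30/50/70/90th percentiles of the
   band's own darkness; linguistic grades VeryLow…VeryHigh are also
   available) and π, σ, μ are its truth, indeterminacy and falsity
   degrees.

The package also provides the full evaluation-metric suite (MSE, RMSE,
PSNR, UIQI; sensitivity, specificity, Dice, Jaccard, accuracy, AUC,
precision, recall, F1, MCC; bounding-box IoU and mean average precision;
image mean/skewness/kurtosis), a 4× rotation data-augmentation scheme,
and a seeded synthetic dermoscopy generator with paired ground-truth
masks, so every stage is testable without downloading any dataset.

Intended users: researchers in medical image analysis who need a
reproducible classical baseline for lesion segmentation, and developers
of dermoscopy pipelines who need the standard metric arithmetic and a
controllable synthetic test bed.

## Worked example

Generate a synthetic scene carrying hair, ruler marks and noise, restore
it, segment it, and score the result against the generator's ground
truth:

```r
library(pnseg)

s  <- generate_scene(scene_spec(size = 512, n_hairs = 3, ruler = TRUE,
                                boundary_irregularity = 0.2,
                                noise_sigma = 6, seed = 7))
pp <- preprocess_image(s$image)
pp
#> Pre-processed dermoscopic image
#>   size: 512 x 512
#>   artifact pixels flagged: 10590 (4.04%)

seg <- segment(pp$image)
seg
#> Two-phase dermoscopic lesion segmentation
#>   image: 512 x 512 px
#>   global threshold gamma: 128.27 (intensity units)
#>   pentagonal threshold theta: 0.3151 (normalized darkness)
#>   boundary band: 9468 px
#>   lesion area: 51850 px (19.78% of image)

summary(seg, truth = s$lesion_mask)
#> gamma = 128.27, theta = 0.3151, band = 9468 px
#> phase-1 area = 53889 px, final area = 51850 px
#> vs truth: Dice 99.98%, Jaccard 99.96%, Sn 100.00%, Sp 99.99%

psnr(s$clean, pp$restored)   # restoration fidelity, pre-enhancement
#> [1] 45.55
```

Reading the numbers: γ = 128.27 is the weighted blend of the unified
image's intensity extremes — every pixel darker than that forms the
rough mask; ϑ = 0.3151 is the pentagonal threshold on the normalized
darkness scale of the 9 468-pixel boundary band, so band pixels scoring
at least 0.3151 are kept as lesion. The final mask overlaps the ground
truth with Dice 99.98%, and the restored (denoised, artifact-free) image
matches the clean reference at 45.6 dB PSNR — far above the 20 dB bar
for a well-restored image.

`plot(seg, img = pp$image)` overlays the mask contour on the image.
A command-line wrapper over the same functions ships in
`inst/cli/pnseg.R` with subcommands `preprocess`, `segment`, `evaluate`,
`quality`, `synth`, `augment` and `run`.

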