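---
title: "Pentagonal-neutrosophic thresholding for dermoscopic lesion segmentation: methods and design notes"
author: "pnseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pentagonal-neutrosophic thresholding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnseg)
```

## The problem

Dermoscopic images of pigmented skin lesions are the standard input to
computer-aided melanoma screening. Before any classifier sees such an
image, two classical steps dominate the quality of everything downstream:
(i) restoring the image — removing sensor noise and digital artifacts
(hair strands, ruler tick marks, dark circular frames) without erasing the
lesion's own texture — and (ii) delineating the lesion against the
surrounding skin. `pnseg` implements a complete classical pipeline for
both steps, a full evaluation-metric suite, a rotation-based augmentation
scheme, and a seeded synthetic dermoscopy generator so that every stage
can be exercised and scored without any external dataset.

The segmentation core rests on an uncertainty formalism: the boundary
zone of a lesion is genuinely ambiguous — pixel intensities there sit
between the lesion and skin modes — and the method treats that ambiguity
explicitly with a pentagonal neutrosophic number rather than a single
crisp threshold.

## Pentagonal neutrosophic numbers

A single-valued pentagonal neutrosophic number (SVPNN) carries three
piecewise-linear membership profiles over five ordered support points
$a \le b \le c \le d \le e$: a *truth* profile peaking at degree
$\pi \in [0,1]$ at the core $c$, and *hesitation* and *falsity* valley
profiles that equal 1 outside the support and dip to their degrees
$\rho, \sigma$ at the core. The three degrees are independent — that is
the neutrosophic idea — subject only to the sum-of-suprema bound
$0 \le \sup\omega + \sup\sigma + \sup\eta \le 3$.

Two numerical conventions are worth stating because the defining
piecewise formulas are delicate at the knots:

* Each linear piece is evaluated exactly as defined, which makes the
  profiles discontinuous at the inner knots $b$ and $d$ (each rising
  piece restarts from its floor). The final falling truth branch as
  commonly printed would be negative on its own interval — an evident
  transcription slip — and is implemented as its mirror
  $\pi(e-x)/(e-d)$.
* Zero-width intervals ($a=b$ etc.) are treated as jumps evaluated by
  right-continuity, which avoids division by zero while preserving the
  core values.

### The scalar threshold

Phase two of the segmentation needs a single number out of a pentagon.
The score-style reduction used is

$$\vartheta \;=\; \tfrac{1}{15}\,(m_1+m_2+m_3+m_4+m_5)\,(2+\pi-\sigma-\mu),$$

with $m_i$ on the normalized intensity axis and $\pi,\sigma,\mu$ the
truth, indeterminacy and falsity parts. Useful algebra, all covered by
tests: with $\pi=1,\sigma=\mu=0$ the reduction is exactly the arithmetic
mean of the $m_i$; it is strictly increasing in $\pi$ and strictly
decreasing in $\sigma$ and $\mu$; and $0 \le \vartheta \le \frac{3}{15}\sum m_i$.

### Linguistic grades and defaults

The five-term vocabulary (VeryLow, Low, Median, High, VeryHigh) is
anchored on $[0,1]$ at cores $0.1, 0.3, 0.5, 0.7, 0.9$ with a symmetric
$\pm 0.2$ spread clipped to the unit interval — the uniform partition is
the only symmetric choice when no numeric anchors are prescribed — e.g.
`Median` $\mapsto (0.3, 0.4, 0.5, 0.6, 0.7)$. The default degrees are
$\pi = 0.9$, $\sigma = 0.3$, $\mu = 0.2$: interior values that exercise
all three terms of the reduction instead of silently degenerating to the
mean. Both the anchor table and the degrees are plain arguments and can
also be read from a flat `key = value` config file
(`read_pnn_config()`); nothing is hidden. Asymmetric pentagons need no
separate type — any non-decreasing quintuple is accepted.

## Pre-processing

### Adaptive denoise

The denoiser is a normalized product of a spatial Gaussian
($\sigma_s$, in pixels) and a brightness Gaussian
($\sigma_b$, in intensity units) in the difference to the centre pixel,
plus a hard *range cutoff*: a neighbour differing by more than
`range_cutoff` (default $3\sigma_b$) contributes nothing. The cutoff is
the package's reading of the filter's adaptive clause — the intent is
that neighbours on the far side of an edge must not bleed across it —
expressed with a single interpretable parameter. Properties used as test
oracles: the filter is exact on constants (the normalization guarantees
it), and with the cutoff disabled and $\sigma_b \to \infty$ it converges
to plain Gaussian convolution. Defaults: $\sigma_s = 2$ px (smooths
sensor noise without rounding the lesion border at 512 px scale),
$\sigma_b = 30$ (edges of interest in dermoscopy are 50–150 intensity
units deep, well above the cutoff). Borders are edge-replicated
everywhere in the package; zero padding would fabricate dark bands that
the artifact detector is specifically hunting for.

### Artifact detection

Hair, ruler marks and frames share two properties: they are *darker than
their immediate surroundings* and *thin or border-hugging*. Detection
works on the monochrome image (geometric channel mean — the same
unification rule the segmenter uses, kept identical on purpose):

1. **Black-hat transform**: morphological closing (structuring window
   11 px, wider than the widest strand) minus the image. Dark structures
   thinner than the window light up; the lesion, far wider, does not.
2. **Binarization** at `mean + 2·sd` of the response, with an absolute
   floor of 10 intensity units. The floor matters: on an already-clean
   image the adaptive threshold collapses towards zero and would start
   flagging noise.
3. **Curvilinearity filter**: a connected component (8-connectivity;
   thin diagonal strands fragment under 4-connectivity) is kept only if
   it is elongated: `area >= 4 * width^2`, with `width` estimated as
   `2*max(distance transform) - 1`, at least 25 px of area, and at most
   5% of the image. Compact, regular blocks — the lesion, blob-like
   noise — are relegated to background. This operationalizes a
   skeleton-length-to-width test without needing a skeletonizer.
4. **Hysteresis**: a strand's contrast drops where it crosses the dark
   lesion. Each surviving strong component is therefore extended through
   the connected weak black-hat response (threshold `mean + 0.5·sd`,
   floor 5), which restores strand continuity without admitting isolated
   weak noise.
5. **Frame rule**: dark (< 60) regions inside a 15% border zone whose
   component actually touches the image border are flagged regardless of
   shape. Requiring border contact keeps a dark lesion that merely
   extends toward the edge out of the frame mask.
6. **Consolidation**: two rounds of dilate (3×3 cross) + 3×3 mean-smooth
   + re-binarize at 0.5, growing the mask to full strand width.

### Inpainting

Flagged pixels are replaced by an inverse-distance-weighted average of
nearby *original, unflagged* pixels, searched over expanding radii (3, 7,
15 px); pixels deeper inside a large artifact (frame corners) are then
filled by iterative propagation from already-inpainted neighbours. The
method is deterministic and dependency-light, and on a constant
neighbourhood returns the constant exactly.

### Enhancement, and where PSNR is measured

Contrast enhancement is cumulative-histogram equalization of the
luminance channel (ITU-R 601 weights) with chroma preserved by
proportional channel rescaling. The luminance histogram is *clipped* at 3
times the uniform bin height before the mapping is built (excess mass
redistributed uniformly; `clip = Inf` recovers the classic mapping).
Unclipped global equalization on a bimodal lesion/skin image stretches
the majority skin band across most of the intensity axis — visually
dramatic, and destructive: it amplifies residual noise by the full
histogram slope and shifts every pixel. The clip bounds the contrast
amplification at 3×, a conventional strength for medical-image
equalization.

Restoration fidelity (MSE/RMSE/PSNR/UIQI) is measured on the
artifact-removed image *before* enhancement (`$restored` in the result).
The enhancement step changes brightness and contrast globally *by
design*, so a PSNR computed across it would measure the intended tone
mapping, not restoration quality; the conventional 20 dB quality bar, and
the 29–41 dB range typical of published artifact-removal tables, are only
meaningful pre-enhancement. On the package's synthetic suite the restored
image scores 30–50 dB against the clean reference.

## Two-phase segmentation

Phase 1 on the unified (geometric-mean) channel:

* global threshold $\gamma = (I_{\min} w_1 + I_{\max} w_2)/(w_1+w_2)$
  with the published weights $w_1 = 0.4$, $w_2 = 0.6$ — lesions are dark,
  so pixels strictly below $\gamma$ form the initial mask;
* a 3×3 sliding *minimum* (full-window erosion) kills speckle, then a
  7×7 sliding *maximum* (dilation) restores the body — the garbled
  stride notation in the source description is read as standard dense
  rank filtering, which is what "minima/maxima of overlaying pixels"
  names;
* the largest connected foreground component is kept (the method
  targets single-lesion images; configurable off).

Phase 2 refines the ambiguous boundary ring: a band of half-width 5 px
around the phase-1 boundary (the 8-connected inner boundary, dilated; for
band extraction the image is treated as surrounded by background so a
full-image mask still has a boundary). Band intensities are normalized to
a *darkness* score $(b_{\max} - I)/(b_{\max} - b_{\min}) \in [0,1]$ over
the band's own range — dark, lesion-like pixels score high, consistent
with the "below $\gamma$" polarity of phase 1 — and a band pixel is kept
iff its score is $\ge \vartheta$. Raising $\vartheta$ can only shrink the
mask (tested). By default the five pentagon components are the
10/30/50/70/90th percentiles of the band's own darkness distribution: a
data-adaptive, generally asymmetric pentagon, overridable by a linguistic
grade or an explicit quintuple. A degenerate band (all one intensity)
keeps its phase-1 labels.

Pixels outside the band are never relabelled, so
`final ⊆ phase1 ∪ band` holds structurally.

## Metrics

The metric suite computes MSE, RMSE, PSNR ($20\log_{10}(255/\mathrm{RMSE})$;
the occasionally printed $-20\log_{10}(I_{max}/\mathrm{MSE})$ form is a
sign/argument garble that yields negative decibels), the universal image
quality index, pixel confusion counts, sensitivity, specificity, Dice,
Jaccard, accuracy, the two-point AUC $(S_n+S_p)/2$, precision, recall,
F1, Matthews correlation, true bounding-box IoU (the Dice-shaped
"IoU" formula sometimes printed is available separately as the Dice
coefficient), mean average precision, and first-order image statistics
(mean, standardized skewness with the dimensionally consistent $\sigma^3$
denominator, non-excess kurtosis). Ratios with zero denominators return
`NA`, never a silent 0. Percentages are rounded half-up to 2 decimals,
the convention of published tables. `confusion_from_rates()` inverts that
convention: given class sizes and printed sensitivity/specificity it
reconstructs the integer confusion matrix by nearest-integer rounding,
which is how the package's acceptance checks re-derive published
accuracy/precision/F1/MCC exactly.

## The synthetic generator

`generate_scene()` emulates the features the pipeline is built to
handle: an ameboid lesion (circle radially perturbed by a low-order
random Fourier series) filled with 2–5 concentric shades from dark
centre to lighter rim, all strictly darker than the skin in
geometric-mean intensity; hair strands as cubic Bézier strokes of width
1–5 px sharing a per-scene growth direction and kept ≥ 3 px apart (so
strand-level ground truth stays well defined); ruler ticks along the top
edge; a dark circular frame vignette; additive Gaussian noise, clipped
and quantized to 8 bits. Everything is driven by one seed per scene;
`default_suite(n, master_seed)` derives per-scene seeds from
`(master_seed, index)` so a suite is stable under reordering. The default
20-scene suite spans a fixed grid: irregularity {0, 0.15, 0.3} ×
artifact load {none, hairs, hairs+ruler+frame} × noise σ {0, 6} × lesion
radius {0.18, 0.25, 0.32} of the image side. Noise σ = 6 and near-black
(≤ 35) artifacts are the package's choice of a realistic operating
point; both are echoed in the suite manifest rather than hidden.

What the generator does *not* emulate — and hence what passing tests do
not show about real dermoscopy: pigment networks, dots/globules and
other dermoscopic microstructure; specular gel reflections; vignetting
gradients; camera-dependent colour casts; multi-lesion fields. The suite
validates the pipeline's contracts and its behaviour under the artifact
classes it targets, not clinical performance.

`augment()` implements the 4× scheme: each sample plus its exact
90/180/270° grid rotations (mask cardinality preserved; no
interpolation), with seeded Gaussian noise injected into the rotated
copies. The count rule maps 25 881 → 103 524.

## Problem sizes and runtime choices

The test-suite and acceptance runs use the generator's native 512×512
scenes for the end-to-end checks (20 scenes), 256 px scenes for
module-level artifact tests, 32×32 images for the brute-force oracle
equivalence of the phase-1 path (50 replicates), and 16×16 patches for
the Gaussian-limit denoise oracle — sizes at which the naive pixel-loop
oracles remain exact and fast while still exercising every branch.

## Known limitations

* The weighted-extremes threshold $\gamma$ is sensitive to single
  extreme pixels by construction; the pipeline relies on denoising and
  artifact removal having run first.
* One lesion per image is assumed (largest-component filter); no soft
  masks.
* The hair detector targets *dark* curvilinear artifacts; blonde/white
  hair and specular reflections are out of scope.
* The equalization clip (3×) trades contrast gain against fidelity; raise
  it (or set `clip = Inf`) for the classic dramatic equalization at the
  cost of noise amplification.
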