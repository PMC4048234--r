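---
title: "Methods: automated islet immunofluorescence scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated islet immunofluorescence scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletscore)
```

## The measurement model

An islet picture is a three-channel fluorescence acquisition: DAPI marks all
nuclei, the 488 channel carries a β-cell surface marker (TMEM27 or BACE2 in
the motivating application), and the 555 channel carries an α-cell
counterstain (glucagon) that, together with the β marker, delimits the
endocrine tissue. A pathologist supplies the islet segmentation; automating
the segmentation would add its own bias to exactly the comparisons the
pipeline is meant to make objective, so the mask is an input here, not an
output.

The quantity of interest is the **area score**: the fraction of the islet
covered by stained, non-nuclear pixels, mapped linearly to the `[0, 3]`
scale a pathologist uses. Two auxiliary features come along: **islet size**
(mask pixel count, or µm² when the pixel size is known) and **β-cell
density** (cells voted β-positive per unit islet area). Deliberately, pixel
*intensities* never enter the final estimator — only the stained/background
classification does — which makes the score insensitive to overall gain and
smooth illumination differences between acquisitions.

## Pipeline stages and their assumptions

**Stain/background separation.** Each stain layer's intensity histogram
(256 equal bins on `[0, 1]`; intensities are normalised on load by the image
bit-depth maximum, making the pipeline agnostic to 8- vs 16-bit input) is
split into two clusters by one-dimensional k-means with k = 2, weighted by
bin counts. The underlying assumption is a bimodal mixture: a large
background mode and a stained mode at higher intensity. The split adapts per
image, so no global threshold has to be tuned. Numerical choices:

- *Initialisation*: centres at the 10% and 90% points of the occupied
  intensity range; Lloyd iterations until centre movement < 1e-6 or 100
  iterations. Deterministic — no random restarts.
- *Boundary refinement*: Lloyd's algorithm can stall on one of two adjacent
  fixed points when the boundary bin is a near-tie. After convergence the
  cut is moved, one occupied bin at a time, while the within-cluster sum of
  squares strictly decreases. In one dimension the optimal two-cluster
  partition is a threshold, and on every synthetic fixture we test, this
  refined split coincides with an exhaustive search over all bin boundaries.
- *Degeneracy*: if the histogram occupies a single bin, or the final centres
  are closer than two bin widths, the image is declared unstained and every
  pixel is background. This keeps a score of 0 reachable for islets with no
  detectable marker expression.
- *Histogram domain*: the whole image, not just the islet. The background
  mode is estimated mostly from tissue outside the islet, which is what
  makes the split robust to where exactly the islet sits in an uneven
  illumination field; the islet mask is applied later, at counting time.

**Nucleus detection.** The DAPI layer is smoothed with a Gaussian of scale
`min_radius / 2`, foreground is separated with the same histogram split,
and touching nuclei are cut apart by watershed on the distance transform.
Each watershed region is then tightened to its half-maximum contour
(pixels above background + half the object's peak elevation), a standard
blob-extent rule that keeps the nucleus mask from bleeding into the
surrounding cytoplasm; components smaller than `π·min_radius²/4` px are
discarded as debris. A nucleus belongs to the islet when its centroid lies
on a mask pixel — the simplest defensible membership rule for boundary
nuclei. The detector used in the original pipeline is an external tool with
unpublished parameters, so equivalence with it cannot be claimed; what the
tests establish is recovery of the synthetic ground truth (recall,
precision and sub-pixel centroid accuracy on well-separated nuclei).

**α/β voting.** For each nucleus, stained pixels of both stain layers are
counted in a disc of `patch_radius` px around the centroid (default
`2.5 × min_radius`, clipped at image borders) and the cell is labelled by
strict majority. Ties — including zero evidence on both channels — stay
`unclassified`: such cells count toward the nucleus total but never toward
β-cell density. The disc stands in for the unknown cytoplasmic extent of a
cell; it is the natural reading of "a patch around each nucleus" and its
radius is an explicit, user-visible parameter.

**Area score.** `score = 3 × |stained ∩ islet ∖ nuclei| / |islet|`. Nucleus
pixels are excluded from the numerator only; the denominator stays the full
islet area (the literal reading of the defining sentence). The alternative
convention — excluding nuclei from the denominator as well — is available as
`denominator = "islet_minus_nuclei"` because the choice is genuinely
underdetermined; with typical nuclear coverage of 10–20% it shifts scores
upward by the same factor. The `[0, 1] → [0, 3]` map is the identity times
three; nothing in the method calls for per-batch renormalisation, and a
data-dependent rescaling would break comparability across islets.

**Manual-score surrogate.** The pathologist's score combines an intensity
grade (0–3) with the stained-cell percentage, in 0.25 steps. The original
decision tree is not recoverable from the published description, so
`manual_score_surrogate()` multiplies grade by fraction and rounds half-up
to the nearest 0.25. It exists to exercise code paths that compare manual
and automated scales, and is documented as an approximation, not a claim of
equivalence.

## Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `histogram_bins` | 256 | bins | histogram resolution of the k-means split |
| `min_radius`, `max_radius` | 3, 8 | px | expected nucleus radius range; smoothing scale and debris cutoff derive from `min_radius` |
| `patch_radius` | `2.5 × min_radius` | px | voting disc radius around each nucleus |
| `denominator` | `"islet"` | — | area-score denominator convention |
| `pixel_size` | unset | µm/px | enables µm² islet size and per-mm² density |

## The synthetic-data generator

`generate_islet()` draws an elliptical islet on a 344 × 258 px canvas
(quarter scale of the 1376 × 1032 acquisition format; full scale is one
parameter away) holding 40 cells by default. Each nucleus is a Gaussian
DAPI blob (scale `nucleus_radius / 1.5`, radius 4 px); each cell stains 90%
of a cytoplasmic annulus (radii 4–10 px) in its class channel, with 70% of
cells β by default. On top: a multiplicative low-order polynomial
illumination field (amplitude 0.15) and additive Gaussian pixel noise.
Stain and background levels default to 0.75 and 0.12 with noise SD 0.05 —
the contrast of a reasonable-quality fluorescence acquisition
(signal-to-noise ratio `(stain − background)/noise ≈ 12.6`). In
well-separated mode (the default) nucleus centres keep at least
`2 × cytoplasm_radius` apart, so annuli are disjoint and per-cell votes
have an unambiguous ground truth. The optional `target_stained_fraction`
tops up or thins the stained 488 pixels among non-nuclear islet pixels
until the true stained fraction hits a requested value to pixel resolution,
which is how the tests sweep the full score range. Ground truth (centres,
classes, pre-noise masks, true stained fraction) is recorded from the
generated masks themselves, and the generator is bit-reproducible from its
seed.

`generate_cohort()` emulates the *feature* layer of a scored cohort:
patient-level mean scores around group means (ND baseline 1.8, T2D lower by
`effect`; between-patient SD 0.1), per-islet scores around the patient mean
(between-islet SD 0.3 in the default study conditions: 20 + 20 patients,
9 islets each), and group BMI/age drawn from the observed cohort
characteristics (ND 26 ± 3, 66 ± 14; T2D 30 ± 4, 64 ± 10).

What the generator does *not* emulate: point-spread blur, chromatic shift,
autofluorescence texture, exocrine tissue outside the islet, irregular
nucleus shapes, and spatially correlated staining. Passing tests therefore
demonstrate that the algorithms recover their own declared model — a
necessary condition, not evidence about behaviour on real tissue, which
would need annotated acquisitions.

## Cohort statistics

Per-patient aggregation is the median over islets, mean-of-middle-two for
even counts. The group comparison is the classic equal-variance unpaired
two-tailed Student's t-test (Welch available but off by default, matching
the stated convention); correlation is Pearson's with r² and a two-tailed p
from the t distribution on n − 2 degrees of freedom; the slope comparison
is one OLS fit `y ~ group + x + group:x` whose per-group slopes provably
equal the within-group least-squares slopes, with the interaction t-test
giving the slope-difference p. These are computed from their closed-form
definitions, and the test suite checks them against R's reference
implementations (`cor.test`, `t.test`, `lm`) to 1e-8, plus a Monte-Carlo
check that the t-test's type-I error at α = 0.05 sits near 5%. "SDM" in
the source table is read as the sample (n − 1) standard deviation. No
multiple-testing correction is applied anywhere; p < 0.05 is the
significance convention, mirroring the analysis the package reproduces.

The shipped `cohort_table1.csv` is a transcription of the published
clinical-characteristics table with invented patient identifiers (the table
prints none). Its footnote's per-source patient counts are internally
inconsistent with the table body (they sum to 29 ND and 33 T2D); the
package follows the body rows, and only body-consistent counts are asserted
in tests.

## Problem sizes and numerical conventions in the test suite

Unit tests run on 140 × 170 px islets with 8 cells; recovery sweeps use the
default 344 × 258 canvas with the true stained fraction in
{0.1, 0.3, 0.5, 0.7, 0.9} × 20 seeds; the thresholding oracle comparison
uses 50 random bimodal 80 × 80 images; statistical calibration uses 1000
null replicates, and cohort power 100 replicates of the 20 + 20 × 9 design.
These sizes were chosen so the whole suite exercises every claim in a few
minutes on a laptop while keeping Monte-Carlo bands tight enough to be
meaningful.

## Known limitations

- **Sparse staining at low SNR.** The histogram k-means split minimises the
  within-cluster sum of squares, and when one class is very small (stained
  fraction ≈ 0.1) and the noise is strong (SNR near 4), the optimal cut
  migrates into the background tail: background pixels leak into the
  stained class and the score is biased upward by several tenths of a score
  unit. This is a property of the thresholding objective itself — the
  exhaustive optimal-threshold search does the same — not of the Lloyd
  implementation. At the default synthetic imaging quality (SNR ≈ 12.6) the
  bias is unmeasurable. Users scoring faint stains in noisy acquisitions
  should inspect the reported per-channel thresholds.
- **Nucleus extent is model-based.** The half-maximum rule matches blobs
  with a single intensity peak; heavily textured or apoptotic nuclei would
  need a dedicated segmenter.
- **Equivalence with the original study's detector and manual decision tree
  cannot be established** from published information; both are replaced by
  documented, testable stand-ins.
- **No real annotated images ship with the package**, so all quantitative
  guarantees are with respect to the synthetic model above.
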