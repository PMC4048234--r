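# isletscore

Automated, unbiased quantification of β-cell–specific immunofluorescence in
pancreatic islets, with the cohort statistics needed to contrast type 2
diabetic (T2D) and non-diabetic (ND) pancreata.

## The problem

Pathologists grade the β-cell marker content of an islet on a `[0, 3]` scale
by eye, combining staining intensity with the share of stained cells. Manual
scoring is slow and carries observer bias. This package implements an
automated per-islet scoring pipeline for three-channel fluorescence images
(DAPI nuclear stain, a 488-channel β-cell marker such as TMEM27 or BACE2, a
555-channel α-cell counterstain such as glucagon), given a manual islet
segmentation:

1. **Nucleus detection** on the DAPI layer (Gaussian smoothing, adaptive
   foreground split, distance-transform watershed).
2. **Stain/background separation** per stain layer: two-cluster k-means
   (k = 2) on the count-weighted intensity histogram of the whole image. No
   per-image threshold is ever chosen by hand, and the split is robust to
   smooth illumination gradients.
3. **Per-pixel classification** into stained vs background from the
   histogram split.
4. **α/β cell classification** by strict majority voting over stained 488
   and 555 pixels in a patch around each nucleus.
5. **Islet features**:
   - *area score* `= 3 × (stained ∩ islet ∖ nuclei) / |islet|` — the stained
     non-nuclear pixel fraction mapped linearly onto the pathologist's
     `[0, 3]` scale;
   - *islet size* in px² (and µm² when the pixel size is known);
   - *β-cell density* = β-classified cells per unit islet area.

A per-patient median over islets feeds the cohort layer: unpaired two-tailed
Student's t-tests between groups, Pearson correlations (r², two-tailed p),
and ANCOVA comparison of marker-vs-BMI regression slopes via the
group × covariate interaction.

Because no acquisition images are publicly deposited, the package ships a
seeded synthetic islet-image generator with full ground truth (nucleus
positions and classes, stained masks, true stained fraction), so every stage
is testable end to end, plus a transcription of the study cohort table
(60 patients: 28 ND, 32 T2D; 1974 pictured islets).

## Worked example

```r
library(isletscore)

syn <- generate_islet(synth_params(n_nuclei = 30, seed = 42))
scored <- score_islet(syn$stack, syn$islet)
scored
#> <islet_score> area score 0.371 (stained fraction 0.124), islet 40265 px
#>   30 nuclei: 21 beta / 9 alpha / 0 unclassified; beta density 5.22 per 1e4 px^2
syn$truth$true_stained_fraction
#> [1] 0.124
```

The score 0.371 equals 3 × the stained non-nuclear fraction (0.124) of this
synthetic islet, matching the generator's ground truth; 21 of 30 cells carry
488 staining and are voted β. `autoplot(scored)` overlays the stained mask
and the per-cell votes; `tidy(scored)` returns the one-row feature table.

Cohort level:

```r
cohort <- load_cohort_table(
  system.file("extdata", "cohort_table1.csv", package = "isletscore"))
summarize_cohort(cohort)
#> <cohort_summary> 60 patients, 1974 islets pictured in total
#>   group n_patients mean_age sd_age mean_bmi sd_bmi
#> 1 ND            28     65.5  13.6      26     3.03
#> 2 T2D           32     63.7   9.82     30.4   3.69
#>   marker  total_islets mean_islets_per_patient
#> 1 tmem27           528                    8.8
#> 2 bace2            541                    9.02
#> 3 insulin          905                   15.1

coh <- generate_cohort(effect = 0.8, seed = 1)   # synthetic scored cohort
rep <- cohort_report(coh$features)
rep$all$ttest
#> <ttest_result> t = 19.1004 (df = 38), two-tailed p = 4.45e-21; means 1.869 vs 0.9541
rep$all$ancova
#> <ancova_slopes> slope[ND] = -0.004427, slope[T2D] = -0.001261; interaction t = 0.2039 (df = 36), p = 0.84
```

The built-in 0.8-score group effect is detected on patient medians
(p ≈ 4e-21); the BMI slopes do not differ (p = 0.84), as expected since the
synthetic cohort draws scores independently of BMI.

A shell wrapper with `synth`, `score` and `cohort` subcommands is installed
at `inst/cli/isletscore.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "isletscore.R", package = "isletscore"))') \
  synth --out islets/ --n 5 --seed 7
```

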