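# cascadeseg

Cascade 3D breast-lesion segmentation and multi-modal prediction of
pathologic complete response (pCR), in pure R.

## The problem

After neoadjuvant chemotherapy, whether axillary lymph nodes achieve pCR is
a strong prognostic factor in breast cancer.  Predicting it non-invasively
from DCE-MRI would support treatment planning.  Two obstacles shape the
pipeline implemented here:

* a breast DCE-MRI volume contains confounders — above all the heart, whose
  contrast-enhanced intensity is close to lesion intensity — so the lesion
  is segmented in **two steps**: the mammary gland region first, then the
  lesion within the gland's bounding box;
* imaging and molecular data carry complementary signal, so the pCR
  classifier **fuses** a 3D convolutional image branch with a fully
  connected branch over four immunohistochemical markers (HER2, ER, PR,
  Ki-67) by multiplying each convolutional stage's feature maps with the
  corresponding FC layer's outputs, channel by channel.

The segmentation network trains under the compound loss
`L_total = L_dice + L_ce`, with soft Dice computed over all classes and
cross-entropy per voxel.  Inference tiles the volume with half-patch
overlap, fuses patch predictions under a center-peaked Gaussian weight map,
and keeps the largest connected component.  Cross-center intensity shifts
are harmonized by gray-level histogram matching built on the cumulative
equalization map `s_k = (L-1)/M * sum_{j<=k} n_j`.  Classifiers are
compared with McNemar's test (uncorrected, `(b-c)^2/(b+c)`) and each is
compared against the ground-truth class distribution with a chi-square
goodness-of-fit test.

The clinical cohort this design targets is access-restricted, so the
package includes a synthetic phantom generator (`phantom_spec()`,
`generate_cohort()`) producing two-center 3D breast phantoms — gland,
lesion, posterior heart confounder with lesion-like intensity — plus marker
covariates with a known logistic link to the pCR label.  Every claim the
test suite makes is computed on these phantoms.

## Worked example

```r
library(cascadeseg)

# a two-center synthetic cohort with a known marker/size -> pCR link
cohort <- generate_cohort(20, phantom_spec(), seed = 7,
                          out_dir = tempfile("demo_"))
table(cohort$center_id, cohort$pcr_label)
#>      0  1
#>   C1  7 10
#>   C2  1  2

# the paired-comparison statistics on published counts
mcnemar_chi2(paired_outcome_table(63, 1, 12, 124))
#> # A tibble: 1 x 5
#>    chi2       p     b     c corrected
#>   <dbl>   <dbl> <dbl> <dbl> <lgl>
#> 1  9.31 0.00228     1    12 FALSE

chisq_gof(c(64, 136), c(83, 117))
#> # A tibble: 1 x 3
#>    chi2    df       p
#>   <dbl> <int>   <dbl>
#> 1  7.43     1 0.00640
```

The McNemar statistic 9.31 (p ≈ 0.002) says the two classifiers disagree
more asymmetrically than chance allows: of the 13 discordant patients, 12
were called pCR only by the second method.  The goodness-of-fit statistic
7.43 (p ≈ 0.006) says the first method's predicted pCR/non-pCR split
(64/136) is significantly distorted relative to the ground-truth split
(83/117).

A full end-to-end run — phantom generation, gland and lesion segmenter
training, two-step inference, fusion-model training, and the comparison
statistics on the demo's own predictions — is one call:

```r
report <- run_demo(seed = 1, verbose = TRUE)
report$seg_metrics        # per-phantom Dice / IoU / HD95
report$classifier_metrics # multi-modal vs image-only accuracy and AUC
```

A thin CLI over the same functions is installed at
`system.file("scripts", "cascadeseg-cli.R", package = "cascadeseg")` with
`phantom`, `histmatch`, `evaluate`, `stats` and `demo` subcommands.

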