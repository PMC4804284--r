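# nucquant

Detection, classification and quantification of cell nuclei in
multi-channel immunofluorescence tissue images where cell borders are
unstained.

## The problem

Quantifying cell-type-specific events in intact tissue — e.g. how many
cardiomyocyte nuclei in an infarcted heart section are synthesizing DNA —
usually requires deciding, nucleus by nucleus, which cell type hosts each
DAPI-stained nucleus. When membranes are not stained, that decision must be
read from the *texture around* the nucleus (striated α-actin-like signal
around myocyte nuclei, diffuse interstitium elsewhere), which is exactly
what trained histologists do by eye, slowly and with considerable
inter-observer disagreement. `nucquant` automates the workflow for R users:

1. **Preprocess** — divide every channel by a Gaussian-blurred (σ = 10 px)
   estimate of the structural-channel background to remove illumination
   gradients; segment nuclei as connected components of the Otsu-binarized
   corrected nuclear channel, discarding components smaller than 5 px.
2. **Featurize** — five per-pixel feature families on the nuclear and
   structural channels (rotation-invariant Fourier histograms of
   gradients; sliding-window Haralick statistics; local intensity entropy;
   a steerable-filter + tensor-voting membrane detector; extracellular
   component size), summarized per nucleus and per perinuclear ring by
   mean, median, standard deviation and median absolute deviation, then
   standardized to zero mean and unit variance within each image
   (360 descriptors per nucleus at defaults).
3. **Classify** — L2-regularized logistic regression (liblinear-style cost
   C) on expert dot annotations matched to nuclei within 15 px;
   leave-image-out cross-validated scores; precision
   P = TP/(TP+FP) and recall R = TP/(TP+FN) at every score threshold; the
   operating threshold is the largest one whose recall meets a chosen
   floor.
4. **Quantify** — optional file-based user corrections, marker (EdU/TUNEL)
   positivity per nucleus (≥ 25% of nucleus pixels above the Otsu
   threshold of the corrected marker channel), and per-image plus pooled
   counts with the four derived percentages.
5. **Agreement** — radius-matched multi-rater selections, Fleiss kappa
   κ = (P̄ − P̄ₑ)/(1 − P̄ₑ) with the Fleiss–Nee–Landis standard error,
   interpretation bands, and the two-sample z-test
   z = (κ₁ − κ₂)/√(se₁² + se₂²).

A seeded synthetic scene generator with known ground truth
(`scene_spec()`, `generate_scene()`, `generate_dataset()`) makes the whole
pipeline testable without any image downloads.

## Worked example

```r
library(nucquant)

# a synthetic 512x512 tissue scene: 150 nuclei, 30% "myocyte-like" targets
scene <- generate_scene(scene_spec(seed = 5))
res <- process_image(scene$stack)   # correct + segment + featurize
length(res$nuclei)
#> [1] 149

# label segmented nuclei from the known target centers, as an annotator would
dots <- scene$truth[scene$truth$is_target, c("row", "col")]
labels <- match_annotations(res$nuclei, dots, radius = 15)
table(labels$label)
#>
#> non_target     target
#>        105         44

# agreement among four simulated annotators of a 2-image dataset
ds <- generate_dataset(scene_spec(), n_images = 2, base_seed = 13,
                       n_raters = 4, hit_rate = 0.9, fp_rate = 0.05)
nd <- data.frame(nucleus_id = seq_len(nrow(ds$truth)),
                 image_id = ds$truth$image_id,
                 row = ds$truth$row, col = ds$truth$col, area = 10L)
fleiss_kappa(build_rater_matrix(nd, ds$rater_dots))
#> Fleiss kappa 0.672 (se 0.0236), 300 items, 4 raters: substantial agreement
```

`length(res$nuclei)` is the number of segmented candidate nuclei (149 of
the 150 planted; two touching nuclei merged). The label table shows 44 of
the 45 planted targets matched by an annotation dot within 15 px. The
kappa line reads: 4 raters over 300 nuclei agree at κ = 0.672, i.e.
"substantial" on the standard interpretation bands.

A thin command-line interface over the same functions is installed at
`inst/cli/nucquant` (subcommands `simulate`, `segment`, `featurize`,
`train`, `evaluate`, `predict`, `quantify`, `agree`, `agree-compare`).

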