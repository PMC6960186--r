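# fwrnet — fuzzy weighted recurrence networks of multi-channel images

`fwrnet` turns a multi-channel raster image into a weighted graph whose
statistics quantify spatial texture, and applies that machinery to
immunohistochemistry (IHC) slide analysis: tiling whole-slide images,
scoring each tile, and relating per-patient tumor-to-biopsy metric
ratios to survival in a screening cohort. It is aimed at computational
pathology and image-analysis researchers who want an objective,
reproducible texture readout of stained tissue — the packaged cohort
application concerns DNp73 staining in rectal-cancer patients treated
with preoperative radiotherapy, but the construction is generic.

## The method in brief

For an $M \times N \times K$ image, every $(2m+1)\times(2m+1)$ window
that fits inside the image is collapsed, per channel, to its Frobenius
norm, giving $L$ feature vectors $\mathbf{y}_{ij} \in \mathbb{R}^K$.
Fuzzy c-means partitions these into $c$ clusters with memberships
$u_{nj}$ (weighting exponent $\alpha$), and the max–min relation

$$\tilde{R}_{ab} = \max_i \, \min(u_{ai}, u_{bi}), \qquad
  \mathbf{W} = \tilde{R} - \mathbf{I}$$

defines the fuzzy weighted recurrence network: nodes are image windows,
edge weights are the strength of their strongest shared cluster. Two
statistics summarize each network — the average weighted clustering
coefficient (geometric-mean triangle form)

$$CC = \frac{1}{L}\sum_i \frac{\sum_{j,k}(w_{ij}w_{ik}w_{jk})^{1/3}}{k_i(k_i-1)}$$

and the characteristic path length
$CP = \sum_{i\neq j} d_{ij} / (L(L-1))$, with $d_{ij}$ the Dijkstra
shortest path over edge lengths $1/w$. For the cohort analysis, per-tile
$CC$ and $CP$ are averaged per specimen and expressed as the per-patient
ratios $CC(\mathrm{tumor})/CC(\mathrm{biopsy})$ and
$CP(\mathrm{tumor})/CP(\mathrm{biopsy})$, which are then correlated with
survival within survival subgroups and evaluated as band-based
predictive rules.

See `vignettes/fwrn-methods.Rmd` for the full account of the model,
parameter meanings, design decisions and limitations.

## Worked example

Generate a synthetic IHC-like tile, build its network and score it:

```r
library(fwrnet)

img <- generate_ihc_image(stain_params(image_size = 64, dab_fraction = 0.3,
                                       blob_scale = 8, seed = 7))
cfg <- fwrn_config(tile_size = 64, c = 8, node_stride = 4, seed = 7)
image_metrics(img, cfg, image_id = "demo")
#>   image_id tile_id n_nodes        CC       CP tau  transform
#> 1     demo       1     225 0.1828064 9.193559   0 reciprocal
```

The tile yields a 225-node network (the 58×58 valid window centers
thinned by stride 4). `CC` ≈ 0.18 says that, on average, triangles
around a node carry about 18% of their maximal weight; `CP` ≈ 9.2 is the
mean number of reciprocal-weight steps between nodes. Coarser stain
blobs push both up; fine speckle pushes both down.

The packaged 25-patient screening cohort and the survival analysis:

```r
cohort <- load_cohort_table()
table(cohort$group)
#> shorter  longer
#>      11      14

# predictive band rule at the published counts: 11 of the 15 patients
# with CC ratio in [0.97, 1.05] survived 101-288 months
ratios <- data.frame(patient_id = cohort$patient_id, cc_ratio = 2)
long_idx  <- which(cohort$survival_months >= 101)
short_idx <- which(cohort$survival_months <= 75)
ratios$cc_ratio[c(long_idx[1:11], short_idx[1:4])] <- 1
survival_range_probability(ratios, cohort, "cc_ratio", c(0.97, 1.05), c(101, 288))
#> $k
#> [1] 11
#> $n
#> [1] 15
#> $probability
#> [1] 0.7333333
```

`subgroup_association()` reports the within-group Pearson correlation
together with the two-sided sign-test probability $2(1/2)^n$
($9.7656\times10^{-4}$ at $n = 11$, $1.2207\times10^{-4}$ at $n = 14$).

A command-line wrapper ships in `inst/cli/fwrn.R` with subcommands
`metrics`, `cohort`, `make-fixtures` and `validate-config`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fwrn.R", package = "fwrnet"))')
Rscript "$CLI" make-fixtures --out-dir fixtures --n-patients 6 --seed 1
Rscript "$CLI" metrics --out metrics.csv fixtures/*.png
```

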