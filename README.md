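# sbpquant

Automated morphometry of the corneal **subbasal nerve plexus (SBP)** from
pre-segmented in vivo confocal laser-scanning microscopy (CLSM) images, for
researchers studying corneal innervation as a non-invasive marker of
diabetic peripheral neuropathy.

The input is a binary nerve mask (nerve pixels traced as foreground,
typically 384 × 384 px over a 400 × 400 µm field). The package quantifies it
in two stages:

1. **Before skeletonisation** — connected-component morphology: nerve pixel
   count, percentual coverage of the field, number of fibre networks, and a
   homogeneity measure (population variance of per-tile coverage
   fractions).
2. **After skeletonisation** — the mask is reduced to its one-pixel-wide,
   topology-preserving medial axis (iterative two-subcycle thinning with an
   explicit topology audit), which is then converted into a graph of typed
   nodes and weighted paths: **branch points** (clustered junction pixels),
   **nerve endings** (interior terminals), **connectivity points**
   (terminals in the 1-px border band, i.e. fibres entering or leaving the
   field), and **single nerve fibres** (segments between nodes). Segment
   lengths use the chain code — 1 per orthogonal step, √2 per diagonal
   step, times the pixel pitch — and yield total/average fibre length and
   **nerve fibre density** (µm of fibre per µm² of image area; ×10⁶ this
   reads as the conventional "mm/mm²").

Counts and lengths can be normalised to 1 mm² (×6.25 for the default
0.16 mm² field). A phantom generator produces synthetic fibre networks with
exact ground-truth topology and analytic lengths for validation, and a
statistics module provides cohort comparison: Kolmogorov–Smirnov-screened
dispatch between Welch's t-test and the Mann–Whitney test, Welch tests from
printed group summaries, and stepwise linear discriminant analysis driven
by Wilks' Λ.

## Worked example

```r
library(sbpquant)

# a synthetic healthy-looking plexus with known ground truth
ph <- generate_phantom(preset("healthy", seed = 42))
compute_metrics(ph$image)
#> <sbp_metrics> (per image)
#>   component_pixels             9335
#>   component_ratio_pct          6.3307
#>   n_components                 7
#>   homogeneity                  0.00294429
#>   skeleton_pixels              2495
#>   single_nerve_fibres          15
#>   fibres_per_component         2.14286
#>   total_fibre_length_um        2868.11
#>   avg_single_fibre_length_um   191.207
#>   fibre_density_um_per_um2     0.0179257
#>   n_branches                   4
#>   n_connectivity_points        11
#>   n_endpoints                  7
ph$truth
#> $true_total_length_um    2725.04
#> $true_n_fibres           15
#> $true_n_branches         4
#> $true_n_endpoints        7
#> $true_n_border_crossings 11
```

The measured topology (15 segments, 4 branch points, 7 endings, 11 border
crossings) matches the generator's ground truth exactly; the measured
length overshoots the analytic curve length by ~5% here, the expected
chain-code digitisation bias. The density 0.0179 µm/µm² is in the healthy
range (≈ 0.02 "mm/mm²").

Group statistics from published summary values:

```r
welch_from_summary(19961.3, 6552.9, 20, 6223.1, 2419.2, 18,
                   "total_fibre_length")
#> total_fibre_length: t_welch, statistic = 8.738, df = 24.56, p = 5.268e-09

summ <- list(control  = list(component_ratio = c(5.7, 2.1),
                             fibre_density   = c(0.02, 0.007)),
             diabetic = list(component_ratio = c(2.4, 0.9),
                             fibre_density   = c(0.006, 0.002)))
cohort <- simulate_cohort(summ, c(control = 20, diabetic = 18), seed = 1)
stepwise_lda(cohort[-1], cohort$group)
#> Stepwise Wilks'-lambda discriminant analysis
#>   selected: fibre_density, component_ratio
#>   Wilks' lambda = 0.1791, p = 5.201e-15
#>   overall accuracy = 97.4%
```

## Command line

A thin wrapper over the same functions is installed at `exec/sbpquant`:

```sh
sbpquant simulate --out phantoms --n 10 --preset healthy --seed 1
sbpquant quantify --out metrics.csv phantoms
sbpquant compare  --metrics cohort.csv --out report.json
```

Flags: `--pitch-um`, `--threshold`, `--invert`, `--tiles`,
`--min-segment-um`, `--normalize`, `--seed`, `--out`, `--log-level`.

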