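---
title: "Quantifying subbasal nerve plexus morphology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subbasal nerve plexus morphology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpquant)
```

## The measurement problem

The corneal subbasal nerve plexus (SBP) is a dense mesh of thin unmyelinated
nerve fibres between the basal epithelium and Bowman's membrane. In vivo
confocal laser-scanning microscopy images it non-invasively, and its
rarefaction — lower fibre density, fewer branches, fewer fibres crossing the
field — tracks diabetic peripheral neuropathy. `sbpquant` takes a
*pre-segmented* binary mask (nerve pixels already traced as foreground) and
turns it into a reproducible parameter vector; it deliberately does **not**
attempt segmentation, image enhancement, or volume-stack handling.

All geometry uses the raster convention: row-major, origin top-left,
0-based pixel grid in the file formats, 1-based matrices inside R; a pixel
is a unit square. Pixel pitch defaults to 400/384 ≈ 1.0417 µm/px (the
HRT II / Rostock Cornea Module field); a JSON sidecar
`{"pixel_pitch_um": ...}` next to an image overrides it. The field is
assumed square (400 × 400 µm at the default size); the resulting image area
0.16 mm² is the only area figure consistent with the normalised group
statistics this package is designed to reproduce.

## Stage 1: morphology before skeletonisation

* **Component pixels** — foreground count.
* **Component ratio** — 100 × foreground / total pixels (%).
* **Connected components** — maximal 8-connected foreground sets,
  interpreted as individual fibre networks. Foreground connectivity is 8,
  background 4 (the Jordan-consistent pairing for thin curvilinear
  structures). Labels are assigned in order of first raster appearance, so
  labeling is deterministic.
* **Homogeneity** — the field is divided into `tiles_per_axis²` near-equal
  tiles (default 8 per axis; the last tile absorbs any remainder) and the
  *population variance of per-tile coverage fractions* is returned. Zero
  means perfectly uniform coverage (both the empty and the full mask give
  0); concentrating a fixed pixel budget into fewer tiles strictly
  increases it. No formula for this uniformity measure is given in the
  literature the package follows; variance-of-coverage was chosen as the
  simplest statistic with the documented qualitative behaviour (sparser,
  patchier diabetic plexuses score higher). Absolute homogeneity values are
  therefore implementation-specific and should only be compared within one
  tool.

## Stage 2: skeleton and graph

### Thinning

The mask is reduced to its medial axis by iterative two-subcycle boundary
thinning (Zhang–Suen-style candidate conditions) with three safeguards
that experience with fibre phantoms showed to be necessary:

1. **Topology audit.** Parallel deletion of a candidate batch almost always
   preserves topology, but the classic failure patterns (isolated 2×2
   blocks, two-pixel-wide diagonal ribbons) do occur in real masks. After
   every batch the number of 8-connected foreground components and
   4-connected background components is recounted; on any change the batch
   is rolled back and replayed pixel-by-pixel, deleting a pixel only if it
   is exactly 8-simple — Yokoi connectivity number 1, a criterion verified
   exhaustively against the component-counting definition on all 256
   neighbourhood configurations — and still satisfies the subcycle
   conditions. Skeletonisation is therefore *strictly* topology-preserving.
2. **Tip protection.** A pixel with exactly two mutually adjacent
   neighbours is either a removable elbow or the tip of a staircase line —
   the two are locally indistinguishable, and deleting tips lets oblique
   line ends recede indefinitely (tens of micrometres of fibre can vanish).
   Such pixels are deletable only during the first two iterations, where
   they are needed to resolve stroke-width thickness.
3. **Border-stub reconstruction.** Thinning erodes the free end of a stroke
   by a few pixels, so the terminal of a fibre crossing the image border
   would come to rest just inside the 1-px border band and be misread as a
   nerve ending. Near-border endpoints are therefore extended outward
   through *original mask foreground only*, stepping along the fibre's own
   tangent direction, and accepted only if a border side the tangent points
   toward is reached. Fibres running parallel to the border are untouched,
   and on an already-thin input the first outward step lands on background,
   which keeps skeletonisation idempotent.

A final cleanup removes redundant staircase pixels (simple pixels with ≥3
neighbours; elbows whose both neighbours continue; one deterministic pixel
of a terminal three-pixel triangle), so paths are minimal and junction
classification is unambiguous. Degenerate blobs are well-defined rather
than errors: a digital disk of any tested radius thins to a single pixel, a
3-px-wide bar to the single line along its middle row.

### Graph extraction

Skeleton pixels are classified by 8-neighbour count: 1 → end, 2 → path,
≥3 → junction; terminals in the outermost 1-px frame are **connectivity
points** (truncated fibres), all other terminals are **endpoints** (true
nerve endings). Maximal 8-connected junction-pixel sets collapse into one
**branch** node — raw junction-pixel counts would double-count thick
junctions. Edges are traced along path pixels; their length is the chain
code (orthogonal step 1, diagonal step √2) times the pixel pitch.

Three cleanup rules operate at graph level, all with physical units:

* **Spur pruning** (`min_segment_um`, default 2 µm ≈ 2 px): edges shorter
  than this that end in a free terminal are thinning artefacts and are
  removed, after which node types are recomputed. Isolated single pixels
  carry no measurable length and are dropped.
* **Junction merging** (`junction_merge_um`, default 10 µm): branch nodes
  joined by an internal edge shorter than this are one anatomical branch
  point. A Y-junction of 3-px strokes meeting at a shallow angle thins into
  3-valent pixels up to ~10 µm apart; without merging, branch counts
  double-count such junctions. The trade-off is that genuinely distinct
  branch points closer than 10 µm (rare at this magnification) would merge.
* **Micro-cycles**: a thinned junction can leave a pixel triangle; self-loop
  edges on a branch node shorter than `junction_merge_um` are absorbed into
  the node. Anatomical fibre loops are orders of magnitude longer.

Closed loops with no node at all are represented by an anchor node carrying
a self-loop edge so total length is conserved; the anchor counts as neither
branch, endpoint nor connectivity point. The handshake identity
(Σ degrees = 2·edges, self-loops twice) and skeleton-pixel conservation
(every skeleton pixel belongs to exactly one node cluster or edge path)
hold by construction and are enforced by tests.

### The metric vector and normalisation

`compute_metrics()` assembles both stages. Fibre density is stored as µm of
fibre per µm² of image area; multiplied by 10⁶ it reads in the conventional
"mm/mm²" — under this convention (and only under it) published normalised
total lengths and printed densities agree, e.g. 19961 µm/mm² ÷ 10⁶ ≈ 0.02.
Average single-fibre length is the mean over traced segments of the image,
not total length divided by area-level counts; the two differ whenever
segment counts vary between images. `normalize_metrics()` divides the
extensive quantities (pixel counts, fibre counts, summed lengths, node
counts) by the image area in mm²; intensive quantities (ratio, homogeneity,
density, averages, fibres-per-component) are unchanged, and a flag guards
against double normalisation. Empty images produce zero counts and, by
convention, zero averages (with a message) so that batch runs never fail on
a blank field.

## The phantom generator

Real SBP images from the underlying study are not available, so validation
rests on synthetic phantoms with *exact* ground truth: fibres are smooth
parametric curves — a chord across the field plus a sinusoidal lateral
displacement that vanishes at the ends — drawn around a dominant direction
(SBP fibres run roughly parallel), optionally carrying one branch event
that spawns a shorter child curve at 25–55°. Truth records the analytic
arc lengths (integrated from the curves before rasterisation) and the
exact numbers of segments, branch events, interior endings and border
crossings.

Exactness imposes configuration constraints, all enforced by rejection
sampling: fibre trees keep a 2-px clearance from each other, children may
not run back into their parent away from the branch point, interior endings
keep a 6-px margin from the border, and border crossings meet the border at
≥20° — a grazing crossing and an ending *next to* the border are genuinely
indistinguishable at raster scale, for any implementation. A stress-test
mode (`allow_intersections = TRUE`) lifts the clearance constraints, with
the caveat that crossings then create branch-like nodes the truth does not
count.

Default parameters were chosen for realism at the default field: stroke
width 3 px (≈3 µm fibre diameter), tortuosity amplitude 8 µm, per-fibre
orientation jitter 8°. The presets target the two study populations:
`preset("healthy")` (7 fibres, branch probability 0.6) measures ≈0.017
µm/µm² density, `preset("neuropathic")` (2 fibres, branch probability 0.2)
≈0.005, inside the published mean ± SD bands of the respective groups. The
phantoms emulate geometry and topology only — no speckle, depth blur,
contrast falloff, or segmentation noise — so passing phantom tests
validates the *measurement* pipeline, not robustness to imperfect
segmentation.

Validation problem sizes: the packaged test suite runs the full pipeline on
100 phantoms of 192 px / 4 fibres for ground-truth recovery and 200
phantoms of 96 px / 3 fibres for idempotence and component preservation;
the presets were validated at the full 384-px field over 20 seeds each.

### Known limitation: chain-code length bias

The √2 chain code systematically *over*-estimates the length of smooth
oblique curves: a straight line at 22.5° measures 8.2% long, and averaged
over orientations the bias is ≈+5%. Junction merging and residual end
effects partially offset it; across the validation phantoms the measured
total length sits at +4% of truth on average, with phantoms whose dominant
orientation falls near 22.5° (mod 45°) reaching +7%. Topological counts
are unaffected — they match ground truth exactly on all validation
phantoms — but a per-phantom 5% length-recovery bound cannot hold for every
orientation under this estimator; comparisons between images measured with
the same estimator are unaffected by the shared bias.

## Statistics module

* `describe()`: mean and sample SD (n−1).
* `dispatch_test()`: each group is screened for normality with a
  Lilliefors-type Kolmogorov–Smirnov test (estimated moments; the plain KS
  test against fixed parameters would be anti-conservative). Both groups
  passing at α = 0.05 dispatches to Welch's t-test, anything else — including
  groups too small to screen (n < 5) — to the two-sided Mann–Whitney test
  (exact enumeration for both n ≤ 8 without ties, tie-corrected normal
  approximation otherwise). Identical constant groups short-circuit to
  p = 1 with a note. The test actually used is always recorded in the
  result.
* `welch_from_summary()`: the Welch statistic and Welch–Satterthwaite df
  from group means/SDs/sizes, so published summary tables can be re-tested
  without raw data.
* `stepwise_lda()`: forward selection minimising Wilks' Λ with partial-F
  entry/removal tests (classical thresholds p-enter 0.05, p-remove 0.10;
  the procedure's single-variable Λ reduces to SS-within / SS-total, which
  the tests verify). The final discriminant uses equal priors — the design
  is near-balanced (20/18) and equal priors keep the rule symmetric —
  and reports *resubstitution* accuracy to mirror how the published
  "36 of 38 correctly classified" figure is stated; a leave-one-out option
  (`loo = TRUE`) is available but not the default. Variables without
  within-group variance would make the pooled covariance singular and are
  excluded up front (the SPSS tolerance rule).
* `simulate_cohort()`: independent normal draws per variable from published
  moments, truncated at zero by redrawing (metric variables are
  non-negative); seeded and reproducible.

Simulated cohorts treat the variables as independent within groups because
published tables carry no covariance information. For the two headline
variables the within-group correlation mainly affects the *variance* of the
achievable accuracy, not its mean, which is why the 200-replicate mean is
the quantity compared against the published figure.

## Degenerate inputs and numerical conventions

Empty masks flow through the whole pipeline producing zeros. Full masks
thin to a small central cluster. Images smaller than 3 × 3 px are rejected.
Calibration sidecars are validated against the pixel grid to 0.5%.
Ties in node/edge ordering are always broken in raster order, making every
stage deterministic; phantom generation and cohort simulation are
deterministic in their seeds and restore the caller's RNG state. Floating
tolerances: the density identity (density × area = total length) holds to
10⁻⁶ relative; graph counts and lengths are invariant under 90° rotation of
a skeleton to 10⁻⁹.

## What is out of scope

Image acquisition and segmentation, esthesiometry, retinopathy grading and
clinical scores are consumed only as numbers where relevant. Fibre
tortuosity coefficients and fibre width estimation are not part of the
metric set. Reproducing the absolute per-group image metrics of the
underlying study is impossible without its images; the package instead
reproduces everything that is arithmetic on published values, and validates
the image pipeline on phantoms with known truth.
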