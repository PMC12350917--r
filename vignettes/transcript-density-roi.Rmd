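---
title: "Sub-regional transcript-density differential expression for imaging spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-regional transcript-density differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatroi)
```

## The problem

Imaging-based spatial transcriptomics assays decode individual mRNA
molecules as points in tissue coordinates (gene symbol, x/y in µm, a
decoding quality score), while high-resolution barcoded-capture assays
report counts on a 2×2 µm bin grid. For developmental questions — here,
the growth of the embryonic palatal shelves and its failure in cleft
palate — the biologically meaningful comparison is often *sub-regional*:
the oral and nasal halves of each palatal shelf follow different
transcriptional programs, and genotype or stage effects can be confined
to one of them. `spatroi` implements a reproducible version of that
analysis:

1. **Nuclei-anchored binning** of 2 µm bin counts into a cell-by-gene
   matrix using a segmented-nuclei label mask, with size/UMI filtering
   of badly segmented nuclei and removal of mitochondrial genes.
2. **Domain partition**: each shelf is split into oral (OP) and nasal
   (NP) domains along an oronasal axis derived from the spatial
   co-expression of two markers — *Shh*, restricted to the oral
   epithelium, and its target *Ptch1* in the adjacent mesenchyme.
3. **Area-standardized ROIs**: a fixed number of regions of interest of
   standardized surface area (6400 µm² ± 100 µm²), three per domain per
   shelf — twelve per section.
4. **Transcript-density DGE**: per-gene two-group comparison of ROI
   transcript densities (counts per µm²) with a variance-gated
   Student/Welch t-test, Benjamini–Hochberg adjustment, and volcano
   classification.

A seeded synthetic-section simulator with known ground truth makes every
stage testable without access to instrument data.

## The statistical procedure

For gene $g$ with ROI densities $x_{1..n_A}$ (group A) and
$y_{1..n_B}$ (group B):

* **Fold change** is computed on *raw* mean densities,
  $\mathrm{LFC}_g = \log_2\!\frac{\bar y + \varepsilon}{\bar x + \varepsilon}$,
  with a symmetric pseudocount $\varepsilon$ (default $1/6400$ µm⁻²,
  one transcript per default-sized ROI). Positive values mean
  enrichment in group B. The pseudocount matters: genes expressed in
  only one group otherwise have undefined or infinite ratios, and the
  very large fold changes such genes produce are a real feature of
  sparse in situ panels.
* **p-values** come from densities transformed as $\log_2(x + 1)$ to
  stabilize variance. A two-tailed F test of the variance ratio (larger
  sample variance in the numerator — the spreadsheet `F.TEST`
  convention) gates the branch at $\alpha_F = 0.05$: unequal variances
  go to Welch's t-test with Welch–Satterthwaite degrees of freedom,
  equal variances to the pooled Student t-test.
* **Multiplicity**: Benjamini–Hochberg step-up adjustment across all
  genes tested in the contrast. Note that the step-up adjustment is not
  idempotent — re-adjusting adjusted values inflates interior order
  statistics again — so adjusted values must be computed from raw
  p-values exactly once.
* **Classification**: `up` if $p < 0.05$ and $\mathrm{LFC} > 1$,
  `down` if $p < 0.05$ and $\mathrm{LFC} < -1$, else `ns`. The absolute
  fold-change rule is used so that downregulated genes are reportable.
  By default the *adjusted* p-value is classified on
  (`use_adjusted_p_for_class = TRUE`); the choice is stamped into every
  output, and raw-p classification is one switch away, since volcano
  plots in the field are frequently drawn on raw p-values.
* **Degenerate genes** (zero variance in both groups, e.g. a gene with
  no transcripts in any ROI of either group) get $p = 1$, are flagged,
  and are never classified up or down.

`over_representation()` adds a generic one-sided hypergeometric
over-representation test for user-supplied gene sets; a set is reported
significant when $p < 0.05$ *and* more than one hit gene overlaps it,
so single-gene overlaps never drive an enrichment call.

## The synthetic section generator

`generate_section_geometry()` builds a coronal-section cartoon in image
coordinates (µm; x rightward, y downward, so "oral" faces +y): two
superellipse shelves (`PL`, `PR`) with per-seed jitter in size, position
and rotation (±8°). Along each shelf's oral boundary runs a thin
epithelial strip (the *Shh* compartment, the outermost ~15% of the
superellipse level sets) and, just inside it, a subepithelial mesenchyme
band (the *Ptch1* compartment). The strip and band extend a little past
the shelf equator (`oral_cut_frac = -0.35`), as the oral epithelium
wraps the medial and lateral faces of the shelf in a real coronal
section; geometrically this places the centroid of the curved marker
band near mid-shelf, which is what makes the co-expression-anchored
axis sit deep enough in the tissue to leave room for oral-side ROIs.

Four regions drive expression: `epithelium`, `subepithelial`, `oral`
and `nasal`, the latter two defined by the side of the ground-truth
oronasal axis. The gene model gives each gene a base intensity
(transcripts per µm²), per-region multipliers, an optional log2
condition effect applied under condition `"B"`, and a mitochondrial
flag. Transcripts are drawn as an inhomogeneous Poisson point process —
expected count = intensity × multiplier × $2^{\mathrm{LFC}\cdot[B]}$ ×
region area — with uniform positions within regions and uniform quality
scores in [20, 40] (a configurable 5% low-quality fraction in [5, 20)
exercises the quality filter).

**The truth axis is defined by the marker model itself.** The generator
evaluates the same estimator the pipeline uses — the product of the two
markers' Gaussian kernel density estimates, anchor at the
co-expression-weighted centroid, direction along the first principal
axis of the top-decile support — on a *noise-free* deterministic grid of
pseudo-points filling the strip and band. The fitted axis therefore
converges to the truth axis as transcript counts grow, and the
recovery tests measure exactly the sampling noise of the estimator
(observed: direction within ~2°, anchor within ~10 µm, >99% domain
agreement at default intensities).

The bin-grid simulator (`simulate_visium_hd()`) places nuclei as
non-overlapping disks (radius 3.5–7 µm) inside the tissue, rasterizes
them into a 16-bit label mask (1 µm pixels), and draws per-nucleus
expression with expected counts proportional to the rasterized nucleus
area. Each nuclear transcript is placed in one of the nucleus's
*interior bins* — bins whose center pixel carries the nucleus label —
so that center-containment binning recovers the per-nucleus ground
truth exactly; the default 30% extra-nuclear fraction goes to tissue
bins whose center pixel is background, exercising the unassigned-bin
path without perturbing the recovery identity.

**What the simulator does not emulate**, and hence what green tests do
not establish about real data: realistic tissue morphology and
segmentation errors (nuclei are disks; masks are perfect), optical
crowding and segmentation-dependent transcript misassignment,
overdispersion beyond Poisson (real section-to-section variability is
usually super-Poissonian, which would widen the t-test's operating
characteristics), spatial correlation of expression within domains, and
probe-specific decoding bias in the quality scores.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `target_area` | 6400 | µm² | standardized ROI surface area |
| `area_tolerance` | 100 | µm² | allowed deviation from target |
| `n_per_domain_side` | 3 | – | ROIs per shelf × domain (12/section) |
| `min_qv` | 20 | – | decoded-transcript quality cutoff (standard practice for this assay class) |
| `f_alpha` | 0.05 | – | variance-gate level choosing Student vs Welch |
| `p_threshold`, `lfc_threshold` | 0.05, 1 | – | volcano significance thresholds |
| `pseudocount` | 1/6400 | µm⁻² | one transcript per default ROI |
| `bandwidth` | 20 | µm | marker KDE kernel sd; ~strip thickness, ≪ shelf size |
| `step` | 5 | µm | KDE grid spacing; ≤ bandwidth/4 |
| `min_area`, `max_area` | 16, 800 | µm² | nucleus size filter (≈2.3–16 µm radius-equivalent) |
| `min_umi` | 10 | – | minimum per-nucleus UMI total |
| `mt_prefix` | `"mt-"` | – | case-insensitive mitochondrial symbol prefix |

The nucleus filter thresholds and the quality cutoff are declared
defaults, not values inferred from data; all are exposed in
configuration objects and recorded in the run manifest.

## Numerical and design choices

* **Bin→nucleus rule**: bin-center containment with nearest-pixel mask
  lookup. It is unambiguous and integer-preserving (every UMI is
  counted exactly once), unlike area-overlap apportionment. Rasterized
  boundaries make assigned-bin counts differ from ideal disk geometry
  by at most a bin or two.
* **ROI shape**: axis-aligned 80 µm squares (area exactly 6400 µm²) by
  default; a 64-gon "circle" scaled to the exact target area is
  available. Placement is a seeded greedy search over a jittered
  candidate lattice ranked by local transcript count, so runs prefer
  transcript-dense tissue and are byte-reproducible; counting a
  transcript on an ROI boundary is inclusive.
* **Oral-side disambiguation**: the half-plane holding the majority of
  the shelf's *Shh* transcripts relative to the fitted axis is oral
  (`marker_oral_reference()`). A single KDE mode is not reliable when
  the epithelium wraps the shelf margin — the mode can land on a strip
  arm that crosses to the nasal side and invert every label. Points
  exactly on the axis are labelled `OP`.
* **Variance gate**: implemented from the F-distribution directly
  (larger variance in the numerator, two-tailed, capped at 1), matching
  the spreadsheet convention of the original manual workflow; the
  t-tests themselves are delegated to `stats::t.test` and are verified
  against closed-form oracles to 1e-10 in the test suite.
* **Degenerate inputs**: zero-area frames, empty marker fields,
  infeasible ROI packings, overlapping nuclei and mismatched
  grid/mask frames all fail fast with messages naming the offending
  quantity.

## Problem sizes used in the validation suite

The test-suite and `scripts/acceptance.R` run at sizes chosen to make
the statistical checks sharp while keeping a full run in the order of a
minute or two: sections of 1600×900 µm with ~190k transcripts over a
26-gene panel; 200 replicate simulations for the Poisson-law check;
2000 null genes at 6 ROIs per group for type-I calibration (raw
p < 0.05 fraction must fall in [0.03, 0.07]); 5 effect genes at true
LFC 3 with ≥50 expected transcripts per ROI for recovery (all must
classify `up`, with ≤2 of 20 null genes significant and fold-change
error below 0.5); and 1000 random problems per statistical engine
against independent brute-force oracles.

## Limitations

* The OP/NP boundary of the original manual workflow was drawn in a
  GUI; this package substitutes a declared, deterministic algorithm.
  Agreement with any particular hand-drawn session cannot be verified
  without those session files.
* ROIs are placed greedily by transcript density, which mimics how an
  annotator picks informative fields but is not an unbiased spatial
  sample; density comparisons between groups remain valid because both
  groups are placed by the same seeded rule.
* With three ROIs per domain, per-domain contrasts have n = 3 per
  section per group; the t-test is exact under normality of the
  transformed densities and only approximate otherwise. Pooling
  sections (the pipeline's default) is advisable.
* The ROI area tolerance is treated as ±100 µm² (the area unit); the
  procedure that inspired it printed the tolerance with a length unit,
  which we take to be a typographical slip.
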