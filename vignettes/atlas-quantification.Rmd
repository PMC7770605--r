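---
title: "Atlas-based cell quantification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based cell quantification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasquant)
```

## The quantification model

`atlasquant` estimates regional cell numbers and densities from 2D profile
counts. The inputs per section are a binary segmentation mask (foreground =
labeled cell material) and a pixel-aligned atlas label map whose values are
leaf identifiers of a region ontology. The chain is:

1. **Extraction.** Maximal connected foreground components under 4- or
   8-connectivity; components below a minimum pixel size are dropped.
2. **Assignment.** Each object is attributed to exactly one region — the
   atlas label covering the most of its pixels. Objects are never split
   across regions, so no object is counted twice at region borders.
3. **Exclusion.** Objects flagged by a manual review (clutter such as
   clustered neuropil that segments like a cell) are retained in the
   object table but removed from every count.
4. **Correction and extrapolation.** With raw profiles $n$ summed over the
   sampled sections, section thickness $T$, mean cell diameter $D$ and
   sampling interval $k$ (every $k$-th section analyzed):
   $$N = \mathrm{round}_{1/2\uparrow}\!\left(k \cdot n \cdot \frac{T}{T+D}\right),
     \qquad \rho = N / V .$$
   $T/(T+D)$ is Abercrombie's correction: a convex particle of extent $D$
   along the cutting axis intersects on average $(T+D)/T$ consecutive
   slabs of thickness $T$, so raw profile counts overcount by that factor.
   $V$ is the region volume taken from the 3D reference atlas — not from
   section areas, which are strongly affected by histological shrinkage.

### Model assumptions

* Cells are convex with a single mean diameter $D$ per marker and
  preparation; $D$ enters only through $T/(T+D)$.
* Cell centers are positioned independently of slab boundaries (uniform
  along the cutting axis), making the correction unbiased in expectation.
* Two biases inherent to profile counting are deliberately **not**
  corrected: lost caps (thin cell fragments at section faces that escape
  detection) and z-occlusion (deep cells hidden under superficial ones in
  thick sections). Neither can be estimated from section images alone, so
  the package does not pretend to; totals should be read with this in
  mind.

## Parameters

| parameter | meaning | unit | default | notes |
|---|---|---|---|---|
| `thickness` ($T$) | section thickness | µm | 40 | from sectioning protocol |
| `diameter` ($D$) | mean cell diameter | µm | 15 | per marker; shrinkage-affected |
| `interval` ($k$) | sampling interval | – | 6 | totals multiplied by $k$ |
| `connectivity` | pixel adjacency | – | 8 | 8 merges diagonal chains |
| `min_size` | smallest object | px | 4 | suppresses single-pixel noise |
| `minGap` (generator) | planting clearance | px | 2 | makes ground truth unambiguous |

$T = 40$, $D = 15$, $k = 6$ are the worked-example values used throughout
the documentation and the reference checks: $k\,T/(T+D) = 6 \cdot 40/55 =
4.3636$, the unique factor consistent with both published entorhinal
worked totals (3,400 → 14,836 and 3,560 → 15,535). All three are plain
arguments of `quantParams()`.

Extraction defaults (`connectivity = 8`, `min_size = 4`) are declared
package choices: published workflow descriptions rarely print these
settings, so both are exposed and recorded in the run manifest.

## Order of operations and rounding

Raw profiles are summed across sections **first**, then corrected, then
multiplied by $k$, then rounded. This order reproduces both published
worked totals exactly and accumulates no per-section rounding error.
Rounding is half-up (away from zero) everywhere a number is displayed or
an integer total is formed; base R's round-half-to-even would make totals
depend on parity. `total = round(k · n_corrected)` and
`density = total / V` hold exactly before display formatting (reports
print densities and percentages with two decimals).

Other numerical conventions, fixed so that results are bit-reproducible:

* **Tie-breaks.** An object overlapping two regions equally goes to the
  lower region id; hemisphere ties likewise. Label 0 (outside the atlas)
  can never outvote a real region — such pixels win only when the object
  overlaps no region at all, and the object is then reported as
  *unassigned*, never added to a region.
* **Coordinates.** Label matrices are indexed `[row, col]`, origin
  top-left, 1-based as is idiomatic in R; object ids follow the row-major
  first-pixel scan order. Flat-file serialization is row-major unsigned
  32-bit little-endian, so files are portable across implementations
  regardless of the in-memory convention.
* **Slab boundaries.** In the sectioning simulator a zero-diameter cell
  whose center falls exactly on a slab boundary belongs to the lower
  slab; this makes the $D = 0$ identity (one profile per cell) exact
  rather than almost-sure.
* **Constant gradients.** Spearman's $\rho$ is undefined for a constant
  density profile; `gradientProfile()` defines it as 0 ("none"), which is
  the only classification consistent with the thresholds.
* **Scope.** Ontology volumes are bilateral. Unilateral estimates use
  $V/2$; `bilateralMerge()` adds counts and recomputes density from the
  full volume.
* **Oversaturation.** A region flagged as oversaturated (staining too
  dense to count, e.g. Purkinje layers) is reported with numbers blanked,
  status `"not reported (oversaturated)"`. The flag propagates downward:
  a flagged parent suppresses its leaves, and a custom group is
  suppressed when any member leaf is affected — a group total that
  silently omitted a saturated member would be misleading.

## The synthetic generator

`generateAtlasSeries()` + `plantCells()` build series where the truth is
known exactly: label maps partition pixels among leaves (vertical bands or
per-section Voronoi tessellations), and cells are ideal filled discs
planted wholly inside one region with at least `minGap` pixels of
clearance from region boundaries and from each other. Clearance makes the
oracle exact: components never merge, and majority assignment is trivially
unambiguous, so per-region counts must equal the registry with **zero
tolerance**. Counts per (section, region) are Poisson draws with mean
density × area, or exact integers in fixed-count mode (used where a test
needs determinism in the count itself). `injectArtifacts()` grows
irregular random-walk blobs — stand-ins for clustered-neuropil false
positives — flagged in the registry so exclusion tests can verify that
flagging restores exact equality.

`simulateSectioning()` reduces 3D spheres to intervals on the depth axis:
a cell at center $c$ produces a profile in every slab intersecting
$(c - D/2,\, c + D/2)$. This isolates exactly the statistical structure
Abercrombie's formula addresses. At 200 replicates of $N = 1000$ cells
($T = 40$, $D = 15$, $k = 6$, 48 mm block), the corrected estimator's mean
is within three standard errors of $N$ while uncorrected totals are biased
by $\approx (T+D)/T = 1.375$ — a parameter-recovery result the test suite
recomputes on every run.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: staining intensity variation (lightly stained
cells missed by a classifier), touching or overlapping cells that a
segmentation would merge (no watershed splitting is attempted), non-convex
morphology, registration error between mask and atlas, and lost caps. The
generator validates the counting arithmetic, not the segmentation.

Test problem sizes are chosen to exercise the statistics while keeping the
suite quick on a single CPU: recovery tests use 20 sections of 80 × 100 px
with 5 regions at per-section means of roughly 2–10 cells; the oracle
comparison uses one hundred 64 × 64 random masks; gradient checks use 8
sections × 20 seeds.

## Downstream analyses

* **Validity**: `percentDifference()` / `validityTable()` use the
  reference (manual) count as the denominator and round half-up for
  display, which reproduces seven published count-pair percentages
  exactly. One published pair (manual 905, automated 961) is stated as
  16% in its source but computes to ≈ 6.2%; the package reports the
  computed value and its reference checks use the seven consistent pairs,
  without guessing which of the stated numbers was intended.
* **Reliability**: `raterReliability()` reports absolute percent
  differences of each rater against a reference. Because a published
  "8%–29%" style range can be read over raters, over regions, or both,
  the summary reports all three granularities.
* **Cross-species**: `crossSpeciesTable()` re-expresses two atlases'
  estimates at mapped target regions. Target densities are recomputed as
  summed totals over summed volumes — volume-weighted, not averaged
  densities, which would overweight small subregions.
* **Gradients**: per-section density is profiles / (region pixel area ×
  pixel size² × $T$); the dorsoventral trend is Spearman's $\rho$ between
  dorsoventral order and density, classified decreasing/increasing at
  $|\rho| \ge 0.5$ with at least 4 usable sections. Published gradient
  statements are qualitative; a rank-based rule is a declared, robust
  operationalization, invariant to monotone transforms of density, and
  both threshold and minimum are arguments. Sections serve as the
  dorsoventral bins.

## Known limitations

* Counting assumes the upstream segmentation and registration are given
  and correct; no pixel classification or atlas registration is included.
* No correction for lost caps, z-occlusion, or shrinkage of $D$ and $V$.
* Touching cells segmented as one component are counted once.
* Group/leaf totals agree only to within 1 count per member region, the
  unavoidable rounding property of integer totals.
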