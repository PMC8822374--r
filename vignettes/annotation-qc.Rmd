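---
title: "Quality control of whole-slide image annotations with annoqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of whole-slide image annotations with annoqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(annoqc)
```

## The problem

Computational-pathology projects collect annotations — region polygons,
cell points, bounding boxes, case-level labels — from several
pathologists working on gigapixel whole-slide images (WSIs). Annotation
quality drives model quality, yet annotations are expensive, partially
subjective, and collected over months by people with very different
time budgets. annoqc implements a *data-dictionary-driven* quality
control layer for such projects: a reference document (the dictionary)
fixes what may be annotated and how much, automatic validation checks
conformance, four metrics quantify quality, and a simulator with known
imperfection parameters lets every metric be verified against
closed-form expectations without any slide data.

## The annotation model

An annotation record carries identity (`annotation_id`), provenance
(`slide_id`, `annotator_id`, `stain_type`), a level (case, region,
cell, descriptive), one of six constructs (bounding box, point, circle,
polygon, line, text), a label (`feature_name`) and geometry in 0-based
base-resolution pixels, origin top-left. Polygons are stored unclosed;
the closing edge is implicit, and is made explicit only in GeoJSON
export, which requires closed rings. Self-intersecting polygons are
*rejected at load* with an error issue rather than repaired: silent
repair changes areas and would corrupt every area-based metric
downstream.

The dictionary ([`anno_dictionary()`]) declares the labels, the
constructs each may use, per-slide requirements (region boxes, cell
boxes, annotators), display styles, the exhaustiveness threshold, and
two structures that matter for agreement analysis:

* **ordinal chains** — labels such as nuclear pleomorphism grades
  NP1 < NP2 < NP3 declare an `ordinal_group` and rank, which weighted
  kappa converts into graded disagreement penalties;
* **merge parents** — NP1/NP2/NP3 all merge to "tumour cell", so
  agreement can be recomputed *without* tumour-cell categorisation by a
  single [`merge_labels()`] call.

## The four QC metrics

**Completeness** is a yes/no per slide: are the required numbers of
region-level boxes, cell-level boxes and distinct annotators present?
Each unmet requirement is reported as a deficit triple.

**Exhaustiveness** asks what percentage of the *tissue* inside a
designated box is covered by region annotations:

$$E = 100\cdot\frac{\mathrm{area}\big(\bigcup_i R_i \cap B \cap T\big)}
                   {\mathrm{area}(B \cap T)}$$

Region polygons are clipped to the box before the union (spill-over
cannot inflate the numerator), the union guarantees overlapping
polygons count once, and the tissue mask $T$ removes glass background
from the denominator. Without a mask the denominator falls back to the
box area and the result carries a warning; a box with no tissue yields
`NA`. Boxes below the dictionary threshold (default 50%) are flagged.

**Diversity** is the number of distinct region types annotated on the
slide, bounded by the dictionary's region-label count. Designated
boxes and "unknown" regions do not count — a box is a work assignment,
not a region type, and "unknown" marks ambiguity rather than a type.

**Agreement** is measured pairwise between annotators, separately for
regions and cells, as described next.

## Region agreement: exact geometry

Region agreement per label is the Jaccard similarity index (JSI) of the
two annotators' polygon *unions*, with the union area also reported in
mm² (`area_mm2 = area_px2 * (mpp/1000)^2`). All polygon set operations
are **exact polygon clipping** (Vatti clipping via the polyclip
library), not rasterisation, so JSI is resolution independent; the test
suite uses a 0.05-px rasterisation of random polygon pairs as an
independent oracle and requires agreement within 0.01. Two conventions
the metric needs but that follow from no formula: empty-vs-empty JSI is
defined as 1 (two annotators agreeing a label is absent agree), and
empty-vs-nonempty is 0 and flagged one-sided. Circles are buffered to
64-gons (area deficit 0.16%) before clipping. Per-polygon JSI can be
had by passing single-ring sets to [`jaccard()`]; the per-label-union
form is the default because split/merge differences between annotators
should not be penalised when the covered area is the same.

## Cell agreement: optimal radius matching

Two annotators' cell points are considered marks of the same cell when
they lie within 3 µm of each other — 12 px at 0.25 µm/px, scaled by
`default_radius_px()` so the criterion is physical, not pixel-bound.
Within that constraint, [`match_points()`] computes the globally
optimal correspondence: maximum cardinality first, minimum total
distance among maximum-cardinality matchings. The implementation
decomposes the within-radius feasibility graph into connected
components and solves a Hungarian assignment per component (dummy
columns absorb unmatched points at a cost exceeding any achievable
matched total, so cardinality dominates). Greedy nearest-neighbour
matching was rejected because its result depends on scan order, which
breaks the A↔B symmetry a pairwise agreement statistic must have; the
test suite checks optimality against brute-force enumeration on all
instances with ≤ 6 points per side.

From a matching, the **breakdown** counts, over the $N$ distinct cells
seen by either annotator, the percentage matched-with-equal-label
(agreed), matched-with-different-label (disagreed), and seen by only
one annotator (missed); the three sum to 100. The **confusion matrix**
is built over matched pairs only, in dictionary declaration order so
ordinal chains stay contiguous; "unknown"-labelled cells are excluded
from it (and from kappa) by default because they encode uncertainty,
not a competing category — they still count in the breakdown.

**Cohen's kappa** on the confusion matrix uses the penalty form
$\kappa_w = 1 - \sum w_{ij} p_{ij} / \sum w_{ij} e_{ij}$ with
disagreement weights $w$: within an ordinal group of $k$ labels,
$w_{ij} = |r_i - r_j|/(k-1)$ (linear; squared for quadratic), and any
disagreement across groups or involving a non-ordinal label weighs 1.
With `weighting = "none"` this reduces to the classical
$(p_o-p_e)/(1-p_e)$. The weighting scheme is selectable because no
single convention is universal; linear is the default. Degenerate
matrices ($p_e = 1$, or empty) return `NA` rather than a number.

With more than two annotators per slide the pipeline evaluates all
unordered pairs and [`aggregate_pairs()`] averages the breakdown
percentages across slide-pairs (unweighted mean), pools confusion
matrices element-wise (the pooled kappa equals the kappa of the summed
matrix), and averages JSI per label. Mean-over-pairs is the default
summary; pooling over cells is available through the pooled matrix.

## Tissue masking

Exhaustiveness needs a tissue/background separation. The default
method is deliberately minimal: Otsu thresholding on the HSV saturation
channel (stained tissue is saturated, glass is bright and unsaturated),
then morphological opening, removal of connected components below
`min_object_area`, and filling of holes below `max_hole_area`. A
saturation floor of 0.05 keeps uniform images well-defined (Otsu is
degenerate on a constant channel): uniform white segments to 0% tissue,
a uniformly stained field to 100%. Masks are computed at thumbnail
scale (default downsample 32) and counted by pixel centres; a stored
mask supplied via the slide context always overrides computation.
Artefact detection (pen marks, blur, coverslip edges) is out of scope —
that is a slide-QC problem, not an annotation-QC problem.

## The automatic pipeline

[`run_qc()`] runs load → validate → completeness → exhaustiveness →
diversity → per-label counts/areas → pairwise agreement → aggregate.
Every violation becomes one row of the issue log with the offending
annotation id, the WSI id, a logged date, a rule id from the documented
catalogue ([`qc_rules()`]) and a severity; a stage failure on one slide
is itself logged and does not abort the rest. In reproducible mode all
timestamps are pinned from the config, making repeated runs
byte-identical — the suite asserts this on the report JSON. Per-label
counts and areas are tabulated to support prioritising what to annotate
next. [`write_report()`] emits the JSON report plus CSV tables.

## The simulator and its closed forms

The simulator exists so that every metric has a known right answer.
[`generate_ground_truth()`] lays out designated boxes, fills region
boxes with simple polygons that *tile* the box (wobbly vertical strips
— truth emulates exhaustive region annotation), and places labelled
cell points with a minimum pairwise separation, by default twice the
matching radius, so truth matched against itself is unambiguous and
perfect; a crowded mode (`min_separation = 0`) stresses the optimal
matcher instead. Cell labels follow a configurable prevalence whose
default is dominated by tumour-nucleus grades with TILs and stromal
cells as minority classes.

[`simulate_annotator()`] degrades truth with an
[`annotator_profile()`]: each cell is independently missed with
probability `miss_rate`, surviving cells get a label drawn from a
row-stochastic confusion kernel (the default test kernel confuses
adjacent NP grades with total mass 0.1, the axis on which human
annotators disagree most) and an isotropic Gaussian position jitter;
spurious cells arrive as a Poisson count uniform in the cell boxes;
region vertices are jittered and re-sampled until the ring stays
simple. Annotators are **conditionally independent given truth** — the
simplest model with closed-form expectations, and a documented
limitation: real annotators share systematic biases, which this model
cannot produce.

Two closed forms make recovery tests exact rather than anecdotal.
[`analytic_expected_kappa()`] computes the expected kappa from
$p(i,j)=\sum_t \pi_t A_{ti} B_{tj}$. [`expected_breakdown()`] computes
the expected agreed/disagreed/missed percentages: a true cell is seen
by both annotators with probability $(1-m_A)(1-m_B)$, by exactly one
with $m_B(1-m_A)+m_A(1-m_B)$, and by neither with $m_A m_B$ — the last
group is absent from the comparison entirely, so the denominator is the
first two terms (plus spurious singletons). With annotator A perfect
and B missing at rate $m$, the expected missed percentage is simply
$100m$.

## Numerical choices and degenerate inputs

* JSON serialisation uses 17 significant digits, so save/load and
  GeoJSON export/import round-trip coordinates bit-exactly.
* polyclip scales coordinates to integers internally; JSI values are
  exact to ~1e-9, and tests compare at that tolerance.
* Empty matrices, empty point sets, zero-tissue boxes and empty
  projects all return explicit `NA`/empty results with warning issues,
  never errors.
* Matching ties (equal total distance) are resolved deterministically
  by the assignment solver; with continuous coordinates exact ties do
  not arise in practice.
* Derived seeds in scripts stay below 2^31.

## Problem sizes used by the test suite

The suite verifies geometry against a Monte-Carlo area oracle at 10⁶
samples and a 0.05-px rasterisation oracle on 100 random polygon pairs;
matching optimality against enumeration on 500 instances with ≤ 6
points per side; kappa against an independent direct-formula
implementation on 1,000 random matrices at 1e-12; miss-rate recovery on
2,000 cells (±2 percentage points); kappa recovery on 5,000 matched
cells over 10 seeds (±0.03); and pipeline determinism on a 3-slide,
2-annotator simulated project. These sizes keep the whole suite under
a minute on one CPU while leaving the statistical tolerances
comfortably wide of their expected fluctuations.

## What passing tests do and do not show

The simulator emulates miss/confusion/jitter disagreement between
independent annotators on clean synthetic layouts. Passing recovery
tests shows the *metrics* are computed correctly, not that real
pathologist disagreement follows this model: real data adds correlated
biases, boundary ambiguity that scales with region size, density-driven
matching ambiguity, and stain variation that the tissue thresholder's
defaults may not survive. Cohort-level values from any particular
project therefore depend on that project's data and protocol; this
package supplies the instruments, calibrated on data where the truth is
known by construction.
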