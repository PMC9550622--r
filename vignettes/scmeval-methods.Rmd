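---
title: "Scoring and benchmarking single-cell localization predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and benchmarking single-cell localization predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmeval)
```

## The problem

In spatial proteomics, a classifier is asked to assign one or more of 19
subcellular localization classes to every segmented cell in a fluorescence
image. Ground truth comes as per-cell instance masks with multi-label
annotations; submissions come as per-cell masks with per-class confidences.
Scoring such predictions couples an instance-segmentation problem (is this
predicted mask the same cell as that ground-truth mask?) with a ranked
multi-label classification problem (are the right classes asserted, with
well-ordered confidences?). scmeval implements that coupled metric —
mask-matched mean average precision (mAP) at a mask-to-mask IOU threshold —
together with the dataset-engineering machinery around it: the 31-label to
19-class annotation ontology, image curation filters, weak-label
refinement, heterogeneity and annotator-agreement statistics, and a seeded
synthetic benchmark generator so that every component can be exercised and
validated without any microscopy data.

## The scoring model

**Mask matching.** For each image, every predicted mask is compared with
every ground-truth mask by intersection over union,
$\mathrm{IOU}(p,g) = |p \cap g| / |p \cup g|$, counted over pixels. Pairs
with IOU at or above the threshold (default 0.6) are candidates; a
one-to-one pairing is formed greedily by descending IOU with a
deterministic tie-break (ascending ground-truth id, then predicted id).
Matching is class-agnostic and mask-first: the pairing is decided before
any label is consulted. The threshold comparison is inclusive
(`IOU >= 0.6`); a strict mode is available because both conventions
circulate. Greedy matching rather than optimal assignment is the
convention of the major instance-segmentation evaluations; the two differ
only in contrived tie structures, and the test suite cross-checks the
pipeline against an exhaustive max-total-IOU assignment oracle.

**Detection classification.** A detection of class $c$ on a matched
predicted cell is a true positive exactly when $c$ belongs to the matched
ground-truth cell's label set; every other detection — wrong class on a
matched cell, or any detection on an unmatched cell — is a false positive.
False negatives for class $c$ are ground-truth instances carrying $c$ that
no true positive accounts for, so $TP_c + FN_c$ always equals the number
of ground-truth instances carrying $c$ (a conserved quantity the tests
assert).

**Average precision.** Within each class, detections are pooled globally
across images and ranked by descending confidence. Confidence ties break
by `(image_id, cell_id, class_id)`, which makes the report invariant to
input row order — a tie-break that favored true positives would inflate
scores. Precision $p = TP/(TP+FP)$ and recall $r = TP/(TP+FN)$ are
evaluated at every cut of the ranking and

$$\mathrm{AP} = \int_0^1 p(r)\,dr$$

is computed with the all-point interpolated precision envelope: the
precision credited at recall $r$ is the maximum precision attained at any
equal-or-higher recall. This avoids the undefined $0/0$ at recall zero and
matches the streaming cumulative-sum implementation exactly (the suite
verifies equality against an independent all-cuts oracle on hundreds of
random rankings, ties included).

**mAP.** The final score is the mean AP over classes. Classes with no
ground-truth positives have no defined AP; they are reported as `NA` and
excluded from the mean by default, with an `absent_as_zero` flag for the
alternative convention. Alongside mAP the report carries the mean IOU over
matched pairs, the standard segmentation-quality summary for a submission.

One accounting question is genuinely underdetermined: whether a matched
cell missing a detection for one of its ground-truth classes contributes
one false negative per missing class or one per cell. scmeval counts per
class, which is what the per-class recall formula implies.

## The class ontology

Annotation happens on 31 fine labels (30 organelle patterns plus
Negative/Unspecific); scoring happens on 19 grouped classes. The grouping
merges functionally and spatially similar patterns: Focal adhesion sites
into Actin filaments; Centriolar satellite into Centrosome; Cell Junctions
into Plasma membrane; and Vesicles, Peroxisomes, Endosomes, Lysosomes,
Lipid droplets and Cytoplasmic bodies into a single vesicles-and-punctate
class. Four fine labels (Microtubule ends, Rods and Rings, Cleavage
furrow, Mitotic chromosome) have no grouped destination and are discarded
during grouping; a cell left with an empty set becomes Negative, the same
fallback refinement uses. Whether Mitotic chromosome should instead merge
into Mitotic spindle is not determinable from the available description;
discarding is the literal reading, and the scheme is a versioned YAML
resource so alternative mappings load through the same interface. Class
ids are 0-based in the declared order with Negative last (id 18).

## Curation filters and agreement statistics

Images are removed when strictly more than 50% of their cells are
Negative, when strictly more than 50% are flagged defective (defectiveness
is an input flag — no pixel-level QC is attempted), or when every cell's
label set equals the image-level label set, since such homogeneous images
carry no single-cell information beyond their weak labels. The strict
inequality matters at the boundary: an image with exactly half its cells
Negative is kept. The homogeneity comparison here operates on grouped
19-class sets — the representation downstream users actually hold — though
the original pipeline applied it before grouping; both behaviors are
reachable since the comparison is set-equality on whatever labels are
supplied.

An image is *heterogeneous* when its eligible cells do not all carry the
same label set; cells whose nucleus touches the image border are excluded
by default because their patterns are only partially observed. The census
aggregates heterogeneous/homogeneous counts per cell line.

Annotator agreement is the fraction of multiply-annotated cells whose
annotators produced identical label sets. As a null reference,
`chance_agreement(n, k)` returns $(1/n)^{2k}$ — the probability that two
annotators independently drawing $k$ specified labels uniformly from $n$
both reproduce a pre-specified selection. This null model is interpretive:
it is the model that reproduces the conventionally quoted reference values
(0.1% for one label of 30, 0.0001% for two), and it is deliberately
conservative; the more common any-label-agreement model gives $1/n$
instead. The function takes both arguments explicitly so either convention
can be computed.

The public/private split assigns a configurable fraction of images
(default 31%) to the public side while preserving per-class cell-count
proportions: from a seeded random split of the right size, greedy pairwise
swaps are accepted whenever they reduce the maximum per-class absolute
proportion gap, for a default of 1,000 candidate swaps. Exact optimization
is a partition problem and unnecessary — on a few hundred synthetic images
the residual gap is well under a percentage point.

## Weak-label refinement

Refinement turns image-level labels into single-cell labels by multiplying
the binary image-label vector with the cell's class-probability vector and
rounding the product. Because the image labels gate the product,
refinement can never add a class the image does not carry; cells whose
sets empty become Negative. "Round up" is ambiguous: a literal ceiling
keeps every image label with any nonzero probability, which contradicts
the stated purpose of removing low-certainty labels. scmeval therefore
defaults to half-up rounding at a threshold (default 0.5, the value at
which rounding a product of a 0/1 gate and a probability is equivalent to
thresholding the probability) and retains literal ceiling as a mode; the
two bracket the plausible readings, ceiling being the limit of half-up as
the threshold goes to zero. The containment guarantee (refined set ⊆
image labels ∪ {Negative}) and the mode ordering (ceiling ⊇ half-up) are
property-tested on 10,000 random draws.

On top of refinement, `single_location_multilocalizers()` lists proteins
whose image-level union spans at least two classes while every refined
cell carries exactly one — the signature of coordinated translocation
(cell-cycle proteins, shuttling transcription factors) rather than
simultaneous multi-compartment residence.

## The synthetic benchmark generator

The generator exists so that every scoring and curation path can be tested
end-to-end, deterministically, with no imaging data. It emulates the
*label and instance structure* of the real benchmark, not its pixels:

* **Geometry.** Each image is a square field with a Poisson-distributed
  number of cells (mean 20 by default, matching a typical confocal field
  of view). Cells are axis-aligned ellipses placed in distinct cells of a
  jittered grid, which guarantees pairwise disjointness by construction;
  each contains an inscribed elliptical nucleus whose bounding box drives
  border detection. A configurable fraction of edge cells is pushed so the
  nucleus touches the boundary.
* **Labels.** Each image draws a base label set: a primary class from the
  configured class frequencies plus `Binomial(3, multilabel_rate)` extra
  classes (default rate 0.25, so roughly half of the sets are multi-label,
  consistent with the known prevalence of multi-localizing proteins; sets
  have 1–4 classes). Default frequencies are log-spaced across two orders
  of magnitude — deterministic rather than randomly drawn, so the
  configured dynamic range is exact — reflecting a benchmark whose class
  imbalance was deliberately compressed from the natural five orders of
  magnitude to two. A configurable fraction of images is a negative
  control (all cells Negative).
* **Heterogeneity.** With the configured probability, an image with at
  least two non-border cells receives a variant label set (one class added
  or removed) on a random proper subset of its non-border cells, making
  the image heterogeneous by the census definition and leaving unplanted
  images exactly homogeneous — so the planted rate is identifiable from
  the data.
* **Weak labels.** Image labels are the union of cell labels, so weak-label
  soundness (every image label carried by a cell, every cell label present
  at image level) holds by construction and is asserted in tests.

The prediction corruptor derives a submission from ground truth and
degrades it along the axes the metric must be sensitive to: morphological
mask erosion/dilation (via EBImage, box structuring element), per-label
drop and swap, and confidence jitter ($1 - |N(0,\sigma)|$, clipped to
$[0.01, 1]$). The zero-corruption configuration reproduces the ground
truth byte-for-byte and must score mAP = 1 and mean matched IOU = 1
exactly — the metric-identity check. Because eroded masks are nested
subsets of the originals, increasing erosion provably never increases
matched-pair counts, giving a monotone-degradation check with no
tolerance.

What passing these tests does *not* show: the generator produces convex,
well-separated cells with exact masks, so it says nothing about
performance under realistic segmentation pathologies (touching cells,
debris, out-of-focus planes) or about texture-dependent classification
difficulty. It validates the *metric machinery*, not any biological model.

## Numerical and design choices

* RLE scan order is column-major (top-to-bottom, then left-to-right),
  recorded in the mask object so row-major dialects can be added; the
  first run is background and may be zero-length, making the encoding
  canonical (equal masks give byte-identical strings).
* Coordinates are 0-based and pixel-centered on disk; bounding boxes are
  half-open `[row0, row1) x [col0, col1)`.
* Border detection uses the nucleus bounding box when nucleus data exist
  (the definition used for heterogeneity accounting) and falls back to the
  full mask otherwise, since user-supplied data may lack nuclei.
* Ground-truth masks must be disjoint and are validated on load; predicted
  masks may overlap across cells, but all detections of one predicted cell
  must carry the identical mask. A prediction row without a confidence is
  taken as confidence 1 (label-only submissions).
* Zero matched pairs, zero eligible cells, or zero-variance correlation
  inputs return `NA` sentinels rather than raising, so cohort-level code
  can aggregate partial results.
* The correlation critical value is $r^* = t^*/\sqrt{t^{*2} + \mathrm{df}}$
  with $t^*$ the Student-t quantile; it inverts the p-value computation to
  $10^{-9}$, and its two-tailed 0.02 level at 48 degrees of freedom gives
  the conventional 0.33. The significance level is an explicit argument
  because quoted critical values do not always state theirs.
* Seeding: every stochastic routine takes or derives from an explicit
  integer seed via `withr::with_seed`, so datasets, corruptions and splits
  are byte-reproducible; nothing touches the global RNG state outside
  those scopes.

## Problem sizes used in validation

The self-scoring identity and erosion-monotonicity checks run on a seeded
benchmark of 50 images and roughly 1,000 cells at 256 px. Oracle
equivalence runs 500 random corrupted instances of 2–7 cells at 64 px
against brute-force matching and all-cuts AP. Parameter recovery uses 200
images / ~1,000 cells with planted drop rate 0.2 and heterogeneity rate
0.3, judged within three binomial standard deviations. Refinement
containment uses 10,000 random draws; null calibration of the critical
value uses 10,000 independent replicates at n = 50. These sizes make the
sampling checks sharp enough to catch rate errors of a few percentage
points while keeping the whole suite around two minutes on one core.

## Limitations

* The toolkit scores and curates; it trains nothing. Class probabilities
  for refinement come from the user's models.
* Competition-platform submission encodings (zlib-compressed, base64 mask
  strings) are not parsed; the CSV/RLE schema here is the package's own
  interchange format.
* The chance-agreement null model and the refinement rounding rule are
  documented interpretations of underdetermined conventions, selectable
  where alternatives exist.
* Greedy matching can differ from optimal assignment on adversarial tie
  structures; the exhaustive oracle used in testing flags such cases, none
  of which arise under the generator's disjoint-cell geometry.
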