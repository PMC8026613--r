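---
title: "Methods: two-condition promoter-interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition promoter-interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canvasnet)
```

## The network model

`canvasnet` compares the promoter interactomes of two cell states measured
by promoter-capture Hi-C (PCHi-C). The unit of resolution is the
restriction fragment: every node of the network is one fragment of the
digest map (for a HindIII digest, ~4 kb on average), and every edge is a
significant promoter interaction called by CHiCAGO, whose score is a
−log-transformed weighted p-value.

The two conditions are merged into a single graph keyed by unordered
fragment pair. Two thresholds govern the merge:

* `sig_threshold` (default **5**): an edge enters the network only if its
  score reaches this value in at least one condition. This is the standard
  CHiCAGO significance convention.
* `support_threshold` (default **3**): an edge significant in one condition
  is labelled *shared* when the other condition's score exceeds this value,
  even if it falls short of significance there. The rationale is caution: a
  strict significant/absent dichotomy would overcall differences whenever a
  real interaction hovers just below the significance line in one dataset.
  A score at or below 3 (or no call at all) leaves the edge
  condition-specific.

Specificity is a pure function of the two stored scores, so it can always
be recomputed from the edge table (`edge_specificity()`); node specificity
is derived from incident edges. Fragments with no qualifying edge never
enter the network — there are no orphan nodes.

Coordinates are 0-based half-open throughout (BED-native); washU-style
`chr:start-end` anchors are interpreted the same way. Interaction anchors
are matched to the fragment map by **exact** start/end equality (with an
optional ±1 bp tolerance for off-by-one dialects) because PCHi-C calls are
fragment-resolved; silent nearest-fragment snapping could re-wire edges and
is deliberately not offered.

Promoter (bait) annotation takes the 1 kb window upstream of each TSS,
strand-relatively: `[tss − 1000, tss)` on the plus strand and the mirrored
window on the minus strand. Unstranded rows default to plus with a warning.
A promoter overlapping two fragments annotates both.

## Multiscale structure

*Sub-networks* are the connected components of the merged graph, numbered
deterministically (size descending, then smallest member fragment id). The
census counts, per component, the edges supported in each condition
(shared + condition-specific) and the nodes incident to at least one such
edge; the quadrant label (`larger_in_A` / `larger_in_B` / `unchanged` /
`mixed`) summarises the direction of change.

*Communities* come from multi-level (Louvain) modularity optimisation run
per component, followed by a single-node refinement pass that accepts moves
while they improve modularity by more than 1e−7. Tie-breaking is made
deterministic by shuffling the vertex order with a recorded seed before the
multi-level pass. Components whose best-partition modularity reaches
`modularity_threshold` (default **0.7**) are flagged `split_applied`;
`community_assignment()` collapses the result so that flagged components
are split into their communities and all others stay whole. The detection
result always records the best partition *and* the flag separately — the
0.7 rule decides what downstream stages treat as a cluster, not what the
optimiser found. This matters in practice: a planted-partition graph with
eight communities, within-community edge probability 0.5 and
between-community probability 0.02 has a ground-truth modularity of about
0.65, below the split threshold, yet the partition itself is perfectly
recoverable.

*Distances* between interacting fragments use fragment midpoints — the
only symmetric, resolution-honest anchor choice at fragment resolution.
Trans (inter-chromosomal) edges are flagged and excluded from distance
statistics. Distance bands are half-open on the left; **long-range is
strictly greater than 1 Mb**, so an exactly 1 Mb interaction is mid-range.
The short/mid breakpoint is not canonical; the default is 250 kb (roughly
the scale separating local promoter–enhancer contacts from
sub-TAD/TAD-scale contacts in mammalian genomes), is configurable, and is
echoed into output metadata. The top-n longest selection (default
n = 1000) breaks distance ties by fragment id so repeated runs select the
same edge set.

## Chromatin-state annotation

Segmentations arrive as BED4 with one of seven reduced state labels
(`active`, `h3k4me1_only`, `bivalent`, `polycomb`, `heterochromatin`,
`unclassified`, `background`). Each fragment receives exactly one label by
the supersession rules: any single state supersedes background; bivalent
supersedes Polycomb; any other mixture of two or more distinct states is
`mixed`. Uncovered bases count as background (segmentation gaps arise from
upstream filtering). The minimum overlap for a state to count toward a
fragment is 1 bp by default (`min_state_bp`), configurable for robustness
analyses. `unclassified` is preserved as its own label and never folded
into background. The per-fragment state → bp overlap table is attached to
the result so every label can be re-derived.

Cross-condition transitions are tabulated per (state in A, state in B)
pair with percentages normalised within the destination state, optionally
restricted to a fragment subset such as long-range interaction anchors.
For the longest interactions, the bait side of each edge is the end with a
gene annotation; when both ends are baited, the edge contributes one row
per direction (documented in the function's output).

## Enhancers and super-enhancers

H3K27ac peaks are stitched transitively whenever the gap between them is at
most **1.5 kb** (touching peaks always merge); a stitched element's signal
is the sum of its constituents'. Elements are ranked by ascending signal,
ranks and signals are scaled to [0, 1], and the super-enhancer cutoff sits
at the element maximising scaled rank minus scaled signal — the point
where a slope-1 line is tangent to the convex rank-signal curve. Elements
with signal strictly above the cutoff element's signal are super-enhancers.
Scaling both axes makes the cutoff invariant to affine rescaling of the
signal vector, which is property-tested. Ties on the rank curve are broken
by genomic order; if every element has the same signal no super-enhancer is
called (with a warning). No TSS-exclusion window is applied by default; the
element/fragment overlap threshold is 1 bp and configurable.

Cross-condition element matching is by ≥1 bp overlap and keeps one-to-many
pairs, so the shared counts of the two conditions may legitimately differ.
Target genes are found by routing each element through the network:
element → overlapped fragments → edges supported in the condition → genes
baited on the opposite end. Elements lying on a baited fragment are still
mapped through edges only (no self-targets). Genes contacted by a
super-enhancer are removed from the typical-enhancer target list so the two
gene sets stay disjoint.

Enhancer decommissioning is quantified two ways: percent DNA methylation
per region as the pooled ratio 100·Σmeth/Σtotal over covered CpGs (regions
without CpGs are missing, excluded from summaries), and per-region histone
gain as a log2 RPM difference exceeding `log2fc_threshold` (default 1),
with the set-level statistic — log2 of the ratio of linear-scale medians —
reported separately, since a per-region rule and a set-level median answer
different questions.

## OSN occupancy and interaction rewiring

Composite OCT4/SOX2/NANOG peaks are built by merging the union of the three
factors' peaks whenever the gap is **strictly below 100 bp** and keeping
only merged regions supported by at least one original peak of each factor.
Upstream of the merge, peaks can be filtered against a binned signal track
(500 bp windows, tiled from position 0 by default with a configurable
offset; the phase is not specified by convention, so it is recorded), keeping
peaks that overlap at least one window with log2 RPM > 0. Missing windows
count as below threshold. A peak's chromatin state is the state at its
centre base; per-set state compositions are percentages that sum to 100.

Per-fragment change classes feed the association analysis: OSN change is
`lost`/`gained`/`retained`/`never` from overlap with each condition's OSN
peaks, and interaction change summarises the specificity of the fragment's
incident edges. The 4×3 count matrix is reported with row percentages, and
every cell is collapsed to a 2×2 table (this row and column against the
rest) with a cross-product odds ratio, its log2, and a chi-squared p-value
without continuity correction — matching the convention of the headline
test — with Fisher's exact test substituted automatically whenever an
expected cell is below 5 (the `test` column records which ran). A 0.5
continuity correction is applied to the OR only when a cell is zero, and
flagged. Fragment granularity is the default; the same functions accept
peak-level inputs.

Control regions are uniformly sampled fixed-width windows (default 10,000 ×
1.2 kb, the approximate average peak size), chromosome-weighted by length,
seed-reproducible, with optional rejection sampling against an exclusion
list.

## Statistics

`mann_whitney_u()` uses exact enumeration when the smaller group has at
most 8 observations and there are no ties, and otherwise the normal
approximation with tie and continuity corrections; the U statistic is
reported for the first group, and identical pooled values give p = 1.
`fisher_or_chisq()` in auto mode runs chi-squared (no continuity
correction) when all expected cells are ≥ 5 and Fisher otherwise; zero-margin
tables return p = 1 with a missing OR. Benjamini–Hochberg adjustment is
provided for lists of results.

The community–TAD overlap test is a permutation test: the observed count of
query regions overlapping any reference region is compared to a null built
by re-placing each query region uniformly within its own chromosome
(width- and chromosome-preserving; a circular-shift strategy is available).
The empirical p-value uses the +1 pseudocount convention,
(1 + #{null ≥ observed})/(N + 1), so it is never zero, and the output
records N, the seed and the strategy because both choices affect the null.

## Layouts

The force-directed layout is a simplified ForceAtlas2: linear attraction
along edges, degree-weighted pairwise repulsion, central gravity, and a
decaying global step with convergence on mean displacement below 1e−4. The
seed controls only the initial placement, so identical seeds give
byte-identical coordinates. Repulsion is computed exactly over all node
pairs in vectorised form rather than by Barnes–Hut approximation: at the
scales this package targets the exact computation is fast, and exactness
keeps the determinism contract simple. The reproducible guarantees are
qualitative — connected nodes end up closer than disconnected ones, and
planted cluster pairs separate — plus full seed determinism and parameter
logging; pixel-level agreement with any interactive layout tool is not a
goal.

The MDS layout embeds a node set so that layout distances approximate
linear genomic distances between fragment midpoints: classical-scaling
initialisation, then metric SMACOF stress majorisation (deterministic, no
random restarts), stopping when the raw-stress improvement falls below
1e−10 relative. Kruskal stress-1, √(Σ(d−δ)²/Σδ²), is computed over **all**
node pairs — not only edges — so it is well-defined for sparse graphs.
Trans pairs receive the maximum observed cis distance and are flagged.
Configurations of fewer than three nodes are placed analytically with
stress 0.

## The synthetic study generator

`generate_fixture()` creates a complete miniature two-condition study:
2 chromosomes × 20 Mb tiled into 4 kb fragments, 60 bait fragments carrying
200 genes, and per-condition interaction calls, segmentations, H3K27ac and
OSN factor peaks, binned signal, expression, methylation and TAD tracks,
all written in the same plain-text formats the readers accept. Planted
structure, recorded in the manifest:

* 8 communities of 10–25 nodes in one component (within-community edge
  probability 0.5, between 0.02, a spanning chain guaranteeing
  connectivity), genomically compact so all intra-component distances stay
  below 1 Mb;
* 15 condition-B-specific bridges spanning >1 Mb, with bivalent chromatin
  at both anchors for 80% of them and one "mixed" anchor (an active patch
  inside a Polycomb block) for the rest, exercising the supersession rules;
* 12 super-enhancers (three high-signal constituent peaks each) among 21
  typical enhancers, wired to target genes with planned
  A-only/B-only/shared classes, including one gene contacted by a
  super-enhancer in one condition and a typical enhancer in the other;
* 500 enhancer fragments whose OSN occupancy change and interaction change
  are coupled at rate 0.9, with short-range (<1 Mb) edges so they never
  contaminate the long-range census;
* expression shifts of +1.5 log2 units for element-target genes in their
  contacted condition.

Significant CHiCAGO scores are simulated as 5 + Exponential(mean 4) and
sub-threshold support scores as Uniform(3, 5); this reproduces the
threshold logic of the merge without modelling the caller itself.
`generate_null_fixture()` removes every planted asymmetry (bridges split
evenly, all elements shared, no expression shift, occupancy independent of
interaction change) for type-I-error and odds-ratio calibration.

What the generator does **not** emulate: read-level noise, distance-decay
of contact frequency, irregular fragment sizes, biological replicate
structure, trans interactions, and realistic genome-wide state
composition. Tests passing on these fixtures therefore demonstrate that
the implemented rules and statistics are correct and recover planted
structure — not that the method's biological conclusions transfer to any
particular real dataset.

## Problem sizes and numerical conventions

The test suite runs the complete pipeline on the default fixture
(~750 nodes, ~1,400 edges), verifies community detection against exhaustive
modularity maximisation on graphs of up to 10 nodes, stitching against an
interval-merge oracle on 1,000 random peak sets, Fisher p-values against
hypergeometric enumeration, and the exact Mann–Whitney branch against full
enumeration for pooled sizes up to 10; null calibration uses 10,000
Mann–Whitney replicates at n = 30 per group and 100 null-fixture seeds for
the odds-ratio bound. These sizes were chosen to make each check exhaustive
or statistically tight at interactive run times.

Degenerate inputs have defined behaviour throughout: empty call sets build
an empty network; singleton components have modularity 0; all-equal element
signals call no super-enhancer; regions without CpGs are missing, not zero;
zero-margin contingency tables give p = 1 with missing OR; empty factor
peak sets give an empty OSN set with a warning.

## Known limitations

* The merged network is unweighted for community detection; CHiCAGO scores
  are carried on edges but do not weight modularity.
* Louvain with refinement is a heuristic; optimality is only guaranteed on
  the small graphs where the suite compares against brute force.
* The ±1 bp anchor-matching tolerance handles off-by-one dialects but not
  genuinely re-digested fragment maps; inputs from a different digest must
  be re-mapped upstream.
* Peak-granularity OSN contingency is available but fragment granularity is
  the tested default.
* The force-directed layout's exact O(n²) repulsion step is comfortable to
  a few thousand nodes per component; far larger graphs would need an
  approximate scheme.
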