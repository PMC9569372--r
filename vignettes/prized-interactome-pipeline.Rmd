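---
title: "Prized interactomes, Steiner forests and 3D nuclear quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prized interactomes, Steiner forests and 3D nuclear quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prizenet)
```

This vignette documents the models, parameter choices and numerical
conventions behind `prizenet`, in the spirit of a methods section: what
is computed, under which assumptions, and where the genuinely open
design decisions were resolved.

## The two-layer interactome

Regulatory events are represented on two layers. *Protein nodes* stand
for gene products that can act (interact, regulate); they are joined by
undirected PPI edges carrying a confidence in (0, 1]. *RNA nodes* stand
for transcripts whose abundance responds to regulation; they are
reachable only through directed TF→target edges from protein nodes. The
same gene symbol may appear on both layers — a transcription factor that
is itself transcriptionally induced is two distinct nodes — so node
identity is the pair (gene, layer). Symbols are compared uppercased
(mouse symbol casing is inconsistent across databases) with original
casing preserved on output.

Edge costs must be low for reliable edges, since the optimization
minimizes cost. PPI confidences are mapped through
`cost = max(1 − confidence, 0.01)`; the floor keeps costs strictly
positive so optimal trees never carry redundant zero-cost edges.
Duplicate PPI rows are merged by maximum confidence: STRING-style
combined scores are already integrated evidence, so taking the best
report is more faithful than averaging. Regulatory edges have no
per-edge confidence (regulon membership is binary across source
databases), so they carry a constant cost, default 0.5 — chosen midway
through the PPI cost range so that regulatory edges are neither free nor
prohibitive. Both the cost rule and the constant are configurable;
we deliberately do not threshold PPI confidences on input, leaving any
pre-filtering to the caller.

## Prizes

Two differential-expression contrasts feed the graph. The early
contrast prizes protein nodes: genes with BH-adjusted p < 0.01 and
positive log2 fold change receive `β · log2FC`. The late contrast
prizes RNA nodes the same way. Only up-regulated genes are prized —
the network is built to explain the activation cascade; down-regulated
genes are retained in the DE tables and reappear in the shared-target
analysis. Missing adjusted p values are treated as non-significant,
never imputed. The scaling β (default 1) trades prize collection
against edge cost globally; on exact solutions the total collected
prize is provably non-decreasing in β, which the tests exercise.

## The Prize-Collecting Steiner Forest solvers

The optimization is stated in minimization form: pay the cost of every
edge kept, forfeit the prize of every node left out. This differs from
the familiar "maximize prize minus cost" by the constant total prize,
so both select the same subgraphs. Two solvers are provided.

**Exact (oracle).** A dynamic program over node subsets: any candidate
tree is a connected node set spanned at its minimum-spanning-tree cost,
and the optimal forest is the cheapest packing of disjoint candidate
trees plus forfeits. Complexity is roughly 3^n, so the solver refuses
instances beyond 15 nodes; its role is to validate the heuristic and to
make small parameter sweeps exactly. With an opening cost ω > 0 per
tree (the rooted forest formulation) a single prized node is a legal
tree; with ω = 0 trees need at least two nodes, otherwise every node
would trivially join the forest and the objective would degenerate to
zero. Ties are broken toward fewer trees, then larger collected prize —
this makes the tree count non-increasing in ω and the collected prize
non-decreasing in β, the two monotonicity properties asserted in the
test suite.

**Primal-dual heuristic.** The Goemans–Williamson moat-growing scheme
on the instance augmented with a dummy root connected to every prized
node at cost ω. Clusters grow dual moats at unit rate while their
remaining prize potential is positive; an edge whose slack is exhausted
merges its two clusters; a cluster that exhausts its potential
deactivates (it may later be absorbed). The tight-edge tree containing
the root is strongly pruned at the root, the root is removed, and the
surviving subtrees are the forest. Singleton survivors are kept: they
paid ω and collect their prize, and the classic factor-2 guarantee is
stated over exactly this solution space. Consequently the
oracle-equivalence test compares *rooted* objectives
(objective + ω·#trees) of heuristic and exact runs at the same ω; the
guarantee does not extend to the ω-free forest optimum, even in theory.
Determinism comes from processing events in a canonical edge order
(edges sorted by endpoint keys; real edges before root edges) with a
10⁻¹² tie tolerance — identical inputs produce byte-identical output
files.

**Strong pruning** is the standard leaf-to-root dynamic program: a
subtree whose accumulated payoff is below the cost of its attaching
edge is discarded. It never increases the objective and is idempotent.
Note that pruning cascades: removing an unprofitable leaf can render
its parent unprofitable, so in the chain r–a–b (costs 1 and 3; prizes
5, 0, 2) both b *and* a are removed.

ω defaults to 1.0. There are two common ways to obtain several trees —
one run of a forest formulation, or repeated single-tree runs — and we
commit to the former, with ω exposed as a plain parameter: larger ω
merges or discards marginal trees, and a single deterministic run is
easier to reason about and to reproduce.

Regulatory edges are treated as undirected during optimization (the
problem is defined on undirected graphs and protein→RNA links are the
only way to reach RNA nodes); their direction is restored when the
network is induced.

## From forest to regulators

The regulatory network is the interactome subgraph induced on the
forest's nodes — connecting every interactome edge whose endpoints both
survived optimization, not just the tree edges. Regulators are protein
nodes with at least one in-network regulatory out-edge. Two criteria
identify a key regulator in this setting — its own early fold change,
and how many of its targets respond late — and no single statistic
combining them is canonical, so the composite rank is the mean of the
two descending dense ranks, with alphabetical tie-breaking for
determinism. The focal-regulator analysis reports, for every regulator
sharing a PPI edge with the focal one, the shared in-network target
set, its late up/down split (adjusted p < 0.01, sign of log2FC), and
which reprogramming factors (default Pou5f1, Nanog, Sox2, Klf4, Myc)
are among the shared targets.

## 3D nuclear segmentation and quantification

Each z-plane of the nuclear-stain channel is binarized by the
*intersection* of a global Otsu threshold and a local one (Otsu per
block, default 64 px, bilinearly interpolated between block centres;
near-constant blocks fall back to the global value). Combining the two
thresholds by intersection is the conservative choice — the global one
rejects dim background, the local one handles uneven illumination — and
an OR mode is available for sensitivity analysis. Near-constant planes
(relative dynamic range below 2%) return an empty mask rather than a
degenerate threshold; because thresholds are computed on normalized
intensities, segmentation is invariant to positive rescaling of the
stain.

Touching nuclei are split by a seeded watershed: regional maxima of the
smoothed Euclidean distance transform, separated by at least half the
nominal nuclear diameter (10 µm), seed a division of the mask along the
distance-map ridge; components without a peak of their own keep a
single label. 2D segments in consecutive planes are linked greedily by
ascending centroid distance, each segment used at most once
(mutual-nearest rule), with a 1 µm ceiling; 3D objects below 100 µm³
are then removed (strictly below — an exactly-100 µm³ object is kept).
All distances and volumes are physical (µm), so anisotropic voxels need
no special casing.

Per-nucleus intensity is the per-voxel mean (total intensity divided by
voxel count). Volume normalization could alternatively mean a per-µm³
density, but the per-voxel mean is what a per-pixel intensity cutoff
presumes, and the high-marker classification uses exactly such a cutoff
(strictly above 300). Colocalization binarizes each
queried channel by Otsu within the nucleus's own voxels (falling back
to the whole-channel threshold when a channel saturates a nucleus) and
reports the fraction of nucleus voxels foreground in all channels.

## Synthetic data: what it emulates, what it does not

The generators encode the study conditions end to end. Interactomes:
preferential-attachment PPI graphs (confidences uniform 0.4–1, STRING
0–1000 score dialect), regulons of heterogeneous size drawn uniformly
from a range. Planted scenarios: the planted TF is the one with the
largest regulon — emulating a master regulator controlling the most
targets — with early log2FC 3.0 at padj 10⁻⁶; 90% of its regulon is
up-regulated late (log2FC 4.0 ± 0.3); decoy TFs draw weaker early
effects from a fixed 0.5–1.5 range (the value implied at the default
planted effect; it is a property of the background biology, so it stays
put when the planted effect is swept downward in the degradation
experiment) and lower regulon up-fractions (10–30%); all remaining
genes are a null background (log2FC ~ N(0, 0.3), padj ~ U(0,1)). DE
tables are generated directly rather than via simulated counts plus a
DE model, because the pipeline consumes DE results and never refits
them.

Confocal stacks paint ellipsoidal nuclei (semi-axes 3.5–5.5 µm) at
pairwise centre distances enforced by rejection sampling, blur each
plane with a 0.5 µm Gaussian and add clipped Gaussian noise. Poisson
shot noise, z-blur, illumination gradients and chromatic shifts are
deliberately omitted: the fixtures exist to test threshold-based
segmentation logic with computable expectations, and passing them
bounds algorithmic correctness, not real-microscope performance. One
known, quantified artefact: with a 0.5 µm blur on 3.5–5.5 µm nuclei the
Otsu mask sits near the 50% intensity contour, so boundary voxels are
blur-diluted and noiseless per-voxel means undershoot the painted truth
by roughly 8–11%. The tests assert this deficit stays within 15% and
that recovery is tightly linear (r > 0.99) — relative comparisons
between nuclei, which is what the intensity statistics use, are
unaffected.

All generators restore the caller's RNG state and derive their
randomness from an explicit seed; a global seed fans out to
per-generator child seeds so modules can be tested independently.

## Problem sizes and numerical conventions

The test and acceptance workloads use 100 solver instances of 4–12
nodes (the exact DP's comfortable range), 50 planted scenarios of
50–200 proteins and 5–10 TFs, a 20-nucleus stack at 0.3 µm/px over a
100×100×30 µm field, and 10 touching-pair fixtures at exactly 10 µm
separation. Objective comparisons use a 10⁻⁹ tolerance, dual growth a
10⁻¹² event tolerance. Degenerate inputs have defined behaviour: empty
input tables yield empty outputs with a warning; all-zero prize
instances yield the empty forest; constant image planes yield empty
masks; an empty measurement table is an error for fraction and
correlation statistics (there is no meaningful value to return).

## Limitations

No ILP or exact solver for large instances; no randomized-rerun
robustness ensembles (one deterministic solve); no identifier mapping
beyond case normalization; no GO enrichment; no deconvolution,
illumination correction beyond local Otsu, or nucleus tracking in
time. Conclusions about any *real* regulator require real data — the
planted-recovery results certify the pipeline's mechanics, not
biological findings.
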