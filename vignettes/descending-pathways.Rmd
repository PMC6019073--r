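---
title: "Quantifying descending-neuron projectomes: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying descending-neuron projectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnproj)
```

## The problem

Descending neurons (DNs) are the exclusive channel from an insect's brain
to the motor circuits of its ventral nerve cord (VNC). Anatomical surveys
of this population produce, per DN type, a compact annotation: which
brain and VNC compartments (neuropils) the cell innervates, and whether
each arbor is *smooth* (fine, postsynaptic-looking dendrites) or
*varicose* (beaded, presynaptic terminals — a morphology validated
against synaptotagmin labeling). Organized into matrices, these
annotations answer population-level questions: which brain regions drive
which motor neuropils, whether wing and leg control are segregated, and
how broadly individual DNs integrate or distribute information.

`dnproj` implements that quantitative layer as a reusable, tested
pipeline: catalog validation and I/O, polarity-filtered innervation
matrices, correlation-based hierarchical clustering, a bipartite
brain-to-VNC connectivity matrix with pathway ranking, census
statistics, anterior–posterior neurite density profiles, and a
synthetic-connectome generator whose planted structure lets every stage
be validated against known ground truth without any external data.

## Data model

A catalog row is one DN *type*: a unique bilateral pair, or a
*population* type counted as the largest number of near-identical cells
labeled by a single driver line (`n_pairs`). Type names follow the
grammar `DN` + soma-group letter (`a b c d g p x`) + two-digit index,
enforced by `validate_dn_name()`. Each type carries a laterality
(ipsilateral or contralateral descent relative to its soma), a
descending tract, and two polarity-code vectors over the brain and VNC
atlases.

Polarity codes are single characters (`N`/`S`/`V`/`B` for
none/smooth/varicose/both), optionally suffixed with an ordinal
intensity digit; bare digits `0/1/2` encode absent/sparse/dense for
fine-grained tables such as optic-glomerulus innervation. The codes are
compact, diff-friendly, and lossless under the CSV/JSON round trip
(`parse_catalog()` / `write_catalog()` is property-tested to be the
identity up to canonical ordering).

Two conventions are worth making explicit:

* **Cell-level weighting.** Catalogs store bilateral-pair counts, not
  per-side cells. "Cell-level" statistics weight each type by
  `n_pairs`, matching how population types are tallied in census
  figures; type-level statistics count rows.
* **Atlases.** The brain atlas is the standard insect-brain
  nomenclature (41 named compartments with the mushroom body split into
  its four parts, plus the gnathal ganglia). The VNC atlas defaults to
  the twelve compartments that are unambiguously derivable from the
  published figures — neck, wing, haltere, tectulum, lower tectulum,
  three leg neuromeres, AMN, VAC, mVAC, AS — because the full
  sixteen-name list was never enumerated in print; both atlases are
  user-extensible with `neuropil_atlas()`. Group labels (dorsal,
  tectulum, lower tectulum, leg, other; posterior slope, gnathal, ...)
  drive the pathway-level aggregation.

The descending tracts are the seven identifiable named bundles (DLT,
MDA, MTD, ITD, VLT, DLV, VTV); the additional unnamed tract is
represented as `"unknown"` and reported separately by
`tract_distribution()` rather than silently dropped.

## Innervation matrices

`build_matrix()` scores entry $(i, j) = 1$ when type $i$'s polarity at
neuropil $j$ matches the filter and its intensity reaches the
threshold. A `both` annotation satisfies the smooth *and* the varicose
filter — the region receives the two kinds of processes — and the
default intensity threshold of 1 counts sparse innervation (the
dense-only view is one argument away). Brain-side input maps use the
smooth filter; VNC-side output maps use the varicose filter, which is
also the direction the anatomy overwhelmingly shows. A smooth VNC
annotation is accepted but logged.

`neuropil_counts()` gives per-compartment totals under either
weighting, `innervation_breadth()` the row sums with mean and
population standard deviation, and `select_types()` conjunctive
filtering (e.g. types hitting wing *and* at least one leg neuromere).

## Clustering

The clustering stage is written from scratch because its exact
conventions are the analysis:

* **Distance.** $d = 1 - r$ with $r$ the Pearson correlation between
  binary innervation profiles, giving $d \in [0, 2]$. The $1 - r$
  transform is stated explicitly here because reported results are only
  comparable under a fixed choice.
* **Degenerate profiles.** A profile with zero variance (a compartment
  no DN innervates, or one every DN innervates) has no defined
  correlation. The default policy excludes such labels with a warning —
  the convention of omitting uninnervated regions — and an alternative
  assigns them maximal distance 2; silent coercion to $r = 0$ would hide
  data problems.
* **Linkage.** Unweighted average linkage (UPGMA): merge the pair of
  clusters $A, B$ minimizing
  $\bar d(A,B) = \frac{1}{|A||B|}\sum_{a \in A, b \in B} d(a,b)$ at
  height $\bar d(A,B)$, maintaining distances by the size-weighted
  Lance–Williams update
  $d(A \cup B, C) = \frac{|A| d(A,C) + |B| d(B,C)}{|A| + |B|}$, which
  keeps them exactly equal to the definition above. Unweighted (UPGMA)
  rather than weighted (WPGMA) averaging matches the common default of
  standard statistics toolboxes.
* **Ties.** When two candidate pairs share the minimal distance, the
  pair whose smallest member leaf indices are lexicographically least
  merges first. This makes results bit-reproducible across platforms.
* **Cuts.** `cut_dendrogram()` undoes merges above the cut (by count
  `k` or height `h`) and numbers clusters stably by leaf order.

Correctness is checked two independent ways in the test suite: against
a naive $O(n^3)$ oracle that recomputes every inter-cluster mean from
the original matrix at every step (200 random matrices, $n \le 12$),
and against the reference average-linkage implementation in base R's
`hclust`. Average-linkage heights are monotone non-decreasing, which is
asserted as an invariant and is what makes the merge list a valid
ultrametric tree for Newick export (`export_newick()`, via ape).

## The bipartite connectivity matrix and pathways

`connectivity_matrix()` counts, for every (VNC neuropil, brain
neuropil) pair, the DN types with smooth processes in the brain
compartment *and* varicose processes in the VNC compartment. Rows and
columns equal the grouped views (`group_counts_by_target()`,
`group_counts_by_source()`), an identity the tests verify on random
catalogs, together with the marginal bound
$C_{vb} \le \min(\text{col marginal}_b, \text{row marginal}_v)$.
Type-level weighting is the default (the published maps count DN
types); cell-level weighting is available. A DN innervating several VNC
targets contributes to each target's group — grouped totals are
deliberately non-exclusive.

`rank_pathways()` orders the nonzero entries (ties by label order), and
`aggregate_by_group()` sums the matrix into (brain group × VNC group)
blocks where the two direct pathways — posterior slope → dorsal
neuropils, GNG → leg neuromeres — dominate when present.

`convergence_index()` quantifies "convergent pathway" claims as the
normalized Shannon entropy of a target's brain-source distribution
(natural log, $0 \log 0 \equiv 0$, normalized by the log count of
active sources): 0 for a single-source target, 1 for perfectly uniform
convergence. Normalizing by active sources keeps the index comparable
across atlases of different size.

## Census statistics

`percent_round()` rounds half-up, not half-to-even: that is the
convention that reproduces printed worked percentages such as
46/131 → 35% and 121/190 → 64% from their printed numerators and
denominators. `coverage_vs_census()` maps soma groups onto census
clusters (anterior = a/b/c/d, posterior = p, gng = g); group x (soma
outside the brain) is excluded because a brain-surface census cannot
contain it. One published inconsistency is surfaced rather than
resolved: 22/41 anterior coverage rounds to 54%, while the printed
value is 51% (which corresponds to 21/41); the package simply computes
whatever catalog and census it is given.

## Axis profiles

`profile_along_axis()` counts neurite-labeled voxels in half-open bins
of fixed width (default 1 µm) along an anatomical axis, excluding soma
and axon labels so the profile reflects dendritic/terminal volume.
Two numerical conventions matter:

* Bins are $[k, k+1)$ µm from the volume origin, and each voxel is
  assigned by its center coordinate. Bins are *reported at their center
  positions*: with start labels, the center of mass of a discretized
  continuous density would be biased by half a bin, while center labels
  make it unbiased. The validation tests require the planted centroid
  of a 5000-voxel synthetic mask (spread 3 µm) to be recovered within
  0.5 µm, and it is, with room to spare.
* `center_of_mass()` uses raw counts. Peak-normalization
  (`normalize_profile()`) is a display transform and never enters the
  measurement.

`com_class_association()` formalizes the observation that
anterior–posterior dendrite position predicts dorsal- vs leg-neuropil
targeting: a Wilcoxon rank-sum statistic on the two classes' centers of
mass with a permutation p-value, enumerated exactly when
$\binom{n}{n_1}$ is small and Monte Carlo otherwise. The statistic is
an extension beyond a graphical trend display and is labeled as such in
its output. Its exact p-values are cross-checked against
`wilcox.test(exact = TRUE)` in the tests.

## The synthetic generator

`generate_catalog()` draws catalogs from a planted architecture chosen
to emulate the statistical structure the analyses assume:

* four pathway classes — `dorsal_direct` (sources IPS/SPS, targets
  neck/wing/haltere), `leg_direct` (source GNG, targets the three leg
  neuromeres), `convergent` (per-type random source sets of breadth
  $K = 6$, targets tectulum/lower tectulum), and a diffuse `other`
  class — with in-block innervation probability `p_in = 0.9` and
  background `p_bg = 0.05`;
* default class sizes 30/30/25/13 (98 types), population fraction
  highest in the dorsal-direct class (population types are
  predominantly dorsal-projecting), pair counts
  $1 + \mathrm{Pois}(4.6)$ so roughly 20 population types carry roughly
  112 cells;
* ipsilateral probability 0.64; soma groups biased per class (posterior
  for dorsal-direct, gnathal for leg-direct); MTD-dominant tract use
  for the dorsal pathway and a broad tract spread for the leg pathway.

Each pathway class consumes its own seeded substream, so adding a class
never perturbs the draws of existing ones, and identical (config, seed)
pairs give identical catalogs. The generator emulates block structure,
marginal rates and label correlations; it does **not** emulate spatial
sub-neuropil geometry, correlated annotations between neighboring
compartments, segment-wise tract anatomy, or annotation noise of human
raters — so passing recovery tests demonstrate the pipeline's
correctness on data with planted structure, not the biological fidelity
of any particular clustering of real data.

Recovery is scored with the adjusted Rand index implemented from its
contingency-table definition (`recovery_score()`), cross-checked in the
tests against an independent pair-counting enumeration and against
`mclust::adjustedRandIndex`. Under the recovery conditions (30 + 30
direct-pathway types, `p_in = 0.9`, `p_bg = 0.05`, 100 seeds), cutting
the VNC-output dendrogram at $k = 2$ attains ARI ≥ 0.9 in well over 95%
of seeds, and the two largest group-aggregated connectivity blocks are
the planted direct pathways.

Name-grammar capacity is one deliberate constraint: two-digit indices
cap each soma group at 99 types, so marginal-convergence tests sample
450 types spread over the seven groups rather than many thousands; the
binomial check on the 0.64 ipsilateral rate uses a 99% interval at that
size.

## Problem sizes used in validation

The shipped test suite and acceptance script run: 200 random
dissimilarity matrices ($n \le 12$) against the naive linkage oracle;
100 synthetic catalogs of 60 types for planted-pathway recovery; 100
random 12-type catalogs for bipartite consistency; synthetic voxel
masks of 5000 neurite voxels for centroid fidelity. These sizes were
chosen as the smallest at which the properties under test are
statistically meaningful.

## Known limitations

* The per-type annotation table deposited with the original study is
  not redistributable here; the matrix statistics that depend on it
  (mean innervation breadth, GNG output share, wing-plus-leg rarity)
  are implemented and tested on synthetic data, and recompute directly
  via `parse_catalog()` + `innervation_breadth()` once a transcription
  is placed at `inst/extdata/published_dn_catalog.csv`.
* Volumes are accepted as in-memory arrays or TIFF stacks; NRRD input
  is not implemented.
* No statistical significance testing of pathway enrichment is
  provided, and positions within a neuropil are not modeled.
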