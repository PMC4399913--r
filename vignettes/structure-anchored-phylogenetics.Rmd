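---
title: "Structure-anchored phylogenetics of 7TM receptors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-anchored phylogenetics of 7TM receptors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrnet)
```

This vignette is the package's account of its methods: the models, the
parameters that matter, the numerical choices, what the synthetic-data
generators do and do not emulate, and the known limitations.

## Why structure-anchored alignment

Rhodopsin-like G protein-coupled receptors diverge far beyond the reach of
ordinary multiple sequence alignment, while their seven-transmembrane fold
is conserved. The Ballesteros–Weinstein (BW) scheme turns that structural
conservation into a cross-receptor coordinate system: the most conserved
residue of helix $x$ is labelled $x.50$ and a residue $k$ positions C- or
N-terminal of it is $x.(50+k)$ or $x.(50-k)$, bounded by the helix span.
`assign_bw_numbers()` applies exactly this offset rule; helix spans and
anchors are *inputs* (from structural annotation or configuration), never
guessed from sequence. Helix alignment blocks then have one column per BW
label in the union over receptors — a receptor lacking a label gets a gap
in that cell and nowhere else, which is the only interpretation of
anchored alignment that introduces no free parameters.

Loops are genuinely sequence-variable, so they are aligned as sequences:
`align_loop()` uses a deterministic progressive aligner — P distances from
pairwise global alignments, a Neighbor-Joining guide whose agglomeration
order drives profile–profile merges, BLOSUM62 scoring, and affine gap cost
$\mathrm{open} + \mathrm{extend}\cdot L$ with defaults $10 + 1\cdot L$.
Column scores between profiles are average-of-pairs substitution scores
over non-gap residues; dynamic-program ties resolve match, then gap in the
second profile, then gap in the first, and profile orientation is
canonicalised by taxon name, so the output is invariant to input order.
Loop boundaries are defined as (end of helix $k$)+1 … (start of helix
$k{+}1$)−1. The thirteen blocks concatenate in membrane topology order
TM1, il1, TM2, el1, …, TM7; stripping gaps from any composite row returns
the receptor's 7TM sequence unchanged, a property the tests assert.

## Substitution model and distances

All likelihood machinery uses the JTT empirical amino-acid model. The
published exchangeabilities $R$ and frequencies $\pi$ ship as a plain-text
table in `inst/extdata/`; the rate matrix is $Q_{ij} = R_{ij}\pi_j$ with
rows summing to zero, normalised so $-\sum_i \pi_i Q_{ii} = 1$ — branch
lengths are therefore expected substitutions per site. Because the model
is reversible, $P(t) = e^{Qt}$ is computed through the symmetric
$\pi^{1/2}$-similarity transform with a cached eigendecomposition; rows
are clamped non-negative and renormalised to absorb rounding at the
$10^{-15}$ level.

Two distances feed the tree and network stages:

* `p_distance()` — mismatches over compared sites, strict pairwise
  deletion; ambiguity codes count as gaps. Used for binding-pocket
  profiles, where sequences are too dissimilar for model-based distances
  to be stable.
* `ml_distance()` — the branch length maximising
  $\sum_i \log(\pi_{a_i} P_{a_i b_i}(t))$, a 1-D bounded Brent search on
  $[0, 10]$ at tolerance $10^{-6}$. Pairs whose likelihood is still rising
  at the bound are saturated: the value is capped at 10 with a warning.
  The cap matches the branch-length bound used in tree optimisation.

## Trees

`neighbor_joining()` implements the standard Q-criterion agglomeration.
Negative branch-length estimates are clamped to zero and ties are broken
lexicographically by the joined clusters' smallest member labels, so runs
are deterministic even on degenerate (all-equal) inputs. NJ is exact on
additive metrics; the tests verify this against four-point-condition
quartet oracles and exhaustive topology enumeration for small $n$.

`ml_tree()` maximises the Felsenstein pruning log-likelihood
(site-pattern compression, per-node scaling, gaps as missing data) by hill
climbing over topologies. Branch lengths are optimised per edge by Brent
on $[10^{-8}, 10]$: for each edge the conditional likelihoods of the two
incident subtrees are computed once, making each 1-D evaluation a single
$20\times20\times\text{patterns}$ product. Candidate rearrangements (all
NNI, or all SPR prune/regraft combinations; unlimited SPR radius at the
package's intended scale of a few dozen taxa) are first *screened* at
their inherited branch lengths; the top five screened candidates then
receive a two-sweep local re-optimisation of the branches touched by the
move, the first improving one is accepted, and an accepted move triggers a
full two-sweep re-optimisation. Screening was chosen over re-optimising
every candidate because it preserves the two properties that matter —
monotone likelihood and determinism — at an order of magnitude less work;
the search finishes with a tight three-sweep polish at tolerance
$10^{-7}$. Following the practice of keeping the better of the two
optimisation orders, the default schedule runs NNI-then-SPR and
SPR-then-NNI and returns the higher-likelihood tree.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds a tree per replicate (NJ by default; full ML search optionally)
and counts, for each internal split of the original tree, the replicates
containing it. Splits are canonicalised as the sorted side not containing
the lexicographically first taxon, which makes support maps invariant to
taxon order. Replicate counts are a parameter: typical studies use
hundreds to a thousand replicates (e.g. 1000 for a small curated set, ~500
when each replicate requires a full ML search on a large set).

## NeighborNet split networks

`neighbornet_ordering()` implements the agglomerative circular-ordering
scheme: clusters (chains of one or two active nodes) are selected with the
net-divergence-corrected criterion $d(A,B) - r(A) - r(B)$ on cluster-mean
distances; within the selected pair, the closest node pair is chosen by
the analogous criterion with the two clusters' nodes treated as
singletons; three-node chains are immediately reduced to two composite
nodes with the published weights $2/3$ and $1/3$
($d(u,\cdot) = \tfrac23 d(x,\cdot) + \tfrac13 d(y,\cdot)$, and
$d(u,v) = \tfrac13(d_{xy}+d_{xz}+d_{yz})$). All ties break
lexicographically. `nnls_split_weights()` then solves
$\min \lVert A w - d \rVert_2$ subject to $w \ge 0$ over all $n(n-1)/2$
circular splits of the ordering (Lawson–Hanson active-set NNLS via
`pracma::lsqnonneg`), and drops splits below $\varepsilon = 10^{-9}$ —
the threshold exists only to remove numerically zero splits, mirroring
standard split-network software. On a circular-decomposable metric the
fit is exact and unique; on an additive metric the retained splits are
exactly the tree's splits with weights equal to branch lengths, which is
the "perfect phylogeny" behaviour the tests assert. Only split *sets* are
compared across variants (`compare_split_systems()`, Jaccard index on
non-trivial splits); weights depend on implementation details of the
solver and are not a robust comparison target.

## Scaling to a full receptor repertoire

Very large repertoires defeat direct ML inference, so `run_repertoire()`
implements a hierarchical decomposition. Sequences longer than `max_len`
(default 1500 residues) are removed and logged. Then, iteratively: the
current set is (optionally re-)aligned, an NJ tree built, and the
*maximal crystal-free subtree* whose leaves lie farthest — by tree path
distance, since leaves of a tree are being extracted — from any
crystal-structure sequence is split off as a group. The published
procedure's stopping rule is qualitative, so the loop is capped (default
seven extractions) and every remaining non-crystal sequence is then
partitioned by nearest template; this cap-then-partition rule guarantees
termination and the partition property (every input ends in exactly one
group or the removal log). Each group's template is the crystal sequence
minimising the *median* distance to the group ("closest to the majority";
mean and mode are defensible too — median was chosen for robustness to a
single outlier member). `trim_to_7tm()` maps the template's TM1-start and
TM7-end columns onto each query through a global BLOSUM62 alignment and
keeps the query substring between them — terminal extensions are removed
exactly, internal insertions are kept. `build_merged_sets()` finally adds
the cross-class crystal 7TM sequences to each class set so the connecting
node between receptor classes can be located in either tree. Full
re-alignment between iterations is the default; `realign = FALSE` reuses
the alignment for speed, which the tests use on already-aligned simulated
sets.

## Binding sites and volumes

`extract_ligand_contacts()` returns every protein residue with a heavy
atom within $r_c$ of any ligand heavy atom; waters are never ligand
probes. `extract_sodium_site()` uses the ion *plus its bound waters* as
the probe set, so a residue touching only a water is included. No
universal contact cutoff exists in the field; the default is
$r_c = 4.0$ Å heavy-atom/heavy-atom, it is a parameter everywhere, and
the value used is recorded in the result and in stage metadata.
Non-helical contacts keep a loop tag (il1…el3) and sort after helix
positions in `build_pocket_profiles()`, whose position index is the
ordered union over receptors. `variant_without_positions()` and
`shared_positions()` support the robustness pattern of removing named
positions (a dominant contact such as Asp3.32, or the positions shared
between the ligand and sodium sites) and checking that the network's
split set is unchanged.

`superpose_7tm()` pairs Cα atoms across receptors by shared BW labels and
solves the least-squares rigid superposition with the Kabsch/SVD
construction (proper rotation enforced). `ligand_volume()` marks every
voxel whose centre lies within `atom_radius` (default 1.7 Å, the carbon
van der Waals radius) of any transformed ligand heavy atom, on a global
lattice of spacing $\Delta$ (default 0.5 Å) anchored at the origin —
anchoring makes grids with equal spacing automatically commensurate, so
`overlap_region()` is an exact voxel-set intersection with volume
$|\text{voxels}| \cdot \Delta^3$. At $\Delta = 0.25$ Å a single-atom
sphere is within half a percent of $\tfrac43\pi r^3$ and halving $\Delta$
moves the estimate by well under 2 %. `el2_occupancy()` reports the
fraction of a residue range's heavy atoms inside the occupied voxels —
the operational form of "the loop matches the region claimed by the
ligand volumes", since no numeric volume is printed in the literature to
compare against.

## Synthetic data: what it emulates, and what it does not

`simulate_alignment()` draws root states from the JTT equilibrium and
evolves them through $P(t)$ along each branch — exactly the generative
model the inference assumes. `make_family_set()` separates family
ancestors by 1.0 expected substitutions/site and members from their
designated template by 0.1 by default, a 10-fold contrast comparable to
the between- versus within-family divergence of real receptor families.
`make_toy_bundle()` builds ideal α-helices (3.6 residues/turn, 1.5 Å
rise, 2.3 Å helix radius) on a seven-fold circle of radius 11 Å with
alternating direction, distinctive anchor motifs (e.g. R at 3.50, Y at
7.50), Cβ pseudo-atoms pointing radially so anchor-facing side chains
line the lumen, and probe atoms planted at an exact distance from chosen
residues' Cβ. The generator *verifies by construction* that no unplanted
residue comes within `pocket_distance + margin` of any probe, so planted
sites are exactly recoverable at the planting cutoff — recovery tests
therefore exercise the extraction pipeline, not luck.

Passing tests on these generators demonstrates internal correctness —
the statistics, search and geometry do what they claim under the model's
own assumptions. They do not demonstrate robustness to what real data
adds: among-site rate variation and heterotachy, alignment error in
loops, non-ideal helix geometry, alternative side-chain rotamers, or
crystallographic artefacts. Runs on real coordinate sets remain a
documented workflow whose inputs (helix spans, anchors, ligand
selections, class labels) are supplied in configuration.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 10-taxon networks
(20 replicates), additive metrics for $n = 4\ldots8$ with exhaustive
enumeration up to $n = 6$, pairwise ML-distance recovery at 20 000 sites
for $t \in \{0.1, 0.5, 1.0\}$ over 10 seeds, 4-taxon exhaustive ML
oracles at 400 sites, 8-taxon strong-signal searches (internal branches
0.3, terminal 0.15) at 800 sites over 10 seeds, bootstrap at 100
replicates on 2000 sites, and voxel grids at $\Delta = 0.25$ Å — sizes
chosen so the whole battery completes in minutes on one core while
keeping every check's expected failure probability negligible.
Remaining numeric constants: branch bounds $[10^{-8}, 10]$; Brent
tolerances $10^{-4}$ during search sweeps, $10^{-7}$ for the final
polish, $10^{-6}$ for pairwise distances; NNLS pruning $10^{-9}$;
likelihood scaling per internal node. Degenerate inputs (all-gap
columns, empty loops, zero-length branches, all-equal distances) are
defined behaviours with tests, not errors.

## Known limitations

* No among-site rate variation (no Γ rates) and no model selection — the
  single empirical model mirrors the workflow this package reproduces.
* The ML search is a local hill climb; the two-schedule strategy and SPR
  neighbourhood make it exact on 4 taxa and reliable on strong signal,
  but very large or weak-signal problems should use a dedicated ML
  engine and can re-enter this pipeline at the network stage.
* The repertoire stopping rule is a cap-then-partition operationalisation
  of a qualitative procedure; group boundaries near the cap can differ
  from other reasonable rules, though the partition property always
  holds.
* Pocket comparisons use uncorrected P distances by design; an
  ML-distance variant exists to reproduce the known instability
  (spreading internal nodes) on such short, dissimilar profiles.
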