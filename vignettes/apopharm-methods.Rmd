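---
title: "Ligand-free pharmacophore elucidation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-free pharmacophore elucidation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(apopharm)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, the numerical choices that were
genuinely open, and what the synthetic-data tests do and do not establish.

## The problem

A pharmacophore encodes the favorable protein–ligand interactions of a
binding site as a small set of typed 3D points — hydrogen acceptor/donor,
hydrophobic, aromatic, negative and positive ion (class codes 0–5, in that
order, throughout the package). With a tolerance radius per point it becomes
a geometric query: a molecule matches if some injective, class-consistent
assignment of query points to molecule feature points can be realized by a
proper rigid motion within the radii. Good pharmacophores are usually read
off a bound ligand; this package addresses the harder setting where only the
apo protein structure is available.

The pipeline has two learned stages: a multilabel **site predictor** that
scores candidate interaction points on the gridded site, and a **Q-learning
agent** that assembles a subset of the candidates into a pharmacophore by
growing a protein–pharmacophore graph, rewarded by retrospective screening
performance (F1) on an active/decoy library.

## Site prediction

**Voxel encoding.** The local environment of a query point is a cubic box of
edge 9.5 Å at 0.5 Å resolution (20 grid points per edge, the
`edge/resolution + 1` convention), with eight typed heavy-atom channels
(aliphatic/aromatic carbon, donor-capable/other nitrogen, acceptor/other
oxygen, sulfur, other heavy; hydrogens contribute nothing). Each atom
deposits a Gaussian of width σ = vdW/2, *shifted and truncated at 4σ* so the
density is continuous at the cutoff. The shift matters numerically: with a
hard truncation the O(h) quadrature error from the density jump breaks the
analytic mass identity at 0.5 Å spacing, whereas the continuous kernel's
grid sum reproduces the closed-form integral to ~10⁻⁴ relative — this is the
mass invariant the test suite asserts at 10⁻³.

**Reference model.** The predictor contract is: six independent logistic
confidences (multilabel, not a simplex — a hydroxyl is donor *and*
acceptor) plus the final hidden layer as a 32-dimensional embedding of the
local environment. The reference trainable model is a compact volumetric
network: 4³ average pooling over the grid, then dense layers
(1000→64→32→6), trained with per-class binary cross-entropy by Adam. The
architecture is deliberately small — it trains on a CPU at fixture scale —
and configurable; the embedding width (32) and the multilabel contract, not
the layer inventory, are what downstream stages depend on.

**Adversarial negatives.** At inference a predictor must not fire where
physics forbids an interaction. Grid points whose fired class (confidence >
0.5, the logistic midpoint) either clashes with the protein (nearest heavy
atom < 2 Å) or lacks its complementary protein group within the class cutoff
become all-zero-label retraining samples. The complementary-group distance
table is: acceptor→donor group 4 Å, donor→acceptor 4 Å, hydrophobic→patch
5 Å, aromatic→ring 6 Å, negative ion→cationic 5 Å, positive ion→anionic 5 Å.
The 4 Å hydrogen-bond cutoff is the table's anchor; the charged/aromatic
values are standard interaction ranges and, like everything in the table,
config-overridable (`default_comp_dist()`). A point firing several classes
is flagged if *any* fired class is unsupported; the conservative reading
costs a few valid multilabel points but never retains a spurious one.

**Functional-group annotation.** Complementary groups come from a
residue/atom-name lookup (`default_group_rules()`): backbone N–H donors
(except proline) and carbonyl acceptors; Ser/Thr/Tyr hydroxyls as both
donor and acceptor; Asn/Gln amides; Asp/Glu carboxylates merged into one
anionic site (each O still an acceptor); Lys ammonium and Arg guanidinium
cations (with N–H donors); His/Phe/Tyr/Trp rings as single centroid sites
(one site per fused system); apolar side-chain carbons as per-atom
hydrophobic patches. This is standard residue chemistry; the table is a
parameter, not a constant.

## From confidence grids to features

The site is gridded at 0.5 Å and the predictor evaluated at every point.
Per class: binarize at 0.5 (strict `>`, so an uninformative constant-0.5
field yields nothing), label 26-connected components (diagonal contact at
0.5 Å spacing is sub-bond-length, so corner contact should connect), then
let the protein chemistry decide how many features a blob contributes: for
each complementary group site within the class cutoff of the component, emit
the component's highest-confidence voxel within that cutoff of the site.
Duplicate choices collapse; confidence ties go to the lexicographically
smallest voxel index. Finally, per class, average-linkage agglomerative
clustering merges points until the smallest between-cluster average distance
exceeds 1.5 Å; each cluster becomes one feature at its unweighted centroid,
carrying the maximum member confidence and the predictor embedding evaluated
at the centroid.

The clustering is hand-rolled rather than delegated to `stats::hclust`
because the merge order must be deterministic under ties: the pair with the
smallest (distance, then smallest member index) merges first. `hclust`'s
tie-breaking is input-order dependent, which changes the result on exactly
the kind of collinear, equally spaced configurations that matter here
(0, 1.2, 2.4 Å must resolve to clusters {0, 1.2} and {2.4}: the 0–1.2 pair
merges first, and the merged cluster's average distance to 2.4, which is
1.8 Å, exceeds the threshold). `hclust`/`cutree` still serves as the
independent oracle on tie-free random data in the tests.

## Screening and metrics

The matcher is a Pharmit-style hard filter: all query features must be
satisfied. The search enumerates injective class-consistent assignments in
lexicographic order, pruned by pairwise distance compatibility
(|d_pharm(i,j) − d_mol(a,b)| ≤ r_i + r_j — a sound bound: any feasible
placement satisfies it), and verifies survivors by Kabsch least-squares
superposition restricted to proper rotations (molecules are physical; mirror
matches are wrong). Feasibility means every per-feature residual ≤ its
radius (boundary inclusive); receptor exclusion, when enabled, rejects
placements with any molecule atom strictly within 1.5 Å of a protein heavy
atom, and the search then continues to other assignments. Default feature
radius is 1.0 Å — a deliberate, prominent default since screening tolerances
are study-specific; per-point radii in pharmacophore JSON files override it.
Stored direction vectors are parsed and preserved but ignored by the
matcher. Multi-conformer molecules are multiple records sharing an id,
matched if any record matches.

Metrics: precision, recall, F1 (0/0 defined as 0, so useless pharmacophores
earn reward 0 rather than an exception), enrichment factor = precision /
active fraction, and optionally F1 normalized by the best F1 achievable from
reference features. The enumeration baseline screens every feature subset of
sizes 3–5 (or a uniform seeded sample of `cap` subsets when the count
explodes) and reports best/mean F1 — the "random selection from ligand
features" yardstick.

## The assembly MDP and Q-learning

The state is a heterogeneous graph: selected feature nodes, protein heavy
atoms within δ_fp = 5 Å of any of them, feature–feature edges within
δ_ff = 8 Å, feature–protein edges within δ_fp. Actions either add a feature
within δ_ff of the current graph or select the current graph itself,
terminating. Rewards are the screening F1 of the resulting graph's
pharmacophore, gated to 0 below 3 features (the matcher's minimum); a
stricter mode gates termination at 4 features when more selective
pharmacophores are wanted. Episodes start from a single-feature seed graph —
sampled uniformly during training, taken from the top-confidence features at
inference — since the construction process needs *some* origin and the
confidence ranking is the natural inference-time prior.

**Value network.** The Q-function must be a scalar invariant under rigid
motions and node relabelling. Geometry therefore enters only through
distances along graph edges: each feature node concatenates its class
one-hot, its 32-d environment embedding, radial-basis sums of its
feature–feature edge distances, and radial-basis sums of its
feature–protein edge distances split by protein element group; node vectors
are sum-pooled with global counts and passed through a dense head
(58→64→32→1). This is one round of distance-kernel message passing with a
deep readout — invariant by construction (the tests assert |ΔQ| ≤ 10⁻⁴ under
random proper rigid motions and permutations; observed deviations are at
machine precision).

**Training.** Standard deep Q-learning: ε-greedy episodes under the
exponential decay ε(t) = ε_T + (ε_0 − ε_T)e^(−t/α) (defaults ε_0 = 0.9,
ε_T = 0.05, α = 100), experience replay (capacity 5000, batch 32), Adam at
3·10⁻³, squared TD error against a target network synchronized every 100
updates, discount γ = 0.99. Targets: y = r for terminal and dead-end
transitions; otherwise y = r + γ·max over the next proposal set (candidates
plus the terminal option) under the target network. Rewards and graph
descriptors are memoized per feature subset, which makes the screening
reward affordable: an episode's reward calls collapse to at most one library
screen per *new* subset. A divergence guard aborts on non-finite loss.
Ensembles (default 5 members) differ only in seed.

**A consistency caveat, and why the tabular check runs at γ = 0.** The value
network conditions on the graph alone, but a graph plays two roles: the
*arrival* target r + γ·max Q(proposals) and the *terminal* target r. For
γ > 0 these disagree on any graph that episodes both pass through and
terminate at, so no graph-conditioned function satisfies both exactly — the
trained Q is a visitation-weighted compromise, which is fine for *policy*
quality (the ordering that drives greedy rollouts is preserved; the planted
optimum's value is inflated relative to its supersets in exactly the helpful
direction) but not for pointwise agreement with a tabular solution. At γ = 0
both target types coincide at y = r and the scheme is exactly
self-consistent, so the package's tabular agreement check — trained Q within
0.05 of exact value iteration at visited state–action pairs on a fully
enumerable 5-feature task — runs in that regime (observed error ~10⁻³–10⁻²).
Policy recovery is checked separately at the full γ = 0.99 defaults.

**Reachability of the planted optimum.** Actions only add features, so a
greedy rollout can end *exactly* at a 3-subset only if its seed belongs to
it. The policy-recovery check therefore draws its 10 rollout seeds (with
replacement) from the planted optimal triple; recovery from all of them
demands that the network has learned the full construction path, not just
the terminal state. The synthetic task mirrors intended usage by giving the
planted triple the top predictor confidences, so confidence-ranked seeding
at inference can reach it.

## Synthetic data: what it emulates, and what it does not

`make_pocket()` plants n (default 4) interaction sites ≥ 4 Å apart in a
12 Å box, with distinct classes (sampled without replacement while n ≤ 6),
one complementary protein group 2 Å from each site *pointing away from the
other sites*, and inert scatter atoms. The away-pointing placement plus
distinct classes guarantees no site can borrow a neighbour's group
(cross distances stay above the 4 Å hydrogen-bond cutoff), so the extraction
closed loop — exactly n features, correct classes, centroids within 0.75 Å —
is a property of the method, not of generator tuning. The pocket's oracle
predictor is a closed-form confidence field: per-class Gaussian bumps
(σ = 0.8 Å) at the planted sites plus a smooth deterministic noise field of
amplitude 0.05 (a sinusoid with pocket-specific random frequencies —
deterministic so that grid evaluation stays a pure function).

`make_library()` builds actives as jittered (σ = 0.3 Å), rigidly moved
copies of the planted features and decoys by class shuffling, geometric
perturbation, or full randomization — every molecule *verified* against the
package's own matcher at generation time (resampled until the label is
certified), making the matcher the single source of truth rather than an
analytic argument. `make_unique_optimum_task()` packs 8 features inside
δ_ff (every subset reachable), gives actives exactly the planted triple's
three features — so any other size 3–5 subset scores F1 = 0 (a 4-feature
query cannot injectively map into a 3-feature molecule) — and certifies
uniqueness by exhaustive enumeration of all 182 subsets.

What passing these tests shows: the geometry, search, clustering, MDP and
learning machinery are correct and the agent can discover a planted
combinatorial optimum from screening reward alone. What they do not show:
performance on real binding sites, where confidence fields are not Gaussian
bumps, complementary chemistry is ambiguous, actives are congeneric and
noisy, and the best pharmacophore is not unique. The generators make no
attempt at physically realistic protein geometry or conformer ensembles.

## Parameters at a glance

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `box_edge` / `resolution` | 9.5 / 0.5 | Å | predictor input cube and grid spacing (20 points/edge) |
| `embedding_size` | 32 | – | final-hidden-layer width; feature embedding length |
| `binarize_threshold` | 0.5 | – | grid binarization (strict >) |
| `cluster_merge_dist` | 1.5 | Å | average-linkage merge criterion |
| `comp_group_dist` | 4/4/5/6/5/5 | Å | per-class complementary-group cutoffs |
| `d_clash` | 2.0 | Å | adversarial clash distance |
| feature `radius` | 1.0 | Å | matcher tolerance per feature (JSON overrides) |
| `r_excl` | 1.5 | Å | receptor-exclusion clash radius (strict <) |
| `delta_ff` / `delta_fp` | 8 / 5 | Å | graph edge/admissibility radii |
| `min_features` | 3 (or 4) | – | terminal gating and reward gating |
| `gamma` | 0.99 | – | reward discount |
| `ensemble_size` | 5 | – | independently seeded Q-networks |
| ε schedule | 0.9 → 0.05, α = 100 | episodes | exponential exploration decay |

## Numerical choices and degenerate inputs

Duplicate features (same class within 0.1 Å) are rejected at pharmacophore
construction to keep graphs simple. Matching uses a 10⁻⁹ slack on the radius
boundary so that exact-copy matches survive floating point. F1 and precision
define 0/0 as 0. Component ordering, point selection and cluster merging all
break ties lexicographically, so every stage is deterministic and
permutation-invariant. Boxes are specified by explicit corners or as a
reference point set's bounding box plus 4 Å padding. All generators and
training loops take explicit seeds; there is no hidden global state beyond
R's RNG, which every entry point sets.

Problem sizes in the shipped tests and acceptance script — 200 matcher
instances against a brute-force oracle, 20 pockets with 4 sites, 8-feature
RL tasks with 60-molecule libraries, 300-episode single-member trainings —
were chosen as the smallest sizes at which each property is decisively
exercised, and run end to end in a few minutes on one CPU.

## Known limitations

- The functional-group lookup and the per-class distance table are sensible
  defaults, not fitted constants; real applications should review them.
- Feature direction vectors are stored and round-tripped but not matched.
- The reference predictor is a small pooled volumetric network; at real
  PDB scale a deeper 3D CNN (and GPU training) would be appropriate. The
  package's contracts (multilabel confidences + 32-d embedding) are
  model-agnostic, so such a model can be dropped in.
- The Q-value's terminal/arrival ambiguity discussed above is inherited
  from conditioning the value on the graph alone; an action-conditioned
  head would remove it at the cost of a different inference interface.
- mmCIF input, altloc handling beyond "first", and protonation-state
  prediction are out of scope.
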