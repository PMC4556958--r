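---
title: "Combinatorial pharmacophore modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial pharmacophore modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combipharm)
library(dplyr)
```

## The model

Transporter inhibition is rarely explained by a single binding mode. A
combinatorial pharmacophore (CP) model represents a classifier as an
unordered set of 3 or 4 pharmacophore hypotheses; a molecule is predicted
active when it matches **any** member (the union rule). Each member is
intended to capture one interaction pattern — e.g. a small hydrophobic
inhibitor binding a deep substrate pocket and a large, ring-rich one
lodging in a central cavity produce different hypotheses, and the union
recovers both populations while a single hypothesis cannot.

A k-site hypothesis consists of

* `sites` — an ordered multiset of feature letters from {A, D, H, N, P, R},
* `dist` — a k×k symmetric inter-site distance matrix in Å (zero diagonal,
  triangle inequality enforced; for k = 3 the angles follow from the
  distances, for k = 4 the distances fix the geometry up to chirality),
* `tol` — one scalar matching tolerance per hypothesis, in Å.

Matching is *distance-based*: no superposition is computed. A conformer
matches when some injective, type-consistent assignment of feature points
to sites satisfies |d~ij~(features) − d~ij~(hypothesis)| ≤ tol for every
site pair. Because only internal distances enter, matching is invariant
under rigid motion by construction, and the assignment search is exact
(complete enumeration with pruning) for k ≤ 4. Among valid assignments we
report the one minimizing the root-mean-square of the k(k−1)/2 pairwise
deviations; ties break on the lexicographically smallest assignment so
results are reproducible. Chirality is deliberately ignored — a
hypothesis and its mirror image are equivalent under distance matching.

## Feature perception

Features are perceived from a heavy-atom molecular graph with a versioned
rule table (`feature_definitions()`, shipped as YAML so it can be audited
or replaced). All rules apply the pH 7.4 convention: carboxylic,
sulfonic and phosphonic acids count as ionized, aliphatic amines and
amidine/guanidine groups as protonated. Per type:

* **R** — one point per aromatic ring (5–7-membered, perceived rings), at
  the ring centroid.
* **N** — carboxylate/sulfonate/phosphonate groups (point at the group
  centroid) and any explicitly anionic atom.
* **P** — aliphatic amines (excluding anilines and amides, which are not
  protonated at pH 7.4), amidine/guanidine carbons (group centroid),
  and explicitly cationic atoms.
* **A** — neutral non-aromatic oxygens; nitrogens without attached
  hydrogens that are neither amide nor claimed by a P group.
* **D** — N/O/S with at least one attached hydrogen, neutral and
  unclaimed.
* **H** — connected components of carbons whose neighbours are only
  carbon, hydrogen or halogen (halogens included), one point per
  component at its centroid.

Two overlap rules prevent double counting inside k-site tuples: atoms
claimed by a charged group (N/P) are excluded from A and D, and aromatic
atoms never count as hydrophobic (an aromatic ring yields R only).
Positions are always arithmetic centroids of the contributing atoms, in Å.

## Conformers

Conformer ensembles must be bit-reproducible for a fixed seed — the match
matrix, and with it every downstream count, depends on them. General
force-field embedders do not offer that guarantee, so the package builds
an idealized geometry itself: covalent-radius bond lengths scaled by bond
order, ideal angles from a simple hybridization guess, planar aromatic
rings traced ring-by-ring, near-chair saturated rings, and a
deterministic steric fallback plus a closure-refinement pass for fused and
bridged systems. The ensemble is then generated by torsion driving on the
acyclic single bonds: the 60°-step grid is enumerated exhaustively when it
is small (≤ `grid_cap`, default 1296 settings), otherwise sampled with the
supplied seed; clashing candidates are rejected and near-duplicates pruned
by the RMSD of sorted interatomic-distance vectors (default 0.5 Å). The
cap of 1000 conformers per molecule is the conventional ensemble budget
for this protocol. These geometries are idealizations: they carry no
force-field energetics and approximate ring puckering, which is adequate
for centroid-level feature geometry but not for conformational energy
analysis.

## Hypothesis generation

Every k-subset (k ∈ {3, 4}) of the feature points of every conformer of
every active is reduced to a canonical form: sites ordered so the type
letters are sorted and, among type-preserving orders, the upper-triangle
distance vector is lexicographically smallest. Tuples are grouped by
discretizing that vector into bins of `bin_width` (default 1.0 Å — the
same order as the matching tolerance, so geometries that would match the
same molecules land in the same cell). Adjacent-bin duplicates are merged
*before* the support quota is applied: exact recurring geometries
frequently sit on bin edges, and counting support per raw cell would
split them. Each surviving group becomes a hypothesis whose geometry is
the medoid tuple (minimum summed distance-vector distance; deterministic
tie-breaks), named by its sorted letters plus an index when several
geometries share a type multiset (`HHR1`, `HHR2`, …). The whole procedure
is invariant to the input order of the actives.

The support quota `min_actives` defaults to half the actives — demanding
*all* actives share a geometry is unrealistic for noisy data, while a
tiny quota floods the pool with coincidences.

## Scoring, filtering, selection

* **Survival** — fraction of actives matched, in [0, 1].
* **Survival-inactive** — survival − λ · (fraction of inactives matched),
  λ ≥ 0, default 1.0: one matched inactive cancels one matched active.
* **Selectivity** — −log10((n~matched~ + 1)/(N + 1)) over a reference
  population regardless of labels (default: the full library; an external
  decoy set can be supplied). The add-one pseudocount keeps the score
  finite; 0 means ubiquitous, 2 means ~1 % of molecules match.

Filtering is two-stage: thresholds on survival-inactive (default 0) and
selectivity (default 0.5, i.e. a hypothesis matched by less than about a
third of the population), then the `inactive_match_top_k` hypotheses with
the fewest inactive matches (default 27, echoing the pool size of the
protocol this package implements). Ties break on higher
survival-inactive, then id.

All 3-/4-member subsets of the pool are then enumerated — never sampled —
and scored on the calibration set; the model with the highest balanced
accuracy wins. BACC = (SE + SP)/2 is the selection criterion because
inhibitor screens are heavily imbalanced and raw accuracy rewards the
trivial all-negative classifier. Equal BACC breaks on higher SE first
(the point of the combination is recovering true actives), then fewer
members, then lexicographic member ids — fully deterministic. Metrics are
stored at full precision and rounded only for display (2 decimals).
Selection uses calibration data only; test-set metrics come from a
separate `evaluate_on_set()` call.

One departure from a fixed-quota pipeline: `cp_pipeline()` relaxes the
support quota stepwise (halving, floor 2) when the filtered pool is
smaller than the smallest requested model size. A very clean library may
contain only the planted/true geometries — fewer than three — and no
3-member model could otherwise be formed; with a relaxed quota, rare
chance geometries (which the fewest-inactive filter keeps essentially
free of false positives) fill the remaining member slots. The quota
actually used is reported in the fitted model.

## The synthetic generator

`make_planted_library()` produces feature-cloud libraries that bypass
chemistry entirely: each active carries one planted hypothesis geometry —
embedded from its distance matrix, randomly rotated and translated,
jittered with isotropic Gaussian noise (default σ = 0.2 Å per coordinate,
comfortably inside the 1.0 Å tolerance) — plus uniform random decoy
features (default 5 per molecule in an 8 Å box); inactives carry only
decoys and are rejection-sampled so none matches any plant. The default
composition, 20 actives / 200 inactives with two planted 3-site
hypotheses (HHR 3-4-5 Å, DRR 4-5-6 Å), mimics the strong class imbalance
of real inhibitor screens at a desk-scale size. A manifest records the
full ground truth, making the generator an oracle for the matcher, the
hypothesis engine and the selector.

What the generator does **not** emulate: real feature-count and
feature-type distributions (decoy types are uniform over the six
letters), conformational flexibility (clouds have one conformer),
correlated pharmacophores, or property skews such as molecular weight
(the MW column is drawn uniformly from 150–800 Da purely so the reporting
functions are exercised). Passing the planted-recovery suite therefore
demonstrates the *machinery* — perception-to-selection correctness and
generalization across seeds — not performance on a real screen.

## Numerical choices and degenerate inputs

* Distance binning uses `floor(d / bin_width)`; boundary effects are
  absorbed by the post-merge (see above).
* The matcher compares each pair deviation to `tol` exactly (no epsilon);
  monotonicity in `tol` is tested as a property.
* Empty feature sets, unmatched types, and hypothesis/feature-count
  mismatches return clean no-match results, not errors; empty inactive
  sets degrade survival-inactive to survival with a warning; single-class
  truth vectors are an error naming the missing class.
* Metric table sizes used in the test and acceptance suites — a
  27-hypothesis pool (20 475 candidate models), 441-molecule calibration
  sets, 20/200 planted libraries — were chosen as the smallest sizes at
  which the combinatorial behaviour of interest is visible.

## Limitations

Feature perception is rule-based, not a pKa calculator or a full
aromaticity model; the shipped table is an explicit stand-in for the
proprietary definitions of commercial packages and will differ from them
molecule by molecule. Conformer geometries are idealized (see above).
Matching has no partial-match mode (all k sites or nothing), no excluded
volumes and no directional constraints on A/D/R. Survival is a plain
matched fraction, not an alignment-quality composite. These are scope
choices: the combinatorial selection layer on top is independent of how
features and matches are produced, and each layer can be replaced behind
its interface.
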