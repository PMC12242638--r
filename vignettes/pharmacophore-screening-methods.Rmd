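---
title: "Methods: pharmacophore-constrained virtual screening with phorescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore-constrained virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phorescreen)
```

# Scope and model

`phorescreen` implements a ligand-based, structure-informed virtual-screening
protocol for ATP-competitive kinase inhibitors, with the two Rho-associated
kinase isoforms (ROCK1, ROCK2) as the worked target. The pipeline has five
stages:

1. **Curation** — ChEMBL-style bioactivity exports are partitioned into
   activity classes on dissociation constants only (Ki/Kd; IC50 values are
   assay-condition dependent and excluded), then filtered structurally and
   reduced to diverse representatives.
2. **Chemical space** — circular fingerprints, PCA or metric MDS embedding,
   and clustering with joint algorithm/k selection by the mean silhouette.
3. **Pharmacophore** — typed 3D interaction points (hydrogen-bond acceptor,
   donor, aromatic-ring centre) with a tolerance radius and a weight;
   consensus maps elucidated from overlaid ligand poses; the published
   four-point ROCK1/ROCK2 screening models shipped as built-ins.
4. **Screening** — frame-free geometric matching of conformer features onto a
   model by correspondence enumeration plus Kabsch superposition, scored as
   the summed weight of satisfied points, with the hinge acceptor required.
5. **Evaluation** — ROC/AUC with grouped ties and enrichment factors, and
   side-by-side comparison of constrained vs unconstrained protocols.

A sixth, structural module compares kinase ATP sites (ligand-radius residue
selection, residue identity, Kabsch RMSD, Shrake–Rupley solvent-accessible
surface area) and describes the affinity pocket between the glycine-rich
loop and the catalytic lysine.

# Curation rules and their parameters

* **Activity classes.** Active: Ki or Kd `<= active_nM` (default 100 nM,
  equivalent to pChEMBL `>= 7`). Inactive: `>= inactive_nM` (default
  5000 nM). Values strictly between the thresholds are excluded as
  "intermediate activity"; IC50 and other types as "unsupported type". The
  inactive boundary is inclusive by default (`inactive_strict = TRUE`
  switches to a strict `>`), because the operational filter the class
  definitions mirror applies `>= 5000`.
* **Duplicates.** When one compound has several Ki/Kd records the most potent
  (lowest nM) decides its class — conservative for the active class.
* **Structural filters.** Salt stripping keeps the largest organic fragment;
  exact duplicates are removed on canonical SMILES; compounds with any
  unspecified potential stereocentre are removed (a potential centre is an
  sp3 carbon whose four branches are pairwise distinct under iterative
  neighbourhood refinement; specified centres are read off the canonical
  SMILES stereo marks); molecular weight `>= 550` Da (inclusive), computed
  with average atomic masses on the desalted parent, removes the compound.
* **Diversity selection.** Average-linkage hierarchical clustering of the
  ECFP-style Tanimoto distance matrix, tree cut at 0.5; the cluster medoid
  (minimum summed Tanimoto distance, ties to the lowest input index) is the
  representative. The linkage criterion is exposed because the reference
  workflow does not state it; `scripts/reproduce_published.R` sweeps
  average/complete/single/Ward when the deposited compound sets are
  available locally.

# Fingerprints and chemical space

Fingerprints are extended-connectivity (Morgan) environments of bond
diameter 6 hashed onto 2048 bits. Initial atom invariants are (element,
heavy degree, hydrogen count, formal charge, ring membership); three
iterations hash each atom's invariant together with its sorted
(bond order, neighbour identifier) pairs; identifiers covering a bond set
already covered at a smaller radius (or by a same-radius duplicate) are
dropped before folding. The implementation is validated against an
independent environment-enumeration oracle that rebuilds the same
abstraction with string labels and compares unfolded identifier-set
Tanimoto similarities.

PCA embedding applies per-bit Z-scores (constant bits map to zero, keeping
column indexing), takes two components, and min–max rescales each to [0, 1];
a degenerate dimension rescales to 0. Metric MDS is least-squares SMACOF
with classical-scaling initialization — fully deterministic, no random
starts — iterating the Guttman transform until the stress-1 improvement
falls below 1e-10 (at most 300 iterations); exactly 2D-realizable distance
matrices are recovered to numerical precision.

Clustering candidates are hierarchical (average linkage), k-means
(deterministic farthest-point initial centres plus nine seeded random
restarts, best within-cluster sum kept) and k-medoids (PAM, from the
`cluster` package). Every method × k in 3..30 (truncated to n−1 with a
warning on small data) is scored by the mean silhouette in the clustered
space; the maximum wins, ties resolved toward smaller k and then
hierarchical < k-means < k-medoids. All-identical points are a "degenerate
data" error rather than a silent answer.

# Pharmacophore models, matching and scoring

The built-in four-point models (one per isoform) place a hinge
hydrogen-bond acceptor (radius 0.5 Å, weight 10), an acceptor toward the
catalytic lysine (0.7 Å, 5), an aromatic-ring centre at the hinge binder
(2 Å, 5) and an aromatic-ring centre in the affinity pocket (2 Å, 5), in
the coordinate frames of PDB entries 6E9W (ROCK1) and 7JNT (ROCK2), plus a
protein hydrogen-bond constraint to the backbone NH of the hinge methionine
(Met156/Met172, weight 10). One published ROCK1 coordinate is misprinted
("48.7.5"); the package adopts 48.7 and the value is exposed in the model
JSON for sensitivity analysis.

**Feature perception** uses explicit typing rules on the heavy-atom graph:
acceptors are neutral N/O excluding amide nitrogens and aromatic N–H
(pyrrole-type nitrogen donates rather than accepts); donors are N/O bearing
a hydrogen, positioned at the heavy atom; aromatic-ring features sit at the
unweighted centroid of each smallest aromatic ring. The rules live in code
(`perceive_features`) rather than an external rules file; they are small,
documented, and unit-tested, which we judged safer than a parseable DSL.

**Matching** enumerates injective, kind-compatible assignments of model
points to ligand features that cover at least the required points, pruned
by pairwise distance compatibility (`|d_features − d_points| <= r_a + r_b`).
Each assignment is scored after a proper-rotation Kabsch superposition of
matched features onto point centres: a point is satisfied when its feature
lands within the point radius, the score is the summed weight of satisfied
points, and required points must be satisfied. Ties break by lower RMSD,
then lexicographically. The matcher is property-tested against an
unpruned exhaustive oracle.

**Protein H-bond constraint.** The reference docking engine blends its
pharmacophore constraints into a fitness function with a minimum H-bond
geometry weight; that blending is unpublished, so the package uses an
explicit geometric gate instead: acceptor-to-H distance `<= 2.5` Å and
donor–H–acceptor angle `>= 120°` (both configurable), applied when the
model's constraint carries resolved donor coordinates, and the weight-10
hinge acceptor point is additionally marked as required during screening.
This is a documented divergence, not an emulation.

**Conformers.** Screening takes up to 200 conformers per compound (the
published cap) from multi-conformer SDF input; `featurize_smiles` embeds a
single 3D conformer per SMILES with OpenBabel when no conformer library is
available. A seeded multi-conformer distance-geometry generator was out of
reach of the available toolchain, so conformational sampling is delegated
to the input; all planted-truth validation operates directly on feature
sets, which makes the screening mathematics independent of any conformer
generator.

# Evaluation

ROC curves sweep thresholds over unique scores with ties grouped into
single steps (diagonal segments), so metrics are stable under input
reordering. The trapezoidal AUC equals the tie-corrected Mann–Whitney
statistic; both are implemented and cross-checked to 1e-12, and against an
established external implementation. Enrichment factors include all
compounds tied at the top-fraction boundary. Unmatched compounds score 0
rather than being dropped, so ROC curves always see the whole library.

# Structure comparison

PDB reading keeps the first model and resolves alternate locations to the
highest occupancy (ties to altloc 'A'). A binding site is every residue
with a heavy atom within the selection radius (default 10 Å, the published
choice) of any ligand heavy atom; waters are excluded by default. Site
pairs align gap-free in residue order when sizes match, otherwise by a
small global alignment of residue-name strings; identity is the percentage
of aligned pairs with equal residue names. RMSD superposes shared named
atoms of aligned identical residues with the Kabsch algorithm (proper
rotations only); the atom selection (`heavy`, default; `backbone`; `ca`) is
a flag because the published 0.885 Å figure does not state its selection.
SASA is Shrake–Rupley with a 1.4 Å probe, 960 deterministic golden-spiral
points per atom and Bondi radii (overridable); exactly coincident
same-element duplicates count once, matching the analytic limit of two
approaching spheres. The affinity-pocket descriptor collects the
glycine-rich loop atoms and the lysine side chain and reports the
0.5 Å-grid point maximizing clearance to their van der Waals surfaces,
with the maximal inscribed-sphere radius (0 when the walls touch, never an
exception).

# Synthetic data: what it emulates and what it does not

The generators plant ground truth for every stage:

* `make_activity_table` draws Ki/Kd values log-uniform inside the correct
  class band (active `<= 100` nM, inactive `>= 5000` nM, intermediates
  strictly between, potent IC50 rows excluded-by-type) with SMILES from a
  bundled fragment grammar — scaffold × substituent combinations that are
  valid by construction — so class recovery must be exact, not approximate.
* `make_planted_feature_library` builds actives as the model's points plus
  isotropic Gaussian jitter (default σ = 0.3 Å, the scale of crystal-pose
  scatter) and three distractor features, under a random rigid motion per
  compound (screening must be frame-free). The default composition is
  20 actives / 180 decoys. Scrambled decoys are active-like realizations
  whose position-to-kind association is permuted — identical position
  statistics, scrambled chemistry — with rejection sampling so that no decoy
  fully satisfies the planted model; this keeps labels true by construction,
  makes zero-jitter separation exact, and gives the honest large-jitter
  limit in which AUC approaches 0.5. Because the AUC of 20 actives carries
  a sampling error of several hundredths, the approach to 0.5 is asserted
  on the distance |AUC − 0.5| over the jitter grid at the fixture seed.
* `make_planted_clusters` places Gaussian blobs with rejection-sampled
  centres at pairwise distance at least the requested separation.
* `make_toy_structure_pair` writes two small PDB files: poly-alanine-like
  five-atom residues around a three-atom ligand, a rigid copy with a chosen
  fraction of site residues renamed. Identity and (zero) RMSD are known
  exactly, up to the 0.001 Å coordinate quantization of the PDB format
  (tests use a 0.01 Å tolerance).

Passing on these fixtures demonstrates the algorithms recover planted truth
under controlled noise. It does not demonstrate performance on real
chemistry: synthetic feature sets have no excluded volume, no conformational
strain, and no correlation between feature positions and chemical
feasibility; the fragment grammar spans a far narrower chemistry than
ChEMBL. Reproducing the published cluster counts (45/67 actives) and the
0.885 Å inter-isoform site RMSD requires the deposited compound sets and
the public PDB entries, which are not redistributable inside the package;
`scripts/reproduce_published.R` performs those checks when the inputs are
present locally.

# Numerical choices

* Kabsch superposition flips the smallest singular direction when the
  optimal orthogonal transform is improper; reflections are never returned.
  With one or two matched pairs the rotation is under-determined but the
  least-squares optimum is still used.
* Silhouettes come from `cluster::silhouette`; tests re-derive them from the
  definition to 1e-12.
* Assignment tie-breaks (score, then RMSD with 1e-12 tolerance, then
  lexicographic order) make screening output deterministic, as do the
  seeded k-means restarts and the deterministic SMACOF and sphere-point
  generators.
* Problem sizes in the validation suite — 500 random matcher instances,
  20/180 planted libraries, 30-point blobs at k ∈ {3, 5, 8}, 100 seeded
  activity tables, 960-point SASA spheres — were chosen as the smallest
  sizes at which each property is sharp (exact counts, AUC tolerances of a
  few hundredths, sub-1% SASA error).

# Known limitations

* Docking is out of scope: scores are geometric constraint satisfaction,
  not binding-energy estimates, and the published docking-based AUCs are
  not comparable quantities.
* Aromaticity, protonation and tautomer states follow OpenBabel's
  perception of the input; no tautomer enumeration or pKa adjustment is
  attempted.
* The consensus-map algorithm assumes pre-aligned poses (e.g. crystal
  ligands of superposed structures); it does not perform flexible
  multi-ligand overlay optimization.
* `extract_site`/`compare_sites` handle single-conformation PDB input; mmCIF
  and whole-chain superposition are out of scope.
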