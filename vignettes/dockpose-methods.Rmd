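---
title: "Label-invariant RMSD and pose clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-invariant RMSD and pose clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockpose)
```

## The problem

Evaluating a molecular docking run usually starts with the root mean square
deviation between each predicted ligand pose and a reference pose — in a
re-docking benchmark, the experimentally determined binding mode.  Two
things make this harder than a one-line formula:

1. **Atom labelling.**  Docking programs routinely write the ligand with a
   different atom order than the input file, so the correspondence between
   reference and pose atoms has to be re-established before any deviation
   can be computed.  This is a graph-isomorphism problem, which has no known
   polynomial-time solution in general.
2. **The frame.**  Poses and reference share the receptor's coordinate
   frame, so the relevant quantity is the *positional* RMSD, computed in
   place.  No superposition is performed anywhere in this package: a rigid
   displacement of the whole ligand contributes fully to the RMSD.  This is
   deliberate and differs from alignment-based RMSD tools; a pose that is
   conformationally perfect but sits in the wrong pocket should score badly.

For $N$ mapped heavy-atom pairs with Euclidean distances $\delta_i$,

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N} \delta_i^2}.$$

Hydrogens are stripped before matching and never enter the calculation.

## Greedy graph matching

`match_atoms()` treats each molecule as a graph — atoms are nodes, bonds are
edges — and walks both graphs depth-first in lockstep:

* **Compatibility** of two atoms is decided by their local signature:
  element, the elements of their bonded neighbours, and the order class of
  those bonds.  Signatures are invariant under relabelling by construction.
* **Root selection.**  The reference atom with the rarest signature seeds
  the walk (ties go to the lowest index); every probe atom with the same
  signature is tried as the opposite root, and the completed mapping with
  the lowest full-molecule RMSD wins.  Rare signatures minimise branching.
* **Branching.**  At every step the unvisited reference neighbours of the
  current atom must be assigned to the unvisited probe neighbours.  All
  signature- and adjacency-consistent bijections are enumerated and ranked
  by the RMSD of everything assigned so far including the candidates, and
  the minimising branch is followed — a greedy choice, since the partial
  RMSD is the only positional information available locally.
* **Backtracking.**  A dead end (no consistent assignment) backtracks to the
  most recent branch and takes the next-ranked option.  The budget is 1000
  alternative-branch expansions per root pair; beyond that the root pair
  fails, keeping the worst case bounded.
* **Consistency guarantee.**  Every accepted pair must preserve adjacency
  (and, at the strict level, bond order) with all pairs already placed, in
  both directions.  A completed greedy mapping is therefore a genuine graph
  isomorphism, which gives the useful invariant that the greedy RMSD can
  never undercut the exhaustive optimum — only equal or exceed it.
* **Strictness ladder.**  Signatures first include bond order classes; if no
  complete mapping exists at that level, matching retries with
  element-plus-neighbour-elements only.  This tolerates bond-order
  disagreements between file dialects (a Kekulé SDF versus an aromatic
  MOL2).  Before that ladder is even needed, rings whose bonds alternate
  single/double are re-classed as aromatic (`normalize_aromatic()`), so the
  common benzene-like cases agree at the strict level.
* **Fragments.**  Multi-fragment ligands (salt pairs) are matched component
  by component, pairing components of equal size and element multiset.

`brute_force_match()` is the exact counterpart: a backtracking enumeration
of *all* signature-consistent isomorphisms with branch-and-bound pruning on
the accumulated squared distance, guarded to 14 heavy atoms.  It exists to
validate the greedy matcher, not to replace it; the two must never be
collapsed into one code path.

**What the validation shows.**  On 100 generated toy molecules (4–12 heavy
atoms, atoms randomly permuted, Gaussian coordinate noise of 0.1 Å), the
greedy matcher returns the exhaustive minimum RMSD in well over 90% of
cases and never exceeds it by more than 5% relative in the rest.  The
tests assert exactly this; the `scripts/acceptance.R` report recomputes it
from scratch.  Noise of 0.1 Å is far below the ~1.5 Å bond scale, which is
the regime where a greedy positional ranking is informative; with noise
approaching bond lengths the heuristic would degrade, as any positional
matcher must.

## Backbone mode for peptide ligands

For peptide ligands the deviation of flexible side chains can swamp the
signal of the binding mode, so `backbone_filter()` restricts the
calculation to the backbone atoms N, C$\alpha$, C′ and (by default) the
carbonyl O of each residue.  When PDB atom names are present they are used
directly; otherwise the repeating N–C–C(=O) motif is found by graph search:
a candidate C$\alpha$ is a carbon bonded both to a nitrogen and to a carbon
bearing a terminal oxygen.  Exactly one oxygen is selected per carbonyl
(double-bonded preferred, then lowest index), so a C-terminal carboxylate
contributes one backbone oxygen, and a molecule with no motif raises a
clear not-a-peptide error.  Whether the carbonyl oxygen belongs to "the
backbone" is a convention, not a fact; the conventional four-atom backbone
is the default and `include_oxygen = FALSE` gives the three-atom variant.

## Clustering docked poses

`rmsd_matrix()` builds the symmetric matrix of pairwise pose RMSDs.  Poses
from a single docking run share an atom order, which is verified by
element-sequence equality and exploited directly; on mismatch the matcher
runs per pair.  Three algorithms operate on the matrix:

* **gromos** (the default): count neighbours (RMSD ≤ cutoff) per remaining
  pose; the pose with the most neighbours becomes a cluster centre and
  leaves the pool with all its neighbours; repeat until the pool is empty.
  The representative is the centre.  Ties in neighbour count go to the
  lowest pose index.
* **single linkage**: agglomerative merging where inter-cluster distance is
  the *minimum* member-pair RMSD.  With a minimum size of 1 this provably
  partitions poses into the connected components of the threshold graph —
  the test suite checks this against an independent component-finding
  oracle on 200 random matrices.  Useful for spotting outliers, which stay
  singletons.
* **complete linkage**: the same merging with the *maximum* member-pair
  RMSD, which bounds every cluster's diameter by the cutoff.

The boundary conventions differ deliberately: gromos counts neighbours at
RMSD ≤ cutoff, while linkage merges only while the linkage distance is
strictly below the cutoff.  Equal merge distances are resolved by the
lexicographically smallest pair of cluster indices (clusters ordered by
their smallest member), making every run deterministic.  The defaults —
cutoff 1.0 Å, minimum cluster size 4 — suit typical re-docking runs of tens
of poses; with few poses a smaller minimum size avoids discarding
everything, and `min_size = 1` reports all groups.  Groups below the
minimum size are reported as unclustered, never silently dropped.  Clusters
are emitted in descending size order (formation order on ties); output
ordering after size filtering is a presentation choice, not part of the
algorithms.

Linkage representatives are the best-scoring (lowest score) members,
falling back to the lowest index without scores; scores are extracted from
the docking program's own output (`REMARK VINA RESULT` lines for AutoDock
Vina, SDF data tags for OpenEye FRED/HYBRID, tried in a configurable
order because the tag spelling varies between releases).  For all three
supported programs lower scores are better, and that polarity is applied
literally.

## Interaction report

`detect_interactions()` replaces a visual inspection step with a
deterministic geometric report.  The criteria are standard literature
values, configurable via `interaction_criteria()`:

| kind        | criterion                                                             |
|-------------|-----------------------------------------------------------------------|
| hbond       | N/O donor to N/O/S acceptor ≤ 3.5 Å; D–H···A ≥ 120° when H present    |
| ionic       | opposite formal-charge groups ≤ 4.0 Å                                 |
| hydrophobic | apolar C to apolar C ≤ 4.0 Å                                          |
| pi_stacking | ring centroids ≤ 5.5 Å; interplanar angle ≤ 30° or 60–90°             |
| metal       | metal ion to N/O/S ≤ 2.8 Å                                            |

Charged groups are recognised by substructure pattern (carboxylate,
phosphate, guanidinium/amidinium, sp3 amines) or, when residue labels are
available, by the canonical charged atoms of amino acids and nucleotides.
Two honest approximations: structures rarely carry formal charges, so any
sp3 amine with only C/H neighbours counts as protonated; and when a
structure has no explicit hydrogens at all (the common case for PDB
receptors), hydrogen bonds are accepted on distance alone.  Both widen
rather than narrow the report, which is the right failure mode for a
screening aid.  Water-mediated bridges are not chained — waters appear as
ordinary HOH residues.

## Synthetic data: what it does and does not emulate

The generator exists so that every claim above is testable without any
external download.  `generate_molecule()` grows a random valence-legal
tree (optionally closed into rings) with ~1.5 Å bonds in random directions
and clash-rejected placement; `permute_atoms()` emulates a docking program
relabelling atoms; `perturb_coordinates()` adds Gaussian noise (expected
RMSD → σ√3 for large N); `generate_pose_set()` plants k binding modes as
rigid translations with pairwise centre distances of at least the requested
separation, populates them with noisy copies, draws scores so the most
populated mode scores best, and redraws any noise draw whose geometry would
change the distance-perceived bond topology, so poses stay self-consistent
in bond-table-free dialects.  Everything is deterministic per seed.

The defaults used in the validation experiments are: ≤ 12 heavy atoms and
0.1 Å noise for the matcher-versus-oracle suite (small enough for the
exhaustive oracle, noise well below bond scale); k = 3 planted clusters,
0.2 Å intra-cluster spread, 3 Å separation and a 1.0 Å cutoff for cluster
recovery (spread ≪ cutoff ≪ separation, the regime where all three
algorithms must agree); 200 random matrices for the set-property checks.
These sizes keep the full suite under a minute while exercising every code
path; they are stated here so the claims are reproducible, and they are
fixed — they were chosen from the constructions above, not tuned against
test outcomes.

What the synthetic data does *not* emulate: realistic conformer geometry
(no force field, no torsional preferences), tautomers, protonation states,
or the score distributions of any real docking program.  Passing tests
demonstrate algorithmic correctness — mapping optimality, set-theoretic
clustering guarantees, format fidelity — not chemical accuracy on real
complexes.  The published worked examples (a GPCR allosteric modulator and
a DNA minor-groove binder) are wired into the acceptance test as an
integration check, but their input files must be supplied by the user under
`inst/extdata/paper-inputs/`; they are not redistributable and the package
does not download anything.

## Numerical and interface choices

* Atom, bond, and pose indices are 1-based throughout, as everywhere else
  in R; `orig_index` preserves each atom's position in its source record.
* Coordinates are written at V2000/PDB precision (4 and 3 decimals), which
  bounds round-trip fidelity at ~5×10⁻⁴ Å; RMSDs are reported to 3
  decimals by the CLI.
* SDF reading and writing is V2000 only; V3000 is rejected with a clear
  error.  Records with zero bonds are parsed by a direct fixed-width
  fallback.
* PDB and PDBQT carry no bond table, so bonds are perceived whenever the
  interatomic distance is at most the sum of covalent radii plus 0.45 Å —
  the standard radii-based rule.  Perceived bonds are all single-order;
  order information is simply not recoverable from coordinates, which is
  one reason the relaxed signature level exists.
* PDBQT atom types (e.g. `OA`, `NA`, `A`) map to elements through the
  AutoDock type table, since element identity drives matching.
* All supported formats use Ångström and a shared frame; no unit or frame
  conversion is ever applied.
* Degenerate inputs fail loudly with classed conditions
  (`dockpose_parse_error`, `dockpose_incompatible`, `dockpose_not_peptide`,
  …) that the CLI maps to exit status 1; unexpected failures map to 2.

## Known limitations

* Matching requires equal heavy-atom counts and element multisets; there is
  no maximum-common-substructure mode for partially resolved ligands.
* Stereochemistry is invisible to the matcher: enantiomeric atom
  assignments with identical graphs are distinguished only by their RMSD.
* The greedy matcher can return a suboptimal mapping for highly symmetric
  molecules under large coordinate noise; the exhaustive oracle is the
  fallback for up to 14 heavy atoms.
* Ring perception examines rings up to size 6, which covers aromatic
  chemistry but not macrocyclic π-systems.
* The interaction report is geometric only — no energies, no solvent model,
  no bridging-water chains.
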