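---
title: "Methods: probing SERT/DAT substrate selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probing SERT/DAT substrate selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transelect)
```

`transelect` analyses why chemically similar phenylethylamine (PEA)
substrates — amphetamines, fenfluramines, methylenedioxyamphetamines,
cathinones — discriminate between the serotonin and dopamine
transporters (SERT, DAT). This vignette documents the models and
procedures the package implements, the parameters that matter and their
defaults, the design decisions taken where several choices were
defensible, and what the synthetic benchmark does and does not
demonstrate.

## The ligand-based layer

### Selectivity index and classification

Potencies are handled as pEC50 (−log10 molar EC50), so differences are
log fold-changes. The selectivity index of a compound is

$$S = \mathrm{p}EC_{50}(\mathrm{SERT}) - \mathrm{p}EC_{50}(\mathrm{DAT}),$$

in log units; $S = +2$ means a hundredfold SERT preference.
`classify_selectivity()` applies a symmetric threshold: $S \ge +t$ is
SERT-selective, $S \le -t$ DAT-selective, otherwise nonselective. The
default $t = 1.0$ log unit is a package convention, not an experimental
constant: selectivity calls of this kind are traditionally made
visually from a potency–potency scatter, and one log unit is the
narrowest band that cleanly separates the compounds usually discussed
as selective from the diagonal. The threshold is an explicit argument
everywhere, and classification is monotone in it (raising $t$ can only
move compounds toward nonselective), which the tests assert as a
property.

### Matched pairs

`matched_pairs()` emits every pair of compounds in the same chemical
family that differ at exactly one substituent position (R1 = N-alkyl,
R2/R3 = alpha substituents, R4 = beta, R5/R6 = ring meta/para) and
agree everywhere else, with the potency change per transporter. Two
stereochemistry rules apply:

* compounds with *defined but different* configurations (R vs S) never
  pair — the comparison would confound the substituent change with the
  configuration change;
* racemates pair with anything by default, because half of a racemate
  is the matching enantiomer and the SAR reading is still informative;
  `require_defined_stereo = TRUE` excludes them for strict analyses.

### Free energy differences from affinity ratios

For two equilibrium (or approximately equilibrium) affinities measured
at temperature $T$,

$$\Delta\Delta G = RT \ln \frac{K_1}{K_2}, \qquad
R = 1.9872 \times 10^{-3}\ \mathrm{kcal\,mol^{-1}\,K^{-1}},$$

positive when $K_1 > K_2$, i.e. when the second species binds more
favourably. Only the ratio enters, so the result is independent of the
concentration unit (asserted as a property test). Ki, KD, IC50 and
EC50 are accepted interchangeably for the ratio — Ki approximates KD
under competitive binding, and IC50/EC50 ratios approximate Ki ratios
when assay conditions match — but an `affinity_pair()` must hold a
single kind: mixing kinds within one ratio is refused. Values are
carried at full precision; the conventional presentation rounds to two
decimals ("about 1.7 kcal/mol"), and literature values quoted at that
precision can differ from the formula by roughly 0.01 kcal/mol
depending on rounding habits, which is why the package never promises
more than ~0.015 kcal/mol agreement with quoted numbers.

## The structure-based layer

The input is post-docking output: for each ligand an ensemble of poses
in the receptor frame (SD file with `LIGAND_ID`/`POSE_ID` fields), a
receptor PDB, and per-pose score tables (CSV, one per scoring
function). Docking itself, homology modelling, force-field minimisation
and the internals of the scoring functions are upstream and out of
scope; scores are consumed as numbers.

### Salt-bridge filter

Transporter substrates anchor their protonated amine to a conserved S1
aspartate (D79 in DAT, D98 in SERT). `ionic_filter()` retains a pose
when the minimum distance between a cationic nitrogen and a carboxylate
oxygen (OD1/OD2, or OE1/OE2 for glutamate) of the designated anchor is
at most `max_distance`. Choices:

* **4.0 Å default.** Docking protocols rarely state their ionic
  criterion; 4.0 Å between heavy atoms is the standard salt-bridge
  definition and is exposed as a parameter rather than hidden.
* **No hydrogens required** — the N–O heavy-atom distance defines the
  interaction, so the filter works on hydrogen-free poses.
* **Charge fallback.** Candidate cations are nitrogens with positive
  formal charge; when a pose carries no formal charges at all (typical
  of PDB-derived ligands) every nitrogen is a candidate and a warning
  is issued. Poses with no candidate nitrogen are discarded and counted
  separately from distance failures; retained + distance-discarded +
  no-nitrogen always equals the input count.

The filter is idempotent and monotone in the cutoff (both asserted as
properties).

### Common-scaffold RMSD

Different analogues cannot be compared by whole-molecule RMSD, so poses
are compared on their shared scaffold: the nine PEA heavy atoms (six
ring carbons, C-beta, C-alpha, N). `extract_scaffold()` matches the
scaffold as a subgraph of the pose's heavy-atom connectivity graph
(element-constrained monomorphism via igraph's LAD matcher). All
matches are kept: the phenyl ring flip makes at least two maps for any
PEA, and naphthalene cores can match through either ring.
`scaffold_rmsd()` minimises over all map pairs, so chemically identical
placements score zero instead of the ~2.4 Å artefact a fixed atom
numbering would produce.

Two deliberate choices:

* **No superposition by default.** All poses share the receptor's
  docking frame, and the question is *where in the site* the scaffold
  sits — a binding-mode distance. Superposed (conformational) RMSD is
  available behind `superpose = TRUE` but is not what mode clustering
  needs.
* **Connectivity-only matching.** No aromaticity or bond-order
  perception: the beta-keto of cathinones and the methylenedioxy bridge
  of MDA-type ligands leave the nine-atom core match untouched, and a
  custom `scaffold_pattern()` can replace the default.

The resulting matrix is a pseudo-metric (symmetric, zero diagonal;
triangle inequality asserted empirically on generated ensembles).

### Complete-linkage clustering at a cutoff

`cluster_poses()` performs agglomerative hierarchical clustering with
complete linkage and stops merging when the smallest linkage distance
exceeds the cutoff, so every cluster's diameter (maximum internal
scaffold RMSD) is bounded by it. The default cutoff of 3.0 Å is the
height at which the dendrogram is cut, in the same Å units as the
matrix — with sub-Å within-mode scatter and many-Å mode separations
this is the natural binding-mode resolution. The cutoff is interpreted
as a *height*, not a target number of clusters; both interpretations
exist in desktop clustering tools, and the height reading is the one
that gives a geometric guarantee.

The implementation is written in the package rather than delegated,
for one reason: deterministic tie-breaking. When two merges are equally
good, the pair of clusters with the lexicographically smallest labels
(a cluster is labelled by its smallest pose index) merges first, making
output identical across platforms. The tests verify exact partition
agreement with two independent oracles — `stats::hclust` +
`stats::cutree` and a naive $O(n^3)$ merge loop — on hundreds of random
matrices, and the full merge tree is returned as a standard `hclust`
object (plottable, exportable as Newick).

`retain_all_ligand_clusters()` then flags, never deletes: a
binding-mode cluster is only credible for the common scaffold if every
docked ligand populates it, so clusters missing a ligand are marked
discarded while membership stays intact.

### Consensus pose and cluster-average rescoring

Scoring functions are noisy in different ways; a pose ranked highly by
two unrelated functions is more trustworthy than either ranking alone.
`consensus_pose()`:

1. takes the top-`n` pose list of each table (default `n = 10`;
   direction — higher- or lower-is-better — is mandatory per table,
   because sign conventions differ between scoring functions and
   guessing silently would be worse than asking);
2. intersects them, restricted to poses of the probe ligand inside
   retained clusters (a flag widens this to all ligands);
3. if the intersection is non-empty and lies in one cluster, reports
   that cluster with mean ± sample (n−1) sd per scoring function over
   *all* its poses — the reported n is the cluster size, since the
   cluster, not the single pose, is the binding-mode estimate;
4. otherwise returns an explicit `no_consensus` (with near misses:
   poses in all but one list) or `ambiguous` outcome (candidate
   clusters ranked by summed rank, `auto_pick = TRUE` required to take
   the best) — never an exception and never a silent choice.

Only ranks matter: any strictly monotone, direction-preserving
transformation of a score table leaves the outcome unchanged (asserted
as a property). `match_cluster_by_orientation()` transfers a consensus
mode across proteins whose frames were pre-aligned upstream: a cluster
of the second ensemble matches when its poses' mean aromatic-ring
centroid lies within 2.0 Å (default) of the reference pose's ring
centroid.

## Pocket comparison

`count_differences()` and `hydropathy_contrast()` operate on a curated
residue pairing of one pocket across two proteins — for the packaged
table, the seven TM3/TM8 residues lining the pocket that hosts
meta/para substituents next to the S1 site in SERT and DAT. Input is
the pairing itself, not raw sequences: the pairing is an alignment
judgement best made once and reviewed, and deriving it from sequence
databases would add an external dependency without adding rigour.
Hydropathy uses the Kyte–Doolittle scale by default (lipophilicity
claims about pockets rarely name their scale; Kyte–Doolittle is the
common default and the scale is pluggable). The contrast reports
per-pair differences, the pocket total, and flags pairs opposing the
pocket-level trend — on the packaged table the threonine/alanine pair
is the single hydrophilic exception in an otherwise more lipophilic
SERT pocket. Totals are antisymmetric under swapping the two proteins
(tested).

## The synthetic benchmark

`generator_spec()` / `generate_ensemble()` / `generate_scores()` build
pose ensembles with planted ground truth so the whole structure-based
pipeline is testable without any deposited docking output.

**What is emulated.** A GOLD-style study of a few scaffold-sharing
ligands: idealised PEA coordinates (planar 1.39 Å hexagon, zig-zag
tail with tetrahedral angles, 1.50/1.52 Å C–C and 1.47 Å C–N bonds;
ligands decorated with alpha-methyl, N-methyl or ring substituents so
scaffold extraction faces non-identical analogues); a small number of
binding modes, each anchored at the salt bridge — the ammonium nitrogen
placed in the contact shell of an aspartate stub and the molecule
extending outward along a mode-specific direction, which is how real
S1 binding modes differ (common ionic anchor, different ring
placement); per-atom Gaussian jitter; ligands assigned round-robin so
every ligand populates every mode; far outliers (≥ 3× the mode
separation) that cluster as singletons; and per-function scores drawn
from `N(mean_in, sd)` in the favoured mode and `N(mean_out, sd)`
elsewhere.

**Planting is exact.** Contact poses are placed with the nitrogen at
N–O ≤ 0.9 × the ionic cutoff, non-contacts beyond 1.5×; jitter is
applied relative to the nitrogen, so the planted N–O distance — and
therefore the contact ground truth — is noise-free. Mode directions
point into the half-space away from the receptor stub so non-contact
placements can never drift inside the cutoff via the second carboxylate
oxygen.

**Geometry cap on mode separation.** Because all modes share the
salt-bridge anchor, the achievable inter-mode scaffold RMSD is bounded
by the molecule's extent: about 10–11 Å for orthogonal mode directions
at contact distance. A larger requested `mode_separation` saturates at
the cap; the realised value is returned as `achieved_separation`, and a
warning is raised only when it falls below the documented validity
regime of 5 × `jitter_sd`. With the default 0.3 Å jitter and 3 Å
clustering cutoff the achieved ~10 Å separation leaves an enormous
margin, and planted-mode recovery (exact cluster count, Rand index 1
against ground truth) holds across all tested seeds.

**Interaction of the two plantings.** Displacing a non-contact pose out
of the ionic shell moves it ~3–4 Å off its mode template, which at a
3 Å cutoff splits a mixed-contact mode into contact and non-contact
subclusters. Mode-recovery guarantees therefore apply to ensembles
with `salt_bridge_fraction` 0 or 1; filter precision/recall is tested
on mixed-fraction ensembles, where it is exact by construction.

**What is not emulated** — and hence what passing tests do not show
about real data: real docking energetics and score landscapes
(synthetic scores are Gaussian by construction, real rescoring
functions are correlated with geometry in complicated ways), receptor
flexibility, conformational diversity within a binding mode beyond
isotropic jitter, chemically realistic decorations, and the actual
SERT/DAT site geometry. The benchmark validates the *logic* of the
pipeline — filtering, symmetry handling, clustering, retention,
consensus — not the scientific accuracy of any particular docking
campaign. For the same reason, absolute rescoring averages of a real
study are not reproduction targets: they depend on undeposited poses
and models.

**Determinism.** One seeded stream, consumed in a fixed order (contact
assignment, then per-pose placement and jitter; scores use an offset
seed), makes generation byte-identical under a fixed seed; the writers
emit exactly the formats the readers parse, and round-trips are tested
to written precision (10⁻⁴ Å).

## Numerical and edge-case conventions

* Distance comparisons use plain `<=` on Å; RMSD ties between symmetry
  maps are resolved by the minimum, merge ties lexicographically.
* Sample (n−1) standard deviation everywhere; single-member clusters
  report sd 0 with a degenerate flag rather than NA.
* Degenerate inputs error early and specifically: fewer than two
  scaffold-bearing poses for a matrix, empty score tables, anchors
  without carboxylate oxygens, unknown residue codes (named), missing
  CSV columns (named).
* Malformed activity rows are rejected row-wise with reasons attached,
  never silently dropped; score entries for unknown poses are ignored
  with a counted warning.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
instances — ensembles of 3–4 ligands with 3–10 poses each (27–40
poses), distance matrices up to 10 × 10 for oracle comparisons (hundreds
of random repetitions), and 20 replicated ensembles for the stochastic
recovery rates. These sizes were chosen because every tested guarantee
(exact partition agreement, Rand index 1, exact precision/recall) is
scale-free: it either holds at n = 27 or is broken at n = 27. The
pipeline itself is comfortable at realistic scales (hundreds of poses;
the RMSD matrix is the quadratic step).

## Known limitations

* The selectivity threshold, ionic cutoff, clustering cutoff and
  centroid-match radius are conventions, not measured constants; all
  are exposed as parameters and the defaults documented above.
* MOL2 input is not parsed; poses are ingested from SD files (the
  writers emit the same), receptors from PDB.
* The pocket comparison trusts the curated pairing; it does not detect
  pockets or align sequences.
* Cross-protein orientation matching assumes the two receptor frames
  were superposed upstream; the package does not superpose structures.
* Scale-dependent lipophilicity judgements can differ between
  hydropathy scales; the package reports the per-pair signs so
  disagreements are visible rather than resolved.
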