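---
title: "Methods: generate-then-retrieve screening with mgvs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generate-then-retrieve screening with mgvs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mgvs` implements a model-guided virtual screening loop: a set of generated
candidate molecules is docked and filtered, the best survivors become
queries, each query retrieves its closest synthesizable analogs from a local
compound library by graph edit distance, and the analogs are docked and
ranked in turn. This vignette describes the models and procedures behind
each stage, the parameters that matter, and what the synthetic fixtures do
and do not establish.

## The screening model

The pipeline assumes the generative step is an *ingestion boundary*: any
generator's output is read as SMILES/SDF. Screening quality is then a
property of three components — the filter that discards chemically
implausible candidates, the retrieval metric that finds purchasable
neighbors of a good binder, and the scoring model that ranks both sets.
Because raw docking scores grow with molecule size, ranking uses **Vina
efficiency** (score divided by heavy-atom count) by default; a config switch
(`ranking = "vina"`) restores raw-score ranking. **ΔVina** (hit minus
reference) summarizes whether a retrieved analog matches its query's
predicted affinity.

## Compound filtering

Three rule families are applied, each independently switchable:

- **Cumulated double bonds.** An atom with two or more non-aromatic double
  bonds (allene-like). We read "consecutive" as *cumulated*, not conjugated:
  conjugated dienes are ubiquitous in drug-like molecules, while cumulated
  systems force the strained geometries the rule exists to exclude. Aromatic
  systems are exempt by construction (perception happens before the check,
  and only non-aromatic double bonds count).
- **Ring rules.** Smallest-set-of-smallest-rings sizes must lie in
  {5, 6} (configurable); a fused system may contain at most four rings; and
  a fused system whose ring-adjacency graph (rings as nodes, edges between
  rings sharing at least one atom) contains a cycle is rejected as
  bridged/cage-like. The two readings of the fused-system rule — more than
  four *rings* vs more than four *atoms*, and what "forms loops" means —
  are genuinely open; we chose rings-count plus adjacency-graph cycles
  because it cleanly separates linear ring assemblies (steroid skeletons
  pass) from cages (adamantane fails), and both thresholds are exposed in
  the configuration.
- **PAINS and property ranges.** Substructure alerts come from a bundled,
  versioned SMARTS catalog — a curated subset spanning the classic
  pan-assay-interference classes (catechols, quinones, ene-rhodanines,
  azo compounds, Mannich phenols, ...), so results are reproducible
  regardless of any toolkit's internal catalog; a fuller file can be
  substituted by path. Default drug-likeness ranges are MW 150–500 Da,
  logP ≤ 5, HBD ≤ 5, HBA ≤ 10, rotatable bonds ≤ 10 — conventional
  oral-drug screening windows — and are fully configurable.

QED is computed from the published desirability-function parameterization
over eight descriptors (MW, logP, HBA, HBD, TPSA, rotatable bonds, aromatic
rings, structural alerts) with the consensus weights; the structural-alert
term uses a bundled reactive-substructure catalog. Synthetic accessibility
is a self-contained graph-complexity heuristic on \[1, 10\] (size, ring
count, macrocycles, bridged/spiro systems, heteroatom density, minus a
repeated-environment bonus): adequate for *relative* ranking of desk-scale
sets, but it is not a trained fragment-contribution model and its absolute
values should not be compared against published SA scores.

## Anonymous-graph GED retrieval

Retrieval treats a molecule as its **anonymous graph**: the heavy-atom
skeleton with all element, charge, aromaticity and bond-order labels
removed. This is a deliberate modeling decision: the retrieval key is
topology, and chemical identity differences are handled downstream by
fingerprint tie-breaking (path/Daylight-style first, then id). Two
consequences follow. First, benzene, cyclohexane and pyridine are *the same
object* at retrieval time (GED 0). Second, label changes are free, which
makes the edit distance a true metric on skeleton isomorphism classes.

The edit set is connectivity-preserving: add a terminal node, delete a
degree-1 node, add an edge between existing nodes, delete an edge whose
removal keeps the graph connected. The index buckets a library by a
canonical key (canonical vertex labeling followed by a stable edge-list
serialization), so query-time work scales with the number of distinct
topologies rather than library size. Distances are computed by
**bidirectional level-wise search** over canonical keys: shells of the edit
lattice around a graph are materialized lazily, memoized package-wide
(they are content-addressed, so reuse across queries and libraries is
sound), and expansion alternates to the cheaper side; a distance is exact
once the radii sum to the bound. A node/edge-count lower bound prunes
hopeless pairs before any expansion. `exact_ged()` exposes the same exact
engine for pairwise validation; the acceptance suite checks that the index
path reproduces the exhaustive query-vs-all answer on random libraries.

The default search radius (`max_ged = 12`) and hit cap (1000, truncated to
the top 100 after ranking) mirror service-scale practice. Shell volume
grows steeply with radius, so desk-scale analyses here use radii 2–3 over
libraries whose members are constructed within a known edit radius of their
seeds — the regime where exactness can be verified against brute force in
minutes on one CPU.

## Fingerprints

Path (Daylight-style, linear paths up to 7 bonds, natively 1024 bits) and
circular (ECFP-style, radius 2 = ECFP4, natively 4096 bits) fingerprints
are generated by OpenBabel and folded by OR-blocks to the requested width
(defaults: 1024 and 2048). Folding preserves determinism and platform
stability. Distances are `1 − Tanimoto similarity`, so low distance means
similar — the orientation used consistently in ranking and correlation.

## Conformers and docking

3D embedding must be bit-reproducible here, so the base conformer comes
from a deterministic chain: 2D layout, a seeded out-of-plane displacement
(±0.35 Å on acyclic atoms, ±0.05 Å on ring atoms) to break the planar
saddle, and MMFF94 minimization. Additional conformers are produced by
seeded torsion driving (60° grid offsets) around rotatable bonds, each
re-minimized; Butina clustering on heavy-atom Kabsch RMSD (cutoff 1.0 Å,
configurable — the clustering radius is a free parameter here) keeps one
centroid per cluster, and the best-scoring conformer represents the
molecule. This trades conformational realism for exact reproducibility,
which is the correct trade for a validation-oriented toolkit; users
docking with a physical engine should treat the external engine's own
sampling as authoritative.

The engine adapter is text-level: an engine is `list(tag, score(mol, pose,
rec))`. The external path prepares PDBQT via OpenBabel, passes the 20 Å box
(the default box edge), and parses either the `mode | affinity` table or
`REMARK VINA RESULT` lines, so Vina-family programs are interchangeable.
Only the best mode is consumed. The **mock engine** used throughout the
tests scores `-0.3 × heavy_atoms` plus a bounded perturbation in
[−1.5, +1.5] keyed by a stable hash of (canonical SMILES, receptor id,
seed), with a +10 penalty for poses whose centroid leaves the box. The size
term intentionally reproduces the size bias of physical docking scores, so
raw-score and efficiency rankings disagree in tests exactly as they do in
practice, and the efficiency normalization is exercised meaningfully.

## Interaction detection and matching

Detection is geometric, with inclusive bounds throughout (≤ for distances,
≥ for angles): hydrogen bonds at donor–acceptor ≤ 3.5 Å **and** D-H-A
≥ 120°; hydrophobic carbon–carbon contacts ≤ 3.8 Å between apolar carbons
(all heavy neighbors carbon); salt bridges at ≤ 4.0 Å between
charged-group centroids; π-stacking at ring-center distance ≤ 4.0 Å with
plane angle ≤ 30° (parallel) or ≤ 5.5 Å with plane angle 50–90°
(perpendicular), lateral offset ≤ 2.0 Å; π-cation at ≤ 4.0 Å. The
plane-angle windows and offset are the conventional profiler defaults; the
distance cutoffs and the stricter H-bond criterion are the working values
of this pipeline. Ring planes are least-squares fits; duplicates per
(kind, ligand atoms, protein atoms) keep the shortest instance; hydrophobic
contacts between atoms of rings already paired in a detected π-stack are
suppressed as redundant.

Hydrogens: the D-H-A angle needs explicit donor hydrogens. Ligand poses
carry them from embedding. For receptors, backbone amide hydrogens are
placed with idealized geometry at load time when the file has none;
rotatable donors (Ser/Thr/Tyr hydroxyls, Cys thiol, Lys ammonium) without
explicit hydrogens are evaluated analytically — the best achievable D-H-A
angle over the tetrahedral cone of hydrogen positions is used, which is
deterministic and avoids placing arbitrary rotamers. Histidine counts as
cationic only when both ring nitrogens carry explicit hydrogens.

Matching compares a hit pose's interactions with its query's at two levels:
same protein **atom** (or atom group, for centroids and rings) or same
**residue**, optionally restricted to the specific (non-hydrophobic) kinds:
hydrogen bonds, salt bridges, π-cation, π-stacking. Parallel and
perpendicular stacks match as one kind by default (configurable), since
matching is about conserved contacts, not sub-geometry. Residue-level
matches are a superset of atom-level matches by construction; the summary
tables report the proportion of hits sharing all (and at least one) query
interactions overall, per kind, and per query.

## Evaluation statistics

The random-screening baseline draws `n = 20` subsets per size from a scored
pool, takes the median of the 10 best efficiency values per draw, and
compares distributions with a two-sided Welch unequal-variance t-test
(two-sided because no direction is assumed a priori). The pool-size curve
reports, for each docked-pool size `s`, the mean over queries of
`min(first s hit scores) − query score`, with a normal-approximation 95% CI
(mean ± 1.96·SE over per-query values — the CI construction was an open
choice; per-query normal approximation is the simplest defensible one at
these sample sizes). "Top-10" medians use exactly the ten best values, or
all values with a flag when fewer exist. Spearman correlations of ΔVina
against GED and both fingerprint distances use average-rank ties; constant
inputs return `NA` with a warning rather than a fabricated value. The
averaged ΔVina in the pool-size curve uses the single best hit per query;
averaging over the top-10 instead is a config-level alternative the
ambiguous protocol also admits.

## Synthetic fixtures and what they show

`make_library()` builds libraries by random chemically valid edits
(terminal atom growth/removal, 5/6-ring opening/closing) of seed molecules,
at most `edit_radius` per member, optionally followed by topology-preserving
element relabels; the recorded edit count is therefore an upper bound on the
true anonymous-graph GED to the seed, checkable by the exact engine.
`plant_complex()` builds minimal receptors from idealized residue fragments
(real residue atom names and plausible covalent geometry, so the typing
code paths run unmocked) positioned to realize prescribed interaction
geometries within 0.05 Å / 2°, with fragments spaced so nothing else comes
within 1.2× of any cutoff.

`plant_recovery_fixture()` builds a screening problem with a provable
answer: query skeletons are size-separated by more than the search radius
plus one edit, so each designated analog (one edit from its query, biased
to dominate its pool through the mock engine's fixture-only bias table)
can appear in exactly one query's hit pool — overlapping pools would make
"best analog per query" ill-posed, since one biased molecule would win
several pools. The related identity-library degeneracy check (every best
analog at GED 0 with ΔVina 0) is run with an analog pool of one per
query: with a larger pool, the minimum-score analog of *some other* query
with a luckier mock score can legitimately win, so the exact equality is
a property of the pool-size-1 regime.

These fixtures establish *correctness*: exact retrieval against brute
force, exact boundary behavior of the interaction rules, exact recovery of
planted best analogs, bit-level reproducibility of the pipeline. They do
not establish *transferability to real data*: the mock engine is not a
physical score, planted receptors are not folded proteins, toy libraries
are not make-on-demand chemical spaces, and desk-scale radii are far below
service-scale search. Headline numbers from large-scale screening
campaigns (correlation magnitudes, shared-interaction proportions,
screening-efficiency multipliers) depend on external generative models,
physical docking, and billion-scale libraries, and are out of scope here by
design.

## Problem sizes and numerical choices

The shipped validation suite uses 50 random libraries of ~24 members
(≤ 14 heavy atoms) for oracle equivalence, 1000 sampled triples for the
metric properties, a 20-molecule generated set against a 200-member library
for planted recovery, and search radii of 2–3 — sizes chosen so the entire
suite verifies exactness in minutes on a single core. Degenerate inputs are
defined errors, not silent passes: empty structures, disconnected query
skeletons, inverted property ranges, hydrogen-free ligand poses, empty
docking-result lists and malformed engine output each raise a typed
condition. Ties are broken deterministically everywhere: `(ged,
daylight_dist, hit_id)` for hits, `(vina, conformer index)` for docking
results, `(metric, raw vina, id)` for query selection. Artifact files
render numbers with a fixed 6-significant-digit format so repeated runs are
byte-identical.
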