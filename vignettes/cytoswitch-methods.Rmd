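---
title: "Detecting polymerization switches from structure ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polymerization switches from structure ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Actin- and tubulin-superfamily proteins polymerize into dynamic,
nucleotide-hydrolyzing filaments. A recurring observation across these
superfamilies is a *subunit assembly switch*: the backbone conformation of a
subunit inside a filament differs discretely from the conformation of the
free subunit, while the hydrolysis state of the bound nucleotide has little
effect on gross conformation. With hundreds of deposited structures per
superfamily, this becomes a statistical question: after placing every
structure in a common residue frame and removing rigid-body differences,
does the dominant axis of conformational variation track the assembly-state
annotation, and not the nucleotide annotation?

`cytoswitch` implements the full chain of computations needed to answer
that question reproducibly, from coordinate files to annotated principal
component scores. This vignette describes the model behind each stage, the
parameters that matter, the synthetic data used to validate the pipeline,
and the design decisions taken where the problem left genuine freedom.

## Pipeline model, stage by stage

### 1. Chain models and annotations (`read_structure`, `read_manifest`)

Each entry contributes one chain, reduced to its ordered C-alpha trace.
Author residue numbering plus insertion codes are the key space — nothing
is renumbered, so every downstream number is traceable to the deposition.
Two deterministic ingestion rules handle real-world PDB messiness:
alternate locations resolve to the highest occupancy (alphabetically first
altloc identifier on ties), and multi-model files keep model 1 only, which
treats NMR ensembles like single-conformer crystal entries. Residues
without a C-alpha are skipped; calcium ions (element Ca, atom name "CA")
are excluded explicitly.

Nucleotide state is classified from the entry's ligand component codes
through an editable mapping table (`nucleotide_code_table()`): ATP/GTP are
hydrolyzable triphosphates (NTP), the common nonhydrolyzable analogs
(AMPPNP, GMPCPP and relatives) are NTPa, ADP/GDP are NDP, an empty ligand
set is apo, and unknown codes fall through to "other". When codes from
several classes co-occur the precedence is NTP > NTPa > NDP, on the logic
that the triphosphate site defines the catalytically relevant state. The
table is configuration, not code, because deposition practice varies.

Assembly state follows a declared-wins rule: a state given in the manifest
is authoritative (the stand-in for manual curation, which cannot be
automated); otherwise a heuristic assigns "polymerized" to entries whose
method string indicates a filament or helical reconstruction and
"unpolymerized" to everything else. Every call records its provenance
(declared vs heuristic) so curation gaps are visible. A third label,
"special", marks ambiguous entries; they are carried through all outputs
but excluded from separation statistics.

### 2. The common column frame (`map_to_alignment`, `build_ensemble`)

The master alignment — one gapped row per entry, built upstream by
whatever structure-aware alignment process the user trusts — defines the
common coordinate system: 1-based columns. The package deliberately treats
this alignment as ground truth and does not construct alignments itself.

What it does reconcile is the *observed* sequence (built residues only)
against the entry's own row: a global alignment with identity-style scores
(match +2, mismatch −1, gap open −5, gap extend −1; `Biostrings`
underneath). A substitution matrix would be wrong here — the sequences are
supposed to be the same molecule, so the only legitimate differences are
unresolved residues. A 95% identity gate over the aligned region turns
manifest/row mix-ups into hard errors rather than silently misplaced
coordinates. Composing residue→row-position with row-position→column gives
each residue's column; the ensemble tensor stores coordinates per
(entry, column) with an occupancy mask.

Analysis frames use *complete columns*: columns occupied by every entry
(occupancy 1.0). A relaxed occupancy threshold exists in the configuration
but stays at 1.0 by default, since downstream fitting and PCA require
complete data and strict intersection is the cleanest reading of
"ungapped positions across representatives".

### 3. Representative selection (`cluster_and_pick`)

Identically annotated structures — same observed sequence, same nucleotide
state, same assembly state — are largely redundant snapshots of one
conformational state. Within each such group the pipeline computes all
pairwise post-fit C-alpha RMSDs and clusters with *complete linkage*, cut
strictly below 1.0 Å. Complete linkage is the only standard linkage whose
cut guarantees the stated property (every cluster's diameter, i.e. maximum
intra-cluster RMSD, below the threshold); single linkage can chain far
beyond it. Each cluster contributes its highest-resolution member, ties
broken by the number of built residues and then lexicographic entry id.
An override list can force a different representative (flagged
`override` in the report), the hook for quality judgments that cannot be
formalized.

### 4. Invariant core (`find_invariant_core`)

Superposing on *all* common columns lets mobile regions drag the fit.
The pipeline therefore finds a structurally invariant core by iterative
removal: fit all entries to their mean (see below), summarize each
column's residual scatter across entries as the volume of its covariance
ellipsoid,

\[ V_c = \tfrac{4}{3}\pi\sqrt{\lambda_1\lambda_2\lambda_3}, \]

with eigenvalues of the 3×3 positional covariance (divisor *n*−1, small
negative eigenvalues clamped to zero), then discard the single
largest-volume column and refit. Removal stops when the total remaining
volume reaches the cutoff (default 0.5 ų, the reference convention for
this algorithm family; the analysis that motivated this package did not
state its cutoff, so the value is configuration and is echoed in every
report) or when only 3 columns remain. One column per iteration — not
batch removal — keeps the trace canonical and deterministic, and ties
break toward the lowest column index. The full removal trace (column,
volume at removal, remaining total) is an output in its own right: the
cut is auditable, and the trace's strictly decreasing remaining volume is
asserted in the test suite.

### 5. Superposition (`kabsch`, `iterative_mean_fit`, `fit_on_core`)

The geometric kernel is the closed-form least-squares rotation via SVD of
the cross-covariance, with the reflection corrected through the sign of
the smallest singular value, so the result is always a proper rotation.
Degenerate (collinear) inputs are rejected. Multi-structure superposition
iterates: fit everything to entry 1, recompute the column-wise mean, refit
to the mean, and repeat until the mean moves less than 1e-6 Å RMS (or 100
rounds). Whole chains are transformed, not just fit columns, so per-column
statistics always see consistently posed coordinates. Core fitting is the
same procedure restricted to the core columns.

The tests cross-check this kernel two independent ways: against a
quaternion-grid brute-force minimizer (random rotation search polished by
Nelder-Mead — no shared code with the SVD route), and against
`bio3d::fit.xyz`/`bio3d::pca.xyz`, the standard R implementations of the
same operations.

### 6. PCA (`ensemble_pca`) and its exports

Fitted coordinates over the analysis columns are flattened to 3L-vectors,
mean-centered, and decomposed by SVD (equivalent to eigendecomposition of
the covariance with divisor *n*−1, numerically stabler). Components are
oriented so the largest-magnitude loading element is positive — a pure
sign convention that makes score plots identical across platforms and
reruns. Eigenvalues are variances (Ų) along collective displacement
modes; proportions sum to one; scores are the centered data projected on
the loadings, so their covariance is exactly diagonal.

PCA runs on the complete columns after fitting on the (stricter) core;
whether variance percentages should be quoted over complete columns or
core columns only is genuinely ambiguous, so the report contains both
tables. Loadings export per column as (dx, dy, dz) triplets with
magnitudes for porcupine-style rendering. Morph trajectories along
component *k* are

\[ \text{frame}_j = \bar{x} + s_j \sqrt{\lambda_k}\, u_k, \qquad
   s_j \in [-a, a] \text{ linearly spaced}, \]

with defaults ±2 SD and 15 frames (the usual morph convention; both
configurable), written as multi-model PDB. `project_structure()` maps any
conforming structure into an existing PC space by superposing it onto the
PCA mean first; for a converged mean-fitted ensemble this projection
reproduces stored scores exactly, a property the tests exercise.

### 7. Annotation separation (`separation_index`, `domain_aligned_rmsd`)

The claim "PC1 tracks assembly state" is inherently visual in a score
plot; the package quantifies it as eta-squared — between-group over total
score variance per component — calibrated by a label-permutation null
(default 9999 permutations, seeded). Under exchangeable labels eta² has
expectation (k−1)/(n−1) for k groups, which the tests verify against the
implementation. For two-level labels the point-biserial correlation
between score and label is also reported. Special/ambiguous entries are
excluded from the statistic but counted and always present in the
exported score scatter.

Domain-aligned RMSD reproduces the "align on one domain, measure the
other" comparison: superpose on a fit column set, report RMSD over a
different column set, with heterodimers handled by concatenating the
ordered chain pair before mapping. On a pure hinge this reduces to the
chord formula — a point at distance *d* from the hinge axis moves
2 d sin(θ/2) — which the tests use as a closed-form oracle.

## The synthetic study conditions

The generator (`synthetic_spec()`, `generate_ensemble()`) emulates the
statistical structure of a real superfamily dataset while staying fully
controlled:

* **Shared fold**: a helical C-alpha curve with exact 3.8 Å consecutive
  spacing, in a seeded random orientation. No side chains, no physical
  realism beyond spacing — the analysis only ever sees C-alpha geometry.
* **The switch**: residues after the hinge column (default 30 of 60)
  rotate about an axis through the hinge residue, perpendicular to the
  local chain direction: 0° for unpolymerized entries, 15° for polymerized
  ones. The hinge is applied to the shared base fold, so the switch is a
  single common mode across subfamilies — mirroring the observation that
  the switch is conserved while subfamilies differ elsewhere.
* **Subfamily structure**: each of 3 families gets a fixed smooth
  deformation mode (low-frequency sinusoids), projected orthogonal (in 3L
  space) to the hinge mode and scaled to 1.0 Å RMS per atom, so planted
  variance fractions stay analytically predictable.
* **Nuisance**: isotropic Gaussian coordinate noise (0.3 Å), per-residue
  dropout at rate 0.01 emulating unresolved residues, family-specific
  two-residue deletions appearing as gap columns in the master alignment,
  and a random rigid pose per entry.
* **The null**: ligand codes (hence nucleotide states) are sampled
  independently of the geometry, planting the negative control that
  hydrolysis state should *not* separate structures.

Defaults — 3 families × 8 entries × 2 states (48 entries), Δθ = 15°,
σ = 0.3 Å — are the package's canonical study conditions: large enough
that representative clustering, core finding and the permutation tests are
all non-trivially exercised, small enough that a full pipeline run takes
seconds. Under these conditions the point-biserial correlation between
PC1 and assembly state exceeds 0.9 in the large majority of seeds (18 of
20 in the fixed-seed acceptance test), and nucleotide eta² behaves like
its permutation null.

What passing these tests does *not* show: real structure collections have
correlated (not isotropic) coordinate error, resolution-dependent noise,
genuinely heterogeneous subfamily sizes, partial-domain depositions, and
annotation errors. The synthetic conditions validate the machinery —
frame construction, clustering, core finding, fitting, PCA, statistics —
not the biology of any particular dataset.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear points; collinearity is
  detected via the second singular value of the centered coordinates.
* Mean-fit convergence: 1e-6 Å RMS mean displacement, cap 100 iterations.
* Covariance divisor *n*−1 everywhere; ellipsoid eigenvalues clamped at 0.
* Ties: equal ellipsoid volumes remove the lowest column index; equal
  resolutions prefer more built residues, then lexicographic entry id;
  equal altloc occupancies prefer the alphabetically first identifier.
* Complete-linkage dendrograms are cut strictly *below* the threshold, so
  a pair at exactly the threshold separates, matching the "< 1.0 Å"
  contract.
* PDB output quantizes coordinates to 1e-3 Å (fixed-width format); "zero
  variance" through a file round trip therefore means eigenvalues at the
  1e-7 Ų scale, not machine zero.
* The identity gate (0.95), cluster threshold (1.0 Å), core cutoff
  (0.5 ų) and occupancy (1.0) are all `pipeline_config()` fields and are
  embedded verbatim in `report.json` for audit.

## Scope decisions

* Core finding runs once per dataset (superfamily), not per subfamily —
  the within-superfamily reading of the procedure; the column-set
  arguments make per-subfamily runs possible if wanted.
* The package consumes alignments and accession lists; it does not search
  sequence databases, build alignments, or fetch structures. With
  downloaded coordinate files and a master alignment for a real
  superfamily, the identical `run_pipeline()` call reproduces the
  full-data analysis, including the two-structure heterodimer RMSD
  comparison via `domain_aligned_rmsd()` with an all-shared-position
  frame.
* No B-factor weighting, no outlier-structure rejection, no nonlinear
  dimensionality reduction: the analysis is deliberately the plain linear
  one, whose assumptions (small-ish displacements around a mean, one
  common frame) are stated and checkable.
* The command-line wrapper (`inst/scripts/cytoswitch.R`) is a thin shell
  over the exported functions; the R API is the primary interface.

## Known limitations

Scores depend on the core through the fit: a very small core (the 0.5 ų
default on noisy data can leave ~5 columns) adds rigid-body jitter to all
positions, inflating within-state scatter. The cutoff is the single most
influential undocumented-in-the-field parameter; when in doubt, inspect
the removal trace and the reported core size rather than trusting the
default. Sequence-identical entries with different built-residue sets do
not share a clustering group (the group key is the observed sequence), so
datasets with heavy partial disorder keep more representatives than a
curator might. And eta² quantifies *separation along an axis*, not
discreteness: a continuum stretched along PC1 can score as high as two
clean clusters — the exported score scatter is the check.
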