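# cytoswitch

Comparative ensemble analysis of C-alpha coordinates for detecting
**polymerization-associated conformational switches** in filament-forming
protein superfamilies (actins, tubulins and their prokaryotic homologs).

Filament-forming, nucleotide-hydrolyzing proteins often change subunit
conformation when they assemble: a structure solved inside a filament sits in
a discretely different region of conformational space than the same protein
solved as a free monomer, while the hydrolysis state of the bound nucleotide
barely moves it. `cytoswitch` makes that claim quantitative on any
structure collection: given coordinate files, an annotation manifest and a
master multiple sequence alignment placing every entry in one column frame,
it

1. parses each entry into a per-chain C-alpha model (altloc and multi-model
   handling, annotation classification),
2. maps observed residues to alignment columns by global sequence/row
   reconciliation,
3. collapses redundant identically annotated depositions into
   representatives by complete-linkage RMSD clustering (diameter < 1.0 Å,
   highest resolution wins),
4. finds the structurally invariant core by iteratively discarding the
   alignment column with the largest positional covariance ellipsoid volume
   `V = (4/3)·π·√(λ₁λ₂λ₃)` until the remaining total volume falls below a
   cutoff (0.5 Å³ by default),
5. superposes all structures on that core by iterated mean-reference Kabsch
   fitting,
6. runs principal component analysis on the fitted coordinates
   (`C = Xᶜᵀ Xᶜ/(n−1)`, eigenvalues `λ_k` = variance along component `k`),
   and
7. correlates PC scores with annotations — assembly state, nucleotide
   state, subfamily — via eta-squared (between-group / total score
   variance) with label-permutation nulls, plus point-biserial correlation
   for two-level labels and domain-aligned RMSD matrices (superpose on one
   domain, report RMSD over another).

Components export as loading-vector tables (porcupine-style arrows) and
interpolated morph trajectories
(`frame_j = mean + s_j·√λ·loading`, multi-model PDB).

A first-class synthetic-data generator plants a known switch — a hinge
rotation between two chain halves tied to the assembly-state label — on a
shared helical fold with subfamily-specific deformation modes, Gaussian
noise, alignment indels and unresolved residues, so the entire pipeline is
testable end-to-end without downloading a single structure.

## Worked example

Generate a synthetic superfamily (3 subfamilies × 8 entries × 2 assembly
states, 15° hinge switch, 0.3 Å noise) and run the full pipeline:

```r
library(cytoswitch)

td  <- tempfile()
gen <- generate_ensemble(synthetic_spec(seed = 42), td)
out <- run_pipeline(gen$manifest, gen$alignment, file.path(td, "out"),
                    verbose = FALSE)

print(out$pca)
#> <ensemble_pca> 39 structures, 32 positions; PC1..3 explain 87.2%

out$n_representatives   # 39 (of 48 entries, after RMSD clustering)
out$core_size           # 6  (invariant-core columns)

man <- out$manifest_table
st  <- man$assembly_state[match(rownames(out$pca$scores), man$entry_id)]
point_biserial(out$pca$scores[, 1], st)
#> [1] 0.978

out$separation$assembly_state[1, c("component", "eta_sq", "p_value")]
#>   component    eta_sq p_value
#> 1       PC1 0.9568865   1e-04
out$separation$nucleotide_state[1, c("component", "eta_sq", "p_value")]
#>   component      eta_sq p_value
#> 1       PC1 0.003126632  0.9886
```

Reading the output: PC1 separates polymerized from unpolymerized subunits
almost perfectly (point-biserial r = 0.98; eta² = 0.96 with permutation
p = 1e-4), while the nucleotide-state labels — assigned independently of
conformation by the generator — explain essentially none of the PC1
variance (eta² = 0.003, p = 0.99). That is the switch signature: assembly
state, not hydrolysis state, determines subunit conformation.

All stage outputs land in the output directory as TSV/PDB plus a
`report.json` with the full configuration, counts, variance table and
separation indices. `pc_trajectory()` + `write_trajectory_pdb()` export a
morph movie of any component; `inst/scripts/cytoswitch.R` wraps
simulate/run/morph for shell use.

Real datasets enter the same way: a manifest naming one chain per entry
(with subfamily, ligand codes, declared assembly state where known,
resolution) plus the superfamily master alignment in gapped FASTA.

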