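#' Synthetic switch-recovery study
#'
#' Runs the full pipeline end-to-end on freshly generated synthetic
#' ensembles across several seeds and summarizes how well the first
#' principal component recovers the planted assembly-state switch, and
#' how the planted nucleotide-state null behaves.  Per seed it reports
#' the point-biserial correlation between PC1 score and assembly state,
#' and PC1's nucleotide-state eta-squared against its permutation 95th
#' percentile (labels with fewer than two representatives are dropped
#' first, per the permutation-test precondition).
#'
#' @param seeds Integer vector of generator seeds (one pipeline run per
#'   seed).
#' @param spec_args Named list of [synthetic_spec()] overrides (the seed
#'   is supplied per run).
#' @param n_permutations Permutations for the nucleotide null.
#' @param verbose Log progress.
#' @return Data frame, one row per seed: `seed`, `r_pc1_assembly`,
#'   `eta2_pc1_nucleotide`, `nucleotide_q95`, `exceeds_null`,
#'   `n_representatives`, `core_size`, `pc1_proportion`,
#'   `cumvar_pc1_pc2`.
#' @export
switch_recovery_study <- function(seeds, spec_args = list(),
                                  n_permutations = 999L, verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    spec <- do.call(synthetic_spec, c(spec_args, list(seed = s)))
    td <- tempfile(paste0("switch_seed", s, "_"))
    gen <- generate_ensemble(spec, td)
    out <- run_pipeline(gen$manifest, gen$alignment, file.path(td, "out"),
                        config = pipeline_config(
                          n_permutations = n_permutations, seed = s),
                        verbose = FALSE)
    man <- out$manifest_table
    sc <- out$pca$scores
    st <- man$assembly_state[match(rownames(sc), man$entry_id)]
    r <- point_biserial(sc[, 1], st)

    nuc <- man$nucleotide_state[match(rownames(sc), man$entry_id)]
    tab <- table(nuc)
    usable <- nuc %in% names(tab)[tab >= 2L]
    eta <- q95 <- NA_real_
    if (length(unique(nuc[usable])) >= 2L) {
      sep <- separation_index(sc[usable, 1, drop = FALSE], nuc[usable],
                              n_permutations = n_permutations, seed = s)
      eta <- sep$stats$eta_sq[1]
      q95 <- sep$stats$null_q95[1]
    }
    unlink(td, recursive = TRUE)
    if (verbose)
      message(sprintf("seed %d: |r| = %.3f, eta2(nuc) = %.3f (q95 %.3f)",
                      s, abs(r), eta, q95))
    data.frame(seed = s, r_pc1_assembly = r, eta2_pc1_nucleotide = eta,
               nucleotide_q95 = q95,
               exceeds_null = !is.na(eta) && eta > q95,
               n_representatives = out$n_representatives,
               core_size = out$core_size,
               pc1_proportion = out$variance$complete_columns$proportion[1],
               cumvar_pc1_pc2 = out$variance$complete_columns$cumulative[2])
  })
  do.call(rbind, rows)
}
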