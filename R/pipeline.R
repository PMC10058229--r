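#' Pipeline configuration
#'
#' Houses every tunable the end-to-end analysis uses.  Defaults follow
#' the analysis conventions: representative clustering below 1.0
#' Angstrom RMSD, invariant-core volume cutoff 0.5 cubic Angstrom, strict
#' (1.0) column occupancy, a 95% sequence/row identity gate, and a
#' 9999-permutation separation test.
#'
#' @param cluster_threshold Representative cluster diameter bound (A).
#' @param core_cutoff Invariant-core total ellipsoid volume cutoff (A^3).
#' @param occupancy Column occupancy required for the common frame.
#' @param min_identity Sequence/alignment-row identity gate in `[0,1]`.
#' @param n_components Number of components to tabulate in outputs.
#' @param n_permutations Permutations for the separation tests.
#' @param trajectory_amplitude,trajectory_frames Morph export settings
#'   (SD units / frame count).
#' @param seed Seed for the permutation RNG.
#' @param override Entry ids forced as cluster representatives.
#' @param domains Optional named list of column-index vectors defining
#'   domains for domain-aligned RMSD panels.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cluster_threshold = 1.0, core_cutoff = 0.5,
                            occupancy = 1.0, min_identity = 0.95,
                            n_components = 10L, n_permutations = 9999L,
                            trajectory_amplitude = 2, trajectory_frames = 15L,
                            seed = 1L, override = NULL, domains = NULL) {
  stopifnot(cluster_threshold > 0, core_cutoff > 0, occupancy > 0,
            min_identity > 0, n_permutations > 0)
  structure(list(cluster_threshold = cluster_threshold,
                 core_cutoff = core_cutoff, occupancy = occupancy,
                 min_identity = min_identity,
                 n_components = as.integer(n_components),
                 n_permutations = as.integer(n_permutations),
                 trajectory_amplitude = trajectory_amplitude,
                 trajectory_frames = as.integer(trajectory_frames),
                 seed = as.integer(seed), override = override,
                 domains = domains),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  do.call(pipeline_config, yaml::yaml.load_file(path))
}

.stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full comparative analysis pipeline
#'
#' Ingest -> alignment-frame mapping -> representative selection ->
#' invariant-core detection -> core superposition -> PCA -> annotation
#' separation analysis.  All stage outputs are written under
#' `output_dir` as TSV/PDB plus a machine-readable `report.json`
#' embedding the configuration, per-stage entry counts, the core size,
#' the variance table, and the separation indices.  Outputs are pure
#' functions of (inputs, config, seed): a rerun writes byte-identical
#' tables.
#'
#' @param manifest Path to the entry manifest TSV (see
#'   [read_manifest()]).
#' @param alignment Path to the master alignment FASTA.
#' @param output_dir Directory for stage outputs (created if needed).
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress and timing to standard error.
#' @return The run report as a list, invisibly.
#' @export
run_pipeline <- function(manifest, alignment, output_dir,
                         config = pipeline_config(), verbose = TRUE) {
  t0 <- Sys.time()
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .stage_log(verbose, name, "done in %.2fs",
               as.numeric(difftime(Sys.time(), ts, units = "secs")))
    out
  }

  man <- stage("ingest:manifest", read_manifest(manifest))
  aln <- stage("ingest:alignment", read_master_alignment(alignment))

  models <- stage("ingest:structures", {
    lapply(seq_len(nrow(man)), function(i) {
      if (!file.exists(man$path[i]))
        stop("entry '", man$entry_id[i], "': file not found: ", man$path[i])
      read_structure(man$path[i], man$entry_id[i], man$chain[i],
                     resolution = man$resolution[i])
    })
  })

  maps <- stage("map", {
    lapply(models, function(m) {
      if (!m$entry_id %in% names(aln$rows))
        stop("entry '", m$entry_id, "' has no row in the master alignment")
      map_to_alignment(m, aln$rows[[m$entry_id]],
                       min_identity = config$min_identity)
    })
  })

  ens_all <- stage("ensemble", build_ensemble(models, maps, aln))
  seqs <- stats::setNames(vapply(models, extract_sequence, character(1)),
                          ens_all$entry_ids)

  clusters <- stage("representatives", {
    cluster_and_pick(ens_all, man, seqs,
                     threshold = config$cluster_threshold,
                     override = config$override)
  })
  reps <- representatives(clusters)
  write_cluster_report(clusters, file.path(output_dir, "clusters.tsv"),
                       file.path(output_dir, "cluster_rmsd.tsv"))
  ens <- subset_entries(ens_all, reps)

  cols <- stage("frame", complete_columns(ens, occupancy = config$occupancy))

  core <- stage("core",
                find_invariant_core(ens, cols, cutoff = config$core_cutoff))
  write_core_trace(core, file.path(output_dir, "core_trace.tsv"),
                   file.path(output_dir, "core_columns.tsv"))

  fit <- stage("fit", fit_on_core(ens, core$core))
  write_ensemble_pdb(fit$ensemble, file.path(output_dir, "fitted.pdb"),
                     columns = cols)

  res <- stage("pca", ensemble_pca(fit$ensemble, cols))
  write_pca_tables(res, output_dir, n_components = config$n_components)
  # variance is also reported over the core columns only, so the choice
  # of analysis frame (complete columns vs core) stays auditable
  res_core <- stage("pca:core", ensemble_pca(fit$ensemble, core$core))

  rep_ann <- man[match(reps, man$entry_id), ]
  sep <- stage("annotate", {
    out <- list()
    for (lab in c("assembly_state", "nucleotide_state", "subfamily")) {
      labels <- stats::setNames(rep_ann[[lab]], rep_ann$entry_id)
      usable <- !(labels %in% "special") & !is.na(labels)
      tab <- table(labels[usable])
      if (length(tab) >= 2L && all(tab >= 2L)) {
        out[[lab]] <- separation_index(
          res$scores, labels, n_permutations = config$n_permutations,
          seed = config$seed)
      } else {
        .stage_log(verbose, "annotate",
                   "skipping '%s': fewer than 2 usable labels or <2 per label", lab)
      }
    }
    out
  })
  sep_tab <- do.call(rbind, lapply(names(sep), function(lab) {
    s <- sep[[lab]]$stats
    s$annotation <- lab
    s
  }))
  if (!is.null(sep_tab))
    utils::write.table(sep_tab, file.path(output_dir, "separation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  # plot-ready score scatter keyed by every annotation
  scatter <- data.frame(entry_id = rownames(res$scores),
                        res$scores[, seq_len(min(3L, ncol(res$scores))),
                                   drop = FALSE],
                        rep_ann[, c("subfamily", "nucleotide_state",
                                    "assembly_state")])
  utils::write.table(scatter, file.path(output_dir, "scores_annotated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("cytoswitch")),
    config = unclass(config),
    n_entries = nrow(man),
    n_representatives = length(reps),
    representatives = reps,
    n_complete_columns = length(cols),
    core_size = length(core$core),
    core_start_volume = core$start_volume,
    variance = list(
      complete_columns = list(
        eigenvalues = res$eigenvalues,
        proportion = res$proportion,
        cumulative = cumsum(res$proportion)),
      core_columns = list(
        eigenvalues = res_core$eigenvalues,
        proportion = res_core$proportion,
        cumulative = cumsum(res_core$proportion))),
    separation = lapply(sep, function(s) s$stats),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  json <- jsonlite::toJSON(report[setdiff(names(report), "elapsed_seconds")],
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(output_dir, "report.json"))
  .stage_log(verbose, "done", "pipeline finished in %.1fs",
             report$elapsed_seconds)

  invisible(c(report, list(
    ensemble = ens, fitted = fit$ensemble, core = core, pca = res,
    pca_core = res_core, clusters = clusters, separation_reports = sep,
    manifest_table = man, columns = cols)))
}
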