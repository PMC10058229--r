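#' Pairwise C-alpha RMSD between two ensemble entries
#'
#' Optimal rigid superposition (Kabsch) over the shared occupied columns
#' (optionally restricted to `columns`), then RMSD over those columns.
#'
#' @param ens An [ensemble_matrix()].
#' @param i,j Entry ids or indices.
#' @param columns Optional columns to restrict to; both entries must
#'   occupy them.
#' @return RMSD in Angstrom.
#' @export
pairwise_rmsd <- function(ens, i, j, columns = NULL) {
  idx <- function(e) if (is.character(e)) match(e, ens$entry_ids) else e
  i <- idx(i); j <- idx(j)
  shared <- which(ens$mask[i, ] & ens$mask[j, ])
  if (!is.null(columns)) {
    if (!all(columns %in% shared))
      stop("entries do not both occupy all requested columns")
    shared <- sort(as.integer(columns))
  }
  if (length(shared) < 3L)
    stop("fewer than 3 shared columns between entries ",
         ens$entry_ids[i], " and ", ens$entry_ids[j])
  kabsch(ens$coords[i, shared, ], ens$coords[j, shared, ])$rmsd
}

#' Cluster identically annotated structures and pick representatives
#'
#' Within each annotation group — same observed mapped-column sequence,
#' same nucleotide state, same assembly state — structures are clustered
#' by pairwise post-fit C-alpha RMSD with complete-linkage agglomeration
#' cut strictly below `threshold`, which guarantees every cluster's
#' diameter (maximum intra-cluster RMSD) is below the threshold.  Each
#' cluster contributes one representative: the highest-resolution member;
#' ties broken by most built residues, then lexicographic entry id.  A
#' manual override names entries that must represent their cluster
#' regardless (flagged with reason `"override"`).
#'
#' @param ens An [ensemble_matrix()] of all candidate entries.
#' @param annotations Data frame with columns `entry_id`,
#'   `nucleotide_state`, `assembly_state`, `resolution` (and optionally
#'   `sequence`; if absent the group sequence key is derived from the
#'   occupancy-masked residue pattern supplied via `sequences`).
#' @param sequences Named character vector of observed sequences keyed by
#'   entry id (used as the "same sequence" part of the group key).
#' @param threshold Cluster diameter bound in Angstrom (default 1.0).
#' @param override Character vector of entry ids to force as
#'   representatives of their clusters.
#' @return A `cluster_report`: data frame `members` (`entry_id`, `group`,
#'   `cluster`, `is_representative`, `reason`), plus per-group RMSD
#'   matrices in `rmsd`.
#' @export
cluster_and_pick <- function(ens, annotations, sequences,
                             threshold = 1.0, override = NULL) {
  stopifnot(nrow(annotations) >= 1L)
  ann <- annotations
  if (!all(ann$entry_id %in% ens$entry_ids))
    stop("annotations contain entries absent from the ensemble")
  seqs <- sequences[ann$entry_id]
  group <- paste(seqs, ann$nucleotide_state, ann$assembly_state, sep = "|")
  # stable, order-insensitive group labels
  glab <- paste0("g", match(group, sort(unique(group))))

  members <- NULL
  rmsd_list <- list()
  for (g in sort(unique(glab))) {
    ids <- sort(ann$entry_id[glab == g])
    m <- length(ids)
    if (m == 1L) {
      cl <- stats::setNames(1L, ids)
      D <- matrix(0, 1, 1, dimnames = list(ids, ids))
    } else {
      D <- matrix(0, m, m, dimnames = list(ids, ids))
      for (a in seq_len(m - 1)) for (b in (a + 1):m)
        D[a, b] <- D[b, a] <- pairwise_rmsd(ens, ids[a], ids[b])
      hc <- stats::hclust(stats::as.dist(D), method = "complete")
      # cut strictly below threshold: merges at exactly the threshold split
      cl <- stats::cutree(hc, h = threshold * (1 - 1e-9))
    }
    rmsd_list[[g]] <- D
    for (k in sort(unique(cl))) {
      cids <- names(cl)[cl == k]
      res <- ann$resolution[match(cids, ann$entry_id)]
      built <- rowSums(ens$mask[match(cids, ens$entry_ids), , drop = FALSE])
      ov <- intersect(override, cids)
      if (length(ov) >= 1L) {
        rep_id <- sort(ov)[1]
        reason <- "override"
      } else {
        ord <- order(res, -built, cids)  # low res value = high resolution
        rep_id <- cids[ord[1]]
        reason <- if (length(cids) > 1L &&
                      sum(res == res[ord[1]], na.rm = TRUE) > 1L)
          "completeness" else "resolution"
      }
      members <- rbind(members, data.frame(
        entry_id = cids, group = g, cluster = paste0(g, ".", k),
        is_representative = cids == rep_id,
        reason = ifelse(cids == rep_id, reason, ""),
        stringsAsFactors = FALSE))
    }
  }
  rownames(members) <- NULL
  structure(list(members = members, rmsd = rmsd_list,
                 threshold = threshold),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d entries -> %d clusters (threshold %.2f A)\n",
              nrow(x$members), length(unique(x$members$cluster)),
              x$threshold))
  invisible(x)
}

#' Representatives chosen by a cluster report
#' @param report A `cluster_report`.
#' @return Character vector of representative entry ids, sorted.
#' @export
representatives <- function(report) {
  sort(report$members$entry_id[report$members$is_representative])
}

#' Write a cluster report (and its RMSD matrices) as TSV
#' @param report A `cluster_report`.
#' @param members_path Output TSV for the membership table.
#' @param rmsd_path Optional output TSV for the stacked RMSD matrices
#'   (long format: group, entry_a, entry_b, rmsd).
#' @return `members_path`, invisibly.
#' @export
write_cluster_report <- function(report, members_path, rmsd_path = NULL) {
  utils::write.table(report$members, members_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(rmsd_path)) {
    long <- do.call(rbind, lapply(names(report$rmsd), function(g) {
      D <- report$rmsd[[g]]
      idx <- which(upper.tri(D, diag = TRUE), arr.ind = TRUE)
      data.frame(group = g, entry_a = rownames(D)[idx[, 1]],
                 entry_b = colnames(D)[idx[, 2]], rmsd = D[idx])
    }))
    utils::write.table(long, rmsd_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(members_path)
}
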