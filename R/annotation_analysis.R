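#' How strongly an annotation separates structures along each component
#'
#' Quantifies, per principal component, the fraction of score variance
#' explained by a categorical annotation as eta-squared
#' (between-group sum of squares / total sum of squares), with a
#' label-permutation null distribution for calibration.  Entries labeled
#' special/ambiguous are excluded from the statistic (but counted), the
#' same treatment the score scatter gives such structures.
#'
#' @param scores Numeric matrix of PC scores (entries x components) with
#'   entry ids as rownames, e.g. `res$scores` from [ensemble_pca()].
#' @param labels Character/factor annotation vector, aligned with the
#'   score rows (or named by entry id).
#' @param n_permutations Size of the permutation null (default 9999).
#' @param exclude Label values to exclude (default `"special"`).
#' @param seed Optional integer seed for the permutation RNG; if `NULL`
#'   the current RNG stream is used.
#' @return A `separation_report`: data frame `stats` (`component`,
#'   `eta_sq`, `p_value`, `null_q95`, `null_mean`), plus `groups`
#'   (per-label mean score and size per component), `n_excluded`,
#'   `n_permutations`.
#' @export
separation_index <- function(scores, labels, n_permutations = 9999L,
                             exclude = "special", seed = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(names(labels)) && !is.null(rownames(scores)))
    labels <- labels[rownames(scores)]
  if (length(labels) != nrow(scores))
    stop("labels must align with score rows")
  keep <- !(as.character(labels) %in% exclude) & !is.na(labels)
  n_excluded <- sum(!keep)
  y <- scores[keep, , drop = FALSE]
  f <- factor(as.character(labels)[keep])
  if (nlevels(f) < 2L)
    stop("need at least 2 annotation labels for a separation index")
  if (any(table(f) < 2L))
    stop("need at least 2 entries per label for the permutation test")
  if (!is.null(seed)) set.seed(seed)

  eta_sq <- function(y, f) {
    # between-group SS / total SS, columnwise
    tot <- colSums(sweep(y, 2, colMeans(y))^2)
    gm <- rowsum(y, f) / as.vector(table(f))
    btw <- colSums(sweep(gm, 2, colMeans(y))^2 * as.vector(table(f)))
    ifelse(tot > 0, btw / tot, 0)
  }
  obs <- eta_sq(y, f)
  null <- matrix(NA_real_, n_permutations, ncol(y))
  for (p in seq_len(n_permutations))
    null[p, ] <- eta_sq(y, sample(f))
  pval <- (colSums(sweep(null, 2, obs, `>=`)) + 1) / (n_permutations + 1)
  q95 <- apply(null, 2, stats::quantile, probs = 0.95, names = FALSE)

  comp <- colnames(scores)
  if (is.null(comp)) comp <- paste0("PC", seq_len(ncol(scores)))
  gm <- rowsum(y, f) / as.vector(table(f))
  groups <- data.frame(label = rep(levels(f), ncol(y)),
                       component = rep(comp, each = nlevels(f)),
                       mean_score = as.vector(gm),
                       n = rep(as.vector(table(f)), ncol(y)))
  structure(list(
    stats = data.frame(component = comp, eta_sq = unname(obs),
                       p_value = unname(pval), null_q95 = unname(q95),
                       null_mean = unname(colMeans(null))),
    groups = groups, n_excluded = n_excluded,
    n_permutations = n_permutations),
    class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("<separation_report> %d permutations, %d excluded\n",
              x$n_permutations, x$n_excluded))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Domain-aligned RMSD between two structures
#'
#' Superposes `b` onto `a` using only the fit positions (e.g. one
#' domain), then reports RMSD over a possibly different set of positions
#' — the construction behind "aligned on the N-terminal domain" style
#' comparisons, where the reported RMSD measures how much the *other*
#' domain moves.  For heterodimers, concatenate the ordered chain pair's
#' positions into one coordinate matrix before calling.
#'
#' @param a,b Coordinate matrices (positions x 3) in a common position
#'   frame (same row ordering), or an [ensemble_matrix()] with `a`, `b`
#'   given as entry ids/indices.
#' @param fit_idx Row indices (or alignment columns, for an ensemble) to
#'   superpose on; at least 3.
#' @param report_idx Row indices/columns to compute the RMSD over;
#'   defaults to `fit_idx`.
#' @return RMSD in Angstrom.
#' @export
domain_aligned_rmsd <- function(a, b, fit_idx, report_idx = fit_idx) {
  if (inherits(a, "ensemble_matrix")) {
    ens <- a
    idx <- function(e) if (is.character(e)) match(e, ens$entry_ids) else e
    shared <- ens$mask[idx(b[1]), ] & ens$mask[idx(b[2]), ]
    if (!all(shared[fit_idx]) || !all(shared[report_idx]))
      stop("entries do not both occupy the fit/report columns")
    A <- ens$coords[idx(b[1]), , ]
    B <- ens$coords[idx(b[2]), , ]
    return(domain_aligned_rmsd(A, B, fit_idx, report_idx))
  }
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("a and b must have identical dimensions")
  if (length(fit_idx) < 3L) stop("need at least 3 fit positions")
  if (any(fit_idx > nrow(a)) || any(report_idx > nrow(a)))
    stop("insufficient overlap: indices outside the shared frame")
  sp <- kabsch(a[fit_idx, , drop = FALSE], b[fit_idx, , drop = FALSE])
  b_fit <- apply_superposition(b, sp)
  rmsd_raw(a[report_idx, , drop = FALSE], b_fit[report_idx, , drop = FALSE])
}

#' All-pairs domain-aligned RMSD matrix
#'
#' @param ens An [ensemble_matrix()].
#' @param entries Entry ids (default all) to compare.
#' @param fit_columns Columns to superpose on.
#' @param report_columns Columns to report RMSD over (default
#'   `fit_columns`).
#' @return A `domain_rmsd_report`: symmetric matrix with zero diagonal
#'   plus the column sets used.
#' @export
rmsd_matrix <- function(ens, entries = ens$entry_ids, fit_columns,
                        report_columns = fit_columns) {
  if (length(entries) < 2L) stop("need at least 2 entries")
  m <- length(entries)
  D <- matrix(0, m, m, dimnames = list(entries, entries))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ci <- ens$coords[match(entries[i], ens$entry_ids), , ]
    cj <- ens$coords[match(entries[j], ens$entry_ids), , ]
    ok <- ens$mask[match(entries[i], ens$entry_ids), ] &
          ens$mask[match(entries[j], ens$entry_ids), ]
    if (!all(ok[fit_columns]) || !all(ok[report_columns]))
      stop("entries ", entries[i], "/", entries[j],
           " do not occupy the fit/report columns")
    D[i, j] <- D[j, i] <- domain_aligned_rmsd(ci, cj, fit_columns,
                                              report_columns)
  }
  structure(list(rmsd = D, fit_columns = fit_columns,
                 report_columns = report_columns),
            class = "domain_rmsd_report")
}

#' @export
print.domain_rmsd_report <- function(x, ...) {
  cat(sprintf("<domain_rmsd_report> %d entries; fit on %d, report over %d columns\n",
              nrow(x$rmsd), length(x$fit_columns), length(x$report_columns)))
  invisible(x)
}

#' Point-biserial correlation between a score and a two-level label
#'
#' The Pearson correlation between a continuous score and a 0/1 coding
#' of a binary annotation — the package's summary of how cleanly a
#' single component separates, e.g., polymerized from unpolymerized
#' subunits.
#'
#' @param score Numeric vector.
#' @param labels Two-level annotation aligned with `score`.
#' @return Correlation in `[-1, 1]`.
#' @export
point_biserial <- function(score, labels) {
  f <- factor(as.character(labels))
  if (nlevels(f) != 2L) stop("labels must have exactly 2 levels")
  stats::cor(score, as.numeric(f) - 1)
}
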