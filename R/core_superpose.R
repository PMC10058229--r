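#' Optimal rigid superposition of two point sets (Kabsch algorithm)
#'
#' Computes the proper rotation and translation that superpose `Y` onto
#' `X` in the least-squares sense, via singular value decomposition of the
#' cross-covariance matrix.  Reflections are corrected by flipping the
#' sign of the smallest singular value's axis, so the returned rotation
#' always has determinant +1.
#'
#' The convention is row-vector: the fitted copy of `Y` is
#' `sweep(Y, 2, cy) %*% rotation + rep(cx)`, i.e. centre `Y` on its
#' (weighted) centroid `cy`, right-multiply by `rotation`, then translate
#' to `X`'s centroid `cx`.  [apply_superposition()] does exactly this.
#'
#' @param X Reference coordinates, n x 3 matrix (n >= 3, not collinear).
#' @param Y Mobile coordinates, n x 3 matrix, rows corresponding to `X`.
#' @param weights Optional non-negative per-point weights.
#' @return A `superposition` list: `rotation` (3 x 3, det +1),
#'   `translation` (length-3; `cx - cy %*% rotation` so that
#'   `Y %*% rotation + translation` is the fitted copy), centroids
#'   `cx`/`cy`, and `rmsd` (Angstrom, weighted if weights given).
#' @export
kabsch <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != 3L || ncol(Y) != 3L || nrow(X) != nrow(Y))
    stop("X and Y must be n x 3 matrices of equal size")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 points to superpose")
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite coordinates")
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
    weights
  }
  wn <- w / sum(w)
  cx <- colSums(X * wn); cy <- colSums(Y * wn)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)

  # degeneracy: all points (weighted) collinear in either set
  for (M in list(Xc, Yc)) {
    sv <- svd(M * sqrt(wn), nu = 0, nv = 0)$d
    if (sv[2] <= max(sv[1], 1) * 1e-10)
      stop("degenerate (collinear) point set: rotation not determined")
  }

  C <- t(Yc * wn) %*% Xc
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Yc %*% R
  rmsd <- sqrt(sum(wn * rowSums((Xc - fitted)^2)))
  structure(list(rotation = R,
                 translation = as.vector(cx - cy %*% R),
                 cx = cx, cy = cy, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param coordinates m x 3 matrix (any points expressed in the mobile
#'   frame, not only those used for the fit).
#' @param sp A `superposition` from [kabsch()].
#' @return m x 3 matrix of transformed coordinates.
#' @export
apply_superposition <- function(coordinates, sp) {
  sweep(as.matrix(coordinates) %*% sp$rotation, 2, sp$translation, `+`)
}

#' Root mean square deviation without refitting
#' @param A,B n x 3 coordinate matrices already in a common frame.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(A, B) sqrt(mean(rowSums((as.matrix(A) - as.matrix(B))^2)))

# internal: check that every entry occupies the given columns
.require_occupied <- function(ens, columns) {
  ok <- apply(ens$mask[, columns, drop = FALSE], 1, all)
  if (!all(ok))
    stop("entries not occupying all fit columns: ",
         paste(ens$entry_ids[!ok], collapse = ", "))
}

#' Iterated mean-reference superposition of an ensemble
#'
#' All entries are first fitted (over `columns`) onto the first entry,
#' then repeatedly onto the column-wise mean of the fitted ensemble until
#' the mean stops moving (RMS displacement below `tol`) or `max_iter`
#' rounds.  Each entry's whole coordinate row is transformed, not only the
#' fit columns, so downstream per-column statistics see consistently
#' posed chains.
#'
#' @param ens An [ensemble_matrix()].
#' @param columns Alignment columns to fit on; every entry must occupy
#'   all of them.
#' @param tol Convergence threshold on the RMS displacement of the mean
#'   between rounds (Angstrom).
#' @param max_iter Maximum number of refitting rounds.
#' @return List: `ensemble` (fitted copy), `mean` (length(columns) x 3),
#'   `iterations`, `mean_shift` (per-round RMS mean displacement).
#' @export
iterative_mean_fit <- function(ens, columns, tol = 1e-6, max_iter = 100L) {
  columns <- sort(as.integer(columns))
  if (length(columns) < 3L) stop("need at least 3 fit columns")
  .require_occupied(ens, columns)
  n <- length(ens$entry_ids)

  fit_all <- function(coords, ref) {
    for (e in seq_len(n)) {
      sp <- kabsch(ref, coords[e, columns, ], weights = NULL)
      occ <- ens$mask[e, ]
      coords[e, occ, ] <- apply_superposition(coords[e, occ, , drop = TRUE], sp)
    }
    coords
  }
  col_mean <- function(coords)
    apply(coords[, columns, , drop = FALSE], c(2, 3), mean)

  coords <- ens$coords
  coords <- fit_all(coords, coords[1, columns, ])
  m <- col_mean(coords)
  shifts <- numeric(0)
  for (it in seq_len(max_iter)) {
    coords <- fit_all(coords, m)
    m2 <- col_mean(coords)
    shift <- sqrt(mean(rowSums((m2 - m)^2)))
    shifts <- c(shifts, shift)
    m <- m2
    if (shift < tol) break
  }
  out <- ens
  out$coords <- coords
  list(ensemble = out, mean = m, iterations = length(shifts),
       mean_shift = shifts)
}

# internal: per-column covariance ellipsoid volumes across entries
# covariance divisor n - 1; tiny negative eigenvalues clamped to zero
.column_volumes <- function(coords, columns) {
  vapply(columns, function(cc) {
    P <- coords[, cc, ]
    ev <- eigen(stats::cov(P), symmetric = TRUE, only.values = TRUE)$values
    ev[ev < 0] <- 0
    (4 / 3) * pi * sqrt(prod(ev))
  }, numeric(1))
}

#' Find the structurally invariant core of an ensemble
#'
#' Iterative high-variance position removal: the ensemble is
#' mean-reference fitted on the current column set, each column's
#' positional scatter across entries is summarized as the volume of its
#' covariance ellipsoid, `(4/3) * pi * sqrt(l1 * l2 * l3)` with
#' eigenvalues of the 3 x 3 covariance (divisor n - 1; negatives clamped
#' to 0), and the single largest-volume column is removed (ties broken
#' toward the lowest column index).  Removal repeats until the total
#' remaining volume drops to `cutoff` or only 3 columns remain.  The full
#' removal trace is recorded so the cut is auditable.
#'
#' @param ens An [ensemble_matrix()] with at least 2 entries.
#' @param start_columns Columns to start from; every entry must occupy
#'   all of them (typically [complete_columns()]).
#' @param cutoff Total remaining ellipsoid volume (cubic Angstrom) at
#'   which removal stops.
#' @param tol,max_iter Passed to [iterative_mean_fit()].
#' @return A `core_trace` list: `trace` data frame (`step`, `column`,
#'   `column_volume`, `remaining_volume`), `core` (selected columns,
#'   ascending), `cutoff`, `start_volume`.
#' @export
find_invariant_core <- function(ens, start_columns, cutoff = 0.5,
                                tol = 1e-6, max_iter = 100L) {
  start_columns <- sort(as.integer(start_columns))
  if (length(start_columns) < 3L) stop("need at least 3 start columns")
  if (length(ens$entry_ids) < 2L) stop("need at least 2 entries")
  .require_occupied(ens, start_columns)

  current <- start_columns
  trace <- data.frame(step = integer(0), column = integer(0),
                      column_volume = numeric(0),
                      remaining_volume = numeric(0))
  start_volume <- NA_real_
  step <- 0L
  repeat {
    fit <- iterative_mean_fit(ens, current, tol = tol, max_iter = max_iter)
    vols <- .column_volumes(fit$ensemble$coords, current)
    total <- sum(vols)
    if (step == 0L) start_volume <- total
    if (total <= cutoff || length(current) <= 3L) break
    worst <- which.max(vols)  # which.max takes the first (lowest index) tie
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, column = current[worst],
      column_volume = vols[worst],
      remaining_volume = total - vols[worst]))
    current <- current[-worst]
  }
  structure(list(trace = trace, core = current, cutoff = cutoff,
                 start_volume = start_volume),
            class = "core_trace")
}

#' @export
print.core_trace <- function(x, ...) {
  cat(sprintf(
    "<core_trace> %d columns removed, %d in core (cutoff %.3g A^3, start volume %.3g A^3)\n",
    nrow(x$trace), length(x$core), x$cutoff, x$start_volume))
  invisible(x)
}

#' Write a core trace as TSV
#' @param ct A `core_trace`.
#' @param trace_path Output TSV for the removal trace.
#' @param core_path Optional output TSV (one column) for the core columns.
#' @return `trace_path`, invisibly.
#' @export
write_core_trace <- function(ct, trace_path, core_path = NULL) {
  utils::write.table(ct$trace, trace_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(core_path))
    utils::write.table(data.frame(column = ct$core), core_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(trace_path)
}

#' Superpose an ensemble on its invariant core
#'
#' Mean-reference fitting restricted to the core columns; whole-chain
#' coordinates are transformed accordingly.
#'
#' @param ens An [ensemble_matrix()].
#' @param core_columns Core columns (every entry must occupy them).
#' @inheritParams iterative_mean_fit
#' @return As [iterative_mean_fit()].
#' @export
fit_on_core <- function(ens, core_columns, tol = 1e-6, max_iter = 100L) {
  iterative_mean_fit(ens, core_columns, tol = tol, max_iter = max_iter)
}
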