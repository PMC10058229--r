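#' Principal component analysis of core-fitted C-alpha coordinates
#'
#' Each entry is flattened to a 3L vector over the analysis columns
#' (x, y, z per column, columns in ascending order), mean-centered, and
#' the covariance (divisor n - 1) eigendecomposed.  For reproducibility
#' across platforms each component is oriented so that its
#' largest-magnitude loading element is positive.  Scores are the
#' centered data projected on the loadings, so the score covariance is
#' diagonal with the eigenvalues on the diagonal.
#'
#' The ensemble should already be superposed (see [fit_on_core()]):
#' PCA itself performs no fitting.
#'
#' @param ens A fitted [ensemble_matrix()] with at least 3 entries.
#' @param columns Analysis columns (fully occupied by every entry);
#'   typically [complete_columns()] after fitting on the invariant core.
#' @return An `ensemble_pca` list: `columns`, `mean` (3L vector),
#'   `eigenvalues` (descending, Angstrom^2), `proportion` (summing to 1),
#'   `scores` (entries x components, rownames = entry ids), `loadings`
#'   (3L x components, orthonormal), `sign_convention`.
#' @export
ensemble_pca <- function(ens, columns) {
  columns <- sort(as.integer(columns))
  n <- length(ens$entry_ids)
  if (n < 3L) stop("need at least 3 entries for PCA")
  .require_occupied(ens, columns)
  X <- t(vapply(seq_len(n), function(e)
    as.vector(t(ens$coords[e, columns, ])), numeric(3 * length(columns))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  # SVD route: numerically stabler than eigen(cov) and O(n^2 p)
  sv <- svd(Xc, nu = 0)
  k <- min(n - 1L, ncol(Xc))
  eig <- (sv$d[seq_len(k)]^2) / (n - 1)
  V <- sv$v[, seq_len(k), drop = FALSE]
  # orient: largest-|element| loading entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  rownames(scores) <- ens$entry_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(V) <- paste0("PC", seq_len(k))
  total <- sum(Xc^2) / (n - 1)
  structure(list(columns = columns, mean = mu, eigenvalues = eig,
                 proportion = if (total > 0) eig / total else rep(0, k),
                 scores = scores, loadings = V,
                 sign_convention = "largest-|element| positive"),
            class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  k <- min(3L, length(x$proportion))
  cat(sprintf("<ensemble_pca> %d structures, %d positions; PC1..%d explain %.1f%%\n",
              nrow(x$scores), length(x$columns), k,
              100 * sum(x$proportion[seq_len(k)])))
  invisible(x)
}

#' Cumulative proportion of variance explained
#' @param res An [ensemble_pca()] result.
#' @param k Number of leading components.
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(res, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > length(res$proportion))
    stop("k must be in 1..", length(res$proportion))
  sum(res$proportion[seq_len(k)])
}

#' Per-position loading vectors of one component
#'
#' Reshapes a unit loading into per-column (dx, dy, dz) displacement
#' triplets plus magnitudes, the data behind porcupine-style arrow
#' rendering on a representative structure.
#'
#' @param res An [ensemble_pca()] result.
#' @param pc Component index (1-based).
#' @return Data frame: `column`, `dx`, `dy`, `dz`, `magnitude`.  Squared
#'   magnitudes sum to 1 across columns.
#' @export
loading_vectors <- function(res, pc) {
  if (!is.numeric(pc) || length(pc) != 1L || pc < 1L ||
      pc > ncol(res$loadings))
    stop("pc must be in 1..", ncol(res$loadings))
  v <- matrix(res$loadings[, pc], ncol = 3, byrow = TRUE)
  data.frame(column = res$columns, dx = v[, 1], dy = v[, 2], dz = v[, 3],
             magnitude = sqrt(rowSums(v^2)))
}

#' Morph trajectory along one principal component
#'
#' Frame j is `mean + s_j * sqrt(eigenvalue) * loading` with `s_j`
#' linearly spaced over `[-amplitude, +amplitude]` (standard-deviation
#' units).  With an odd frame count the middle frame is exactly the mean.
#'
#' @param res An [ensemble_pca()] result.
#' @param pc Component index (1-based).
#' @param amplitude Half-range in SD units.
#' @param n_frames Number of frames (>= 2).
#' @return A `pc_trajectory` list: `coords` (n_frames x L x 3 array),
#'   `columns`, `pc`, `sd_units` (the s_j), `scores` (s_j * sqrt(lambda)).
#' @export
pc_trajectory <- function(res, pc, amplitude = 2, n_frames = 15L) {
  if (n_frames < 2L) stop("need at least 2 frames")
  if (pc < 1L || pc > ncol(res$loadings))
    stop("pc must be in 1..", ncol(res$loadings))
  s <- seq(-amplitude, amplitude, length.out = n_frames)
  lam <- res$eigenvalues[pc]
  flat <- outer(s * sqrt(lam), res$loadings[, pc]) +
    matrix(res$mean, n_frames, length(res$mean), byrow = TRUE)
  L <- length(res$columns)
  arr <- array(NA_real_, dim = c(n_frames, L, 3))
  for (f in seq_len(n_frames))
    arr[f, , ] <- matrix(flat[f, ], ncol = 3, byrow = TRUE)
  structure(list(coords = arr, columns = res$columns, pc = pc,
                 sd_units = s, scores = s * sqrt(lam)),
            class = "pc_trajectory")
}

#' Write a morph trajectory as a multi-model PDB
#'
#' @param traj A [pc_trajectory()].
#' @param path Output PDB path.
#' @param resno Residue numbering for the frames; defaults to the
#'   alignment columns, or supply a representative's author numbering.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, resno = NULL) {
  L <- length(traj$columns)
  if (is.null(resno)) resno <- traj$columns
  if (length(resno) != L) stop("resno must have one entry per column")
  xyz <- t(vapply(seq_len(dim(traj$coords)[1]), function(f)
    as.vector(t(traj$coords[f, , ])), numeric(3 * L)))
  bio3d::write.pdb(file = path, xyz = bio3d::as.xyz(xyz),
                   resno = resno, resid = rep("ALA", L),
                   elety = rep("CA", L), chain = rep("A", L))
  invisible(path)
}

#' Project coordinates into an existing PC space
#'
#' The structure is rigidly superposed (Kabsch) onto the PCA mean over
#' the PCA columns, mean-centered, and dotted with the loadings.
#' Projecting an ensemble member used in the PCA reproduces its stored
#' score row.
#'
#' @param coordinates L x 3 matrix over exactly the PCA columns (in
#'   column order), or an [ensemble_matrix()] entry occupying them.
#' @param res An [ensemble_pca()] result.
#' @return Numeric score vector (one value per component).
#' @export
project_structure <- function(coordinates, res) {
  L <- length(res$columns)
  X <- as.matrix(coordinates)
  if (nrow(X) != L || ncol(X) != 3L)
    stop("coordinates must be ", L, " x 3 over the PCA columns")
  mean_mat <- matrix(res$mean, ncol = 3, byrow = TRUE)
  sp <- kabsch(mean_mat, X)
  flat <- as.vector(t(apply_superposition(X, sp))) - res$mean
  drop(flat %*% res$loadings)
}

#' Write PCA summary tables as TSV
#'
#' @param res An [ensemble_pca()] result.
#' @param dir Output directory.
#' @param n_components Number of components to tabulate (default all).
#' @return Character vector of written paths, invisibly.
#' @export
write_pca_tables <- function(res, dir, n_components = NULL) {
  k <- length(res$eigenvalues)
  if (!is.null(n_components)) k <- min(k, n_components)
  p1 <- file.path(dir, "pca_variance.tsv")
  utils::write.table(
    data.frame(component = seq_len(k),
               eigenvalue = res$eigenvalues[seq_len(k)],
               proportion = res$proportion[seq_len(k)],
               cumulative = cumsum(res$proportion)[seq_len(k)]),
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "pca_scores.tsv")
  utils::write.table(
    data.frame(entry_id = rownames(res$scores),
               res$scores[, seq_len(k), drop = FALSE]),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "pca_loadings.tsv")
  tabs <- lapply(seq_len(k), function(j) {
    lv <- loading_vectors(res, j)
    lv$component <- j
    lv
  })
  utils::write.table(do.call(rbind, tabs), p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2, p3))
}
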