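# Independent oracles used to cross-check the closed-form implementations.

# Brute-force superposition RMSD: minimize over rotations parameterized as
# unit quaternions, by random-grid search followed by Nelder-Mead polish.
# Shares no code path with the SVD-based Kabsch solution.
quaternion_rmsd_oracle <- function(X, Y, n_grid = 2000L) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rot_from_quat <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) sqrt(mean(rowSums((Xc - Yc %*% t(rot_from_quat(q)))^2)))
  qs <- matrix(stats::rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# Power-iteration eigenvalue oracle with deflation, on the covariance of
# flattened coordinates (divisor n - 1).
power_iteration_eigenvalues <- function(X, k, iterations = 5000L) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (n - 1)
  vals <- numeric(k)
  for (j in seq_len(k)) {
    v <- stats::rnorm(ncol(C)); v <- v / sqrt(sum(v^2))
    for (i in seq_len(iterations)) {
      v2 <- C %*% v
      nv <- sqrt(sum(v2^2))
      if (nv < 1e-30) break
      v <- as.vector(v2) / nv
    }
    lam <- drop(t(v) %*% C %*% v)
    vals[j] <- lam
    C <- C - lam * tcrossprod(v)
  }
  vals
}
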