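test_that("kabsch recovers exact rigid motions", {
  X <- test_fold(10)
  sp <- kabsch(X, X)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_superposition(X, sp), X, tolerance = 1e-9)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # +90 deg
  Y <- sweep(X %*% t(Rz), 2, c(1, 2, 3), `+`)
  sp <- kabsch(X, Y)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_superposition(Y, sp), X, tolerance = 1e-9)
})

test_that("kabsch matches the quaternion-grid brute-force oracle", {
  set.seed(101)
  for (i in 1:8) {
    X <- matrix(stats::rnorm(30, sd = 5), ncol = 3)
    Y <- random_rigid(X) + matrix(stats::rnorm(30, sd = 0.5), ncol = 3)
    expect_equal(kabsch(X, Y)$rmsd, quaternion_rmsd_oracle(X, Y),
                 tolerance = 1e-3)
  }
})

test_that("kabsch rmsd is symmetric and rigid-motion invariant", {
  set.seed(13)
  X <- matrix(stats::rnorm(24, sd = 4), ncol = 3)
  Y <- matrix(stats::rnorm(24, sd = 4), ncol = 3)
  d <- kabsch(X, Y)$rmsd
  expect_equal(kabsch(Y, X)$rmsd, d, tolerance = 1e-9)
  for (i in 1:5) {
    expect_equal(kabsch(random_rigid(X), Y)$rmsd, d, tolerance = 1e-9)
    expect_equal(kabsch(X, random_rigid(Y))$rmsd, d, tolerance = 1e-9)
  }
})

test_that("kabsch enforces proper rotations even on mirrored inputs", {
  set.seed(17)
  X <- matrix(stats::rnorm(30, sd = 3), ncol = 3)
  Y <- X %*% diag(c(-1, 1, 1))  # reflection
  sp <- kabsch(X, Y)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_gt(sp$rmsd, 0.1)  # a reflection cannot be matched by rotation
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  X <- matrix(stats::rnorm(15), ncol = 3)
  expect_error(kabsch(X, line), "collinear")
  expect_error(kabsch(line, X), "collinear")
  expect_error(kabsch(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("iterated mean fitting collapses identical structures in any pose", {
  set.seed(23)
  fold <- test_fold(15)
  ens <- make_ensemble(lapply(1:5, function(i) random_rigid(fold)))
  fit <- iterative_mean_fit(ens, 1:15)
  for (e in 2:5)
    expect_equal(fit$ensemble$coords[e, , ], fit$ensemble$coords[1, , ],
                 tolerance = 1e-6)
  expect_lte(fit$iterations, 2L)
})

test_that("two-structure mean fit yields the midpoint with symmetric residuals", {
  set.seed(29)
  a <- test_fold(12)
  b <- a + matrix(stats::rnorm(36, sd = 0.5), ncol = 3)
  ens <- make_ensemble(list(a, random_rigid(b)))
  fit <- iterative_mean_fit(ens, 1:12)
  mid <- (fit$ensemble$coords[1, , ] + fit$ensemble$coords[2, , ]) / 2
  expect_equal(fit$mean, mid, tolerance = 1e-5)
  r1 <- fit$ensemble$coords[1, , ] - fit$mean
  r2 <- fit$ensemble$coords[2, , ] - fit$mean
  expect_equal(r1, -r2, tolerance = 1e-5)
})

test_that("mean displacement decreases monotonically after the first rounds", {
  set.seed(37)
  fold <- test_fold(20)
  for (trial in 1:4) {
    ens <- make_ensemble(lapply(1:6, function(i)
      random_rigid(fold + matrix(stats::rnorm(60, sd = 0.8), ncol = 3))))
    fit <- iterative_mean_fit(ens, 1:20)
    shifts <- fit$mean_shift
    if (length(shifts) > 2)
      expect_true(all(diff(shifts[-1]) <= 1e-12))
    expect_lt(shifts[length(shifts)], 1e-6)
  }
})

test_that("a zero-scatter ensemble needs no removals and keeps all columns", {
  set.seed(41)
  fold <- test_fold(10)
  ens <- make_ensemble(lapply(1:4, function(i) random_rigid(fold)))
  ct <- find_invariant_core(ens, 1:10)
  expect_equal(ct$core, 1:10)
  expect_equal(nrow(ct$trace), 0L)
  expect_lt(ct$start_volume, 1e-12)
})

test_that("the highest-variance column is removed first", {
  set.seed(43)
  fold <- test_fold(12)
  perturbed <- lapply(1:8, function(i) {
    f <- fold + matrix(stats::rnorm(36, sd = 0.1), ncol = 3)
    f[7, ] <- f[7, ] + stats::rnorm(3, sd = 1.0)  # 10x the positional sd
    f
  })
  ens <- make_ensemble(lapply(perturbed, random_rigid))
  ct <- find_invariant_core(ens, 1:12, cutoff = 1e-6)
  expect_equal(ct$trace$column[1], 7L)
})

test_that("remaining total volume decreases strictly along the removal order", {
  set.seed(47)
  fold <- test_fold(15)
  ens <- make_ensemble(lapply(1:6, function(i)
    random_rigid(fold + matrix(stats::rnorm(45, sd = 0.4), ncol = 3))))
  ct <- find_invariant_core(ens, 1:15, cutoff = 1e-9)
  expect_gt(nrow(ct$trace), 2L)
  expect_true(all(diff(ct$trace$remaining_volume) < 0))
  expect_true(all(ct$trace$column_volume > 0))
  expect_length(intersect(ct$core, ct$trace$column), 0L)
  expect_gte(length(ct$core), 3L)
})

test_that("core finding is invariant to the initial poses of the entries", {
  set.seed(53)
  fold <- test_fold(15)
  members <- lapply(1:5, function(i)
    fold + matrix(stats::rnorm(45, sd = 0.3), ncol = 3))
  ct1 <- find_invariant_core(make_ensemble(members), 1:15, cutoff = 0.05)
  ct2 <- find_invariant_core(make_ensemble(lapply(members, random_rigid)),
                             1:15, cutoff = 0.05)
  expect_equal(ct1$trace$column, ct2$trace$column)
  expect_equal(ct1$core, ct2$core)
})

test_that("a planted rigid core is recovered (Jaccard >= 0.9 at 20x variance)", {
  set.seed(59)
  fold <- test_fold(30)
  mobile <- 21:30
  members <- lapply(1:8, function(i) {
    f <- fold + matrix(stats::rnorm(90, sd = 0.12), ncol = 3)
    f[mobile, ] <- f[mobile, ] +
      matrix(stats::rnorm(30, sd = 0.12 * sqrt(20)), ncol = 3)
    random_rigid(f)
  })
  ens <- make_ensemble(members)
  ct <- find_invariant_core(ens, 1:30, cutoff = 0.5)
  planted <- 1:20
  jaccard <- length(intersect(ct$core, planted)) /
    length(union(ct$core, planted))
  expect_gte(jaccard, 0.9)
})

test_that("core fitting tightens core columns relative to a mobile tail", {
  set.seed(61)
  fold <- test_fold(24)
  core_cols <- 1:16
  tail_cols <- 17:24
  members <- lapply(1:8, function(i) {
    f <- fold + matrix(stats::rnorm(72, sd = 0.05), ncol = 3)
    f[tail_cols, ] <- f[tail_cols, ] + matrix(stats::rnorm(24, sd = 1.5),
                                              ncol = 3)
    random_rigid(f)
  })
  ens <- make_ensemble(members)
  fit <- fit_on_core(ens, core_cols)
  scatter <- function(cols) {
    m <- apply(fit$ensemble$coords[, cols, , drop = FALSE], c(2, 3), mean)
    mean(vapply(seq_along(cols), function(j)
      mean(rowSums(sweep(fit$ensemble$coords[, cols[j], ], 2, m[j, ])^2)),
      numeric(1)))
  }
  expect_lt(scatter(core_cols), scatter(tail_cols))
  # core = all columns is plain mean fitting
  fit_all <- fit_on_core(ens, 1:24)
  ref <- iterative_mean_fit(ens, 1:24)
  expect_equal(fit_all$ensemble$coords, ref$ensemble$coords, tolerance = 1e-9)
})

test_that("single-entry fitting returns the structure up to a rigid motion", {
  set.seed(67)
  fold <- test_fold(10)
  ens <- make_ensemble(list(random_rigid(fold)))
  fit <- fit_on_core(ens, 1:10)
  expect_equal(kabsch(fit$ensemble$coords[1, , ], fold)$rmsd, 0,
               tolerance = 1e-9)
})
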