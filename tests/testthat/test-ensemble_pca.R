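# Ensembles with planted linear modes: entry i = base + score_i * mode,
# already in a common frame (no fitting needed before PCA).
planted_mode_ensemble <- function(base, modes, scores) {
  members <- lapply(seq_len(nrow(scores)), function(i) {
    f <- base
    for (m in seq_along(modes)) f <- f + scores[i, m] * modes[[m]]
    f
  })
  make_ensemble(members)
}

unit_mode <- function(L, seed) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * L), ncol = 3)
  v / sqrt(sum(v^2))
}

orthogonalize <- function(v, u) {
  v <- v - sum(v * u) * u / sum(u * u)
  v / sqrt(sum(v^2))
}

test_that("identical structures give vanishing eigenvalues", {
  fold <- test_fold(10)
  ens <- make_ensemble(rep(list(fold), 4))
  res <- ensemble_pca(ens, 1:10)
  expect_true(all(res$eigenvalues <= 1e-12))
})

test_that("a single planted linear mode is rank one", {
  L <- 12
  base <- test_fold(L)
  mode <- unit_mode(L, 1)
  ens <- planted_mode_ensemble(base, list(mode), cbind(c(-3, -1, 2, 2)))
  res <- ensemble_pca(ens, 1:L)
  expect_equal(res$proportion[1], 1.0, tolerance = 1e-9)
  expect_equal(variance_explained(res, 1), 1.0, tolerance = 1e-9)
})

test_that("two orthogonal modes with 4:1 score variance give 0.8/0.2", {
  L <- 15
  base <- test_fold(L)
  m1 <- unit_mode(L, 2)
  m2 <- orthogonalize(unit_mode(L, 3), m1)
  set.seed(4)
  s1 <- stats::rnorm(12); s1 <- (s1 - mean(s1)) / stats::sd(s1) * 2  # var 4
  s2 <- stats::rnorm(12); s2 <- stats::resid(stats::lm(s2 ~ s1))
  s2 <- (s2 - mean(s2)) / stats::sd(s2)                              # var 1
  ens <- planted_mode_ensemble(base, list(m1, m2), cbind(s1, s2))
  res <- ensemble_pca(ens, 1:L)
  expect_equal(res$proportion[1:2], c(0.8, 0.2), tolerance = 1e-6)
  expect_equal(variance_explained(res, 1), 0.8, tolerance = 1e-6)
  expect_equal(variance_explained(res, length(res$proportion)), 1.0,
               tolerance = 1e-9)
  expect_error(variance_explained(res, 0), "must be in")
  expect_error(variance_explained(res, 99), "must be in")
})

test_that("PCA invariants hold on noisy ensembles", {
  set.seed(5)
  L <- 18
  base <- test_fold(L)
  members <- lapply(1:8, function(i)
    base + matrix(stats::rnorm(3 * L, sd = 0.7), ncol = 3))
  res <- ensemble_pca(make_ensemble(members), 1:L)
  # loadings orthonormal
  expect_equal(crossprod(res$loadings),
               diag(ncol(res$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # eigenvalue sum equals total centered variance
  X <- t(sapply(1:8, function(i) as.vector(t(members[[i]]))))
  total <- sum(sweep(X, 2, colMeans(X))^2) / 7
  expect_equal(sum(res$eigenvalues), total, tolerance = 1e-9 * total)
  # score covariance diagonal with eigenvalues on the diagonal
  expect_equal(stats::cov(res$scores),
               diag(res$eigenvalues), tolerance = 1e-9 * total,
               ignore_attr = TRUE)
  # scores are centered data times loadings
  expect_equal(res$scores,
               sweep(X, 2, colMeans(X)) %*% res$loadings,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("eigenvalues match the power-iteration oracle", {
  L <- 10
  base <- test_fold(L)
  for (trial in 1:3) {
    set.seed(trial)
    members <- lapply(1:7, function(i)
      base + matrix(stats::rnorm(3 * L, sd = 1), ncol = 3))
    res <- ensemble_pca(make_ensemble(members), 1:L)
    X <- t(sapply(members, function(m) as.vector(t(m))))
    oracle <- power_iteration_eigenvalues(X, 4)
    expect_equal(res$eigenvalues[1:4], oracle, tolerance = 1e-6)
  }
})

test_that("eigen-decomposition agrees with bio3d's structure PCA", {
  L <- 12
  base <- test_fold(L)
  set.seed(8)
  members <- lapply(1:6, function(i)
    base + matrix(stats::rnorm(3 * L, sd = 0.5), ncol = 3))
  res <- ensemble_pca(make_ensemble(members), 1:L)
  xyz <- t(sapply(members, function(m) as.vector(t(m))))
  ref <- bio3d::pca.xyz(xyz, fit = FALSE)
  k <- length(res$eigenvalues)
  expect_equal(res$eigenvalues, ref$L[1:k], tolerance = 1e-6)
  expect_equal(abs(diag(crossprod(res$loadings, ref$U[, 1:k]))),
               rep(1, k), tolerance = 1e-6)
})

test_that("PCA is invariant to rigid motions applied before fitting", {
  set.seed(9)
  L <- 14
  base <- test_fold(L)
  members <- lapply(1:6, function(i)
    base + matrix(stats::rnorm(3 * L, sd = 0.5), ncol = 3))
  run <- function(ms) {
    fit <- fit_on_core(make_ensemble(ms), 1:L)
    ensemble_pca(fit$ensemble, 1:L)
  }
  res1 <- run(members)
  res2 <- run(lapply(members, random_rigid))
  expect_equal(res1$eigenvalues, res2$eigenvalues, tolerance = 1e-6)
  expect_equal(res1$proportion, res2$proportion, tolerance = 1e-6)
})

test_that("loading vectors reshape to unit total magnitude", {
  L <- 10
  base <- test_fold(L)
  set.seed(10)
  members <- lapply(1:5, function(i)
    base + matrix(stats::rnorm(3 * L, sd = 0.5), ncol = 3))
  res <- ensemble_pca(make_ensemble(members), 1:L)
  lv <- loading_vectors(res, 1)
  expect_equal(nrow(lv), L)
  expect_equal(sum(lv$magnitude^2), 1, tolerance = 1e-9)
  expect_error(loading_vectors(res, 0), "pc must be")
})

test_that("a planted hinge concentrates PC1 loadings on the mobile half", {
  set.seed(12)
  L <- 40
  base <- test_fold(L)
  split <- 20
  members <- lapply(1:10, function(i) {
    theta <- sample(c(0, 15), 1)
    apply_hinge(base, split, theta) +
      matrix(stats::rnorm(3 * L, sd = 0.05), ncol = 3)
  })
  fit <- fit_on_core(make_ensemble(members), 1:split)  # fit on static half
  res <- ensemble_pca(fit$ensemble, 1:L)
  lv <- loading_vectors(res, 1)
  top_decile <- lv$column[order(-lv$magnitude)][1:4]
  expect_true(all(top_decile > split))
})

test_that("trajectories interpolate the mean plus scaled loadings", {
  L <- 10
  base <- test_fold(L)
  set.seed(14)
  members <- lapply(1:6, function(i)
    base + matrix(stats::rnorm(3 * L, sd = 0.8), ncol = 3))
  # projection refits onto the mean, so the algebraic round trip is exact
  # only for a converged mean-fitted ensemble
  fit <- iterative_mean_fit(make_ensemble(members), 1:L, tol = 1e-12)
  res <- ensemble_pca(fit$ensemble, 1:L)

  flat <- pc_trajectory(res, 1, amplitude = 0, n_frames = 5)
  mean_mat <- matrix(res$mean, ncol = 3, byrow = TRUE)
  for (f in 1:5)
    expect_equal(flat$coords[f, , ], mean_mat, tolerance = 1e-12)

  traj <- pc_trajectory(res, 2, amplitude = 2, n_frames = 15)
  expect_equal(traj$coords[8, , ], mean_mat, tolerance = 1e-12)  # middle frame
  # projecting frames back gives scores only on the morphed component
  for (f in c(1, 4, 15)) {
    sc <- unname(project_structure(traj$coords[f, , ], res))
    expect_equal(sc[2], traj$scores[f], tolerance = 1e-8)
    expect_lt(max(abs(sc[-2])), 1e-8 * max(1, abs(traj$scores[f])))
  }
  expect_error(pc_trajectory(res, 1, n_frames = 1), "at least 2 frames")
})

test_that("projection reproduces stored scores and handles the mean", {
  L <- 12
  base <- test_fold(L)
  set.seed(15)
  members <- lapply(1:6, function(i)
    base + matrix(stats::rnorm(3 * L, sd = 0.6), ncol = 3))
  fit <- iterative_mean_fit(make_ensemble(members), 1:L, tol = 1e-12)
  ens <- fit$ensemble
  res <- ensemble_pca(ens, 1:L)
  for (e in c(1, 4)) {
    sc <- unname(project_structure(ens$coords[e, , ], res))
    expect_equal(sc, unname(res$scores[e, ]), tolerance = 1e-8)
    # projection is pose-independent
    sc2 <- unname(project_structure(random_rigid(ens$coords[e, , ]), res))
    expect_equal(sc2, unname(res$scores[e, ]), tolerance = 1e-6)
  }
  mean_mat <- matrix(res$mean, ncol = 3, byrow = TRUE)
  expect_equal(unname(project_structure(mean_mat, res)),
               rep(0, ncol(res$scores)), tolerance = 1e-9)
  displaced <- mean_mat + 2 * sqrt(res$eigenvalues[2]) *
    matrix(res$loadings[, 2], ncol = 3, byrow = TRUE)
  sc <- unname(project_structure(displaced, res))
  expect_equal(sc[2], 2 * sqrt(res$eigenvalues[2]), tolerance = 1e-8)
  expect_lt(max(abs(sc[-2])), 1e-8)
})

test_that("PCA requires at least 3 entries", {
  fold <- test_fold(8)
  ens <- make_ensemble(list(fold, fold))
  expect_error(ensemble_pca(ens, 1:8), "at least 3 entries")
})

test_that("trajectory PDB export is a readable multi-model file", {
  L <- 9
  base <- test_fold(L)
  set.seed(16)
  members <- lapply(1:5, function(i)
    base + matrix(stats::rnorm(3 * L, sd = 0.5), ncol = 3))
  res <- ensemble_pca(make_ensemble(members), 1:L)
  traj <- pc_trajectory(res, 1, n_frames = 5)
  tf <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, tf)
  pdb <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(pdb$xyz), 5L)
  expect_equal(matrix(pdb$xyz[3, ], ncol = 3, byrow = TRUE),
               traj$coords[3, , ], tolerance = 1e-3)
})
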