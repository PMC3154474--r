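# Kabsch superposition, iterative mean structures, family RMSD,
# centroids and smoothed RMSD series.

test_that("kabsch recovers rigid transforms and is optimal among rotations", {
  set.seed(501)
  X <- matrix(stats::rnorm(30), 10, 3)
  s0 <- kabsch(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_all_close(s0$rotation, diag(3), 1e-9)
  R <- rand_rotation(); t <- c(1, -4, 2)
  Y <- X %*% t(R) + matrix(t, 10, 3, byrow = TRUE)
  s <- kabsch(X, Y)
  expect_lt(s$rmsd, 1e-9)
  expect_all_close(s$rotation, R, 1e-9)
  expect_all_close(s$translation, t, 1e-9)
  # optimality: no sampled rotation beats the Kabsch optimum
  # (rmsd^2 = c1 - 2 tr(R S) / n with optimal translation, so comparing
  # traces over random rotations suffices)
  Y2 <- Y + matrix(stats::rnorm(30, sd = 0.3), 10, 3)
  sopt <- kabsch(X, Y2)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y2, 2, colMeans(Y2))
  S <- crossprod(Xc, Yc)
  tr_opt <- sum(diag(t(sopt$rotation) %*% t(S)))
  trs <- vapply(1:2000, function(i) {
    Rr <- rand_rotation()
    sum(Rr * t(S))
  }, 0)
  expect_true(all(trs <= tr_opt + 1e-9))
})

test_that("weights reduce to the unweighted case when uniform", {
  set.seed(502)
  X <- matrix(stats::rnorm(24), 8, 3)
  Y <- X + matrix(stats::rnorm(24, sd = 0.2), 8, 3)
  expect_equal(kabsch(X, Y, weights = rep(2, 8))$rmsd,
               kabsch(X, Y)$rmsd, tolerance = 1e-12)
  expect_warning(kabsch(matrix(c(1:5, 1:5 * 2, 1:5 * 3), 5, 3,
                               byrow = FALSE) %*% diag(c(1, 0, 0)),
                        matrix(stats::rnorm(15), 5, 3)),
                 "degenerate|collinear")
})

test_that("the iterative mean structure honours its fixed points", {
  m <- build_duplex()
  e <- duplex_ensemble(rep(list(m), 4))
  mu <- mean_structure(e)
  expect_all_close(ptggdyn:::model_xyz(mu), ptggdyn:::model_xyz(m), 1e-9)
  # two rigid copies of one structure average back to it (up to fit)
  set.seed(503)
  m2 <- transform_model(m, rand_rotation(), c(4, 4, 4))
  e2 <- duplex_ensemble(list(m, m2))
  mu2 <- mean_structure(e2)
  expect_lt(kabsch(ptggdyn:::model_xyz(mu2), ptggdyn:::model_xyz(m))$rmsd,
            1e-6)
})

test_that("family RMSD matches the isotropic-noise expectation", {
  set.seed(504)
  m <- build_duplex()
  sigma <- 0.3
  nat <- nrow(m)
  models <- lapply(1:20, function(i) {
    mi <- m
    mi[, c("x", "y", "z")] <- mi[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nat, sd = sigma), ncol = 3)
    mi
  })
  e <- duplex_ensemble(models)
  rep_all <- family_rmsd(e)
  # per-atom iid noise: E[rmsd^2] ~ 3 sigma^2 (1 - 1/M), slightly reduced
  # by the 6 fitted dof over 3N coordinates
  expected <- sigma * sqrt(3 * (1 - 1 / 20) * (1 - 2 / nat))
  expect_lt(abs(rep_all$mean - expected) / expected, 0.05)
  expect_equal(mean(rep_all$per_model), rep_all$mean, tolerance = 1e-9)
  # identical models give all zeros
  e0 <- duplex_ensemble(rep(list(m), 3))
  expect_all_close(family_rmsd(e0)$per_model, rep(0, 3), 1e-9)
  # invariant to pre-rotating one model
  models2 <- models
  models2[[7]] <- transform_model(models2[[7]], rand_rotation(), c(9, 0, 0))
  expect_equal(family_rmsd(duplex_ensemble(models2))$mean, rep_all$mean,
               tolerance = 1e-6)
})

test_that("the centroid minimizes mean pairwise RMSD (brute-force check)", {
  set.seed(505)
  m <- build_duplex()
  # model B is the coordinate average of A and C
  xyzA <- ptggdyn:::model_xyz(m)
  pert <- matrix(stats::rnorm(length(xyzA), sd = 0.5), ncol = 3)
  mA <- m; mA[, c("x", "y", "z")] <- xyzA + pert
  mC <- m; mC[, c("x", "y", "z")] <- xyzA - pert
  expect_equal(centroid_model(duplex_ensemble(list(mA, m, mC))), 2)
  expect_equal(centroid_model(duplex_ensemble(rep(list(m), 4))), 1)
  models <- lapply(1:12, function(i) {
    mi <- m
    mi[, c("x", "y", "z")] <- xyzA +
      matrix(stats::rnorm(length(xyzA), sd = 0.4), ncol = 3)
    transform_model(mi, rand_rotation(), stats::rnorm(3))
  })
  e <- duplex_ensemble(models)
  d <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    if (i != j) d[i, j] <- kabsch(ptggdyn:::model_xyz(models[[i]]),
                                  ptggdyn:::model_xyz(models[[j]]))$rmsd
  }
  expect_equal(centroid_model(e), unname(which.min(rowMeans(d))))
})

test_that("rmsd series smoothing equals a direct loop average", {
  set.seed(506)
  m <- build_duplex()
  models <- lapply(1:30, function(i) {
    mi <- m
    mi[, c("x", "y", "z")] <- ptggdyn:::model_xyz(m) +
      matrix(stats::rnorm(3 * nrow(m), sd = 0.1 * i / 30), ncol = 3)
    mi
  })
  e <- duplex_ensemble(models)
  w <- atomic_mass(m$element)
  raw <- rmsd_series(e, m, window = 1, weights = w)
  sm <- rmsd_series(e, m, window = 5, weights = w)
  oracle <- vapply(1:30, function(i) {
    mean(raw[max(1, i - 2):min(30, i + 2)])
  }, 0)
  expect_all_close(sm, oracle, 1e-12)
  # constant series unchanged; unit masses match unweighted
  e0 <- duplex_ensemble(rep(list(models[[4]]), 6))
  expect_equal(var(rmsd_series(e0, m, window = 3)), 0, tolerance = 1e-18)
  expect_all_close(rmsd_series(e, m, window = 1, weights = rep(1, nrow(m))),
                   rmsd_series(e, m, window = 1), 1e-12)
  expect_error(rmsd_series(e, m, window = 31), "window")
  expect_error(rmsd_series(e, m, window = 4), "odd")
})
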