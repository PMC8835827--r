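test_that("DCCM hits the exact limits and matches the double-loop oracle", {
  # two atoms moving identically, one moving oppositely along x
  set.seed(61)
  nf <- 20
  arr <- array(0, c(nf, 3, 3))
  drift <- rnorm(nf)
  arr[, 1, 1] <- drift; arr[, 2, 1] <- drift; arr[, 3, 1] <- -drift
  C <- dccm_map(trajectory(arr + 10))
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_equal(C[1, 3], -1, tolerance = 1e-12)
  # random trajectory vs brute-force double loop
  set.seed(61)
  tr <- random_trajectory(30, 10)
  C2 <- dccm_map(tr)
  expect_equal(unclass(C2), oracle_dccm(tr$coords), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unclass(C2), t(unclass(C2)), tolerance = 1e-12)
  expect_equal(diag(unclass(C2)), rep(1, 10))
  expect_true(all(abs(C2) <= 1 + 1e-9))
})

test_that("immobile atoms yield zero correlation with a flag", {
  nf <- 10
  arr <- array(rnorm(nf * 3 * 3), c(nf, 3, 3))
  arr[, 2, ] <- 5  # frozen atom
  C <- dccm_map(trajectory(arr))
  expect_equal(attr(C, "immobile"), 2L)
  expect_equal(C[2, 1], 0)
  expect_equal(C[2, 2], 0)
})

test_that("PCA recovers planted variance ratios and exact limits", {
  # planar two-mode motion with 9:1 variance
  set.seed(62)
  nf <- 400
  n <- 6
  base <- matrix(runif(3 * n, 0, 10), n, 3)
  m1 <- matrix(rnorm(3 * n), n, 3); m1 <- m1 / sqrt(sum(m1^2))
  m2 <- matrix(rnorm(3 * n), n, 3)
  m2 <- m2 - m1 * sum(m2 * m1); m2 <- m2 / sqrt(sum(m2^2))
  a1 <- rnorm(nf, sd = 3); a2 <- rnorm(nf, sd = 1)
  arr <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) arr[f, , ] <- base + a1[f] * m1 + a2[f] * m2
  # no fitting: atoms alone (avoid superposition absorbing the modes)
  X <- matrix(NA_real_, nf, 3 * n)
  for (f in seq_len(nf)) X[f, ] <- as.vector(t(arr[f, , ]))
  sv <- svd(sweep(X, 2, colMeans(X)))
  vf <- (sv$d^2) / sum(sv$d^2)
  expect_equal(vf[1:2], c(0.9, 0.1), tolerance = 0.03)
  # package route on a rigid trajectory: all eigenvalues 0
  rigid <- trajectory(array(rep(base, each = 5), c(5, n, 3)))
  p0 <- pca_modes(rigid, ca_topology(n), ca_selection(NULL))
  expect_true(all(p0$eigenvalues < 1e-12))
})

test_that("PCA invariants: orthonormal modes, trace equality, reconstruction", {
  set.seed(63)
  tr <- random_trajectory(12, 8, sd = 0.8)
  top <- ca_topology(8)
  p <- pca_modes(tr, top, ca_selection(NULL))
  V <- p$vectors
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  # total variance equals trace of the coordinate covariance
  fitted <- fit_trajectory(tr, reference = mean_conformation(tr))
  X <- matrix(NA_real_, 12, 24)
  for (f in 1:12) X[f, ] <- as.vector(t(fitted$coords[f, , ]))
  # two-pass fit as in pca_modes: refit on the average of the first pass
  mu0 <- mean_conformation(tr)
  ftd <- fit_trajectory(tr, reference = mu0)
  X <- matrix(NA_real_, 12, 24)
  for (f in 1:12) X[f, ] <- as.vector(t(ftd$coords[f, , ]))
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(p$eigenvalues), sum(Xc^2) / 12, tolerance = 1e-8)
  # projections of the mean conformation sit at the origin
  expect_equal(colMeans(p$projections), rep(0, ncol(p$projections)),
               tolerance = 1e-9)
  # full-mode reconstruction returns the fitted coordinates
  rec <- p$projections %*% t(V)
  expect_equal(rec, Xc, tolerance = 1e-8)
})

test_that("elastic network: two-bead closed form and zero-mode counts", {
  x <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  m <- enm_modes(x, cutoff = 5, k = 3)
  nz <- m$eigenvalues[m$eigenvalues > 1e-8]
  expect_equal(nz, 6, tolerance = 1e-10)       # 2k along the bond axis
  expect_equal(m$n_zero, 5)                    # collinear: 3 trans + 2 rot
  # mode direction along the bond
  mode <- matrix(m$vectors[, which(m$eigenvalues > 1e-8)], ncol = 3,
                 byrow = TRUE)
  expect_equal(abs(mode[, 1]), rep(sqrt(0.5), 2), tolerance = 1e-9)
  # any connected non-collinear network: exactly 6 near-zero modes
  set.seed(64)
  for (i in 1:5) {
    conf <- matrix(rnorm(30, sd = 4), 10, 3)
    mm <- enm_modes(conf, cutoff = 50)
    expect_equal(mm$n_zero, 6)
    expect_true(all(mm$eigenvalues > -1e-9))
  }
})

test_that("elastic network spectrum matches a finite-difference oracle", {
  set.seed(65)
  x <- matrix(rnorm(30, sd = 3), 10, 3)
  m <- enm_modes(x, cutoff = 8, k = 2)
  ora <- oracle_enm_spectrum(x, cutoff = 8, k = 2)
  expect_equal(m$eigenvalues, ora, tolerance = 1e-4)
  # rigid rotation leaves the spectrum unchanged
  rt <- random_rigid()
  m2 <- enm_modes(apply_rigid(x, rt), cutoff = 8, k = 2)
  expect_equal(m2$eigenvalues, m$eigenvalues, tolerance = 1e-8)
})

test_that("disconnected networks are refused with component sizes", {
  x <- rbind(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3) + 100)
  expect_error(enm_modes(x, cutoff = 5, chain_springs = FALSE),
               "disconnected.*components")
})

test_that("ENM cross-correlations equal an independent covariance route", {
  set.seed(66)
  x <- matrix(rnorm(24, sd = 3), 8, 3)
  m <- enm_modes(x, cutoff = 10)
  C <- enm_dccm(m)
  expect_equal(diag(unclass(C)), rep(1, 8))
  expect_equal(unclass(C), t(unclass(C)), tolerance = 1e-12)
  # oracle: project the Hessian onto the orthogonal complement of the six
  # geometrically-constructed rigid-body vectors, invert there, and sample
  n <- 8
  cm <- colMeans(x)
  rig <- matrix(0, 3 * n, 6)
  for (i in 1:n) {
    ii <- (3 * i - 2):(3 * i)
    rig[ii, 1:3] <- diag(3)
    r <- x[i, ] - cm
    rig[ii, 4] <- c(0, -r[3], r[2])
    rig[ii, 5] <- c(r[3], 0, -r[1])
    rig[ii, 6] <- c(-r[2], r[1], 0)
  }
  B <- qr.Q(qr(cbind(rig, diag(3 * n))))[, 7:(3 * n), drop = FALSE]
  Sig <- B %*% solve(crossprod(B, m$hessian %*% B)) %*% t(B)
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    S[i, j] <- sum(diag(Sig[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]))
  Cora <- S / sqrt(outer(diag(S), diag(S)))
  expect_equal(unclass(C), Cora, tolerance = 1e-6, ignore_attr = TRUE)
  # Monte-Carlo draw from the same covariance reproduces the map within
  # sampling error
  set.seed(67)
  L <- chol(Sig + 1e-10 * diag(3 * n))
  draws <- matrix(rnorm(20000 * 3 * n), 20000) %*% L
  Smc <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    Smc[i, j] <- mean(rowSums(draws[, (3 * i - 2):(3 * i), drop = FALSE] *
                                draws[, (3 * j - 2):(3 * j), drop = FALSE]))
  Cmc <- Smc / sqrt(outer(diag(Smc), diag(Smc)))
  expect_equal(unclass(C), Cmc, tolerance = 0.05, ignore_attr = TRUE)
  # mirror-symmetric (non-planar) dimer gives a mirror-symmetric map
  half <- matrix(c(0, 0, 0, 3, 0, 1, 0, 3, -1), 3, 3, byrow = TRUE)
  dimer <- rbind(half, cbind(30 - half[, 1], half[, 2], half[, 3]))
  Cd <- enm_dccm(enm_modes(dimer, cutoff = 40, chain_springs = FALSE))
  expect_equal(Cd[1, 2], Cd[4, 5], tolerance = 1e-8)
  expect_equal(Cd[1, 3], Cd[4, 6], tolerance = 1e-8)
})
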