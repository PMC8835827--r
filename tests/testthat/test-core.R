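test_that("superposition is exact on identity and rigid motions", {
  set.seed(1)
  A <- matrix(rnorm(60, sd = 5), 20, 3)
  s <- superpose(A, A)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$coords, A, tolerance = 1e-10)
  # 90-degree rotation about z plus translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  B <- sweep(A %*% Rz, 2, c(5, -3, 2), "+")
  expect_lt(superpose(B, A)$rmsd, 1e-10)
  # invariance under any proper rigid motion of mobile
  for (i in 1:10) {
    rt <- random_rigid()
    noisy <- A + matrix(rnorm(60, sd = 0.3), 20, 3)
    r1 <- superpose(noisy, A)$rmsd
    r2 <- superpose(apply_rigid(noisy, rt), A)$rmsd
    expect_lt(abs(r1 - r2), 1e-8)
  }
})

test_that("superposition RMSD matches a quaternion-based oracle", {
  set.seed(2)
  for (i in 1:25) {
    A <- matrix(rnorm(60, sd = 4), 20, 3)
    rt <- random_rigid()
    B <- apply_rigid(A, rt) + matrix(rnorm(60, sd = 0.1), 20, 3)
    expect_lt(abs(superpose(B, A)$rmsd - quaternion_rmsd(B, A)), 1e-8)
  }
})

test_that("degenerate fit selections are rejected", {
  A <- matrix(rnorm(30), 10, 3)
  expect_error(superpose(A, A, fit = 1:2), "degenerate")
  line <- cbind(1:10, 0, 0)
  jitterless <- line
  expect_error(superpose(jitterless, jitterless + 0.1, fit = 1:10),
               "collinear")
})

test_that("rmsd_series matches the direct definition", {
  set.seed(3)
  top <- ca_topology(12)
  # identical frames: all zero
  base <- matrix(runif(36, 0, 10), 12, 3)
  tr <- trajectory(array(rep(base, each = 5), c(5, 12, 3)))
  expect_equal(rmsd_series(tr, top = top)$rmsd, rep(0, 5), tolerance = 1e-10)
  # single displaced measure atom against fixed fit atoms: 2/sqrt(n)
  f2 <- base; f2[12, ] <- f2[12, ] + c(2, 0, 0)
  arr <- array(NA_real_, c(2, 12, 3)); arr[1, , ] <- base; arr[2, , ] <- f2
  tr2 <- trajectory(arr)
  rs <- rmsd_series(tr2, fit = 1:11, measure = 12, top = top)
  expect_equal(rs$rmsd[2], 2, tolerance = 1e-10)
  rs_all <- rmsd_series(tr2, fit = 1:11, measure = 1:12, top = top)
  expect_equal(rs_all$rmsd[2], 2 / sqrt(12), tolerance = 1e-10)
  # random trajectory equals oracle recomputation
  tr3 <- random_trajectory(10, 15)
  rs3 <- rmsd_series(tr3, fit = 1:15, measure = 1:15,
                     top = ca_topology(15))
  ref <- tr3$coords[1, , ]
  for (f in 1:10) {
    fitted <- superpose(tr3$coords[f, , ], ref, 1:15)$coords
    expect_lt(abs(rs3$rmsd[f] - direct_rmsd(fitted, ref)), 1e-8)
  }
  expect_true(all(rs3$rmsd >= 0))
})

test_that("rmsf equals its brute-force definition and closed forms", {
  top <- ca_topology(10)
  base <- matrix(runif(30, 0, 10), 10, 3)
  tr <- trajectory(array(rep(base, each = 4), c(4, 10, 3)))
  expect_equal(rmsf(tr, top = top)$rmsf, rep(0, 10), tolerance = 1e-10)
  # one atom alternating +/- d about its mean along x (fit on the others)
  d <- 1.7
  arr <- array(rep(base, each = 4), c(4, 10, 3))
  arr[, 10, 1] <- base[10, 1] + c(d, -d, d, -d)
  tr2 <- trajectory(arr)
  r <- rmsf(tr2, fit = 1:9, measure = 1:10, top = top)
  expect_equal(r$rmsf[10], d, tolerance = 1e-10)
  expect_equal(r$rmsf[1:9], rep(0, 9), tolerance = 1e-10)
  # random trajectory vs oracle
  set.seed(4)
  tr3 <- random_trajectory(8, 12, sd = 0.5)
  top3 <- ca_topology(12)
  r3 <- rmsf(tr3, top = top3)
  frames <- lapply(1:8, function(f)
    superpose(tr3$coords[f, , ], tr3$coords[1, , ], 1:12)$coords)
  expect_equal(r3$rmsf, oracle_rmsf(frames), tolerance = 1e-8)
  expect_error(rmsf(trajectory(tr3$coords[1, , , drop = FALSE])), "single")
})

test_that("radius of gyration: closed forms, oracle, invariances", {
  top1 <- ca_topology(1)
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1), top1), 0)
  # two equal masses separated by d -> d/2
  top2 <- ca_topology(2)
  x2 <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radius_of_gyration(x2, top2), 3, tolerance = 1e-12)
  # 50 random atoms/masses vs two-pass oracle
  set.seed(5)
  n <- 50
  m <- runif(n, 1, 30)
  top <- topology(atom_name = rep("X", n), element = rep("C", n),
                  res_index = seq_len(n), res_name = "UNK", mass = m)
  x <- matrix(rnorm(3 * n, sd = 8), n, 3)
  expect_equal(radius_of_gyration(x, top), oracle_rg(x, m),
               tolerance = 1e-10)
  # translation/rotation invariance; exact lambda scaling
  rt <- random_rigid()
  expect_equal(radius_of_gyration(apply_rigid(x, rt), top),
               radius_of_gyration(x, top), tolerance = 1e-9)
  lam <- 2.5
  expect_equal(radius_of_gyration(x * lam, top),
               lam * radius_of_gyration(x, top), tolerance = 1e-9)
  expect_error(radius_of_gyration(x, top, sel = integer(0)))
})

test_that("mean conformation averages fitted frames", {
  top <- ca_topology(6)
  base <- matrix(runif(18, 0, 5), 6, 3)
  tr <- trajectory(array(rep(base, each = 3), c(3, 6, 3)))
  expect_equal(mean_conformation(tr), base, tolerance = 1e-10)
  # +d / -d atom averages to its centre when fit atoms pin the frames
  arr <- array(rep(base, each = 2), c(2, 6, 3))
  arr[1, 6, 1] <- base[6, 1] + 2; arr[2, 6, 1] <- base[6, 1] - 2
  m <- mean_conformation(trajectory(arr), fit = 1:5, top = top)
  expect_equal(m[6, 1], base[6, 1], tolerance = 1e-10)
  # random frames: equals oracle mean of superposed frames
  set.seed(6)
  tr3 <- random_trajectory(5, 8, sd = 0.4)
  m3 <- mean_conformation(tr3)
  frames <- lapply(1:5, function(f)
    superpose(tr3$coords[f, , ], tr3$coords[1, , ])$coords)
  expect_equal(m3, Reduce(`+`, frames) / 5, tolerance = 1e-10)
})

test_that("selections resolve with validation", {
  top <- topology(atom_name = c("N", "CA", "C", "N", "CA", "C"),
                  element = c("N", "C", "C", "N", "C", "C"),
                  res_index = c(1, 1, 1, 2, 2, 2), res_name = "GLY")
  expect_equal(resolve_selection(ca_selection(NULL), top), c(2L, 5L))
  expect_equal(resolve_selection(selection(residues = 2), top), 4:6)
  expect_error(resolve_selection(selection(residues = 99), top), "zero atoms")
  expect_error(topology(atom_name = "CA", element = "", res_index = 1,
                        res_name = "GLY"), "element")
  expect_error(topology(atom_name = c("CA", "CA"), element = "C",
                        res_index = c(2, 1), res_name = "GLY"),
               "nondecreasing")
})

test_that("PDB and DCD round trips preserve the system", {
  seg <- build_ideal_segment("alpha", 8)
  arr <- array(NA_real_, c(3, nrow(seg$coords), 3))
  for (f in 1:3) arr[f, , ] <- seg$coords + (f - 1) * 0.5
  tr <- trajectory(arr)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb_system(seg$topology, tr, pdb)
  back <- read_pdb_system(pdb)
  expect_equal(nrow(back$topology), nrow(seg$topology))
  expect_equal(back$topology$res_index, seg$topology$res_index)
  expect_equal(n_frames(back$trajectory), 3)
  expect_equal(back$trajectory$coords, tr$coords, tolerance = 1e-3)
  dcd <- tempfile(fileext = ".dcd")
  write_dcd(tr, dcd)
  back2 <- read_dcd_trajectory(dcd, seg$topology)
  expect_equal(back2$coords, tr$coords, tolerance = 1e-4)
})
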