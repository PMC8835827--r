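test_that("ideal helices and sheets get their canonical labels", {
  helix <- build_ideal_segment("alpha", 15)
  lab <- assign_secondary_structure(helix$coords, helix$topology)
  interior <- lab[3:13]
  expect_gte(mean(interior == "H"), 0.9)
  g310 <- build_ideal_segment("three_ten", 10)
  labg <- assign_secondary_structure(g310$coords, g310$topology)
  expect_gte(mean(labg[3:8] == "G"), 0.9)
  sheet <- build_beta_sheet(8)
  labs <- assign_secondary_structure(sheet$coords, sheet$topology)
  strand1 <- labs[2:7]; strand2 <- labs[10:15]
  expect_gte(mean(c(strand1, strand2) == "E"), 0.8)
})

test_that("a lone extended strand has no bridge partners, so no E", {
  strand <- build_ideal_segment("beta", 10)
  lab <- assign_secondary_structure(strand$coords, strand$topology)
  expect_false(any(lab %in% c("E", "B")))
})

test_that("assignment is invariant under rigid motion", {
  set.seed(21)
  helix <- build_ideal_segment("alpha", 12)
  lab0 <- assign_secondary_structure(helix$coords, helix$topology)
  for (i in 1:5) {
    rt <- random_rigid()
    lab <- assign_secondary_structure(apply_rigid(helix$coords, rt),
                                      helix$topology)
    expect_identical(unname(lab), unname(lab0))
  }
})

test_that("timeline frequencies sum to one and track a folding schedule", {
  spec <- synthetic_spec(
    segments = list(list(name = "core", kind = "alpha", n_res = 14),
                    list(name = "sw", kind = "alpha", n_res = 12)),
    fold_schedule = list(sw = list(kinds = c("alpha", "coil"),
                                   fractions = c(0.6, 0.4))),
    n_frames = 50, core_jitter = 0.02, seed = 31)
  g <- generate_trajectory(spec)
  ss <- ss_timeline(g$trajectory, g$topology)
  expect_equal(unname(rowSums(ss$frequencies)),
               rep(1, nrow(ss$frequencies)), tolerance = 1e-12)
  # interior of the switching segment is helical in the helix phase only
  sw_int <- paste0("A:", 18:24)
  hfreq <- ss$frequencies[sw_int, "H"]
  expect_true(all(hfreq > 0.4 & hfreq < 0.8))
  # per-frame check against the planted schedule
  hel_frames <- which(g$truth$fold_kind$sw == "alpha")
  frac_h <- mean(ss$labels[hel_frames, sw_int] == "H")
  expect_gt(frac_h, 0.85)
  coil_frames <- which(g$truth$fold_kind$sw == "coil")
  expect_lt(mean(ss$labels[coil_frames, sw_int] == "H"), 0.15)
  expect_error(ss_timeline(g$trajectory, g$topology, stride = 0), "stride")
})

test_that("static ideal helix trajectory is 100% H in the interior", {
  helix <- build_ideal_segment("alpha", 15)
  arr <- array(NA_real_, c(5, nrow(helix$coords), 3))
  for (f in 1:5) arr[f, , ] <- helix$coords
  ss <- ss_timeline(trajectory(arr), helix$topology)
  expect_equal(unname(ss$frequencies[paste0("A:", 4:12), "H"]), rep(1, 9))
})

test_that("residues missing backbone atoms fall back to coil", {
  helix <- build_ideal_segment("alpha", 8)
  keep <- !(helix$topology$res_index == 4 &
              helix$topology$atom_name == "O")
  top2 <- topology(atom_name = helix$topology$atom_name[keep],
                   element = helix$topology$element[keep],
                   res_index = helix$topology$res_index[keep],
                   res_name = helix$topology$res_name[keep])
  expect_warning(lab <- assign_secondary_structure(helix$coords[keep, ],
                                                   top2), "backbone")
  expect_equal(unname(lab["A:4"]), "C")
  # tiny chains are all coil
  tri <- build_ideal_segment("alpha", 3)
  short <- assign_secondary_structure(tri$coords[1:8, ],
                                      topology(
                                        atom_name = tri$topology$atom_name[1:8],
                                        element = tri$topology$element[1:8],
                                        res_index = tri$topology$res_index[1:8],
                                        res_name = "ALA"))
  expect_true(all(short == "C"))
})

test_that("assignment agrees with an independent reference implementation", {
  structs <- list(build_ideal_segment("alpha", 15, with_cb = FALSE),
                  build_ideal_segment("three_ten", 12, with_cb = FALSE),
                  build_beta_sheet(8),
                  build_beta_sheet(10))
  spec <- synthetic_spec(
    segments = list(list(name = "h1", kind = "alpha", n_res = 12),
                    list(name = "c", kind = "coil", n_res = 6),
                    list(name = "h2", kind = "alpha", n_res = 12)),
    n_frames = 1, core_jitter = 0, seed = 2)
  g <- generate_trajectory(spec)
  structs$mixed <- list(topology = g$topology,
                        coords = get_frame(g$trajectory, 1))
  for (s in structs) {
    mine <- assign_secondary_structure(s$coords, s$topology)
    ref <- mdtraj_dssp(s$topology, s$coords)
    expect_equal(length(ref), length(mine))
    expect_gte(mean(unname(mine) == ref), 0.95)
  }
})
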