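two_atom_hbond_system <- function(da_dist, dha_angle) {
  # donor N with explicit H, acceptor O placed at the requested geometry
  top <- topology(atom_name = c("ND", "HD", "OA"),
                  element = c("N", "H", "O"),
                  res_index = c(1, 1, 2), res_name = "UNK")
  N <- c(0, 0, 0); H <- c(1.0, 0, 0)
  th <- (180 - dha_angle) * pi / 180
  # acceptor on a ray from H making the requested D-H...A angle; bisect
  # the H-A distance until the D-A distance matches
  dir <- c(cos(th), sin(th), 0)
  f <- function(rr) sqrt(sum((H + rr * dir - N)^2)) - da_dist
  lo <- 0; hi <- 10
  for (j in 1:60) { r <- (lo + hi) / 2
    if (f(r) > 0) hi <- r else lo <- r }
  A <- H + r * dir
  list(top = top, frame = rbind(N, H, A))
}

test_that("H-bond geometric criteria behave at their boundaries", {
  s <- two_atom_hbond_system(3.5, 150)
  ev <- detect_hbonds(s$frame, s$top)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 3.5, tolerance = 1e-6)
  expect_equal(ev$angle, 150, tolerance = 1e-6)
  expect_equal(nrow(detect_hbonds(two_atom_hbond_system(3.7, 180)$frame,
                                  s$top)), 0)
  expect_equal(nrow(detect_hbonds(two_atom_hbond_system(3.5, 110)$frame,
                                  s$top)), 0)
})

test_that("bifurcated hydrogen bonds give separate events", {
  top <- topology(atom_name = c("ND", "HD", "OA", "OB"),
                  element = c("N", "H", "O", "O"),
                  res_index = c(1, 1, 2, 3), res_name = "UNK")
  frame <- rbind(c(0, 0, 0), c(1, 0, 0),
                 c(2.8, 0.5, 0), c(2.8, -0.5, 0))
  ev <- detect_hbonds(frame, top)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$acceptor, c(3, 4))
})

test_that("detection equals the exhaustive oracle on random instances", {
  set.seed(41)
  for (i in 1:30) {
    s <- random_polar_system(n = sample(c(60, 120, 200), 1))
    mine <- detect_hbonds(s$frame, s$top)
    mine <- mine[order(mine$donor, mine$acceptor), ]
    ora <- oracle_hbonds(s$frame, s$top)
    expect_identical(paste(mine$donor, mine$acceptor),
                     paste(ora$donor, ora$acceptor))
    ph <- detect_hydrophobic_contacts(s$frame, s$top)
    po <- oracle_hydrophobic(s$frame, s$top)
    expect_equal(paste(ph$res_i, ph$res_j), paste(po$res_i, po$res_j))
  }
})

test_that("detection is invariant under rigid motion", {
  set.seed(42)
  s <- random_polar_system(100)
  base <- detect_hbonds(s$frame, s$top)
  for (i in 1:5) {
    rt <- random_rigid()
    ev <- detect_hbonds(apply_rigid(s$frame, rt), s$top)
    expect_identical(paste(sort(paste(ev$donor, ev$acceptor))),
                     paste(sort(paste(base$donor, base$acceptor))))
  }
})

test_that("hydrophobic contacts respect the 4-Angstrom side-chain rule", {
  # two Leu side-chain atoms at 3.8 and 4.2 Angstrom
  top <- topology(atom_name = c("CA", "CD1", "CA", "CD1"),
                  element = c("C", "C", "C", "C"),
                  res_index = c(1, 1, 2, 2), res_name = "LEU")
  near <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(4.8, 0, 0))
  expect_equal(nrow(detect_hydrophobic_contacts(near, top)), 1)
  far <- near; far[4, 1] <- 5.2
  expect_equal(nrow(detect_hydrophobic_contacts(far, top)), 0)
  # polar residues never count
  top2 <- top; top2$res_name <- "SER"
  expect_equal(nrow(detect_hydrophobic_contacts(near, top2)), 0)
})

test_that("occurrence pattern recovers planted fractions", {
  spec <- synthetic_spec(
    segments = list(list(name = "core", kind = "alpha", n_res = 16),
                    list(name = "tail", kind = "coil", n_res = 8)),
    hbond_plants = list(list(donor_res = 20, acceptor_res = 4,
                             occurrence = 0.3),
                        list(donor_res = 22, acceptor_res = 6,
                             occurrence = 1.0)),
    n_frames = 200, core_jitter = 0.03, seed = 43)
  g <- generate_trajectory(spec)
  pat <- occurrence_pattern(g$trajectory, g$topology, type = "hbond")
  p30 <- pat[pat$res_i == 4 & pat$res_j == 20, ]
  p100 <- pat[pat$res_i == 6 & pat$res_j == 22, ]
  expect_equal(p30$occurrence, 0.30, tolerance = 0.021)
  expect_equal(p100$occurrence, 1.0)
  # a never-bonded distant pair is absent
  expect_false(any(pat$res_i == 1 & pat$res_j == 24))
  expect_true(all(pat$occurrence >= 0 & pat$occurrence <= 1))
})

test_that("regular-structure exclusion removes helix backbone bonds only", {
  # helix: i,i+4 backbone bonds inside it must be excluded; a side-chain
  # mediated bond and an inter-domain backbone bond must be retained
  spec <- synthetic_spec(
    segments = list(list(name = "helix", kind = "alpha", n_res = 14),
                    list(name = "loop", kind = "coil", n_res = 8)),
    hbond_plants = list(list(donor_res = 18, acceptor_res = 4,
                             occurrence = 1.0)),
    n_frames = 20, core_jitter = 0.02, seed = 44)
  g <- generate_trajectory(spec)
  map <- domain_map(list(HELIX = c(1L, 14L), LOOP = c(15L, 22L)))
  pat <- occurrence_pattern(g$trajectory, g$topology, type = "hbond",
                            domains = map)
  ss <- ss_timeline(g$trajectory, g$topology)
  ex <- exclude_regular_structure(pat, ss, map)
  # exclusion is a subset
  expect_true(all(paste(ex$res_i, ex$res_j) %in%
                    paste(pat$res_i, pat$res_j)))
  # i,i+4 helical backbone pairs present before, gone after
  helical_bb <- pat$res_j - pat$res_i == 4 & pat$res_j <= 14 &
    !pat$sidechain
  expect_true(any(helical_bb))
  expect_false(any(ex$res_j - ex$res_i == 4 & ex$res_j <= 14 &
                     !ex$sidechain))
  # planted inter-domain bond (loop backbone N to helix O) is retained
  expect_true(any(ex$res_i == 4 & ex$res_j == 18))
})

test_that("terminal-residue bonds are flagged, not removed", {
  spec <- synthetic_spec(
    segments = list(list(name = "a", kind = "coil", n_res = 10)),
    hbond_plants = list(list(donor_res = 10, acceptor_res = 3,
                             occurrence = 1.0)),
    n_frames = 5, core_jitter = 0.01, seed = 45)
  g <- generate_trajectory(spec)
  pat <- occurrence_pattern(g$trajectory, g$topology, type = "hbond")
  row <- pat[pat$res_i == 3 & pat$res_j == 10, ]
  expect_equal(nrow(row), 1)
  expect_true(row$terminal_flag)
})
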