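# programmatic fixtures shared across test files

# random all-atom-ish system with polar and hydrophobic content
random_polar_system <- function(n = 150, n_res = 30, box = 25) {
  an <- sample(c("N", "O", "SG", "CB", "CG", "CA", "H"), n, TRUE)
  top <- topology(atom_name = an, element = substr(an, 1, 1),
                  res_index = sort(sample.int(n_res, n, TRUE)),
                  res_name = "SER")
  list(top = top, frame = matrix(stats::runif(3 * n, 0, box), n, 3))
}

# small random Calpha-like trajectory
random_trajectory <- function(n_frames = 10, n_atoms = 20, sd = 1) {
  base <- matrix(stats::runif(3 * n_atoms, 0, 20), n_atoms, 3)
  arr <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames))
    arr[f, , ] <- base + matrix(stats::rnorm(3 * n_atoms, 0, sd), n_atoms, 3)
  trajectory(arr)
}

ca_topology <- function(n, res_name = "ALA") {
  topology(atom_name = rep("CA", n), element = rep("C", n),
           res_index = seq_len(n), res_name = res_name)
}

# canonical two-state benchmark: rigid helical core, 12-residue appendage
# hopping between mirror-symmetric poses (+/-25 degrees) with declared
# occupancies
two_state_spec <- function(weights = c(0.65, 0.35), n_frames = 2000,
                           seed = 11, jitter = 0.15) {
  synthetic_spec(
    segments = list(list(name = "core", kind = "alpha", n_res = 20),
                    list(name = "app", kind = "alpha", n_res = 12)),
    appendages = list(list(
      segment = "app",
      states = list(list(angle = -25, axis = c(0, 1, 0)),
                    list(angle = 25, axis = c(0, 1, 0))),
      weights = weights, mean_dwell = 20, jitter = jitter)),
    n_frames = n_frames, core_jitter = 0.05, seed = seed)
}

# reference DSSP labels from an independent implementation (mdtraj),
# called through the system python
mdtraj_dssp <- function(top, coords) {
  pdb <- tempfile(fileext = ".pdb")
  write_pdb_system(top, coords, pdb)
  py <- sprintf(paste0(
    "import mdtraj as md\n",
    "t = md.load_pdb('%s')\n",
    "ss = md.compute_dssp(t, simplified=False)[0]\n",
    "print(''.join(ss))"), pdb)
  out <- system2("python", "-", input = py, stdout = TRUE, stderr = FALSE)
  lab <- strsplit(utils::tail(out, 1), "")[[1]]
  lab[lab == " "] <- "C"
  lab
}
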