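#' Read a topology (and any models) from a PDB file
#'
#' Wraps \code{bio3d::read.pdb} with the pipeline's policy: ATOM records
#' only, alternate locations restricted to blank/'A', multi-model files kept
#' as a trajectory.  Coordinates are in Angstrom.
#'
#' @param path PDB file path.
#' @param multi read all MODEL blocks as frames (default TRUE).
#' @param time_step_ps time step to stamp on the returned trajectory.
#' @return list with \code{topology} and \code{trajectory} (one frame for a
#'   single-model file).
#' @export
read_pdb_system <- function(path, multi = TRUE, time_step_ps = 10) {
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  keep <- which(pdb$atom$type == "ATOM")
  elt <- at$elesy
  bad <- is.na(elt) | !nzchar(trimws(elt))
  if (any(bad)) elt[bad] <- substr(trimws(at$elety[bad]), 1, 1)
  top <- topology(atom_name = trimws(at$elety),
                  element = trimws(elt),
                  res_index = at$resno,
                  res_name = trimws(at$resid),
                  chain = ifelse(is.na(at$chain), "A", at$chain))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  xyz <- xyz[, cols, drop = FALSE]
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, nrow(top), 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  list(topology = top,
       trajectory = trajectory(coords, time_step_ps = time_step_ps,
                               topology = top))
}

#' Write coordinates to a (multi-model) PDB file
#'
#' @param top a \code{\link{topology}}.
#' @param coords one \code{atoms x 3} matrix or a \code{\link{trajectory}}.
#' @param path output file.
#' @export
write_pdb_system <- function(top, coords, path) {
  if (inherits(coords, "trajectory")) {
    nf <- n_frames(coords)
    xyz <- matrix(NA_real_, nf, 3 * nrow(top))
    for (f in seq_len(nf))
      xyz[f, ] <- as.vector(t(get_frame(coords, f)))
  } else {
    xyz <- matrix(as.vector(t(coords)), nrow = 1)
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$res_index, resid = top$res_name,
                   eleno = seq_len(nrow(top)), elety = top$atom_name,
                   chain = top$chain, elesy = top$element)
  invisible(path)
}

#' Read a DCD binary trajectory
#'
#' @param path DCD file.
#' @param topology optional topology for atom-count validation.
#' @param time_step_ps time step to stamp on the trajectory.
#' @export
read_dcd_trajectory <- function(path, topology = NULL, time_step_ps = 10) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nf, na, 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(coords, time_step_ps = time_step_ps, topology = topology)
}

#' Write a CHARMM-format DCD binary trajectory
#'
#' Minimal single-precision DCD writer (no unit cell), compatible with
#' standard readers; round-tripped against \code{bio3d::read.dcd} in the
#' test-suite.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output file.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); na <- dim(traj$coords)[2]
  wr_block <- function(writer) {
    # Fortran unformatted record: byte length, payload, byte length
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    payload <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  wr_block(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    writeBin(icntrl, c2, size = 4, endian = "little")
  })
  title <- formatC("created by kitdyn", width = 80, flag = "-")
  wr_block(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeChar(title, c2, nchars = 80, eos = NULL)
  })
  wr_block(function(c2) writeBin(as.integer(na), c2, size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    for (k in 1:3)
      wr_block(function(c2) writeBin(as.numeric(fr[, k]), c2, size = 4,
                                     endian = "little"))
  }
  invisible(path)
}

#' Write a (frame, time_ps, value...) table as TSV
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param comment optional header comment line (prefixed with '#').
#' @export
write_tsv_table <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
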