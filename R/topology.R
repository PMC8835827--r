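#' Standard atomic masses by element symbol
#'
#' Conventional standard atomic weights (amu) for the elements that occur in
#' protein systems.  Used wherever a mass-weighted quantity (centre of mass,
#' radius of gyration, mass-weighted centroid) is requested and the topology
#' does not carry explicit masses.
#'
#' @return Named numeric vector of masses in amu.
#' @export
atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
    P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
    CA = 40.078, "NA" = 22.990, K = 39.098, CL = 35.45)
}

#' Construct a molecular topology
#'
#' A topology records, per atom: name, element, mass (amu), residue index
#' (author numbering, 1-based, e.g. I516--R946 for the KIT cytoplasmic
#' construct), residue name and chain id.  Coordinates live in a separate
#' trajectory object so one topology can serve many frames.
#'
#' @param atom_name character vector of PDB-style atom names (e.g. "CA").
#' @param element character vector of element symbols.
#' @param res_index integer vector of residue numbers, nondecreasing within a
#'   chain.
#' @param res_name character vector of three-letter residue names.
#' @param chain character vector of chain identifiers (default "A").
#' @param mass optional numeric vector of atomic masses (amu); derived from
#'   \code{element} via \code{\link{atomic_masses}} when missing.
#' @return Object of class \code{"topology"}: a data.frame with one row per
#'   atom.
#' @export
topology <- function(atom_name, element, res_index, res_name,
                     chain = "A", mass = NULL) {
  n <- length(atom_name)
  element <- toupper(element)
  if (any(!nzchar(element)) || anyNA(element))
    stop("every atom must have a nonempty element symbol")
  if (is.null(mass)) {
    mass <- unname(atomic_masses()[element])
    if (anyNA(mass))
      stop("unknown element(s): ",
           paste(unique(element[is.na(mass)]), collapse = ", "))
  }
  if (any(mass <= 0)) stop("atomic masses must be positive")
  res_index <- as.integer(res_index)
  chain <- rep_len(chain, n)
  for (ch in unique(chain)) {
    ri <- res_index[chain == ch]
    if (is.unsorted(ri)) stop("residue indices must be nondecreasing within chain ", ch)
  }
  top <- data.frame(atom_name = as.character(atom_name),
                    element = element,
                    mass = as.numeric(mass),
                    res_index = res_index,
                    res_name = as.character(rep_len(res_name, n)),
                    chain = chain,
                    stringsAsFactors = FALSE)
  class(top) <- c("topology", "data.frame")
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, chain(s) %s\n",
              nrow(x), length(unique(paste(x$chain, x$res_index))),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param coords numeric array \code{frames x atoms x 3} of coordinates in
#'   Angstrom, or a single \code{atoms x 3} matrix (one frame).
#' @param time_step_ps simulation time between stored frames, ps.
#' @param frame_stride stride (in original saved frames) this trajectory
#'   represents; kept so derived strides can be reported in physical time.
#' @param topology optional \code{\link{topology}}; when given the atom count
#'   is validated.
#' @return Object of class \code{"trajectory"} with elements \code{coords},
#'   \code{time_step_ps}, \code{frame_stride}.
#' @export
trajectory <- function(coords, time_step_ps = 10, frame_stride = 1L,
                       topology = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  if (time_step_ps <= 0) stop("time_step_ps must be positive")
  if (frame_stride < 1) stop("frame_stride must be a positive integer")
  if (!is.null(topology) && nrow(topology) != dim(coords)[2])
    stop("atom count mismatch: trajectory has ", dim(coords)[2],
         ", topology has ", nrow(topology))
  structure(list(coords = coords,
                 time_step_ps = as.numeric(time_step_ps),
                 frame_stride = as.integer(frame_stride)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %g ps\n",
              d[1], d[2], x$time_step_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{\link{trajectory}}.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an atoms x 3 coordinate matrix
#' @param traj a \code{\link{trajectory}}.
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Define an atom selection
#'
#' A selection is a declarative predicate over residue ranges, atom names,
#' elements and chains; it is resolved against a concrete topology with
#' \code{\link{resolve_selection}}.  The default fit selection used
#' throughout the pipeline is the tyrosine-kinase domain
#' (residues 582--688 and 769--931, i.e. W582--S688 plus L769--S931).
#'
#' @param residues integer vector of residue numbers, or NULL for all.
#' @param atom_names character vector of atom names (e.g. "CA"), or NULL.
#' @param elements character vector of element symbols, or NULL.
#' @param chains character vector of chain ids, or NULL.
#' @return Object of class \code{"selection"}.
#' @export
selection <- function(residues = NULL, atom_names = NULL,
                      elements = NULL, chains = NULL) {
  structure(list(residues = if (is.null(residues)) NULL else as.integer(residues),
                 atom_names = atom_names,
                 elements = if (is.null(elements)) NULL else toupper(elements),
                 chains = chains),
            class = "selection")
}

#' Resolve a selection to atom indices
#'
#' @param sel a \code{\link{selection}} or an integer vector of atom indices
#'   (passed through).
#' @param top a \code{\link{topology}}.
#' @param allow_empty if FALSE (default) an empty result is an error.
#' @return Integer vector of atom indices into \code{top}.
#' @export
resolve_selection <- function(sel, top, allow_empty = FALSE) {
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > nrow(top))) stop("atom index out of range")
    if (!allow_empty && length(idx) == 0L)
      stop("selection resolves to zero atoms")
    return(idx)
  }
  stopifnot(inherits(sel, "selection"))
  keep <- rep(TRUE, nrow(top))
  if (!is.null(sel$residues))   keep <- keep & top$res_index %in% sel$residues
  if (!is.null(sel$atom_names)) keep <- keep & top$atom_name %in% sel$atom_names
  if (!is.null(sel$elements))   keep <- keep & top$element %in% sel$elements
  if (!is.null(sel$chains))     keep <- keep & top$chain %in% sel$chains
  idx <- which(keep)
  if (!allow_empty && length(idx) == 0L)
    stop("selection resolves to zero atoms")
  idx
}

#' Expand residue ranges to a residue-number vector
#'
#' @param ranges list of length-2 vectors \code{c(first, last)} or a single
#'   such vector.
#' @return Integer vector of residue numbers.
#' @export
range_residues <- function(ranges) {
  if (!is.list(ranges)) ranges <- list(ranges)
  unlist(lapply(ranges, function(r) seq.int(r[1], r[2])))
}

#' Selection of Calpha atoms for a residue set
#' @param residues integer residue numbers (NULL for all residues).
#' @export
ca_selection <- function(residues = NULL)
  selection(residues = residues, atom_names = "CA")
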