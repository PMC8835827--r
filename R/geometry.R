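#' Centroid (local centre of gravity) of a selection
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}}.
#' @param sel selection of atoms.
#' @param mass_weighted weight by atomic mass (default TRUE, i.e. centre of
#'   mass); FALSE gives the geometric mean position.
#' @return length-3 point (Angstrom).
#' @export
centroid <- function(frame, top, sel = NULL, mass_weighted = TRUE) {
  idx <- if (is.null(sel)) seq_len(nrow(top)) else resolve_selection(sel, top)
  x <- frame[idx, , drop = FALSE]
  w <- if (mass_weighted) top$mass[idx] else rep(1, length(idx))
  colSums(x * w) / sum(w)
}

#' Inter-node geometry of a labelled tetrahedron
#'
#' Nodes are centroids of domain selections or single Calpha atoms; the six
#' pairwise distances track relative inter-domain positions over time.  A
#' near-coplanar node set is flagged (degenerate tetrahedron) but distances
#' are still returned.
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}}.
#' @param nodes named list of four selections (or atom index vectors).
#' @param mass_weighted passed to \code{\link{centroid}}.
#' @return object of class \code{"tetrahedron"}: \code{points} (4 x 3,
#'   rownames = node labels), \code{distances} (long data.frame node_i,
#'   node_j, distance), \code{planar} flag.
#' @export
tetrahedron <- function(frame, top, nodes, mass_weighted = TRUE) {
  if (length(nodes) != 4L) stop("a tetrahedron needs exactly four nodes")
  labs <- names(nodes)
  if (is.null(labs)) labs <- paste0("node", 1:4)
  pts <- t(vapply(nodes, function(s) centroid(frame, top, s, mass_weighted),
                  numeric(3)))
  rownames(pts) <- labs
  pr <- utils::combn(4, 2)
  dists <- data.frame(node_i = labs[pr[1, ]], node_j = labs[pr[2, ]],
                      distance = apply(pr, 2, function(ij)
                        sqrt(sum((pts[ij[1], ] - pts[ij[2], ])^2))))
  # 6 * volume = |det of edge matrix|; flag coplanarity relative to size
  e <- sweep(pts[2:4, , drop = FALSE], 2, pts[1, ])
  vol6 <- abs(det(e))
  planar <- vol6 < 1e-6 * max(dists$distance)^3
  structure(list(points = pts, distances = dists, planar = planar),
            class = "tetrahedron")
}

#' Tetrahedron distance series over a trajectory
#'
#' @param traj a \code{\link{trajectory}}.
#' @param top a \code{\link{topology}}.
#' @param nodes named list of four selections.
#' @param mass_weighted passed to \code{\link{centroid}}.
#' @return long data.frame (frame, time_ps, node_pair, distance).
#' @export
tetrahedron_series <- function(traj, top, nodes, mass_weighted = TRUE) {
  out <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    tet <- tetrahedron(get_frame(traj, f), top, nodes, mass_weighted)
    d <- tet$distances
    out[[f]] <- data.frame(frame = f,
                           time_ps = (f - 1) * traj$time_step_ps,
                           node_pair = paste(d$node_i, d$node_j, sep = "-"),
                           distance = d$distance)
  }
  do.call(rbind, out)
}

#' Representative axis (hint vector) of a secondary-structure segment
#'
#' The principal axis of the segment's Calpha coordinates, sign-fixed to
#' point from the N-terminal half towards the C-terminal half of the
#' segment.  For a regular helix this is the helix axis.
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}}.
#' @param range \code{c(first, last)} residue range.
#' @return object of class \code{"hint_vector"}: \code{origin} (segment
#'   centroid), \code{direction} (unit vector, N-to-C), \code{segment}.
#' @export
segment_vector <- function(frame, top, range) {
  idx <- resolve_selection(ca_selection(range_residues(list(range))), top)
  if (length(idx) < 2L) stop("segment vector needs at least 2 Calpha atoms")
  x <- frame[idx, , drop = FALSE]
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- svd(xc, nu = 0, nv = 1)$v[, 1]
  # orient N -> C: positive projection going down the sequence
  half <- ceiling(nrow(x) / 2)
  nc <- colMeans(x[(nrow(x) - half + 1):nrow(x), , drop = FALSE]) -
    colMeans(x[1:half, , drop = FALSE])
  if (sum(v * nc) < 0) v <- -v
  structure(list(origin = mu, direction = v / sqrt(sum(v^2)),
                 segment = paste(range, collapse = "-")),
            class = "hint_vector")
}

#' Bending angle between two representative vectors
#'
#' Theta = arccos( v1 . v2 / (|v1| |v2|) ), reported in degrees in
#' [0, 180].
#'
#' @param v1,v2 \code{hint_vector} objects or plain length-3 vectors.
#' @return angle in degrees.
#' @export
bending_angle <- function(v1, v2) {
  a <- if (inherits(v1, "hint_vector")) v1$direction else as.numeric(v1)
  b <- if (inherits(v2, "hint_vector")) v2$direction else as.numeric(v2)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("bending angle undefined for a zero vector")
  ct <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Helix kink angle at a hinge residue
#'
#' The angle between the axis of the N-terminal half-helix and the axis of
#' the C-terminal half-helix, both anchored at the hinge Calpha and pointing
#' away from it (towards their respective termini).  Under this convention a
#' perfectly straight helix gives 180 degrees and a right-angle kink gives
#' 90 degrees.  The frame should already be fitted on the helix Calpha of
#' its initial conformation when a time series relative to t = 0 is wanted.
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}}.
#' @param helix_range \code{c(first, last)} residues of the helix.
#' @param hinge_residue residue number of the hinge (strictly inside the
#'   range, with at least 2 Calpha on each side).
#' @return kink angle in degrees.
#' @export
kink_angle <- function(frame, top, helix_range, hinge_residue) {
  first <- helix_range[1]; last <- helix_range[2]
  if (hinge_residue - first < 2 || last - hinge_residue < 2)
    stop("hinge must lie inside the helix with >=2 Calpha on each side")
  hidx <- resolve_selection(ca_selection(hinge_residue), top)
  hinge <- frame[hidx[1], ]
  vN <- segment_vector(frame, top, c(first, hinge_residue))
  vC <- segment_vector(frame, top, c(hinge_residue, last))
  # both half-vectors point away from the hinge
  dN <- if (sum(vN$direction * (vN$origin - hinge)) >= 0)
    vN$direction else -vN$direction
  dC <- if (sum(vC$direction * (vC$origin - hinge)) >= 0)
    vC$direction else -vC$direction
  bending_angle(dN, dC)
}

#' Bending-angle time series between two hint segments
#'
#' @param traj a \code{\link{trajectory}}.
#' @param top a \code{\link{topology}}.
#' @param range1,range2 residue ranges of the two segments.
#' @return data.frame (frame, time_ps, angle_deg).
#' @export
bending_series <- function(traj, top, range1, range2) {
  nf <- n_frames(traj)
  ang <- vapply(seq_len(nf), function(f) {
    fr <- get_frame(traj, f)
    bending_angle(segment_vector(fr, top, range1),
                  segment_vector(fr, top, range2))
  }, numeric(1))
  data.frame(frame = seq_len(nf),
             time_ps = (seq_len(nf) - 1) * traj$time_step_ps,
             angle_deg = ang)
}
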