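#' Least-squares rigid-body superposition (Kabsch)
#'
#' Fits \code{mobile} onto \code{reference} by the rotation + translation
#' minimizing the RMSD over the fit atoms, using the Kabsch SVD algorithm
#' with determinant correction so no reflection is ever applied.  This is
#' the normalization step applied before every deviation metric: MD
#' conformations are least-square fitted to the initial conformation on a
#' declared fit selection (by default the rigid tyrosine-kinase core), so
#' that rigid-body motion does not contaminate internal dynamics.
#'
#' @param mobile atoms x 3 coordinate matrix to transform (Angstrom).
#' @param reference atoms x 3 coordinate matrix (same atom order).
#' @param fit selection (or atom indices) defining the fit atoms; default:
#'   all atoms.
#' @param top optional \code{\link{topology}} (needed when \code{fit} is a
#'   \code{\link{selection}}).
#' @return list: \code{coords} (fitted mobile, all atoms), \code{rmsd}
#'   (minimized RMSD over fit atoms, Angstrom), \code{rotation} (3x3),
#'   \code{translation} (length 3; fitted = (mobile - cm_mob) R + cm_ref).
#' @export
superpose <- function(mobile, reference, fit = NULL, top = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, all(dim(mobile) == dim(reference)))
  idx <- if (is.null(fit)) seq_len(nrow(mobile)) else resolve_selection(fit, top)
  if (length(idx) < 3L)
    stop("degenerate selection: superposition needs at least 3 fit atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  cm_p <- colMeans(P); cm_q <- colMeans(Q)
  Pc <- sweep(P, 2, cm_p); Qc <- sweep(Q, 2, cm_q)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  # rank-deficient (collinear) fit atoms leave the rotation under-determined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("rank-deficient selection: fit atoms are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- sweep(mobile, 2, cm_p) %*% R
  fitted <- sweep(fitted, 2, cm_q, FUN = "+")
  dev <- fitted[idx, , drop = FALSE] - Q
  list(coords = fitted,
       rmsd = sqrt(sum(dev^2) / length(idx)),
       rotation = R,
       translation = cm_q)
}

#' Fit every frame of a trajectory to a reference frame
#'
#' @param traj a \code{\link{trajectory}}.
#' @param reference atoms x 3 reference frame; default frame 1.
#' @param fit fit selection (see \code{\link{superpose}}).
#' @param top topology (needed for selection objects).
#' @return trajectory with all frames superposed on \code{reference}.
#' @export
fit_trajectory <- function(traj, reference = NULL, fit = NULL, top = NULL) {
  if (is.null(reference)) reference <- get_frame(traj, 1)
  out <- traj$coords
  for (f in seq_len(n_frames(traj)))
    out[f, , ] <- superpose(get_frame(traj, f), reference, fit, top)$coords
  trajectory(out, time_step_ps = traj$time_step_ps,
             frame_stride = traj$frame_stride)
}

plain_rmsd <- function(a, b) sqrt(sum((a - b)^2) / nrow(a))

#' Per-frame RMSD series against a reference conformation
#'
#' Each frame is first fitted to the reference on the \code{fit} atoms, then
#' the RMSD is measured over the \code{measure} atoms.  This mirrors the
#' standard normalization: Calpha RMSD with the initial model (t = 0) as
#' reference, after least-square fitting on the tyrosine-kinase core.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param reference atoms x 3 reference frame; default frame 1.
#' @param fit fit selection; default all atoms.
#' @param measure measurement selection; default same as \code{fit}.
#' @param top topology for selection resolution.
#' @return data.frame (frame, time_ps, rmsd) in Angstrom.
#' @export
rmsd_series <- function(traj, reference = NULL, fit = NULL, measure = NULL,
                        top = NULL) {
  if (is.null(reference)) reference <- get_frame(traj, 1)
  midx <- if (is.null(measure)) {
    if (is.null(fit)) seq_len(dim(traj$coords)[2]) else resolve_selection(fit, top)
  } else resolve_selection(measure, top)
  if (length(midx) == 0L) stop("empty measure selection")
  nf <- n_frames(traj)
  val <- numeric(nf)
  for (f in seq_len(nf)) {
    fitted <- superpose(get_frame(traj, f), reference, fit, top)$coords
    val[f] <- plain_rmsd(fitted[midx, , drop = FALSE],
                         reference[midx, , drop = FALSE])
  }
  data.frame(frame = seq_len(nf),
             time_ps = (seq_len(nf) - 1) * traj$time_step_ps,
             rmsd = val)
}

#' Per-atom root-mean-square fluctuation
#'
#' RMS deviation of each measured atom from its own time-mean position,
#' after fitting every frame to the reference on the fit atoms.
#'
#' @inheritParams rmsd_series
#' @return data.frame (atom, rmsf) over the measure atoms, Angstrom.
#' @export
rmsf <- function(traj, reference = NULL, fit = NULL, measure = NULL,
                 top = NULL) {
  if (n_frames(traj) < 2L)
    stop("rmsf undefined for a single frame")
  fitted <- fit_trajectory(traj, reference, fit, top)
  midx <- if (is.null(measure)) seq_len(dim(traj$coords)[2]) else
    resolve_selection(measure, top)
  sub <- fitted$coords[, midx, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mu)^2
  r <- sqrt(colMeans(apply(dev2, c(1, 2), sum)))
  data.frame(atom = midx, rmsf = r)
}

#' Mass-weighted radius of gyration
#'
#' Rg = sqrt( sum_i m_i r_i^2 / sum_i m_i ), with r_i the distance of atom i
#' from the selection's centre of mass.
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}} (source of masses).
#' @param sel selection of atoms to include; default: all atoms.  Whether to
#'   use all atoms or heavy atoms only is a user choice, e.g.
#'   \code{selection(elements = c("C","N","O","S"))}.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, top, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(top)) else resolve_selection(sel, top)
  if (length(idx) == 0L) stop("empty selection")
  m <- top$mass[idx]
  if (any(m <= 0)) stop("selected masses must be positive")
  x <- frame[idx, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  d2 <- rowSums(sweep(x, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' Per-frame radius-of-gyration series
#'
#' @inheritParams rmsd_series
#' @param sel atom selection for Rg (default all atoms).
#' @return data.frame (frame, time_ps, rg).
#' @export
rg_series <- function(traj, top, sel = NULL) {
  nf <- n_frames(traj)
  val <- vapply(seq_len(nf),
                function(f) radius_of_gyration(get_frame(traj, f), top, sel),
                numeric(1))
  data.frame(frame = seq_len(nf),
             time_ps = (seq_len(nf) - 1) * traj$time_step_ps,
             rg = val)
}

#' Mean conformation of a fitted trajectory
#'
#' Per-atom arithmetic mean of the coordinates after fitting each frame to
#' the reference on the fit atoms; used as the reference for PCA.
#'
#' @inheritParams rmsd_series
#' @return atoms x 3 matrix.
#' @export
mean_conformation <- function(traj, reference = NULL, fit = NULL, top = NULL) {
  if (n_frames(traj) < 1L) stop("empty trajectory")
  fitted <- fit_trajectory(traj, reference, fit, top)
  apply(fitted$coords, c(2, 3), mean)
}
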