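#' Dynamical cross-correlation map
#'
#' Normalized covariance of atomic displacements:
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), with dr the deviation
#' from each atom's time-mean position.  Frames should be superposed on the
#' reference first (use \code{fit} to do it here); raw deviations are used,
#' with no mode filtering.  Atoms with zero positional variance have
#' undefined correlations, reported as 0 and flagged.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param top a \code{\link{topology}}.
#' @param sel selection of atoms (typically Calpha).
#' @param fit optional fit selection; when given, frames are fitted to
#'   frame 1 on it before the covariance is accumulated.
#' @return n x n matrix of class \code{"dccm_matrix"} with attributes
#'   \code{source = "trajectory"} and \code{immobile} (indices of
#'   zero-variance atoms).
#' @export
dccm_map <- function(traj, top = NULL, sel = NULL, fit = NULL) {
  if (n_frames(traj) < 2L) stop("dccm needs at least 2 frames")
  if (!is.null(fit)) traj <- fit_trajectory(traj, fit = fit, top = top)
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    resolve_selection(sel, top)
  nf <- n_frames(traj)
  Xs <- lapply(1:3, function(k) {
    M <- traj$coords[, idx, k, drop = FALSE]
    dim(M) <- dim(M)[1:2]
    sweep(M, 2, colMeans(M))
  })
  S <- (crossprod(Xs[[1]]) + crossprod(Xs[[2]]) + crossprod(Xs[[3]])) / nf
  v <- diag(S)
  immobile <- which(v <= .Machine$double.eps * max(v, 1))
  denom <- sqrt(outer(v, v))
  C <- S / denom
  if (length(immobile)) { C[immobile, ] <- 0; C[, immobile] <- 0 }
  diag(C) <- ifelse(seq_along(v) %in% immobile, 0, 1)
  C[C > 1] <- 1; C[C < -1] <- -1
  structure(C, source = "trajectory", immobile = immobile,
            class = c("dccm_matrix", "matrix", "array"))
}

#' Principal component analysis of backbone fluctuations
#'
#' Eigendecomposition of the 3m x 3m coordinate covariance after fitting
#' every frame on the average conformation (computed internally).  The
#' backbone set is N, H, Calpha, C, O when amide hydrogens are present and
#' the heavy-atom backbone otherwise.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param top a \code{\link{topology}}.
#' @param sel atom selection; default: backbone atoms.
#' @param fit fit selection used for the initial superposition (default:
#'   the analysis selection).
#' @return object of class \code{"pca_result"}: \code{eigenvalues}
#'   (variances, Angstrom^2, descending), \code{vectors} (3m x k,
#'   orthonormal, sign fixed so each mode's first nonzero component is
#'   positive), \code{projections} (frames x k), \code{variance_fraction},
#'   \code{mean} (m x 3), \code{atoms}.
#' @export
pca_modes <- function(traj, top = NULL, sel = NULL, fit = NULL) {
  if (n_frames(traj) < 2L) stop("pca needs at least 2 frames")
  idx <- if (is.null(sel)) {
    if (is.null(top)) seq_len(dim(traj$coords)[2]) else
      resolve_selection(selection(atom_names = c("N", "H", "CA", "C", "O")), top)
  } else resolve_selection(sel, top)
  # fit on the average conformation (two passes: fit to frame 1, average,
  # refit to the average)
  mu0 <- mean_conformation(traj, fit = fit %||% idx, top = top)
  fitted <- fit_trajectory(traj, reference = mu0, fit = fit %||% idx, top = top)
  nf <- n_frames(fitted)
  X <- matrix(NA_real_, nf, 3 * length(idx))
  for (f in seq_len(nf))
    X[f, ] <- as.vector(t(fitted$coords[f, idx, ]))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  lambda <- sv$d^2 / nf
  keep <- seq_len(min(nf - 1, ncol(Xc)))
  lambda <- lambda[keep]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: first nonzero component positive
  for (k in seq_len(ncol(V))) {
    nz <- which(abs(V[, k]) > 1e-12)[1]
    if (!is.na(nz) && V[nz, k] < 0) V[, k] <- -V[, k]
  }
  proj <- Xc %*% V
  structure(list(eigenvalues = lambda, vectors = V, projections = proj,
                 variance_fraction = lambda / sum(lambda),
                 mean = matrix(mu, ncol = 3, byrow = TRUE), atoms = idx),
            class = "pca_result")
}

#' Elastic-network normal modes of one conformation
#'
#' Builds a mass-uniform Hookean network on the Calpha coordinates and
#' diagonalizes its Hessian.  Spring rules: \code{"cutoff"} (uniform force
#' constant k for pairs within \code{cutoff}; anisotropic-network-model
#' style) or \code{"inverse_sq"} (all pairs, k_ij = k / d_ij^2).  The six
#' rigid-body modes of a connected network come out at (numerically) zero
#' and are excluded from thermal averages.  These parameterized rules are
#' this package's elastic-network force fields; they are not numerically
#' identical to any third-party parameterization.
#'
#' @param conformation n x 3 Calpha coordinate matrix.
#' @param rule "cutoff" or "inverse_sq".
#' @param cutoff spring cutoff in Angstrom (cutoff rule; default 13).
#' @param k uniform force constant (arbitrary units, default 1).
#' @param temperature temperature in K for thermal amplitudes (default 310).
#' @param chain_springs treat consecutive beads as covalently bonded and
#'   always spring-connect them (default TRUE; the usual Calpha-chain
#'   convention).  Set FALSE when the beads are not an ordered chain.
#' @return object of class \code{"enm_model"}: \code{coords},
#'   \code{hessian}, \code{eigenvalues} (ascending), \code{frequencies}
#'   (sqrt of nonzero eigenvalues), \code{vectors} (3n x 3n, columns sorted
#'   with eigenvalues), \code{n_zero}, \code{rule}, \code{temperature}.
#' @export
enm_modes <- function(conformation, rule = c("cutoff", "inverse_sq"),
                      cutoff = 13, k = 1, temperature = 310,
                      chain_springs = TRUE) {
  rule <- match.arg(rule)
  x <- as.matrix(conformation)
  n <- nrow(x)
  if (n < 2) stop("elastic network needs at least 2 beads")
  D <- pdist2(x, x)
  K <- matrix(0, n, n)
  if (rule == "cutoff") {
    K[D <= cutoff] <- k
  } else {
    K <- k / pmax(D, 1e-12)^2
  }
  if (chain_springs && n > 1) {
    for (i in seq_len(n - 1)) { K[i, i + 1] <- k; K[i + 1, i] <- k }
  }
  diag(K) <- 0
  # connectivity check on the spring graph
  adj <- K > 0
  comp <- integer(n); comp[1] <- 1L; queue <- 1L; cid <- 1L
  while (any(comp == 0L)) {
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
    left <- which(comp == 0L)
    if (length(left)) { cid <- cid + 1L; comp[left[1]] <- cid; queue <- left[1] }
  }
  if (max(comp) > 1L)
    stop("disconnected spring network: ", max(comp), " components of sizes ",
         paste(tabulate(comp), collapse = ", "))
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    js <- which(K[i, (i + 1):n] > 0) + i
    for (j in js) {
      d <- x[j, ] - x[i, ]
      b <- K[i, j] * tcrossprod(d) / sum(d^2)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] - b
      H[jj, ii] <- H[jj, ii] - b
      H[ii, ii] <- H[ii, ii] + b
      H[jj, jj] <- H[jj, jj] + b
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  ev <- rev(eig$values)
  V <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  for (m in seq_len(ncol(V))) {
    nz <- which(abs(V[, m]) > 1e-9)[1]
    if (!is.na(nz) && V[nz, m] < 0) V[, m] <- -V[, m]
  }
  tol <- 1e-6 * max(ev)
  n_zero <- sum(ev < tol)
  structure(list(coords = x, hessian = H, eigenvalues = ev,
                 frequencies = sqrt(pmax(ev[ev >= tol], 0)),
                 vectors = V, n_zero = n_zero, rule = rule,
                 cutoff = cutoff, k = k, temperature = temperature),
            class = "enm_model")
}

#' Cross-correlation map predicted by an elastic network
#'
#' Thermal covariance from the pseudo-inverse of the Hessian,
#' Sigma = sum_{nonzero modes} (1/lambda) v v^T, reduced to per-bead 3x3
#' blocks and normalized like \code{\link{dccm_map}}.  Temperature scales
#' the covariance uniformly and cancels in the normalization.
#'
#' @param model an \code{enm_model}.
#' @return \code{dccm_matrix} with attribute \code{source = "ENM"}.
#' @export
enm_dccm <- function(model) {
  n <- nrow(model$coords)
  nz <- which(model$eigenvalues >= 1e-6 * max(model$eigenvalues))
  V <- model$vectors[, nz, drop = FALSE]
  Sigma <- V %*% (t(V) / model$eigenvalues[nz])
  ix <- function(i) (3 * i - 2):(3 * i)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    s <- sum(diag(Sigma[ix(i), ix(j), drop = FALSE]))
    S[i, j] <- s; S[j, i] <- s
  }
  v <- diag(S)
  C <- S / sqrt(outer(v, v))
  C[C > 1] <- 1; C[C < -1] <- -1
  structure(C, source = "ENM", immobile = integer(0),
            class = c("dccm_matrix", "matrix", "array"))
}

#' Write a correlation matrix (or mode vectors) to disk
#'
#' @param m a \code{dccm_matrix} (dense TSV) or \code{pca_result} /
#'   \code{enm_model} (per-atom displacement triples per mode).
#' @param path output path.
#' @param modes mode indices for vector export (default 1:3).
#' @export
write_dynamics <- function(m, path, modes = 1:3) {
  if (inherits(m, "dccm_matrix")) {
    utils::write.table(round(unclass(m), 6), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    V <- if (inherits(m, "pca_result")) m$vectors else
      m$vectors[, m$n_zero + seq_along(modes), drop = FALSE]
    modes <- modes[modes <= ncol(V)]
    out <- do.call(rbind, lapply(modes, function(k) {
      w <- matrix(V[, k], ncol = 3, byrow = TRUE)
      data.frame(mode = k, atom = seq_len(nrow(w)),
                 dx = w[, 1], dy = w[, 2], dz = w[, 3])
    }))
    write_tsv_table(out, path, "mode displacement vectors")
  }
  invisible(path)
}
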