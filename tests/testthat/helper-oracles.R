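# Independent brute-force oracles used to validate the package's optimized
# implementations.  These deliberately use different algorithms / code
# paths than the functions they check.

# Horn quaternion-based rigid superposition: returns minimized RMSD
quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# direct-definition RMSD between two coordinate matrices
direct_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# two-pass mass-weighted radius of gyration
oracle_rg <- function(x, m) {
  com <- c(sum(x[, 1] * m), sum(x[, 2] * m), sum(x[, 3] * m)) / sum(m)
  sqrt(sum(m * colSums((t(x) - com)^2)) / sum(m))
}

# brute-force RMSF from a stack of pre-fitted frames (list of matrices)
oracle_rmsf <- function(frames) {
  arr <- simplify2array(frames)            # atoms x 3 x frames
  mu <- apply(arr, c(1, 2), mean)
  sqrt(apply((arr - array(mu, dim(arr)))^2, 1, function(v) mean(rowSums(
    matrix(v, ncol = 3)))))
}

# double-loop DCCM oracle
oracle_dccm <- function(coords) {
  n <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    di <- sweep(coords[, i, , drop = TRUE], 2, mu[i, ])
    dj <- sweep(coords[, j, , drop = TRUE], 2, mu[j, ])
    C[i, j] <- mean(rowSums(di * dj)) /
      sqrt(mean(rowSums(di^2)) * mean(rowSums(dj^2)))
  }
  C
}

# exhaustive O(N^2) H-bond oracle (same geometric criteria, no grid)
oracle_hbonds <- function(frame, top, dc = 3.6, ac = 120) {
  hpairs <- kitdyn:::attach_hydrogens(frame, top)
  polar <- which(top$element %in% c("N", "O", "S"))
  dons <- hpairs[top$element[hpairs$heavy] %in% c("N", "O", "S"), ,
                 drop = FALSE]
  Hrec <- reconstruct_amide_h(frame, top)
  bb <- kitdyn:::backbone_table(frame, top)
  ex_d <- unique(dons$heavy)
  for (k in seq_len(nrow(bb$res))) {
    ni <- bb$idx$N[k]
    if (is.na(ni) || ni %in% ex_d || is.na(Hrec[k, 1])) next
    dons <- rbind(dons, data.frame(h = NA_integer_, heavy = ni))
  }
  out <- list()
  for (r in seq_len(nrow(dons))) {
    d <- dons$heavy[r]
    hxyz <- if (is.na(dons$h[r]))
      Hrec[match(paste(top$chain[d], top$res_index[d], sep = ":"),
                 rownames(Hrec)), ]
    else frame[dons$h[r], ]
    a_ok <- polar[polar != d &
                    !(top$res_index[polar] == top$res_index[d] &
                        top$chain[polar] == top$chain[d])]
    if (!length(a_ok)) next
    dist <- sqrt(rowSums(sweep(frame[a_ok, , drop = FALSE], 2,
                               frame[d, ])^2))
    U <- matrix(frame[d, ] - hxyz, length(a_ok), 3, byrow = TRUE)
    V <- sweep(frame[a_ok, , drop = FALSE], 2, hxyz)
    ang <- acos(pmin(1, pmax(-1, rowSums(U * V) /
                               sqrt(rowSums(U^2) * rowSums(V^2))))) * 180 / pi
    hit <- which(dist <= dc & ang >= ac)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(donor = d, acceptor = a_ok[hit])
  }
  if (!length(out)) return(data.frame(donor = integer(0),
                                      acceptor = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$donor, res$acceptor), , drop = FALSE]
}

# exhaustive hydrophobic-contact oracle
oracle_hydrophobic <- function(frame, top, cutoff = 4) {
  sc <- which(top$res_name %in% hydrophobic_residues() &
                top$element != "H" &
                !kitdyn:::is_backbone_atom(top$atom_name))
  res <- sort(unique(top$res_index[sc]))
  out <- list()
  for (i in res) for (j in res) if (i < j) {
    ai <- sc[top$res_index[sc] == i]; aj <- sc[top$res_index[sc] == j]
    d <- min(kitdyn:::pdist2(frame[ai, , drop = FALSE],
                             frame[aj, , drop = FALSE]))
    if (d <= cutoff)
      out[[length(out) + 1L]] <- data.frame(res_i = i, res_j = j,
                                            min_distance = d)
  }
  if (!length(out)) return(data.frame(res_i = integer(0),
                                      res_j = integer(0),
                                      min_distance = numeric(0)))
  do.call(rbind, out)
}

# ENM Hessian by central finite differences of the network potential
# V = 1/2 sum k_ij (|r_i - r_j| - d0_ij)^2 around the reference structure
oracle_enm_spectrum <- function(x, cutoff = 13, k = 1,
                                chain_springs = TRUE, h = 1e-5) {
  n <- nrow(x)
  D0 <- as.matrix(stats::dist(x))
  K <- matrix(0, n, n)
  K[D0 <= cutoff] <- k
  if (chain_springs) for (i in seq_len(n - 1)) {
    K[i, i + 1] <- k; K[i + 1, i] <- k
  }
  diag(K) <- 0
  V <- function(xy) {
    xm <- matrix(xy, n, 3, byrow = TRUE)
    Dm <- as.matrix(stats::dist(xm))
    sum(K[upper.tri(K)] * (Dm[upper.tri(Dm)] - D0[upper.tri(D0)])^2) / 2
  }
  x0 <- as.vector(t(x))
  m <- 3 * n
  H <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    pp <- x0; pp[i] <- pp[i] + h; pp[j] <- pp[j] + h
    pm <- x0; pm[i] <- pm[i] + h; pm[j] <- pm[j] - h
    mp <- x0; mp[i] <- mp[i] - h; mp[j] <- mp[j] + h
    mm <- x0; mm[i] <- mm[i] - h; mm[j] <- mm[j] - h
    H[i, j] <- (V(pp) - V(pm) - V(mp) + V(mm)) / (4 * h^2)
    H[j, i] <- H[i, j]
  }
  sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

# cylinder-axis fit oracle: axis minimizing the variance of point-to-axis
# distances; returns a unit direction (sign arbitrary)
oracle_cylinder_axis <- function(pts) {
  obj <- function(p) {
    d <- c(cos(p[1]) * cos(p[2]), cos(p[1]) * sin(p[2]), sin(p[1]))
    c0 <- colMeans(pts)
    rel <- sweep(pts, 2, c0)
    proj <- rel - outer(as.vector(rel %*% d), d)
    stats::var(sqrt(rowSums(proj^2)))
  }
  best <- NULL
  for (st in list(c(0, 0), c(pi / 4, pi / 3), c(-pi / 3, 2), c(1.2, -1)))
    { f <- stats::optim(st, obj); if (is.null(best) || f$value < best$value) best <- f }
  p <- best$par
  c(cos(p[1]) * cos(p[2]), cos(p[1]) * sin(p[2]), sin(p[1]))
}

# random rigid motion (proper rotation + translation)
random_rigid <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 10))
}
apply_rigid <- function(x, rt) sweep(x %*% rt$R, 2, rt$t, "+")
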