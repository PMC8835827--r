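## Synthetic-trajectory generator: geometric/statistical stand-ins with
## planted, known ground truth for every downstream analysis stage.  No
## force-field realism is attempted or needed.

# NeRF placement: position D with |C-D| = bond, angle(B,C,D) = angle_deg,
# dihedral(A,B,C,D) = torsion_deg
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180; chi <- torsion_deg * pi / 180
  ubc <- c - b; ubc <- ubc / sqrt(sum(ubc^2))
  uab <- b - a; uab <- uab / sqrt(sum(uab^2))
  n <- c(uab[2] * ubc[3] - uab[3] * ubc[2],
         uab[3] * ubc[1] - uab[1] * ubc[3],
         uab[1] * ubc[2] - uab[2] * ubc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * ubc[3] - n[3] * ubc[2],
         n[3] * ubc[1] - n[1] * ubc[3],
         n[1] * ubc[2] - n[2] * ubc[1])
  d_local <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c + d_local[1] * ubc + d_local[2] * m + d_local[3] * n
}

# idealized backbone geometry constants (Angstrom / degrees)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, ca_cb = 1.53, ang_c_ca_cb = 110.1,
                dihed_n_c_ca_cb = 122.6)

#' Canonical backbone torsions for ideal secondary structures
#'
#' alpha: phi = -57, psi = -47; 3_10: phi = -49, psi = -26;
#' beta: phi = -119, psi = 113; coil: randomized torsions.
#'
#' @param kind one of "alpha", "three_ten", "beta", "coil".
#' @param length number of residues.
#' @param rng function(n) returning n uniform values in [0,1) used for coil
#'   torsions (default \code{runif}; seed it for determinism).
#' @return data.frame (phi, psi, omega) in degrees.
#' @export
ideal_torsions <- function(kind = c("alpha", "three_ten", "beta", "coil"),
                           length, rng = stats::runif) {
  kind <- match.arg(kind)
  tor <- switch(kind,
    alpha = c(-57, -47),
    three_ten = c(-49, -26),
    beta = c(-119, 113),
    coil = NULL)
  if (is.null(tor)) {
    # broad left-half Ramachandran draw; avoids steric pile-ups without
    # ever forming two consecutive helical turns
    phi <- -150 + 100 * rng(length)
    psi <- ifelse(rng(length) < 0.5, 100 + 60 * rng(length),
                  -80 + 40 * rng(length))
    data.frame(phi = phi, psi = psi, omega = 180)
  } else {
    data.frame(phi = rep(tor[1], length), psi = rep(tor[2], length),
               omega = 180)
  }
}

# Build backbone coordinates (N, CA, C, O [, CB]) from per-residue torsions.
# Returns list(coords, atoms): atoms is a data.frame (atom_name, element,
# res_local).
build_backbone <- function(torsions, with_cb = TRUE) {
  nres <- nrow(torsions)
  g <- BB_GEOM
  nm <- if (with_cb) c("N", "CA", "C", "O", "CB") else c("N", "CA", "C", "O")
  per <- length(nm)
  xyz <- matrix(NA_real_, nres * per, 3)
  at <- function(i, a) (i - 1) * per + match(a, nm)
  # seed the first residue in the xy-plane
  xyz[at(1, "N"), ] <- c(0, 0, 0)
  xyz[at(1, "CA"), ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  xyz[at(1, "C"), ] <- xyz[at(1, "CA"), ] +
    g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(nres)) {
    N <- xyz[at(i, "N"), ]; CA <- xyz[at(i, "CA"), ]; C <- xyz[at(i, "C"), ]
    if (i < nres) {
      Nn <- place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, torsions$psi[i])
      xyz[at(i + 1, "N"), ] <- Nn
      CAn <- place_atom(CA, C, Nn, g$n_ca, g$ang_c_n_ca, torsions$omega[i])
      xyz[at(i + 1, "CA"), ] <- CAn
      xyz[at(i + 1, "C"), ] <- place_atom(C, Nn, CAn, g$ca_c, g$ang_n_ca_c,
                                          torsions$phi[i + 1])
    }
    xyz[at(i, "O"), ] <- place_atom(N, CA, C, g$c_o, g$ang_ca_c_o,
                                    torsions$psi[i] + 180)
    if (with_cb)
      xyz[at(i, "CB"), ] <- place_atom(N, C, CA, g$ca_cb, g$ang_c_ca_cb,
                                       g$dihed_n_c_ca_cb)
  }
  atoms <- data.frame(atom_name = rep(nm, nres),
                      element = rep(substr(nm, 1, 1), nres),
                      res_local = rep(seq_len(nres), each = per))
  list(coords = xyz, atoms = atoms)
}

#' Build an ideal secondary-structure segment
#'
#' Backbone (N, CA, C, O, optional pseudo-side-chain CB) placed from
#' canonical torsions; bond lengths are the construction constants
#' N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom.
#'
#' @inheritParams ideal_torsions
#' @param res_name residue name stamped on all residues (default "ALA").
#' @param first_res residue number of the first residue.
#' @param with_cb include a CB pseudo-side-chain atom.
#' @return list(topology, coords).
#' @export
build_ideal_segment <- function(kind, length, res_name = "ALA",
                                first_res = 1L, with_cb = TRUE,
                                rng = stats::runif) {
  if (length < 3) stop("segment needs length >= 3")
  tor <- ideal_torsions(kind, length, rng)
  bb <- build_backbone(tor, with_cb)
  top <- topology(atom_name = bb$atoms$atom_name,
                  element = bb$atoms$element,
                  res_index = bb$atoms$res_local + first_res - 1L,
                  res_name = res_name)
  list(topology = top, coords = bb$coords)
}

#' Build an idealized two-strand antiparallel beta-sheet
#'
#' Two ideal strands; the second is placed by a deterministic rigid-body
#' optimization that drives the inter-strand backbone H-bond geometry
#' (N...O about 2.9 Angstrom at alternating positions of the antiparallel
#' register) to ideality.
#'
#' @param length residues per strand.
#' @param gap residue-numbering gap between the strands (default 4).
#' @return list(topology, coords); strand 2 residues run antiparallel.
#' @export
build_beta_sheet <- function(length = 8, gap = 4L) {
  s1 <- build_ideal_segment("beta", length, with_cb = FALSE)
  s2 <- build_ideal_segment("beta", length, with_cb = FALSE,
                            first_res = length + gap + 1L)
  idx_of <- function(res, an) (res - 1) * 4 + match(an, c("N", "CA", "C", "O"))
  # amide H of each strand in its own geometry (moves rigidly with it)
  H1 <- reconstruct_amide_h(s1$coords, s1$topology)
  H2 <- reconstruct_amide_h(s2$coords, s2$topology)
  # antiparallel register: residue i pairs with residue length+1-i (local
  # numbering in strand 2); "wide" pairs (odd i) carry both backbone
  # H-bonds.  Targets: O...N = 2.9 with the amide H collinear (O...H = 1.9)
  # in both directions.
  wide <- seq(1, length, by = 2)
  score <- function(x2r, H2r) {
    s <- 0
    for (i in wide) {
      j <- length + 1 - i
      if (j <= 1 || i <= 1) next  # residue 1 of a strand has no amide H
      s <- s +
        (sqrt(sum((s1$coords[idx_of(i, "O"), ] - x2r[idx_of(j, "N"), ])^2)) - 2.9)^2 +
        (sqrt(sum((s1$coords[idx_of(i, "O"), ] - H2r[j, ])^2)) - 1.9)^2 +
        (sqrt(sum((x2r[idx_of(j, "O"), ] - s1$coords[idx_of(i, "N"), ])^2)) - 2.9)^2 +
        (sqrt(sum((x2r[idx_of(j, "O"), ] - H1[i, ])^2)) - 1.9)^2
    }
    s
  }
  move <- function(p) {
    R <- euler_rot(p[1:3])
    cm <- colMeans(s2$coords)
    shift <- colMeans(s1$coords) + p[4:6]
    list(x = sweep(sweep(s2$coords, 2, cm) %*% R, 2, shift, "+"),
         h = sweep(sweep(H2, 2, cm) %*% R, 2, shift, "+"))
  }
  obj <- function(p) { m <- move(p); score(m$x, m$h) }
  starts <- list(c(0, 0, pi, 0, 4.8, 0), c(pi, 0, 0, 0, 4.8, 0),
                 c(0, pi, 0, 0, 4.8, 0), c(0, 0, pi, 0, -4.8, 0),
                 c(pi, 0, 0, 0, -4.8, 0), c(0, pi, 0, 0, -4.8, 0))
  fits <- lapply(starts, function(p0)
    stats::optim(p0, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)))
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  x2 <- move(best$par)$x
  top <- topology(atom_name = c(s1$topology$atom_name, s2$topology$atom_name),
                  element = c(s1$topology$element, s2$topology$element),
                  res_index = c(s1$topology$res_index, s2$topology$res_index),
                  res_name = "ALA")
  list(topology = top, coords = rbind(s1$coords, x2))
}

euler_rot <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rx %*% Ry %*% Rz
}

rot_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

#' Build a helix with a planted kink
#'
#' An ideal straight helix whose C-terminal half is rotated about an axis
#' through the hinge Calpha, perpendicular to the helix axis, so that the
#' two half-helix axes meet at the requested kink angle (180 = straight).
#'
#' @param length residues.
#' @param hinge hinge residue (interior).
#' @param kink_deg planted kink angle in degrees.
#' @return list(topology, coords, kink_deg).
#' @export
build_kinked_helix <- function(length = 15, hinge = 8, kink_deg = 150) {
  seg <- build_ideal_segment("alpha", length, with_cb = FALSE)
  top <- seg$topology
  ca <- resolve_selection(ca_selection(NULL), top)
  axis_fit <- svd(sweep(seg$coords[ca, ], 2, colMeans(seg$coords[ca, ])),
                  nu = 0, nv = 1)$v[, 1]
  hinge_ca <- seg$coords[ca[hinge], ]
  perp <- c(-axis_fit[2], axis_fit[1], 0)
  if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
  R <- rot_about_axis(perp, 180 - kink_deg)
  idx <- which(top$res_index > top$res_index[1] + hinge - 1)
  x <- seg$coords
  x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, hinge_ca) %*% t(R),
                    2, hinge_ca, "+")
  list(topology = top, coords = x, kink_deg = kink_deg)
}

#' Declare a synthetic multi-state trajectory
#'
#' The chain is a sequence of named segments built from canonical torsions;
#' appendage segments hop between discrete rigid anchor poses following a
#' Markov dwell process with declared occupancy weights, optionally switch
#' secondary structure on a schedule, and carry harmonic positional jitter.
#' Planted H-bonds force donor/acceptor geometry in a declared fraction of
#' frames.  The generator emits the full ground truth alongside, so every
#' downstream stage can be scored without re-deriving it.
#'
#' @param segments list of \code{list(name, kind, n_res)} in chain order.
#' @param appendages list of \code{list(segment, states, weights,
#'   mean_dwell, jitter)}; \code{states} is a list of
#'   \code{list(angle, axis, shift)} rigid poses applied about the
#'   segment's anchor (its first N atom).
#' @param fold_schedule named list: segment ->
#'   \code{list(kinds, fractions)}; the segment's coordinates follow kind 1
#'   for the first fraction of frames, kind 2 next, etc.
#' @param hbond_plants list of \code{list(donor_res, acceptor_res,
#'   occurrence)}.
#' @param n_frames,time_step_ps trajectory dimensions.
#' @param core_jitter positional jitter (sd, Angstrom) of non-appendage
#'   atoms.
#' @param first_res numbering of the first residue.
#' @param res_name_cycle residue names recycled along the chain (default
#'   alternates polar/hydrophobic so contact detection has substrate).
#' @param seed RNG seed.
#' @return object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(segments, appendages = list(),
                           fold_schedule = list(), hbond_plants = list(),
                           n_frames = 1000L, time_step_ps = 10,
                           core_jitter = 0.05, first_res = 1L,
                           res_name_cycle = c("SER", "LEU", "GLN", "VAL"),
                           seed = 1L) {
  for (ap in appendages) {
    w <- ap$weights
    if (abs(sum(w) - 1) > 1e-9) stop("appendage weights must sum to 1")
    if (length(ap$states) != length(w))
      stop("one weight per state required")
    if (!is.null(ap$jitter) && ap$jitter < 0) stop("jitter must be >= 0")
  }
  if (n_frames < 1) stop("n_frames must be >= 1")
  structure(list(segments = segments, appendages = appendages,
                 fold_schedule = fold_schedule, hbond_plants = hbond_plants,
                 n_frames = as.integer(n_frames),
                 time_step_ps = time_step_ps, core_jitter = core_jitter,
                 first_res = as.integer(first_res),
                 res_name_cycle = res_name_cycle, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# dwell process with exact occupancies: each state holds a frame quota
# round(weight * n); segments of approximately geometric dwell length are
# drawn from the remaining quotas until all are spent.  Realized
# occupancies therefore equal the declared weights up to rounding, which is
# what makes the declared weights usable as ground truth.
dwell_states <- function(n, weights, mean_dwell) {
  quota <- floor(weights * n)
  rem <- n - sum(quota)
  if (rem > 0) {
    extra <- order(weights * n - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  states <- integer(n)
  i <- 1L
  while (i <= n) {
    s <- sample.int(length(weights), 1L, prob = quota)
    len <- min(1L + stats::rgeom(1, 1 / max(mean_dwell, 1)), quota[s])
    j <- i + len - 1L
    states[i:j] <- s
    quota[s] <- quota[s] - len
    i <- j + 1L
  }
  states
}

#' Generate a synthetic trajectory with ground truth
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list: \code{topology}, \code{trajectory}, \code{truth} (list:
#'   \code{states} frames x appendages matrix, \code{occupancy} realized
#'   per-appendage state fractions, \code{weights} declared weights,
#'   \code{hbond_frames} per plant, \code{fold_kind} per scheduled segment
#'   and frame, \code{segment_residues}).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  nf <- spec$n_frames
  # --- base chain ---------------------------------------------------------
  nres_tot <- sum(vapply(spec$segments, function(s) as.integer(s$n_res), 0L))
  tor <- do.call(rbind, lapply(spec$segments, function(s)
    ideal_torsions(s$kind, s$n_res)))
  bb <- build_backbone(tor, with_cb = TRUE)
  per <- 5L
  res_first <- spec$first_res
  seg_res <- list(); r0 <- res_first
  for (s in spec$segments) {
    seg_res[[s$name]] <- c(r0, r0 + s$n_res - 1L)
    r0 <- r0 + s$n_res
  }
  top <- topology(atom_name = bb$atoms$atom_name,
                  element = bb$atoms$element,
                  res_index = bb$atoms$res_local + res_first - 1L,
                  res_name = rep(rep_len(spec$res_name_cycle, nres_tot),
                                 each = per))
  base <- bb$coords
  seg_atom_idx <- function(name) {
    rr <- seg_res[[name]]
    which(top$res_index >= rr[1] & top$res_index <= rr[2])
  }
  # --- alternative fold coordinates for scheduled segments ----------------
  alt_coords <- list()
  for (nm in names(spec$fold_schedule)) {
    sched <- spec$fold_schedule[[nm]]
    idx <- seg_atom_idx(nm)
    n_res <- length(idx) / per
    alt <- list()
    for (kind in sched$kinds) {
      tor_k <- ideal_torsions(kind, n_res)
      blk <- build_backbone(tor_k, with_cb = TRUE)$coords
      # anchor the rebuilt block on the base block (fit on first 3 atoms'
      # rigid placement via Kabsch over the whole block's first residue)
      anchor <- idx[1:min(12, length(idx))]
      sp <- superpose(blk, base[idx, , drop = FALSE],
                      fit = seq_len(min(12, nrow(blk))))
      alt[[kind]] <- sp$coords
    }
    alt_coords[[nm]] <- alt
  }
  # --- appendage state machinery ------------------------------------------
  n_ap <- length(spec$appendages)
  states <- matrix(1L, nf, max(1L, n_ap))
  ap_transforms <- list()
  for (a in seq_len(n_ap)) {
    ap <- spec$appendages[[a]]
    states[, a] <- dwell_states(nf, ap$weights, ap$mean_dwell %||% 20)
    idx <- seg_atom_idx(ap$segment)
    anchor <- base[idx[1], ]
    ap_transforms[[a]] <- lapply(ap$states, function(st) {
      R <- if (!is.null(st$angle) && st$angle != 0)
        rot_about_axis(st$axis %||% c(0, 0, 1), st$angle) else diag(3)
      list(R = R, shift = st$shift %||% c(0, 0, 0), anchor = anchor,
           idx = idx)
    })
  }
  # --- H-bond plant schedule ----------------------------------------------
  hb_frames <- lapply(spec$hbond_plants, function(p) {
    k <- round(p$occurrence * nf)
    sort(sample.int(nf, k))
  })
  # --- frame assembly ------------------------------------------------------
  coords <- array(NA_real_, c(nf, nrow(top), 3L))
  fold_kind <- list()
  for (nm in names(spec$fold_schedule)) {
    sched <- spec$fold_schedule[[nm]]
    cuts <- round(cumsum(sched$fractions) * nf)
    kind_per_frame <- rep(sched$kinds[length(sched$kinds)], nf)
    lo <- 1L
    for (q in seq_along(sched$kinds)) {
      kind_per_frame[lo:cuts[q]] <- sched$kinds[q]
      lo <- cuts[q] + 1L
      if (lo > nf) break
    }
    fold_kind[[nm]] <- kind_per_frame
  }
  for (f in seq_len(nf)) {
    x <- base
    for (nm in names(fold_kind)) {
      idx <- seg_atom_idx(nm)
      x[idx, ] <- alt_coords[[nm]][[fold_kind[[nm]][f]]]
    }
    for (a in seq_len(n_ap)) {
      tr <- ap_transforms[[a]][[states[f, a]]]
      blk <- sweep(x[tr$idx, , drop = FALSE], 2, tr$anchor)
      x[tr$idx, ] <- sweep(blk %*% t(tr$R), 2, tr$anchor + tr$shift, "+")
    }
    jit <- matrix(stats::rnorm(length(x), 0, spec$core_jitter), ncol = 3)
    for (a in seq_len(n_ap)) {
      ap <- spec$appendages[[a]]
      if (!is.null(ap$jitter)) {
        idx <- seg_atom_idx(ap$segment)
        jit[idx, ] <- stats::rnorm(length(idx) * 3, 0, ap$jitter)
      }
    }
    x <- x + jit
    # planted H-bond geometry (after jitter so it is exact)
    for (p in seq_along(spec$hbond_plants)) {
      pl <- spec$hbond_plants[[p]]
      don_n <- which(top$res_index == pl$donor_res & top$atom_name == "N")
      acc_o <- which(top$res_index == pl$acceptor_res & top$atom_name == "O")
      if (f %in% hb_frames[[p]]) {
        Hr <- reconstruct_amide_h(x, top)
        hrow <- match(paste(top$chain[don_n], pl$donor_res, sep = ":"),
                      rownames(Hr))
        hxyz <- Hr[hrow, ]
        u <- hxyz - x[don_n, ]; u <- u / sqrt(sum(u^2))
        x[acc_o, ] <- x[don_n, ] + 2.9 * u
      }
    }
    coords[f, , ] <- x
  }
  occ <- lapply(seq_len(n_ap), function(a)
    tabulate(states[, a], nbins = length(spec$appendages[[a]]$weights)) / nf)
  list(topology = top,
       trajectory = trajectory(coords, time_step_ps = spec$time_step_ps,
                               topology = top),
       truth = list(states = states[, seq_len(max(1, n_ap)), drop = FALSE],
                    occupancy = occ,
                    weights = lapply(spec$appendages, function(a) a$weights),
                    hbond_frames = hb_frames,
                    fold_kind = fold_kind,
                    segment_residues = seg_res))
}

#' KIT-like synthetic fixture
#'
#' A reduced-backbone stand-in for the KIT cytoplasmic region I516--R946
#' (~430 residues; N, CA, C, O + pseudo-side-chain CB): a rigid
#' tyrosine-kinase core with a TM helix, disordered juxtamembrane region,
#' a two-state kinase insert domain (KID, rotational hopping) and a
#' two-anchor C-terminal tail, over 2,000 frames.  Ground truth (state
#' labels, occupancies) is emitted for end-to-end pipeline scoring.  This
#' is a geometric stand-in, not a model of the real fold.
#'
#' @param n_frames frames (default 2000).
#' @param seed RNG seed.
#' @return list(topology, trajectory, domain_map, truth).
#' @export
kit_like_fixture <- function(n_frames = 2000L, seed = 42L) {
  segs <- list(
    list(name = "NTERM", kind = "coil",  n_res = 9L),    # 516-524
    list(name = "TM",    kind = "alpha", n_res = 21L),   # 525-545
    list(name = "JMR",   kind = "coil",  n_res = 36L),   # 546-581
    list(name = "NLOBE", kind = "alpha", n_res = 99L),   # 582-680
    list(name = "HINGE", kind = "coil",  n_res = 8L),    # 681-688
    list(name = "KID",   kind = "alpha", n_res = 80L),   # 689-768
    list(name = "CLOBE", kind = "alpha", n_res = 163L),  # 769-931
    list(name = "CTAIL", kind = "coil",  n_res = 15L))   # 932-946
  aps <- list(
    list(segment = "KID",
         states = list(list(angle = 0),
                       list(angle = 35, axis = c(0, 1, 0))),
         weights = c(0.7, 0.3), mean_dwell = 25, jitter = 0.3),
    list(segment = "CTAIL",
         states = list(list(angle = 0),
                       list(angle = 60, axis = c(1, 0, 0),
                            shift = c(0, 8, 0))),
         weights = c(0.6, 0.4), mean_dwell = 25, jitter = 0.3))
  spec <- synthetic_spec(segments = segs, appendages = aps,
                         n_frames = n_frames, time_step_ps = 10,
                         core_jitter = 0.15, first_res = 516L, seed = seed)
  gen <- generate_trajectory(spec)
  map <- kit_domain_map()
  validate_domain_map(map, gen$topology)
  list(topology = gen$topology, trajectory = gen$trajectory,
       domain_map = map, truth = gen$truth)
}
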