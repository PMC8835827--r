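#' @keywords internal
#' Pairwise distance matrix between two point sets
pdist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Reconstruct backbone amide hydrogens
#'
#' Places H on each amide nitrogen along the bisector of the C(i-1)-N and
#' CA-N directions at an N-H length of 1.01 Angstrom; the first residue of a
#' chain and prolines carry no amide hydrogen.  Used whenever the input
#' lacks explicit hydrogens (heavy-atom-only trajectories).
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}}.
#' @return matrix n_residues x 3 of H positions (NA rows where undefined),
#'   rownames = residue keys "chain:res_index".
#' @export
reconstruct_amide_h <- function(frame, top) {
  bb <- backbone_table(frame, top)
  H <- matrix(NA_real_, nrow(bb$res), 3)
  for (k in seq_len(nrow(bb$res))) {
    if (k == 1 || bb$res$chain[k] != bb$res$chain[k - 1]) next
    if (bb$res$res_name[k] == "PRO") next
    if (is.na(bb$idx$N[k]) || is.na(bb$idx$CA[k]) || is.na(bb$idx$C[k - 1]))
      next
    n <- frame[bb$idx$N[k], ]
    u1 <- n - frame[bb$idx$C[k - 1], ]; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- n - frame[bb$idx$CA[k], ];    u2 <- u2 / sqrt(sum(u2^2))
    d <- u1 + u2; d <- d / sqrt(sum(d^2))
    H[k, ] <- n + 1.01 * d
  }
  rownames(H) <- paste(bb$res$chain, bb$res$res_index, sep = ":")
  H
}

# residue-level backbone index table: one row per residue, atom indices of
# N, CA, C, O, H (NA when absent)
backbone_table <- function(frame, top) {
  key <- paste(top$chain, top$res_index, sep = ":")
  ukey <- unique(key)
  res <- data.frame(key = ukey,
                    chain = sub(":.*", "", ukey),
                    res_index = as.integer(sub(".*:", "", ukey)),
                    stringsAsFactors = FALSE)
  res$res_name <- top$res_name[match(ukey, key)]
  idx <- list()
  for (an in c("N", "CA", "C", "O", "H")) {
    sel <- which(top$atom_name == an)
    idx[[an]] <- sel[match(ukey, key[sel])]
  }
  list(res = res, idx = idx)
}

#' Kabsch-Sander secondary-structure assignment for one frame
#'
#' Implements the original hydrogen-bond-based assignment: a backbone
#' H-bond exists between CO(i) and NH(j) when the electrostatic energy
#' E = 0.084 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol is below
#' -0.5 kcal/mol.  Two consecutive n-turns define a helix (G/H/I for
#' n = 3/4/5), bridge patterns define parallel/antiparallel bridges (B) and
#' ladders (E), remaining turn residues are T, residues with a Calpha bend
#' above 70 degrees are S, everything else is coil C.  Structural overlaps
#' are resolved in the priority order H, B, E, G, I, T, S.  Amide hydrogens
#' are reconstructed when absent; residues missing a backbone heavy atom are
#' labelled C.
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}}.
#' @return character vector of labels over residues (names = "chain:res"),
#'   with attribute \code{bridge_sense} ("P", "A" or "" per residue, the
#'   parallel/antiparallel distinction of strand residues).
#' @export
assign_secondary_structure <- function(frame, top) {
  bb <- backbone_table(frame, top)
  nres <- nrow(bb$res)
  labels <- rep("C", nres)
  sense <- rep("", nres)
  names(labels) <- bb$res$key
  if (nres < 3) return(structure(labels, bridge_sense = sense))

  has_bb <- !(is.na(bb$idx$N) | is.na(bb$idx$CA) | is.na(bb$idx$C) |
                is.na(bb$idx$O))
  if (any(!has_bb))
    warning(sum(!has_bb), " residue(s) missing backbone heavy atoms; labelled C")

  Nx <- frame[ifelse(is.na(bb$idx$N), 1L, bb$idx$N), , drop = FALSE]
  CAx <- frame[ifelse(is.na(bb$idx$CA), 1L, bb$idx$CA), , drop = FALSE]
  Cx <- frame[ifelse(is.na(bb$idx$C), 1L, bb$idx$C), , drop = FALSE]
  Ox <- frame[ifelse(is.na(bb$idx$O), 1L, bb$idx$O), , drop = FALSE]
  Hx <- matrix(NA_real_, nres, 3)
  expl <- !is.na(bb$idx$H)
  Hx[expl, ] <- frame[bb$idx$H[expl], , drop = FALSE]
  Hrec <- reconstruct_amide_h(frame, top)
  take <- !expl & !is.na(Hrec[, 1])
  Hx[take, ] <- Hrec[take, , drop = FALSE]
  has_h <- !is.na(Hx[, 1]) & bb$res$res_name != "PRO"

  # H-bond energy: donor NH of residue j accepting from CO of residue i
  r_ON <- pdist2(Ox, Nx)
  r_CN <- pdist2(Cx, Nx)
  Hsafe <- Hx; Hsafe[!has_h, ] <- 1e6
  r_OH <- pdist2(Ox, Hsafe)
  r_CH <- pdist2(Cx, Hsafe)
  E <- 0.084 * (1 / r_ON + 1 / r_CH - 1 / r_OH - 1 / r_CN) * 332
  ok <- outer(has_bb, has_bb & has_h, "&")
  same_chain <- outer(bb$res$chain, bb$res$chain, "==")
  diag(ok) <- FALSE
  # minimal-distance clamp as in the reference algorithm
  E[r_ON < 0.5] <- -9.9
  hb <- ok & (E < -0.5)

  chain_id <- bb$res$chain
  contiguous <- function(i, j) {
    # residues i..j consecutive within one chain (table rows are sequential)
    same_chain[i, j]
  }
  turn <- list()
  for (n in 3:5) {
    t_n <- rep(FALSE, nres)
    rng <- seq_len(nres - n)
    t_n[rng] <- hb[cbind(rng, rng + n)] & same_chain[cbind(rng, rng + n)]
    turn[[as.character(n)]] <- t_n
  }

  helix_flag <- function(n) {
    t_n <- turn[[as.character(n)]]
    fl <- rep(FALSE, nres)
    for (i in 2:max(1, nres - n)) {
      if (t_n[i] && t_n[i - 1]) fl[i:(i + n - 1)] <- TRUE
    }
    fl
  }
  is_H <- helix_flag(4)
  is_G <- helix_flag(3)
  is_I <- helix_flag(5)

  # bridges
  brP <- matrix(FALSE, nres, nres)
  brA <- matrix(FALSE, nres, nres)
  if (nres >= 5) {
    for (i in 2:(nres - 1)) {
      if (!has_bb[i]) next
      js <- which(ok[i, ] | ok[, i])
      js <- js[js > i + 2 & js > 1 & js < nres]
      for (j in js) {
        if (!has_bb[j]) next
        p <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
        a <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
        if (p) { brP[i, j] <- TRUE; brP[j, i] <- TRUE }
        if (a) { brA[i, j] <- TRUE; brA[j, i] <- TRUE }
      }
    }
  }
  bridge <- brP | brA
  in_bridge <- rowSums(bridge) > 0
  # ladder: this bridge extends a neighbouring one -> strand E
  is_E <- rep(FALSE, nres)
  for (i in which(in_bridge)) {
    for (j in which(bridge[i, ])) {
      ext <- FALSE
      for (di in c(-1L, 1L)) for (dj in c(-1L, 1L)) {
        i2 <- i + di; j2 <- j + dj
        if (i2 >= 1 && i2 <= nres && j2 >= 1 && j2 <= nres &&
              bridge[i2, j2]) ext <- TRUE
      }
      if (ext) { is_E[i] <- TRUE; is_E[j] <- TRUE }
    }
  }
  is_B <- in_bridge & !is_E
  sense[in_bridge] <- ifelse(rowSums(brA)[in_bridge] > 0, "A", "P")

  # turns not already structure
  is_T <- rep(FALSE, nres)
  for (n in 3:5) {
    t_n <- turn[[as.character(n)]]
    for (i in which(t_n)) {
      span <- (i + 1):(i + n - 1)
      is_T[span[span <= nres]] <- TRUE
    }
  }

  # bend: Calpha direction change > 70 degrees
  is_S <- rep(FALSE, nres)
  if (nres >= 5) {
    for (i in 3:(nres - 2)) {
      if (!all(has_bb[(i - 2):(i + 2)])) next
      if (!(same_chain[i - 2, i] && same_chain[i, i + 2])) next
      u <- CAx[i, ] - CAx[i - 2, ]
      v <- CAx[i + 2, ] - CAx[i, ]
      ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      if (acos(min(1, max(-1, ct))) * 180 / pi > 70) is_S[i] <- TRUE
    }
  }

  labels[is_S] <- "S"
  labels[is_T] <- "T"
  labels[is_I] <- "I"
  labels[is_G] <- "G"
  labels[is_E] <- "E"
  labels[is_B] <- "B"
  labels[is_H] <- "H"
  labels[!has_bb] <- "C"
  structure(labels, bridge_sense = sense)
}

#' Secondary-structure timeline over a trajectory
#'
#' Assigns every sampled frame and returns the frames x residues label
#' matrix plus per-residue label frequencies.  The analysis stride defaults
#' to sampling every frame; with 10 ps frames a stride of 1 reproduces the
#' usual every-10-ps sampling.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param top a \code{\link{topology}}.
#' @param stride sample every \code{stride}-th frame (>= 1).
#' @param fold_pi fold pi-helix (I) into H for reporting (default TRUE).
#' @return object of class \code{"ss_assignment"}: \code{labels} (frames x
#'   residues), \code{frames}, \code{time_ps}, \code{res_index},
#'   \code{frequencies} (residues x labels, rows sum to 1).
#' @export
ss_timeline <- function(traj, top, stride = 1L, fold_pi = TRUE) {
  if (stride < 1) stop("stride must be >= 1")
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  if (length(frames) == 0L) stop("empty stride window")
  lab <- NULL
  for (k in seq_along(frames)) {
    l <- assign_secondary_structure(get_frame(traj, frames[k]), top)
    if (is.null(lab)) lab <- matrix("", length(frames), length(l),
                                    dimnames = list(NULL, names(l)))
    lab[k, ] <- l
  }
  rep_lab <- lab
  if (fold_pi) rep_lab[rep_lab == "I"] <- "H"
  lvls <- c("H", "G", "I", "E", "B", "T", "S", "C")
  freq <- t(apply(rep_lab, 2, function(col)
    table(factor(col, levels = lvls)) / length(col)))
  structure(list(labels = lab, frames = frames,
                 time_ps = (frames - 1) * traj$time_step_ps,
                 res_index = colnames(lab), frequencies = freq),
            class = "ss_assignment")
}

#' Write a secondary-structure timeline as TSV
#'
#' Long format (frame, time_ps, residue, label) plus a compact run-length
#' encoded sidecar (residue, label, start_frame, run_length).
#'
#' @param ss an \code{ss_assignment}.
#' @param path output TSV; the RLE sidecar gets suffix ".rle.tsv".
#' @export
write_ss_timeline <- function(ss, path) {
  long <- data.frame(frame = rep(ss$frames, times = ncol(ss$labels)),
                     time_ps = rep(ss$time_ps, times = ncol(ss$labels)),
                     residue = rep(colnames(ss$labels), each = nrow(ss$labels)),
                     label = as.vector(ss$labels))
  write_tsv_table(long, path, "secondary-structure timeline")
  rle_rows <- do.call(rbind, lapply(seq_len(ncol(ss$labels)), function(j) {
    r <- rle(ss$labels[, j])
    data.frame(residue = colnames(ss$labels)[j], label = r$values,
               start_frame = ss$frames[c(1, head(cumsum(r$lengths), -1) + 1)],
               run_length = r$lengths)
  }))
  write_tsv_table(rle_rows, paste0(path, ".rle.tsv"),
                  "run-length encoded timeline")
  invisible(path)
}
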