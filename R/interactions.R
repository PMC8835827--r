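#' @keywords internal
#' Map each hydrogen to its bound heavy atom (nearest heavy atom < 1.25 A)
attach_hydrogens <- function(frame, top) {
  h_idx <- which(top$element == "H")
  heavy <- which(top$element != "H")
  if (length(h_idx) == 0L)
    return(data.frame(h = integer(0), heavy = integer(0)))
  d <- pdist2(frame[h_idx, , drop = FALSE], frame[heavy, , drop = FALSE])
  nearest <- apply(d, 1, which.min)
  dist <- d[cbind(seq_along(h_idx), nearest)]
  keep <- dist < 1.25
  data.frame(h = h_idx[keep], heavy = heavy[nearest[keep]])
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: donor and acceptor are N, O or S atoms;
#' d(D-A) <= 3.6 Angstrom and the D-H...A angle >= 120 degrees.  Every
#' (D, H, A) triple satisfying both is reported, so a bifurcated hydrogen
#' (one H, two acceptors) yields separate events.  Backbone amide hydrogens
#' are reconstructed when the frame carries no explicit hydrogens.
#' Intra-residue donor/acceptor pairs are excluded.  Candidate pairs are
#' pruned with a 4-Angstrom spatial grid; the result is identical to an
#' exhaustive all-pairs scan.
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}}.
#' @param dist_cutoff donor-acceptor distance bound, Angstrom (default 3.6).
#' @param angle_cutoff D-H...A angle bound, degrees (default 120).
#' @return data.frame (donor, hydrogen, acceptor, donor_res, acceptor_res,
#'   distance, angle, sidechain) -- one row per event; \code{hydrogen} is NA
#'   for reconstructed H (virtual index), with its coordinates used for the
#'   angle.
#' @export
detect_hbonds <- function(frame, top, dist_cutoff = 3.6, angle_cutoff = 120) {
  polar <- which(top$element %in% c("N", "O", "S"))
  if (length(polar) == 0L)
    return(hbond_empty())
  hpairs <- attach_hydrogens(frame, top)
  # donors: polar atoms carrying >=1 hydrogen; plus backbone N with
  # reconstructed amide H when no explicit H exists on it
  don_list <- list()
  for (k in seq_len(nrow(hpairs))) {
    if (top$element[hpairs$heavy[k]] %in% c("N", "O", "S"))
      don_list[[length(don_list) + 1L]] <-
        list(d = hpairs$heavy[k], h = hpairs$h[k], hxyz = frame[hpairs$h[k], ])
  }
  expl_don <- unique(vapply(don_list, function(x) x$d, 0L))
  Hrec <- reconstruct_amide_h(frame, top)
  bb <- backbone_table(frame, top)
  for (k in seq_len(nrow(bb$res))) {
    ni <- bb$idx$N[k]
    if (is.na(ni) || ni %in% expl_don || is.na(Hrec[k, 1])) next
    don_list[[length(don_list) + 1L]] <-
      list(d = ni, h = NA_integer_, hxyz = Hrec[k, ])
  }
  if (length(don_list) == 0L) return(hbond_empty())
  dons <- vapply(don_list, function(x) x$d, 0L)
  hyds <- vapply(don_list, function(x) x$h, 0L)
  Hmat <- do.call(rbind, lapply(don_list, function(x) x$hxyz))
  acc <- polar
  # grid pruning on donor/acceptor positions
  cand <- grid_pairs(frame[dons, , drop = FALSE], frame[acc, , drop = FALSE],
                     dist_cutoff)
  if (nrow(cand) == 0L) return(hbond_empty())
  di <- dons[cand[, 1]]; ai <- acc[cand[, 2]]
  keep <- di != ai &
    !(top$res_index[di] == top$res_index[ai] & top$chain[di] == top$chain[ai])
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(hbond_empty())
  di <- dons[cand[, 1]]; ai <- acc[cand[, 2]]
  dv <- frame[ai, , drop = FALSE] - frame[di, , drop = FALSE]
  dist <- sqrt(rowSums(dv^2))
  U <- frame[di, , drop = FALSE] - Hmat[cand[, 1], , drop = FALSE]
  V <- frame[ai, , drop = FALSE] - Hmat[cand[, 1], , drop = FALSE]
  ct <- rowSums(U * V) / sqrt(rowSums(U^2) * rowSums(V^2))
  ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  keep <- dist <= dist_cutoff & ang >= angle_cutoff
  if (!any(keep)) return(hbond_empty())
  res <- data.frame(donor = di[keep], hydrogen = hyds[cand[keep, 1]],
                    acceptor = ai[keep],
                    donor_res = top$res_index[di[keep]],
                    acceptor_res = top$res_index[ai[keep]],
                    distance = dist[keep], angle = ang[keep],
                    sidechain = !is_backbone_atom(top$atom_name[di[keep]]) |
                      !is_backbone_atom(top$atom_name[ai[keep]]))
  rownames(res) <- NULL
  res
}

hbond_empty <- function()
  data.frame(donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
             donor_res = integer(0), acceptor_res = integer(0),
             distance = numeric(0), angle = numeric(0), sidechain = logical(0))

is_backbone_atom <- function(an)
  an %in% c("N", "CA", "C", "O", "OXT", "H", "HA", "HA2", "HA3")

# grid-based candidate pair pruning: all (i, j) with |A_i - B_j| <= cutoff;
# exact (the 27-cell neighbourhood covers every pair within one cell width)
grid_pairs <- function(A, B, cutoff) {
  cell <- cutoff
  ka <- floor(A / cell); kb <- floor(B / cell)
  lookup <- split(seq_len(nrow(B)), paste(kb[, 1], kb[, 2], kb[, 3]))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  hits <- vector("list", 27L)
  for (o in seq_len(27L)) {
    keys <- paste(ka[, 1] + offs[o, 1], ka[, 2] + offs[o, 2],
                  ka[, 3] + offs[o, 3])
    js <- lookup[keys]
    len <- lengths(js)
    hits[[o]] <- cbind(rep.int(seq_len(nrow(A)), len), unlist(js, use.names = FALSE))
  }
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0L) return(matrix(integer(0), 0, 2))
  keep <- rowSums((A[out[, 1], , drop = FALSE] -
                     B[out[, 2], , drop = FALSE])^2) <= (cutoff + 1e-9)^2
  out[keep, , drop = FALSE]
}

#' Hydrophobic residue names used for contact detection
#' @export
hydrophobic_residues <- function()
  c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

#' Detect hydrophobic side-chain contacts in one frame
#'
#' Two hydrophobic residues are in contact when any pair of side-chain
#' heavy atoms lies within the cutoff (default 4 Angstrom, minimum
#' heavy-atom distance; hydrogens never enter the distance test).
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param top a \code{\link{topology}}.
#' @param cutoff distance bound in Angstrom (default 4).
#' @param residue_set hydrophobic residue names (default
#'   \code{\link{hydrophobic_residues}}).
#' @return data.frame (res_i, res_j, min_distance) with res_i < res_j.
#' @export
detect_hydrophobic_contacts <- function(frame, top, cutoff = 4,
                                        residue_set = hydrophobic_residues()) {
  sc <- which(top$res_name %in% residue_set &
                top$element != "H" &
                !is_backbone_atom(top$atom_name))
  if (length(sc) < 2L)
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      min_distance = numeric(0)))
  cand <- grid_pairs(frame[sc, , drop = FALSE], frame[sc, , drop = FALSE],
                     cutoff)
  if (nrow(cand) == 0L)
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      min_distance = numeric(0)))
  ai <- sc[cand[, 1]]; aj <- sc[cand[, 2]]
  ri <- top$res_index[ai]; rj <- top$res_index[aj]
  keep <- ri < rj
  if (!any(keep))
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      min_distance = numeric(0)))
  d <- sqrt(rowSums((frame[ai[keep], , drop = FALSE] -
                       frame[aj[keep], , drop = FALSE])^2))
  df <- data.frame(res_i = ri[keep], res_j = rj[keep], d = d)
  df <- df[df$d <= cutoff, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      min_distance = numeric(0)))
  agg <- stats::aggregate(d ~ res_i + res_j, data = df, FUN = min)
  names(agg)[3] <- "min_distance"
  agg <- agg[order(agg$res_i, agg$res_j), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Residue-pair occurrence pattern over a trajectory
#'
#' Fraction of sampled frames in which each residue pair forms at least one
#' event (H-bond or hydrophobic contact).  Pairs are keyed symmetrically;
#' for H-bonds the constituent atom pairs and whether any event was
#' side-chain-mediated are recorded, and bonds formed by a chain-terminal
#' residue are flagged as potential construct-terminus artefacts (flagged,
#' never removed).
#'
#' @param traj a \code{\link{trajectory}}.
#' @param top a \code{\link{topology}}.
#' @param stride sample every stride-th frame.
#' @param type "hbond" or "hydrophobic".
#' @param domains optional \code{\link{domain_map}} used to tag each pair
#'   inter- or intra-domain.
#' @param ... passed to the per-frame detector.
#' @return object of class \code{"contact_pattern"}: data.frame (res_i,
#'   res_j, occurrence, n_frames, sidechain, terminal_flag, domain_i,
#'   domain_j, tag) plus attrs \code{frames_sampled}, \code{type}.
#' @export
occurrence_pattern <- function(traj, top, stride = 1L, type = c("hbond", "hydrophobic"),
                               domains = NULL, ...) {
  type <- match.arg(type)
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  if (length(frames) == 0L) stop("no frames sampled")
  all_keys <- vector("list", length(frames))
  sc_keys <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- get_frame(traj, frames[k])
    if (type == "hbond") {
      ev <- detect_hbonds(fr, top, ...)
      if (nrow(ev) == 0) next
      key <- paste(pmin(ev$donor_res, ev$acceptor_res),
                   pmax(ev$donor_res, ev$acceptor_res))
      all_keys[[k]] <- unique(key)
      sc_keys[[k]] <- unique(key[ev$sidechain])
    } else {
      ev <- detect_hydrophobic_contacts(fr, top, ...)
      if (nrow(ev) == 0) next
      all_keys[[k]] <- paste(ev$res_i, ev$res_j)
      sc_keys[[k]] <- all_keys[[k]]
    }
  }
  tab <- table(unlist(all_keys))
  keys <- names(tab)
  sc_set <- unique(unlist(sc_keys))
  if (length(keys) == 0L) {
    pat <- data.frame(res_i = integer(0), res_j = integer(0),
                      occurrence = numeric(0), n_frames = integer(0),
                      sidechain = logical(0), terminal_flag = logical(0),
                      domain_i = character(0), domain_j = character(0),
                      tag = character(0))
  } else {
    ij <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
    n <- as.integer(tab)
    sc <- keys %in% sc_set
    term <- range(top$res_index)
    pat <- data.frame(res_i = ij[, 1], res_j = ij[, 2],
                      occurrence = as.numeric(n) / length(frames),
                      n_frames = n, sidechain = sc,
                      terminal_flag = ij[, 1] %in% term | ij[, 2] %in% term)
    if (!is.null(domains)) {
      lab <- function(res) {
        for (nm in names(domains$domains))
          if (res %in% range_residues(domains$domains[[nm]])) return(nm)
        NA_character_
      }
      pat$domain_i <- vapply(pat$res_i, lab, "")
      pat$domain_j <- vapply(pat$res_j, lab, "")
      pat$tag <- ifelse(!is.na(pat$domain_i) & !is.na(pat$domain_j) &
                          pat$domain_i == pat$domain_j, "intra", "inter")
    } else {
      pat$domain_i <- NA_character_; pat$domain_j <- NA_character_
      pat$tag <- NA_character_
    }
    pat <- pat[order(pat$res_i, pat$res_j), , drop = FALSE]
    rownames(pat) <- NULL
  }
  structure(pat, frames_sampled = length(frames), type = type,
            class = c("contact_pattern", "data.frame"))
}

#' Exclude regular-structure and intra-domain framework H-bonds
#'
#' Reproduces the pattern-cleaning step applied before interpreting the
#' inter-domain H-bond network: backbone-backbone bonds between residues
#' co-assigned to the same helix (sequence separation <= 5, both helical by
#' modal label) or to the same beta-ladder (both strand by modal label) are
#' removed, as are backbone-backbone pairs lying wholly inside a single
#' domain; side-chain-mediated and inter-domain bonds are retained.  The
#' same-helix / same-ladder reading of "regular structures" and the
#' same-domain backbone rule for the "intra-domain framework" are this
#' package's interpretation of a qualitative published procedure.
#'
#' @param pattern a \code{contact_pattern} from
#'   \code{\link{occurrence_pattern}} (type "hbond").
#' @param ss an \code{ss_assignment} covering the pattern's frames.
#' @param domains a \code{\link{domain_map}}.
#' @return filtered \code{contact_pattern} (always a subset of the input).
#' @export
exclude_regular_structure <- function(pattern, ss, domains) {
  if (nrow(pattern) == 0L) return(pattern)
  modal <- apply(ss$labels, 2, function(col)
    names(sort(table(col), decreasing = TRUE))[1])
  res_of <- as.integer(sub(".*:", "", colnames(ss$labels)))
  lab_of <- function(res) {
    k <- match(res, res_of)
    ifelse(is.na(k), "C", modal[k])
  }
  helical <- function(l) l %in% c("H", "G", "I")
  strand <- function(l) l %in% c("E", "B")
  li <- lab_of(pattern$res_i); lj <- lab_of(pattern$res_j)
  sep <- abs(pattern$res_j - pattern$res_i)
  same_dom <- !is.na(pattern$tag) & pattern$tag == "intra"
  bb <- !pattern$sidechain
  drop <- bb & ((helical(li) & helical(lj) & sep <= 5) |
                  (strand(li) & strand(lj)) |
                  same_dom)
  out <- pattern[!drop, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, frames_sampled = attr(pattern, "frames_sampled"),
            type = attr(pattern, "type"),
            class = class(pattern))
}

#' Write a contact pattern as TSV (plus chord-diagram input)
#'
#' @param pattern a \code{contact_pattern}.
#' @param path output TSV; a domain-level chord file (domain_i, domain_j,
#'   weight = summed occurrence) gets suffix ".chord.tsv".
#' @export
write_contact_pattern <- function(pattern, path) {
  df <- as.data.frame(pattern)
  df$occurrence_pct <- 100 * df$occurrence
  write_tsv_table(df, path, paste0(attr(pattern, "type"),
                                   " occurrence pattern"))
  if (!all(is.na(df$domain_i))) {
    ch <- stats::aggregate(occurrence ~ domain_i + domain_j, data = df, FUN = sum)
    names(ch)[3] <- "weight"
    write_tsv_table(ch, paste0(path, ".chord.tsv"), "chord-diagram input")
  }
  invisible(path)
}
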